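# Shared helpers: small hand-built tables and independent oracles.

# Minimal differential table with the differential_analysis shape.
make_diff <- function(protein_id, log2_fold, p_value,
                      status = "quantified", tissue = NULL, age = NULL) {
  d <- data.frame(protein_id = protein_id, log2_fold = log2_fold,
                  p_value = p_value, status = status,
                  stringsAsFactors = FALSE)
  attr(d, "tissue") <- tissue
  attr(d, "age_months") <- age
  d
}

# Altered-set fixture: the named recapitulated proteins plus disjoint filler,
# so the intersection is exactly the named set.
make_altered_set <- function(shared, extra, stratum) {
  ids <- c(shared, extra)
  s <- data.frame(protein_id = ids,
                  log2_fold = rep(6, length(ids)),
                  p_value = rep(0.001, length(ids)),
                  stringsAsFactors = FALSE)
  attr(s, "stratum") <- stratum
  s
}

# Independent multinomial log-likelihood-ratio oracle for the G-test:
# 2 * [log L(saturated) - log L(totals-proportional null)] via dmultinom.
g_oracle <- function(c_A, c_B, T_A, T_B) {
  x <- c(c_A, c_B)
  n <- sum(x)
  p0 <- c(T_A, T_B) / (T_A + T_B)
  p_hat <- x / n
  2 * (stats::dmultinom(x, prob = p_hat, log = TRUE) -
         stats::dmultinom(x, prob = p0, log = TRUE))
}

# Brute-force hypergeometric upper tail by enumeration.
hyper_oracle <- function(overlap, set_size, n_sig, universe) {
  k <- overlap:min(set_size, n_sig)
  sum(choose(n_sig, k) * choose(universe - n_sig, set_size - k)) /
    choose(universe, set_size)
}

# Mann-Whitney pair-counting AUC oracle (ties count one half).
auc_oracle <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Small PSM experiment with exactly known counts: one stratum, one replicate
# per genotype, counts supplied directly.
make_psm <- function(counts_wt, counts_tg, tissue = "plasma_EV", age = 3L) {
  counts <- cbind(WT_r1 = counts_wt, TG_r1 = counts_tg)
  rownames(counts) <- sprintf("P%02d", seq_along(counts_wt))
  meta <- data.frame(
    sample_id = c("WT_r1", "TG_r1"), tissue = tissue, age_months = age,
    genotype = c("WT", "5xFAD"), replicate_id = 1L,
    stringsAsFactors = FALSE
  )
  psm_experiment(counts, meta)
}
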