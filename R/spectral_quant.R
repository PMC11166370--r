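# Spectral-count quantification: cumulative and normalized PSM indices,
# log2 fold changes with a pseudocount, and the G-test (multinomial
# likelihood-ratio test) for WT vs 5xFAD contrasts within a tissue x age
# stratum. Technical replicates are pooled by summation ("cumulative PSM"),
# so no replicate-level variance model is fitted; the G-test treats the
# pooled counts as a two-cell goodness-of-fit problem against expectations
# proportional to the group totals.

#' PSM count experiment container
#'
#' A matrix of non-negative integer PSM counts (proteins in rows, samples in
#' columns) with per-sample metadata.
#'
#' @param counts Integer matrix, rownames = protein ids, colnames = sample ids.
#' @param meta data.frame with columns `sample_id`, `tissue`
#'   (hippocampus/cortex/plasma_EV), `age_months` (3 or 6), `genotype`
#'   (WT/5xFAD), `replicate_id`; one row per column of `counts`.
#'
#' @return An object of class `psm_experiment`.
#' @export
psm_experiment <- function(counts, meta) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop("counts must carry unique protein ids as rownames")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  req <- c("sample_id", "tissue", "age_months", "genotype", "replicate_id")
  missing_cols <- setdiff(req, names(meta))
  if (length(missing_cols))
    stop("meta is missing columns: ", paste(missing_cols, collapse = ", "))
  if (anyNA(meta[req])) stop("sample metadata must be complete")
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (!setequal(colnames(counts), meta$sample_id) ||
      anyDuplicated(meta$sample_id))
    stop("meta$sample_id must match the count matrix columns one-to-one")
  meta <- meta[match(colnames(counts), meta$sample_id), req]
  rownames(meta) <- NULL
  bad <- setdiff(unique(meta$tissue), c("hippocampus", "cortex", "plasma_EV"))
  if (length(bad)) stop("unknown tissue: ", paste(bad, collapse = ", "))
  if (!all(meta$age_months %in% c(3L, 6L)))
    stop("age_months must be 3 or 6")
  if (!all(meta$genotype %in% c("WT", "5xFAD")))
    stop("genotype must be WT or 5xFAD")
  if (any(colSums(counts) == 0))
    stop("every sample must have a positive total PSM count")
  structure(list(counts = counts, meta = meta), class = "psm_experiment")
}

#' @export
print.psm_experiment <- function(x, ...) {
  cat(sprintf("psm_experiment: %d proteins x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  print(table(tissue = x$meta$tissue, age = x$meta$age_months,
              genotype = x$meta$genotype))
  invisible(x)
}

#' Select sample ids by metadata
#'
#' @param x A [psm_experiment()].
#' @param tissue,age_months,genotype Optional filters; `NULL` means "any".
#' @return Character vector of matching sample ids (may be empty).
#' @export
select_samples <- function(x, tissue = NULL, age_months = NULL, genotype = NULL) {
  keep <- rep(TRUE, nrow(x$meta))
  if (!is.null(tissue)) keep <- keep & x$meta$tissue %in% tissue
  if (!is.null(age_months)) keep <- keep & x$meta$age_months %in% age_months
  if (!is.null(genotype)) keep <- keep & x$meta$genotype %in% genotype
  x$meta$sample_id[keep]
}

#' Cumulative PSM counts over a sample group
#'
#' Sums counts over the selected samples per protein (the cumulative PSM index
#' across technical replicates) and returns the group total.
#'
#' @param x A [psm_experiment()].
#' @param sample_ids Character vector of sample ids to pool.
#' @return List with `c` (named integer vector, per-protein cumulative count)
#'   and `total` (sum over all proteins).
#' @export
accumulate_psm <- function(x, sample_ids) {
  if (length(sample_ids) == 0L)
    stop("sample selector matched no samples")
  missing_ids <- setdiff(sample_ids, colnames(x$counts))
  if (length(missing_ids))
    stop("unknown sample ids: ", paste(missing_ids, collapse = ", "))
  cc <- rowSums(x$counts[, sample_ids, drop = FALSE])
  list(c = cc, total = sum(cc))
}

#' Normalized PSM index
#'
#' Scales a cumulative PSM count to counts per `scale` total PSMs:
#' `scale * c / total` (default per 10^4 PSMs).
#'
#' @param c Cumulative PSM count(s), non-negative.
#' @param total Group total PSM count, strictly positive.
#' @param scale Normalization scale (default `1e4`).
#' @return Numeric normalized index, same length as `c`.
#' @export
normalize_psm_index <- function(c, total, scale = 1e4) {
  if (any(total <= 0)) stop("group total must be strictly positive")
  if (scale <= 0) stop("scale must be positive")
  scale * c / total
}

#' G-test for a two-group spectral-count contrast
#'
#' Likelihood-ratio (G) test of whether a protein's counts split between two
#' groups in proportion to the group totals:
#' `G = 2 * sum_j c_j * ln(c_j / e_j)` with
#' `e_j = (c_A + c_B) * T_j / (T_A + T_B)` and the convention `0 * ln 0 = 0`.
#' p-values come from the upper tail of the chi-square distribution with one
#' degree of freedom. All arguments recycle; the function is vectorized.
#'
#' @param c_A,c_B Per-group cumulative counts (non-negative integers,
#'   `c_A + c_B > 0`).
#' @param T_A,T_B Group total counts (positive, `c_j <= T_j`).
#' @param correct `"none"` (default) or `"williams"` for the Williams
#'   small-sample correction `G / (1 + 1/(2(c_A + c_B)))`.
#' @return data.frame with columns `G` and `p_value`.
#' @export
g_test <- function(c_A, c_B, T_A, T_B, correct = c("none", "williams")) {
  correct <- match.arg(correct)
  n <- max(length(c_A), length(c_B), length(T_A), length(T_B))
  c_A <- rep_len(c_A, n); c_B <- rep_len(c_B, n)
  T_A <- rep_len(T_A, n); T_B <- rep_len(T_B, n)
  if (any(c_A < 0 | c_B < 0)) stop("counts must be non-negative")
  if (any(T_A <= 0 | T_B <= 0)) stop("group totals must be positive")
  if (any(c_A > T_A | c_B > T_B)) stop("a count exceeds its group total")
  if (any(c_A + c_B == 0))
    stop("c_A + c_B = 0 is undefined; mark such proteins ND instead")
  tot <- c_A + c_B
  e_A <- tot * T_A / (T_A + T_B)
  e_B <- tot * T_B / (T_A + T_B)
  term <- function(o, e) ifelse(o == 0, 0, o * log(o / e))
  G <- 2 * (term(c_A, e_A) + term(c_B, e_B))
  G <- pmax(G, 0)  # guard tiny negative rounding at c == e
  if (correct == "williams") G <- G / (1 + 1 / (2 * tot))
  data.frame(G = G, p_value = stats::pchisq(G, df = 1, lower.tail = FALSE))
}

#' Differential abundance within one tissue-by-age stratum
#'
#' For every protein: pools technical replicates per genotype (cumulative PSM),
#' normalizes to indices per `scale` PSMs, computes
#' `log2_fold = log2((i_5xFAD + pseudocount) / (i_WT + pseudocount))` and the
#' G-test on the raw cumulative counts. Proteins undetected in both genotypes
#' get `status = "ND"` and no statistics. The pseudocount enters only the
#' fold-change ratio, never the test, so proteins detected in a single group
#' still receive finite fold changes alongside an exact-count test.
#'
#' @param x A [psm_experiment()].
#' @param tissue,age_months The stratum; must contain both genotypes.
#' @param pseudocount Pseudocount in normalized-index units (default 0.5).
#' @param scale Normalization scale (default 1e4).
#' @param correct G-test correction, see [g_test()].
#' @return data.frame (one row per protein) with columns `protein_id`, `c_WT`,
#'   `c_5xFAD`, `T_WT`, `T_5xFAD`, `i_WT`, `i_5xFAD`, `log2_fold`, `G`,
#'   `p_value`, `status`; rows ordered by p ascending, then |log2_fold|
#'   descending, then protein id; ND rows last. The stratum is attached as
#'   attributes `tissue` and `age_months`.
#' @export
differential_analysis <- function(x, tissue, age_months, pseudocount = 0.5,
                                  scale = 1e4, correct = "none") {
  if (pseudocount <= 0) stop("pseudocount must be positive")
  ids_wt <- select_samples(x, tissue, age_months, "WT")
  ids_tg <- select_samples(x, tissue, age_months, "5xFAD")
  if (length(ids_wt) == 0L || length(ids_tg) == 0L)
    stop(sprintf("stratum %s/%sm lacks genotype %s", tissue, age_months,
                 if (length(ids_wt) == 0L) "WT" else "5xFAD"))
  A <- accumulate_psm(x, ids_wt)   # group A = WT
  B <- accumulate_psm(x, ids_tg)   # group B = 5xFAD

  i_A <- normalize_psm_index(A$c, A$total, scale)
  i_B <- normalize_psm_index(B$c, B$total, scale)
  nd <- A$c == 0 & B$c == 0

  res <- data.frame(
    protein_id = rownames(x$counts),
    c_WT = unname(A$c), c_5xFAD = unname(B$c),
    T_WT = A$total, T_5xFAD = B$total,
    i_WT = unname(i_A), i_5xFAD = unname(i_B),
    log2_fold = log2((i_B + pseudocount) / (i_A + pseudocount)),
    G = NA_real_, p_value = NA_real_,
    status = ifelse(nd, "ND", "quantified"),
    stringsAsFactors = FALSE
  )
  res$log2_fold[nd] <- NA_real_
  if (any(!nd)) {
    gt <- g_test(A$c[!nd], B$c[!nd], A$total, B$total, correct = correct)
    res$G[!nd] <- gt$G
    res$p_value[!nd] <- gt$p_value
  }
  ord <- order(res$p_value, -abs(res$log2_fold), res$protein_id,
               na.last = TRUE)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "tissue") <- tissue
  attr(res, "age_months") <- age_months
  res
}

#' Filter differential records on significance and fold change
#'
#' Retains quantified records with `p_value < p_max` (strict) and
#' `|log2_fold| >= lfc_min` (inclusive), optionally restricted to one sign.
#' Input order is preserved; ND records are always dropped.
#'
#' @param records Output of [differential_analysis()].
#' @param p_max Strict p-value ceiling (default 0.05).
#' @param lfc_min Inclusive minimum |log2 fold| (default 0).
#' @param direction `"any"`, `"up"` (log2_fold > 0) or `"down"`.
#' @return The filtered subset (possibly empty), attributes preserved.
#' @export
filter_significant <- function(records, p_max = 0.05, lfc_min = 0,
                               direction = c("any", "up", "down")) {
  direction <- match.arg(direction)
  if (lfc_min < 0) stop("lfc_min must be non-negative")
  keep <- records$status == "quantified" &
    !is.na(records$p_value) & records$p_value < p_max &
    abs(records$log2_fold) >= lfc_min
  if (direction == "up") keep <- keep & records$log2_fold > 0
  if (direction == "down") keep <- keep & records$log2_fold < 0
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "tissue") <- attr(records, "tissue")
  attr(out, "age_months") <- attr(records, "age_months")
  out
}

#' Read / write PSM count tables
#'
#' Tab-separated interchange: the count table has proteins in rows (first
#' column `protein_id`), samples in columns; the metadata sidecar has columns
#' `sample_id`, `tissue`, `age_months`, `genotype`, `replicate_id`.
#'
#' @param counts_path,meta_path File paths.
#' @return [psm_experiment()] for the reader; invisible paths for the writer.
#' @export
read_psm_counts <- function(counts_path, meta_path) {
  tab <- utils::read.delim(counts_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- tab[[1]]
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  psm_experiment(counts, meta)
}

#' @rdname read_psm_counts
#' @param x A [psm_experiment()] to write.
#' @export
write_psm_counts <- function(x, counts_path, meta_path) {
  tab <- data.frame(protein_id = rownames(x$counts), x$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(counts = counts_path, meta = meta_path))
}

#' Write a differential table as TSV
#'
#' @param records Output of [differential_analysis()].
#' @param path Output file.
#' @export
write_differential <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
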