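# Directional pathway activation scoring on user-supplied gene sets.
# Each pathway carries an expected direction (+1/-1) per member; the
# activation z-score is the directional consistency of the significant
# members' fold-change signs, (sum of sign agreements)/sqrt(N), and a call
# additionally requires hypergeometric enrichment of the pathway in the
# significant set (-log10 p > logp_cut, i.e. 1.3 <=> p < 0.05).

#' Construct a directional pathway definition
#'
#' @param name Pathway name.
#' @param members Character vector of protein ids (>= 2).
#' @param directions Integer vector in {-1, +1}, one per member: the
#'   fold-change sign consistent with pathway activation.
#' @return A `pathway_def` list.
#' @export
pathway_def <- function(name, members, directions) {
  if (length(members) < 2L) stop("a pathway needs >= 2 members")
  if (length(directions) != length(members))
    stop("directions must be defined for every member")
  if (!all(directions %in% c(-1L, 1L)))
    stop("directions must be +1 or -1")
  if (anyDuplicated(members)) stop("pathway members must be unique")
  list(name = name, members = as.character(members),
       directions = as.integer(directions))
}

#' Hypergeometric enrichment p-value
#'
#' Upper-tail probability `P(X >= overlap)` for
#' `X ~ Hypergeom(universe, n_sig, set_size)`: the chance that a random set of
#' `set_size` proteins drawn from a universe containing `n_sig` significant
#' ones overlaps the significant set at least as much as observed (one-sided
#' Fisher exact test).
#'
#' @param overlap Observed number of significant pathway members.
#' @param set_size Number of pathway members in the universe.
#' @param n_sig Number of significant proteins in the universe.
#' @param universe Number of quantified proteins.
#' @return p-value in \[0, 1\].
#' @export
enrichment_p <- function(overlap, set_size, n_sig, universe) {
  if (any(c(overlap, set_size, n_sig, universe) < 0))
    stop("all counts must be non-negative")
  if (set_size > universe || n_sig > universe)
    stop("set_size and n_sig must not exceed the universe")
  if (overlap > min(set_size, n_sig))
    stop("overlap exceeds min(set_size, n_sig)")
  stats::phyper(overlap - 1, n_sig, universe - n_sig, set_size,
                lower.tail = FALSE)
}

#' Directional activation z-score of a pathway
#'
#' Over pathway members with a quantified differential record at
#' `p_value < p_max`, each contributes
#' `s_k = sign(log2_fold_k) * expected_direction_k`; the score is
#' `z = sum(s_k) / sqrt(N)`. `N = 0` yields `z = NA` (no call possible).
#'
#' @param diff A [differential_analysis()] table.
#' @param pathway A [pathway_def()].
#' @param p_max Significance ceiling for member inclusion (default 0.05).
#' @return List with `N` (overlap size) and `z`.
#' @export
activation_z <- function(diff, pathway, p_max = 0.05) {
  idx <- match(pathway$members, diff$protein_id)
  present <- !is.na(idx)
  rec_p <- diff$p_value[idx[present]]
  rec_lfc <- diff$log2_fold[idx[present]]
  sig <- !is.na(rec_p) & rec_p < p_max
  s <- sign(rec_lfc[sig]) * pathway$directions[present][sig]
  N <- length(s)
  list(N = N, z = if (N == 0L) NA_real_ else sum(s) / sqrt(N))
}

#' Classify a pathway activation call
#'
#' `activated` if `z >= z_cut` and `-log10(p) > logp_cut`; `deactivated` if
#' `z <= -z_cut` under the same enrichment condition; otherwise `no_call`.
#' Defaults are the activation criteria z cut-off 0.5 and -log10 p > 1.3.
#'
#' @param z Activation z-score (`NA` forces `no_call`).
#' @param p Enrichment p-value.
#' @param z_cut,logp_cut Call thresholds.
#' @return One of `"activated"`, `"deactivated"`, `"no_call"`.
#' @export
classify_pathway <- function(z, p, z_cut = 0.5, logp_cut = 1.3) {
  if (is.na(z) || is.na(p)) return("no_call")
  enriched <- -log10(p) > logp_cut
  if (enriched && z >= z_cut) return("activated")
  if (enriched && z <= -z_cut) return("deactivated")
  "no_call"
}

#' Score all pathways against one or more differential tables
#'
#' For each stratum and pathway: overlap N and z via [activation_z()],
#' enrichment via [enrichment_p()] (universe = quantified proteins in that
#' stratum, significant = quantified with `p < p_max`; set size counts only
#' members present in the universe), and the call label.
#'
#' @param diff_tables Named list of differential tables (names = strata).
#' @param pathways List of [pathway_def()]s.
#' @param p_max Member-level significance ceiling.
#' @param z_cut,logp_cut Call thresholds, see [classify_pathway()].
#' @return data.frame: `pathway`, `stratum`, `N`, `z`, `enrichment_p`, `label`.
#' @export
pathway_calls <- function(diff_tables, pathways, p_max = 0.05,
                          z_cut = 0.5, logp_cut = 1.3) {
  if (is.null(names(diff_tables)) || any(names(diff_tables) == ""))
    stop("diff_tables must be a named list")
  rows <- list()
  for (stratum in names(diff_tables)) {
    diff <- diff_tables[[stratum]]
    quantified <- diff[diff$status == "quantified", , drop = FALSE]
    n_sig <- sum(quantified$p_value < p_max, na.rm = TRUE)
    universe <- nrow(quantified)
    for (pw in pathways) {
      az <- activation_z(quantified, pw, p_max = p_max)
      set_size <- sum(pw$members %in% quantified$protein_id)
      p <- if (set_size == 0L) 1 else
        enrichment_p(az$N, set_size, n_sig, universe)
      rows[[length(rows) + 1L]] <- data.frame(
        pathway = pw$name, stratum = stratum, N = az$N, z = az$z,
        enrichment_p = p,
        label = classify_pathway(az$z, p, z_cut, logp_cut),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cross-proteome activation summary
#'
#' Per pathway, over its per-stratum labels: `activated` if every non-no_call
#' label is activated (and at least one exists), `deactivated` symmetrically,
#' `mixed` if both directions occur. Pathways with only `no_call` labels are
#' excluded from the denominator. Percentages are reported to one decimal.
#'
#' @param calls Output of [pathway_calls()] (columns `pathway`, `label`).
#' @return List with `per_pathway` (data.frame pathway/direction), `counts`,
#'   `percent` (named numeric: activated/deactivated/mixed) and `denominator`.
#' @export
cross_summary <- function(calls) {
  if (is.null(calls) || nrow(calls) == 0L) stop("empty label table")
  split_labels <- split(calls$label, calls$pathway)
  dir_of <- function(lab) {
    lab <- lab[lab != "no_call"]
    if (length(lab) == 0L) return(NA_character_)
    has_a <- any(lab == "activated"); has_d <- any(lab == "deactivated")
    if (has_a && has_d) "mixed" else if (has_a) "activated" else "deactivated"
  }
  dirs <- vapply(split_labels, dir_of, "")
  per_pathway <- data.frame(pathway = names(dirs), direction = unname(dirs),
                            stringsAsFactors = FALSE)
  kept <- dirs[!is.na(dirs)]
  denom <- length(kept)
  counts <- c(activated = sum(kept == "activated"),
              deactivated = sum(kept == "deactivated"),
              mixed = sum(kept == "mixed"))
  percent <- if (denom > 0) round(100 * counts / denom, 1) else counts * NA_real_
  list(per_pathway = per_pathway, counts = counts, percent = percent,
       denominator = denom)
}

#' Read / write GMT pathway files with a direction string
#'
#' Format: one pathway per line, tab-separated — name, description, member
#' ids. The description field encodes the expected direction of each member
#' as a string of `+`/`-` characters (one per member, in member order).
#'
#' @param path File path.
#' @return List of [pathway_def()]s for the reader.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 4L) stop("malformed GMT line (need name, directions, >=2 members): ", f[1])
    dirs <- strsplit(f[2], "")[[1]]
    members <- f[-(1:2)]
    if (length(dirs) != length(members))
      stop("direction string length mismatch for pathway ", f[1])
    pathway_def(f[1], members, ifelse(dirs == "+", 1L, -1L))
  })
}

#' @rdname read_gmt
#' @param pathways List of [pathway_def()]s to write.
#' @export
write_gmt <- function(pathways, path) {
  lines <- vapply(pathways, function(pw) {
    paste(c(pw$name,
            paste(ifelse(pw$directions > 0, "+", "-"), collapse = ""),
            pw$members), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
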