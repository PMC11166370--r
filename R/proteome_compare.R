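# Cross-proteome comparison: significantly altered protein sets per stratum,
# recapitulation (intersection) between strata, and 3- vs 6-month age trends.

#' Significantly altered protein set per stratum
#'
#' Applies [filter_significant()] with `direction = "any"` to each differential
#' table and keeps the signed log2 fold changes.
#'
#' @param diff_tables Named list of [differential_analysis()] outputs; names
#'   label the strata (e.g. `"hippocampus_3m"`).
#' @param p_max,lfc_min Thresholds (defaults 0.05 and 5, the headline
#'   "log2 fold >= 5" criterion).
#' @return Named list of data.frames with columns `protein_id`, `log2_fold`,
#'   `p_value`; each carries its stratum label as attribute `stratum`.
#' @export
altered_protein_sets <- function(diff_tables, p_max = 0.05, lfc_min = 5) {
  if (length(diff_tables) == 0L) stop("at least one differential table required")
  if (is.null(names(diff_tables)) || any(names(diff_tables) == ""))
    stop("diff_tables must be a named list (stratum labels)")
  out <- lapply(names(diff_tables), function(nm) {
    hits <- filter_significant(diff_tables[[nm]], p_max = p_max,
                               lfc_min = lfc_min, direction = "any")
    s <- hits[, c("protein_id", "log2_fold", "p_value")]
    rownames(s) <- NULL
    attr(s, "stratum") <- nm
    s
  })
  stats::setNames(out, names(diff_tables))
}

#' Recapitulated proteins between two altered sets
#'
#' Intersection of two strata's altered protein sets, annotated with each
#' stratum's signed log2 fold change. An empty intersection is a valid result.
#'
#' @param set_1,set_2 Elements of [altered_protein_sets()] output.
#' @return data.frame with columns `protein_id`, `log2_fold_1`, `log2_fold_2`,
#'   ordered lexicographically by protein id.
#' @export
recapitulation <- function(set_1, set_2) {
  m <- merge(set_1[, c("protein_id", "log2_fold")],
             set_2[, c("protein_id", "log2_fold")],
             by = "protein_id", suffixes = c("_1", "_2"))
  m <- m[order(m$protein_id), , drop = FALSE]
  rownames(m) <- NULL
  attr(m, "strata") <- c(attr(set_1, "stratum"), attr(set_2, "stratum"))
  m
}

#' Age trend per protein within one tissue
#'
#' Joins the 3- and 6-month differential tables of one tissue on protein id and
#' flags fold-change concordance: `concordant` (same sign at both ages),
#' `discordant` (opposite signs), or `single_age` (quantified at one age only).
#'
#' @param diff_3m,diff_6m [differential_analysis()] outputs for the same
#'   tissue at 3 and 6 months (checked via their `tissue` attribute).
#' @return data.frame with columns `protein_id`, `log2_fold_3m`, `p_value_3m`,
#'   `log2_fold_6m`, `p_value_6m`, `concordance`.
#' @export
age_contrast <- function(diff_3m, diff_6m) {
  t1 <- attr(diff_3m, "tissue"); t2 <- attr(diff_6m, "tissue")
  if (!is.null(t1) && !is.null(t2) && !identical(t1, t2))
    stop(sprintf("tissue mismatch: %s vs %s", t1, t2))
  a <- diff_3m[, c("protein_id", "log2_fold", "p_value", "status")]
  b <- diff_6m[, c("protein_id", "log2_fold", "p_value", "status")]
  names(a)[2:4] <- paste0(c("log2_fold", "p_value", "status"), "_3m")
  names(b)[2:4] <- paste0(c("log2_fold", "p_value", "status"), "_6m")
  m <- merge(a, b, by = "protein_id", all = TRUE)
  q3 <- !is.na(m$status_3m) & m$status_3m == "quantified"
  q6 <- !is.na(m$status_6m) & m$status_6m == "quantified"
  m$concordance <- ifelse(
    q3 & q6,
    ifelse(sign(m$log2_fold_3m) == sign(m$log2_fold_6m),
           "concordant", "discordant"),
    "single_age"
  )
  m <- m[order(m$protein_id),
         c("protein_id", "log2_fold_3m", "p_value_3m",
           "log2_fold_6m", "p_value_6m", "concordance")]
  rownames(m) <- NULL
  attr(m, "tissue") <- t1 %||% t2
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Long-format export of altered sets plus intersections report
#'
#' @param sets Output of [altered_protein_sets()].
#' @param tsv_path Long-format TSV (stratum, protein_id, log2_fold, p_value).
#' @param json_path Pairwise intersections report (JSON).
#' @return Invisibly, the written paths.
#' @export
write_compare <- function(sets, tsv_path, json_path) {
  long <- do.call(rbind, lapply(names(sets), function(nm) {
    if (nrow(sets[[nm]]) == 0L) return(NULL)
    cbind(stratum = nm, sets[[nm]])
  }))
  if (is.null(long))
    long <- data.frame(stratum = character(), protein_id = character(),
                       log2_fold = numeric(), p_value = numeric())
  utils::write.table(long, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  nm <- names(sets)
  inter <- list()
  if (length(nm) >= 2L) {
    for (i in seq_len(length(nm) - 1L)) for (j in seq(i + 1L, length(nm))) {
      r <- recapitulation(sets[[nm[i]]], sets[[nm[j]]])
      inter[[paste(nm[i], nm[j], sep = "|")]] <-
        list(n = nrow(r), proteins = r$protein_id)
    }
  }
  jsonlite::write_json(inter, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(tsv = tsv_path, json = json_path))
}
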