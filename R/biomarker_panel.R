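# Human plasma-EV biomarker panel analysis: MMSE staging, candidate selection
# from the mouse EV differential tables, three-group statistics with
# Bonferroni-adjusted pairwise comparisons, and class 1/2/3 expression-pattern
# assignment via a replaceable rule table.

#' Stage a subject from an MMSE score
#'
#' Cognitive staging by mini-mental state examination score: late-stage if
#' score < 16, early-stage if 16 <= score <= 23, healthy if score >= 24.
#' Vectorized; every integer in \[0, 30\] maps to exactly one stage.
#'
#' @param score Integer MMSE score(s) in \[0, 30\].
#' @return Character vector in {"healthy", "early", "late"}.
#' @export
stage_from_mmse <- function(score) {
  if (any(is.na(score)) || any(score != round(score)))
    stop("MMSE scores must be integers")
  if (any(score < 0 | score > 30))
    stop("MMSE scores must lie in [0, 30]")
  ifelse(score < 16, "late", ifelse(score <= 23, "early", "healthy"))
}

#' Select biomarker candidates from the EV differential tables
#'
#' Candidates are proteins significant (`p < p_max`) in at least one plasma-EV
#' contrast (3- or 6-month), annotated with both ages' log2 fold changes and
#' p-values and ordered by the smaller of the two p-values.
#'
#' @param ev_3m,ev_6m Plasma-EV differential tables at 3 and 6 months:
#'   data.frames with columns `protein_id`, `log2_fold`, `p_value` (the
#'   [differential_analysis()] output shape, or the packaged Table-1-style
#'   fixture columns renamed accordingly).
#' @param p_max Strict significance ceiling (default 0.05).
#' @return data.frame: `protein_id`, `log2_fold_3m`, `p_3m`, `log2_fold_6m`,
#'   `p_6m`, `min_p`, ordered by `min_p` then protein id.
#' @export
select_candidates <- function(ev_3m, ev_6m, p_max = 0.05) {
  pick <- function(tab, suffix) {
    out <- tab[, c("protein_id", "log2_fold", "p_value")]
    names(out)[2:3] <- paste0(c("log2_fold_", "p_"), suffix)
    out
  }
  m <- merge(pick(ev_3m, "3m"), pick(ev_6m, "6m"),
             by = "protein_id", all = TRUE)
  m$min_p <- pmin(m$p_3m, m$p_6m, na.rm = TRUE)
  m$min_p[is.infinite(m$min_p)] <- NA_real_
  keep <- !is.na(m$min_p) & m$min_p < p_max
  m <- m[keep, , drop = FALSE]
  m <- m[order(m$min_p, m$protein_id), , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Three-group comparison of one panel protein
#'
#' One-way ANOVA across healthy/early/late followed by the three pairwise
#' comparisons at a Bonferroni-adjusted level (alpha/3). Pairwise tests use
#' the ANOVA pooled error (mean squared error with N - 3 degrees of freedom),
#' the convention of Bonferroni multiple-comparison post-hoc tests; set
#' `welch = TRUE` for per-pair Welch t-tests instead. Flags are `up`/`down`
#' by the sign of the mean difference (second group minus first) when the
#' adjusted comparison is significant, else `ns`.
#'
#' @param panel Panel data.frame: columns `subject_id`, `group`
#'   (healthy/early/late), `mmse`, then one column per protein.
#' @param protein Protein column name.
#' @param alpha Family-wise level (default 0.05; each pair tested at alpha/3).
#' @param welch Use Welch per-pair t-tests instead of the pooled-MSE tests.
#' @return One-row data.frame: `protein_id`, `he`, `hl`, `el` (flags for
#'   healthy-vs-early, healthy-vs-late, early-vs-late), `anova_p`, `p_he`,
#'   `p_hl`, `p_el`.
#' @export
group_compare <- function(panel, protein, alpha = 0.05, welch = FALSE) {
  if (!protein %in% names(panel)) stop("unknown protein column: ", protein)
  groups <- c("healthy", "early", "late")
  if (!all(panel$group %in% groups))
    stop("panel groups must be healthy/early/late")
  vals <- split(panel[[protein]], factor(panel$group, levels = groups))
  n <- vapply(vals, length, 0L)
  if (any(n < 3L)) stop("every group needs >= 3 subjects")
  means <- vapply(vals, mean, 0)
  ss_within <- sum(vapply(vals, function(v) sum((v - mean(v))^2), 0))
  df_err <- sum(n) - 3L
  mse <- ss_within / df_err

  pairs <- list(he = c("healthy", "early"),
                hl = c("healthy", "late"),
                el = c("early", "late"))

  if (mse == 0 && !welch) {
    # degenerate: zero within-group variance everywhere
    flags <- vapply(pairs, function(pr) {
      d <- means[pr[2]] - means[pr[1]]
      if (d == 0) "ns" else if (d > 0) "up" else "down"
    }, "")
    pvals <- vapply(pairs, function(pr)
      if (means[pr[2]] == means[pr[1]]) 1 else 0, 0)
    anova_p <- if (all(means == means[1])) 1 else 0
  } else {
    grand <- sum(unlist(vals)) / sum(n)
    ss_between <- sum(n * (means - grand)^2)
    f_stat <- (ss_between / 2) / mse
    anova_p <- stats::pf(f_stat, 2, df_err, lower.tail = FALSE)
    pvals <- vapply(pairs, function(pr) {
      if (welch) {
        stats::t.test(vals[[pr[2]]], vals[[pr[1]]])$p.value
      } else {
        se <- sqrt(mse * (1 / n[pr[1]] + 1 / n[pr[2]]))
        tt <- (means[pr[2]] - means[pr[1]]) / se
        2 * stats::pt(-abs(tt), df_err)
      }
    }, 0)
    flags <- vapply(names(pairs), function(k) {
      pr <- pairs[[k]]
      if (pvals[[k]] < alpha / 3) {
        if (means[pr[2]] > means[pr[1]]) "up" else "down"
      } else "ns"
    }, "")
  }
  data.frame(protein_id = protein,
             he = flags[["he"]], hl = flags[["hl"]], el = flags[["el"]],
             anova_p = anova_p,
             p_he = pvals[["he"]], p_hl = pvals[["hl"]], p_el = pvals[["el"]],
             stringsAsFactors = FALSE)
}

#' Three-group comparison for every panel protein
#'
#' @param panel Panel data.frame (see [group_compare()]).
#' @param proteins Protein columns to test (default: all non-metadata columns).
#' @inheritParams group_compare
#' @return data.frame of significance flags, one row per protein.
#' @export
group_compare_all <- function(panel, proteins = NULL, alpha = 0.05,
                              welch = FALSE) {
  if (is.null(proteins))
    proteins <- setdiff(names(panel), c("subject_id", "group", "mmse"))
  out <- do.call(rbind, lapply(proteins, function(p)
    group_compare(panel, p, alpha = alpha, welch = welch)))
  rownames(out) <- NULL
  out
}

#' Default class-assignment rule table
#'
#' Rules are matched top to bottom against the (he, hl, el) flag triple;
#' `"*"` matches any value and `"!ns"` matches up or down. The defaults encode:
#' class 3 = elevated early and late; class 1 = elevated early, late back at
#' the healthy level with a detected early-to-late return; class 2 = elevated
#' (or changed) early with indeterminate late behavior; no early change =
#' unclassified. The table is plain data and can be replaced wholesale.
#'
#' @return data.frame with columns `he`, `hl`, `el`, `class`.
#' @export
default_class_rules <- function() {
  data.frame(
    he = c("ns", "up", "up",  "up",  "up",  "down"),
    hl = c("*",  "up", "ns",  "ns",  "down", "*"),
    el = c("*",  "*",  "!ns", "ns",  "*",   "*"),
    class = c("unclassified", "class3", "class1", "class2", "class1",
              "class2"),
    stringsAsFactors = FALSE
  )
}

#' Assign class 1/2/3 expression patterns from significance flags
#'
#' Applies a rule table (first matching row wins) to each protein's pairwise
#' comparison flags. Proteins matching no rule are `unclassified`; the
#' assignment is total and deterministic.
#'
#' @param flags data.frame with columns `protein_id`, `he`, `hl`, `el`
#'   (values in up/down/ns), e.g. from [group_compare_all()].
#' @param rules Rule table, see [default_class_rules()].
#' @return data.frame: `protein_id`, `class`
#'   (class1/class2/class3/unclassified), input order preserved.
#' @export
classify_pattern <- function(flags, rules = default_class_rules()) {
  req <- c("protein_id", "he", "hl", "el")
  missing_cols <- setdiff(req, names(flags))
  if (length(missing_cols))
    stop("flags missing columns: ", paste(missing_cols, collapse = ", "))
  ok <- c("up", "down", "ns")
  for (col in c("he", "hl", "el")) {
    if (anyNA(flags[[col]]) || !all(flags[[col]] %in% ok))
      stop("incomplete or invalid flags in column ", col)
  }
  matches <- function(rule_val, flag_val) {
    rule_val == "*" || (rule_val == "!ns" && flag_val != "ns") ||
      rule_val == flag_val
  }
  cls <- vapply(seq_len(nrow(flags)), function(i) {
    for (r in seq_len(nrow(rules))) {
      if (matches(rules$he[r], flags$he[i]) &&
          matches(rules$hl[r], flags$hl[i]) &&
          matches(rules$el[r], flags$el[i]))
        return(rules$class[r])
    }
    "unclassified"
  }, "")
  data.frame(protein_id = flags$protein_id, class = cls,
             stringsAsFactors = FALSE)
}

#' Ponceau normalization of a band density
#'
#' Ratio of a band's raw density to the density of the Ponceau-stained
#' loading control; scale-invariant in the common factor.
#'
#' @param raw_density Raw band density (> 0).
#' @param loading_density Ponceau loading-control density (> 0).
#' @return Normalized intensity `raw_density / loading_density`.
#' @export
ponceau_normalize <- function(raw_density, loading_density) {
  if (any(loading_density <= 0)) stop("loading density must be positive")
  if (any(raw_density <= 0)) stop("raw density must be positive")
  raw_density / loading_density
}

#' Read a human panel TSV
#'
#' Expected columns: `subject_id`, `group`, `mmse`, then one column per
#' protein. Group consistency with the MMSE staging rule is checked.
#'
#' @param path File path.
#' @param check_stage Verify `group == stage_from_mmse(mmse)` (default TRUE).
#' @return Panel data.frame.
#' @export
read_panel <- function(path, check_stage = TRUE) {
  panel <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
  req <- c("subject_id", "group", "mmse")
  if (!all(req %in% names(panel)))
    stop("panel must have columns subject_id, group, mmse")
  if (check_stage && !all(panel$group == stage_from_mmse(panel$mmse)))
    stop("group labels inconsistent with MMSE staging rule")
  panel
}

#' Path to a packaged fixture
#'
#' Packaged plain-text fixtures: `table1_fixture.tsv` (the 21 significantly
#' changed mouse proteins with log2 fold and p per proteome and age,
#' transcribed from the published table; ND cells are NA),
#' `flags_fixture.tsv` (pairwise-comparison outcomes of the 14 human
#' candidates as reported for the stage-divided cohorts), and
#' `availability_fixture.tsv` (per-group marker availability; the per-group
#' lists are a synthetic reconstruction consistent with the reported
#' nine-protein common intersection — only the intersection was published).
#'
#' @param name Fixture file name.
#' @return Absolute path to the installed fixture.
#' @export
evpanel_fixture <- function(name) {
  p <- system.file("extdata", name, package = "evpanel")
  if (p == "") stop("no packaged fixture named ", name)
  p
}
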