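# Panel selection by sequential feature accumulation around a linear
# soft-margin SVM: t-test feature ranking recomputed inside every training
# fold, repeated stratified 10-fold cross-validation, and ROC/AUC reporting.
# Feature ranking inside the fold (rather than once globally) avoids
# selection bias leaking from held-out subjects into the panel choice.

#' Common feature intersection across per-group marker availability
#'
#' Features entering the classifier must be registered (measurable) in every
#' diagnostic group; this returns the set intersection of the per-group marker
#' lists, ordered lexicographically.
#'
#' @param availability Named list of character vectors (one per group), or a
#'   long data.frame with columns `group` and `protein_id`.
#' @return Sorted character vector of common features.
#' @export
common_intersection <- function(availability) {
  if (is.data.frame(availability)) {
    if (!all(c("group", "protein_id") %in% names(availability)))
      stop("availability data.frame needs columns group and protein_id")
    availability <- split(availability$protein_id, availability$group)
  }
  if (length(availability) < 2L) stop("need marker lists for >= 2 groups")
  common <- Reduce(intersect, availability)
  if (length(common) == 0L)
    stop("no marker is available in every group; review the feature lists")
  sort(common)
}

#' Rank features by two-sample t-test
#'
#' Per-feature two-tailed pooled-variance t-test between the two groups;
#' features are ordered by ascending p, ties broken by descending |t| then
#' lexicographic id. Degenerate features (zero variance in both groups) get
#' p = 1 when the group means agree and p = 0 (perfect separation, ranked
#' first) when they differ.
#'
#' @param X Numeric matrix, subjects x features (colnames = feature ids).
#' @param y Two-level grouping (factor or character), length `nrow(X)`.
#' @return data.frame `feature`, `t`, `p`, in rank order.
#' @export
rank_features <- function(X, y) {
  y <- factor(y)
  if (nlevels(y) != 2L) stop("y must have exactly two levels")
  g1 <- y == levels(y)[1]
  n1 <- sum(g1); n2 <- sum(!g1)
  if (n1 < 2L || n2 < 2L) stop("both groups need >= 2 subjects")
  stats_one <- function(v) {
    m1 <- mean(v[g1]); m2 <- mean(v[!g1])
    sp2 <- (sum((v[g1] - m1)^2) + sum((v[!g1] - m2)^2)) / (n1 + n2 - 2)
    if (sp2 == 0) {
      if (m1 == m2) return(c(t = 0, p = 1))
      return(c(t = sign(m2 - m1) * Inf, p = 0))
    }
    tt <- (m2 - m1) / sqrt(sp2 * (1 / n1 + 1 / n2))
    c(t = tt, p = 2 * stats::pt(-abs(tt), n1 + n2 - 2))
  }
  st <- t(apply(X, 2, stats_one))
  out <- data.frame(feature = colnames(X), t = st[, "t"], p = st[, "p"],
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, -abs(out$t), out$feature), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' ROC curve and AUC from decision scores
#'
#' Threshold sweep over the unique scores (higher score = more positive);
#' points are (false positive rate, true positive rate) starting at (0,0) and
#' ending at (1,1), and the AUC is the trapezoidal area, which equals the
#' Mann-Whitney pair-counting statistic with ties counted one half.
#'
#' @param scores Numeric decision values.
#' @param labels Logical (or coercible) positive-class indicator.
#' @return List with `points` (data.frame `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (anyNA(scores) || anyNA(labels)) stop("scores/labels must be complete")
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present to build a ROC curve")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  # collapse tied scores into single threshold steps
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(l)[last_of_tie]
  fp <- cumsum(!l)[last_of_tie]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

# Stratified fold assignment: within each class, subjects are shuffled and
# dealt round-robin so every fold's class proportions differ from the global
# ones by at most one subject.
.stratified_folds <- function(y, folds) {
  assignment <- integer(length(y))
  for (lev in unique(y)) {
    idx <- which(y == lev)
    assignment[idx[sample.int(length(idx))]] <-
      rep_len(seq_len(folds), length(idx))
  }
  assignment
}

# Fit a linear soft-margin SVM on standardized training features and return
# held-out class predictions plus decision scores oriented so that larger
# values favor the positive class.
.svm_eval <- function(X_train, y_train, X_test, positive, cost) {
  mu <- colMeans(X_train)
  sd_ <- apply(X_train, 2, stats::sd)
  sd_[sd_ == 0] <- 1
  Zt <- scale(X_train, mu, sd_)
  Zs <- scale(X_test, mu, sd_)
  fit <- e1071::svm(Zt, factor(y_train), kernel = "linear", cost = cost,
                    scale = FALSE)
  pred <- stats::predict(fit, Zs, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  # libsvm orients the decision value toward the first named class
  first <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
  score <- if (first == positive) dv[, 1] else -dv[, 1]
  list(pred = as.character(pred), score = unname(score))
}

#' Sequential feature accumulation with repeated stratified cross-validation
#'
#' For each of `repeats` seeded repetitions: stratified `folds`-fold split;
#' within each training fold the features are ranked by [rank_features()] and,
#' for every panel size k, a linear soft-margin SVM (cost `cost`, features
#' standardized with training-fold statistics) is trained on the top-k
#' features and evaluated on the held-out fold. Accuracy, sensitivity and
#' specificity are averaged over all folds and repeats per k; `best_k` is the
#' smallest k attaining the maximal mean accuracy. Held-out decision scores at
#' `best_k` are pooled within each repeat for a ROC curve; the reported AUC is
#' the mean over repeats, and the reported ROC points pool all repeats.
#'
#' @param panel Data.frame with a `group` column and feature columns.
#' @param contrast One of `"healthy_vs_early"`, `"healthy_vs_late"`,
#'   `"early_vs_late"`; the second-named group is the positive class. Any
#'   `"A_vs_B"` pair of groups present in the panel is accepted.
#' @param universe Feature columns to use (e.g. from [common_intersection()]).
#' @param folds,repeats Cross-validation layout (default 10 x 10).
#' @param seed Base seed; repeat r uses `seed + r - 1`.
#' @param cost SVM soft-margin cost (default 1).
#' @return List of class `panel_performance`: `contrast`, `performance`
#'   (data.frame k/accuracy/sensitivity/specificity), `best_k`, `best_panel`
#'   (top `best_k` features ranked on the full data), `mean_rank` (per-feature
#'   mean rank across all training folds), `roc` (pooled points), `auc`
#'   (mean over repeats), `auc_per_repeat`, plus the per-repeat
#'   `fold_assignments`, per-fold `fold_rankings` and subject `groups` for
#'   auditing fold construction and ranking provenance.
#' @export
accumulate_cv <- function(panel, contrast, universe, folds = 10L,
                          repeats = 10L, seed = 0L, cost = 1) {
  parts <- strsplit(contrast, "_vs_", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop("contrast must look like 'groupA_vs_groupB'")
  missing_feats <- setdiff(universe, names(panel))
  if (length(missing_feats))
    stop("panel lacks features: ", paste(missing_feats, collapse = ", "))
  sub <- panel[panel$group %in% parts, , drop = FALSE]
  y <- sub$group
  if (!all(parts %in% y)) stop("both contrast groups must be present")
  if (min(table(y)) < folds)
    stop("fewer subjects than folds in a group; reduce folds")
  X <- as.matrix(sub[, universe, drop = FALSE])
  positive <- parts[2]
  K <- length(universe)

  acc <- sen <- spe <- array(NA_real_, c(repeats, folds, K))
  rank_sum <- stats::setNames(numeric(K), universe)
  rank_n <- 0L
  scores_by_repeat <- vector("list", repeats)
  labels_by_repeat <- vector("list", repeats)
  ranks_by_fold <- vector("list", repeats * folds)
  fold_assignments <- vector("list", repeats)

  for (r in seq_len(repeats)) {
    set.seed(seed + r - 1L)
    fold_id <- .stratified_folds(y, folds)
    fold_assignments[[r]] <- fold_id
    rep_scores <- vector("list", folds)
    rep_labels <- vector("list", folds)
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      ranking <- rank_features(X[tr, , drop = FALSE], y[tr])
      rank_sum <- rank_sum + seq_len(K)[match(universe, ranking$feature)]
      rank_n <- rank_n + 1L
      ranks_by_fold[[(r - 1L) * folds + f]] <- ranking$feature
      fold_scores <- NULL
      for (k in seq_len(K)) {
        feats <- ranking$feature[seq_len(k)]
        ev <- .svm_eval(X[tr, feats, drop = FALSE], y[tr],
                        X[!tr, feats, drop = FALSE], positive, cost)
        truth_pos <- y[!tr] == positive
        acc[r, f, k] <- mean(ev$pred == y[!tr])
        sen[r, f, k] <- if (any(truth_pos)) mean(ev$pred[truth_pos] == positive) else NA
        spe[r, f, k] <- if (any(!truth_pos)) mean(ev$pred[!truth_pos] != positive) else NA
        if (is.null(fold_scores)) fold_scores <- matrix(NA_real_, sum(!tr), K)
        fold_scores[, k] <- ev$score
      }
      rep_scores[[f]] <- fold_scores
      rep_labels[[f]] <- y[!tr] == positive
    }
    scores_by_repeat[[r]] <- rep_scores
    labels_by_repeat[[r]] <- rep_labels
  }

  perf <- data.frame(
    k = seq_len(K),
    accuracy = apply(acc, 3, mean, na.rm = TRUE),
    sensitivity = apply(sen, 3, mean, na.rm = TRUE),
    specificity = apply(spe, 3, mean, na.rm = TRUE)
  )
  best_k <- which(perf$accuracy == max(perf$accuracy))[1]

  auc_per_repeat <- numeric(repeats)
  all_scores <- c(); all_labels <- logical(0)
  for (r in seq_len(repeats)) {
    sc <- unlist(lapply(scores_by_repeat[[r]], function(m) m[, best_k]))
    lb <- unlist(labels_by_repeat[[r]])
    auc_per_repeat[r] <- roc_auc(sc, lb)$auc
    all_scores <- c(all_scores, sc); all_labels <- c(all_labels, lb)
  }
  full_rank <- rank_features(X, y)
  structure(list(
    contrast = contrast,
    performance = perf,
    best_k = best_k,
    best_panel = full_rank$feature[seq_len(best_k)],
    mean_rank = sort(rank_sum / rank_n),
    roc = roc_auc(all_scores, all_labels)$points,
    auc = mean(auc_per_repeat),
    auc_per_repeat = auc_per_repeat,
    fold_assignments = fold_assignments,
    fold_rankings = ranks_by_fold,
    groups = y,
    folds = folds, repeats = repeats, seed = seed, cost = cost
  ), class = "panel_performance")
}

#' @export
print.panel_performance <- function(x, ...) {
  cat(sprintf("panel_performance: %s (%dx%d-fold CV)\n", x$contrast,
              x$repeats, x$folds))
  cat(sprintf("  best k = %d  accuracy = %.3f  AUC = %.3f\n", x$best_k,
              x$performance$accuracy[x$best_k], x$auc))
  cat("  best panel:", paste(x$best_panel, collapse = ", "), "\n")
  invisible(x)
}

#' Write panel performance outputs
#'
#' @param perf A `panel_performance` object.
#' @param dir Output directory; writes `<contrast>_performance.tsv`,
#'   `<contrast>_roc.tsv` and `<contrast>_report.json`.
#' @return Invisibly, the written paths.
#' @export
write_performance <- function(perf, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(dir, perf$contrast)
  paths <- c(performance = paste0(base, "_performance.tsv"),
             roc = paste0(base, "_roc.tsv"),
             report = paste0(base, "_report.json"))
  utils::write.table(perf$performance, paths[["performance"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(perf$roc, paths[["roc"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(contrast = perf$contrast, best_k = perf$best_k,
         best_panel = perf$best_panel, auc = perf$auc,
         accuracy_at_best_k = perf$performance$accuracy[perf$best_k],
         folds = perf$folds, repeats = perf$repeats, seed = perf$seed),
    paths[["report"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
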