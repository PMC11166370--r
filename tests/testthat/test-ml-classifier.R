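# Feature ranking, ROC/AUC, and sequential feature accumulation with
# repeated stratified cross-validation.

test_that("common_intersection returns the shared markers, sorted", {
  av <- list(g1 = c("B", "A", "C"), g2 = c("C", "B"), g3 = c("B", "C", "D"))
  expect_identical(common_intersection(av), c("B", "C"))
  expect_identical(common_intersection(list(a = c("X", "Y"), b = c("Y", "X"))),
                   c("X", "Y"))
  expect_error(common_intersection(list(a = "A", b = "B")), "review")
  expect_error(common_intersection(list(a = "A")), ">= 2")
})

test_that("rank_features orders by p with |t| and id tie-breaks", {
  set.seed(50)
  n <- 20
  y <- rep(c("a", "b"), each = n)
  X <- cbind(
    strong = c(rnorm(n), rnorm(n, 3)),
    weak = c(rnorm(n), rnorm(n, 0.2)),
    noise = rnorm(2 * n)
  )
  r <- rank_features(X, y)
  expect_identical(r$feature[1], "strong")
  expect_true(all(diff(r$p) >= 0))

  # exact ties: identical columns tie on p and |t|, broken lexicographically
  X2 <- cbind(zeta = X[, "strong"], alpha = X[, "strong"])
  r2 <- rank_features(X2, y)
  expect_identical(r2$feature, c("alpha", "zeta"))

  # degenerate: zero variance, equal means -> p = 1; perfect separation -> first
  X3 <- cbind(flat = rep(1, 2 * n), sep = rep(c(0, 1), each = n),
              mid = c(rnorm(n), rnorm(n, 1)))
  r3 <- rank_features(X3, y)
  expect_identical(r3$feature[1], "sep")
  expect_equal(r3$p[r3$feature == "sep"], 0)
  expect_equal(r3$p[r3$feature == "flat"], 1)
})

test_that("label permutation makes top-ranked features uniform", {
  set.seed(51)
  n <- 12; n_feat <- 5
  X <- matrix(rnorm(2 * n * n_feat), 2 * n,
              dimnames = list(NULL, sprintf("F%d", seq_len(n_feat))))
  y <- rep(c("a", "b"), each = n)
  top <- vapply(1:300, function(i) {
    rank_features(X, sample(y))$feature[1]
  }, "")
  counts <- table(factor(top, levels = colnames(X)))
  gof <- suppressWarnings(chisq.test(counts))
  expect_gt(gof$p.value, 0.01)
})

test_that("roc_auc matches the pair-counting oracle and handles ties", {
  r <- roc_auc(c(0.9, 0.8, 0.4, 0.2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auc, 1)
  r2 <- roc_auc(c(0.9, 0.4, 0.8, 0.2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r2$auc, 0.75)

  # curve anchored at (0,0) and (1,1), monotone
  expect_equal(unlist(r2$points[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(r2$points[nrow(r2$points), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(r2$points$fpr) >= 0) && all(diff(r2$points$tpr) >= 0))

  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")

  # independent library cross-check on a noisy score vector with ties
  set.seed(60)
  sc <- round(rnorm(40), 1)
  lb <- rep(c(TRUE, FALSE), 20)
  ref <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                        direction = "<", levels = c(FALSE, TRUE))))
  expect_equal(roc_auc(sc, lb)$auc, ref, tolerance = 1e-10)
})

test_that("trapezoid AUC equals pair counting exhaustively for small n", {
  set.seed(52)
  for (n in c(4, 6, 8, 10, 12)) {
    # tied scores arise from rounding; enumerate many label splits
    scores <- round(runif(n), 1)
    labels_all <- if (n <= 8) {
      lapply(1:(2^n - 2), function(m) as.logical(intToBits(m)[1:n]))
    } else {
      lapply(1:300, function(i) sample(c(TRUE, FALSE), n, replace = TRUE))
    }
    for (lab in labels_all) {
      if (all(lab) || !any(lab)) next
      expect_equal(roc_auc(scores, lab)$auc, auc_oracle(scores, lab),
                   tolerance = 1e-10)
    }
  }
})

test_that("stratified folds keep class proportions within one subject", {
  sep <- simulate_binary_panel(25, 4, 2, effect_d = 1, seed = 53)
  perf <- accumulate_cv(sep$panel, "healthy_vs_early",
                        sprintf("F%02d", 1:4), folds = 5, repeats = 3,
                        seed = 54)
  y <- perf$groups
  for (fold_id in perf$fold_assignments) {
    for (f in unique(fold_id)) {
      for (g in unique(y)) {
        n_g <- sum(y == g)
        in_fold <- sum(y[fold_id == f] == g)
        expect_lte(abs(in_fold - n_g / max(fold_id)), 1)
      }
    }
  }
})

test_that("a separable contrast reaches perfect accuracy and AUC", {
  sep <- simulate_binary_panel(40, 9, 5, effect_d = 6, seed = 3)
  perf <- accumulate_cv(sep$panel, "healthy_vs_early",
                        sort(sprintf("F%02d", 1:9)), seed = 7)
  expect_equal(max(perf$performance$accuracy), 1)
  expect_equal(perf$auc, 1)
  # monotone sanity: best k at least as accurate as a single feature
  expect_gte(perf$performance$accuracy[perf$best_k],
             perf$performance$accuracy[1])
})

test_that("label-permuted panels perform at chance", {
  pl <- simulate_binary_panel(40, 9, 5, effect_d = 1.5, seed = 4)
  set.seed(9)
  nullp <- pl$panel
  nullp$group <- sample(nullp$group)
  perf <- accumulate_cv(nullp, "healthy_vs_early", sort(sprintf("F%02d", 1:9)),
                        seed = 9)
  expect_gte(perf$performance$accuracy[perf$best_k], 0.40)
  expect_lte(perf$performance$accuracy[perf$best_k], 0.60)
  expect_gte(perf$auc, 0.40)
  expect_lte(perf$auc, 0.60)
})

test_that("planted informative features dominate the ranking and best_k", {
  pl <- simulate_binary_panel(40, 9, 5, effect_d = 1.5, seed = 4)
  perf <- accumulate_cv(pl$panel, "healthy_vs_early",
                        sort(sprintf("F%02d", 1:9)), seed = 8)
  top5 <- names(perf$mean_rank)[1:5]
  expect_setequal(top5, pl$truth$informative)
  expect_gte(perf$best_k, 3)
  expect_lte(perf$best_k, 7)
})

test_that("cross-validation is deterministic under a fixed seed", {
  pl <- simulate_binary_panel(15, 4, 2, effect_d = 1, seed = 55)
  a <- accumulate_cv(pl$panel, "healthy_vs_early", sprintf("F%02d", 1:4),
                     folds = 5, repeats = 2, seed = 56)
  b <- accumulate_cv(pl$panel, "healthy_vs_early", sprintf("F%02d", 1:4),
                     folds = 5, repeats = 2, seed = 56)
  expect_identical(a$performance, b$performance)
  expect_identical(a$fold_assignments, b$fold_assignments)
  expect_identical(a$auc, b$auc)
})

test_that("held-out subjects never influence training-fold rankings", {
  pl <- simulate_binary_panel(15, 4, 2, effect_d = 1, seed = 57)
  universe <- sprintf("F%02d", 1:4)
  base <- accumulate_cv(pl$panel, "healthy_vs_early", universe,
                        folds = 5, repeats = 2, seed = 58)
  # corrupt one subject's measurements; folds depend only on labels and seed
  corrupted <- pl$panel
  j <- 7L
  corrupted[j, universe] <- corrupted[j, universe] * 1000
  alt <- accumulate_cv(corrupted, "healthy_vs_early", universe,
                       folds = 5, repeats = 2, seed = 58)
  expect_identical(base$fold_assignments, alt$fold_assignments)
  for (r in seq_along(base$fold_assignments)) {
    held_out_fold <- base$fold_assignments[[r]][j]
    idx <- (r - 1L) * 5L + held_out_fold
    # subject j is excluded from training in its held-out fold: identical ranking
    expect_identical(base$fold_rankings[[idx]], alt$fold_rankings[[idx]])
  }
})

test_that("errors guide fold and group misuse", {
  pl <- simulate_binary_panel(5, 3, 1, effect_d = 1, seed = 59)
  expect_error(accumulate_cv(pl$panel, "healthy_vs_early",
                             sprintf("F%02d", 1:3), folds = 10),
               "reduce folds")
  expect_error(accumulate_cv(pl$panel, "healthy_vs_late",
                             sprintf("F%02d", 1:3), folds = 2),
               "present")
  expect_error(accumulate_cv(pl$panel, "healthy_vs_early", c("F01", "NOPE"),
                             folds = 2), "lacks features")
})
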