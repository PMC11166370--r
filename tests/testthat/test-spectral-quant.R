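# Cumulative/normalized PSM indices and the G-test.

test_that("accumulate_psm sums replicate counts exactly", {
  counts <- cbind(a = c(3L, 0L, 7L), b = c(2L, 0L, 1L), c = c(5L, 0L, 2L))
  rownames(counts) <- c("P1", "P2", "P3")
  meta <- data.frame(sample_id = c("a", "b", "c"), tissue = "cortex",
                     age_months = 3L, genotype = "WT",
                     replicate_id = 1:3, stringsAsFactors = FALSE)
  # psm_experiment requires positive sample totals, satisfied here
  x <- psm_experiment(counts, meta)

  acc <- accumulate_psm(x, c("a", "b", "c"))
  expect_identical(unname(acc$c), c(10, 0, 10))
  expect_identical(acc$total, 20)

  one <- accumulate_psm(x, "b")
  expect_identical(unname(one$c), c(2, 0, 1))

  expect_error(accumulate_psm(x, character(0)), "no samples")
  expect_error(accumulate_psm(x, "nope"), "unknown sample ids")
})

test_that("normalize_psm_index scales counts per total", {
  expect_equal(normalize_psm_index(10, 1000), 100)
  expect_equal(normalize_psm_index(0, 1000), 0)
  # equal totals: index ratio equals raw count ratio
  expect_equal(normalize_psm_index(30, 500) / normalize_psm_index(10, 500), 3)
  expect_error(normalize_psm_index(5, 0), "positive")
})

test_that("g_test matches closed-form and independent oracles", {
  # perfectly expected counts
  r0 <- g_test(5, 5, 100, 100)
  expect_equal(r0$G, 0)
  expect_equal(r0$p_value, 1)

  # closed-form: 2*(20*ln(20/12.5) + 5*ln(5/12.5))
  r1 <- g_test(20, 5, 1000, 1000)
  expect_equal(r1$G, 2 * (20 * log(20 / 12.5) + 5 * log(5 / 12.5)),
               tolerance = 1e-12)
  expect_equal(r1$G, 9.637238, tolerance = 1e-6)
  # independent chi-square(1) tail: P(X > G) = 2 * (1 - Phi(sqrt(G)))
  expect_equal(r1$p_value, 2 * pnorm(-sqrt(r1$G)), tolerance = 1e-12)
  expect_equal(r1$p_value, 0.00190672, tolerance = 1e-5)

  # single-group detection uses the 0*ln(0) = 0 convention
  r2 <- g_test(0, 10, 1000, 1000)
  expect_equal(r2$G, 2 * 10 * log(2), tolerance = 1e-12)
  expect_equal(r2$G, g_oracle(0, 10, 1000, 1000), tolerance = 1e-10)

  expect_error(g_test(0, 0, 10, 10), "ND")
  expect_error(g_test(11, 0, 10, 10), "exceeds")
})

test_that("G equals the brute-force multinomial likelihood ratio", {
  # all count pairs over a grid of group totals
  for (tot in list(c(10, 10), c(10, 25), c(30, 20), c(50, 50))) {
    grid <- expand.grid(c_A = 0:min(tot[1], 15), c_B = 0:min(tot[2], 15))
    grid <- grid[grid$c_A + grid$c_B > 0, ]
    got <- g_test(grid$c_A, grid$c_B, tot[1], tot[2])$G
    want <- mapply(g_oracle, grid$c_A, grid$c_B, tot[1], tot[2])
    expect_equal(got, unname(want), tolerance = 1e-10)
  }
})

test_that("G is symmetric in group relabeling and monotone in imbalance", {
  ab <- g_test(17, 4, 900, 1100)
  ba <- g_test(4, 17, 1100, 900)
  expect_equal(ab$G, ba$G, tolerance = 1e-12)
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)

  # fixed c_A + c_B = 30, equal totals: G non-decreasing in |c_A - c_B|
  c_A <- 15:30
  G <- g_test(c_A, 30 - c_A, 500, 500)$G
  expect_true(all(diff(G) >= -1e-12))
})

test_that("differential_analysis computes folds, tests and ND convention", {
  # protein P01: WT 40 vs 5xFAD 10; equal totals via balancing protein P02;
  # P03 absent in both groups
  x <- make_psm(c(40L, 160L, 0L), c(10L, 190L, 0L))
  d <- differential_analysis(x, "plasma_EV", 3, pseudocount = 1e-9)
  p1 <- d[d$protein_id == "P01", ]
  expect_equal(p1$log2_fold, -2, tolerance = 1e-6)
  expect_equal(p1$G, 2 * (40 * log(40 / 25) + 10 * log(10 / 25)),
               tolerance = 1e-10)
  expect_equal(p1$G, 19.27448, tolerance = 1e-5)
  expect_equal(p1$p_value, 2 * pnorm(-sqrt(p1$G)), tolerance = 1e-12)

  nd <- d[d$protein_id == "P03", ]
  expect_identical(nd$status, "ND")
  expect_true(is.na(nd$p_value) && is.na(nd$log2_fold))

  # detected in one group only: finite fold via the pseudocount
  x2 <- make_psm(c(0L, 9988L), c(12L, 9988L))
  d2 <- differential_analysis(x2, "plasma_EV", 3, pseudocount = 0.5)
  p <- d2[d2$protein_id == "P01", ]
  expect_equal(p$log2_fold, log2((p$i_5xFAD + 0.5) / 0.5), tolerance = 1e-12)
  # with T = 1e4 the index equals the count, so the fold is log2(12.5/0.5)
  expect_equal(p$log2_fold, log2(12.5 / 0.5), tolerance = 1e-3)

  expect_error(differential_analysis(x, "cortex", 3), "lacks genotype|stratum")
})

test_that("swapping genotype labels negates log2 folds, preserves G and p", {
  set.seed(71)
  cw <- as.integer(rpois(40, 30)) + 1L
  ct <- as.integer(rpois(40, 30)) + 1L
  x <- make_psm(cw, ct)
  x_swap <- make_psm(ct, cw)
  d <- differential_analysis(x, "plasma_EV", 3)
  d2 <- differential_analysis(x_swap, "plasma_EV", 3)
  m <- merge(d, d2, by = "protein_id")
  expect_equal(m$log2_fold.x, -m$log2_fold.y, tolerance = 1e-12)
  expect_equal(m$G.x, m$G.y, tolerance = 1e-12)
  expect_equal(m$p_value.x, m$p_value.y, tolerance = 1e-12)
})

test_that("filter_significant applies strict p and inclusive fold thresholds", {
  d <- make_diff(c("A", "B", "C", "D", "E"),
                 log2_fold = c(7.1, 4.6, -6.0, 5.0, 2.0),
                 p_value = c(0.001, 0.02, 0.03, 0.049, 0.05))
  out <- filter_significant(d, p_max = 0.05, lfc_min = 5, direction = "any")
  expect_identical(out$protein_id, c("A", "C", "D"))
  # boundary: p = 0.05 excluded (strict), |lfc| = 5 retained (inclusive)
  expect_false("E" %in% out$protein_id)
  expect_true("D" %in% out$protein_id)

  up <- filter_significant(d, 0.05, 5, "up")
  expect_identical(up$protein_id, c("A", "D"))
  down <- filter_significant(d, 0.05, 5, "down")
  expect_identical(down$protein_id, "C")

  d$status[1] <- "ND"; d$p_value[1] <- NA; d$log2_fold[1] <- NA
  expect_false("A" %in% filter_significant(d, 0.05, 0)$protein_id)
})

test_that("differential output ordering is p, then |fold|, then id", {
  x <- make_psm(c(40L, 10L, 25L, 25L), c(10L, 40L, 25L, 25L))
  d <- differential_analysis(x, "plasma_EV", 3)
  expect_identical(d$protein_id[1:2], c("P01", "P02"))  # tied p, tied |fold|: id
  expect_true(all(diff(d$p_value[!is.na(d$p_value)]) >= 0))
})

test_that("count table round-trips through TSV", {
  x <- make_psm(c(3L, 0L, 5L), c(1L, 2L, 0L))
  cp <- tempfile(fileext = ".tsv"); mp <- tempfile(fileext = ".tsv")
  write_psm_counts(x, cp, mp)
  y <- read_psm_counts(cp, mp)
  expect_identical(x$counts, y$counts)
  expect_identical(x$meta, y$meta)
})
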