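test_that("bootstrap P-values obey the add-one floor and degenerate cases", {
  # exactly-zero observed score: nothing is more extreme -> P = 1
  # (0.25 = 0.5 * 0.5 exactly in binary floating point)
  b <- bootstrap_p_fscore(0.25, 0, 0.5, 0, 0.5, 0, 1.0, 0, cv2 = 0,
                          n_trials = 1000, seed = 1)
  expect_equal(b$p_value, 1)

  # overwhelming interaction: P sits at the floor 1/(n_trials+1)
  b2 <- bootstrap_p_fscore(0.36, 0.03, 0.8, 0.01, 0.9, 0.01, 1.0, 0.01,
                           cv2 = 0.03, n_trials = 10000, seed = 1)
  expect_equal(b2$p_value, 1 / 10001)

  # degenerate CVs, zero observed S-score
  b3 <- bootstrap_p_sscore(0.72, 0, 0.8, 0, 0.9, 0, 1.0, 0,
                           0.36, 0, 0.4, 0, 0.45, 0, 0.5, 0,
                           0, 0, n_trials = 1000, seed = 1)
  expect_equal(b3$p_value, 1)
})

test_that("fixed seeds reproduce P-values exactly; seeds differ by MC noise", {
  args <- list(0.70, 0.02, 0.8, 0.01, 0.9, 0.01, 1.0, 0.01, cv2 = 0.02,
               n_trials = 5000)
  p1 <- do.call(bootstrap_p_fscore, c(args, seed = 42))$p_value
  p2 <- do.call(bootstrap_p_fscore, c(args, seed = 42))$p_value
  expect_identical(p1, p2)
  p3 <- do.call(bootstrap_p_fscore, c(args, seed = 43))$p_value
  expect_false(identical(p1, p3))
  expect_lt(abs(p1 - p3), 0.05)  # same input, O(n^-1/2) seed wobble
})

test_that("power rises with |epsilon| and falls with noise", {
  p_at <- function(eps, cv) {
    m_xy <- (1 + eps) * 0.72
    bootstrap_p_fscore(m_xy, cv, 0.8, cv, 0.9, cv, 1.0, cv, cv2 = cv,
                       n_trials = 5000, seed = 5)$p_value
  }
  for (cv in c(0.02, 0.05, 0.1)) {
    p <- vapply(c(0.1, 0.25, 0.5), p_at, numeric(1), cv = cv)
    expect_true(all(diff(p) <= 0))
  }
  for (eps in c(0.1, 0.25, 0.5)) {
    p <- vapply(c(0.02, 0.05, 0.1), function(cv) p_at(eps, cv), numeric(1))
    expect_true(all(diff(p) >= 0))
  }
})

test_that("null pairs are not over-rejected (conservative-to-calibrated)", {
  p <- simulate_null_pair_tests(n_pairs = 400, cv = 0.03, n_trials = 2000,
                                seed = 31)
  for (fam in colnames(p)) {
    expect_lt(mean(p[, fam] < 0.05), 0.10)
    expect_gt(mean(p[, fam] < 0.05), 0.005)
  }
  # ES fixed-mode null is first-order exact: P approximately uniform
  expect_gt(suppressWarnings(ks.test(p[, "ES"], "punif")$p.value), 1e-4)
})

test_that("planted interactions are detected with high power", {
  # environment-modulated pair at screen-like noise: S-score P below 0.01
  set.seed(77)
  hits <- 0L
  for (i in 1:20) {
    cv <- 0.03; nw <- 19; ns <- 19; nd <- 4
    sim <- function(m, n) {
      x <- m * (1 + rnorm(n, 0, cv)); c(mean(x), sd(x) / mean(x) / sqrt(n))
    }
    w1 <- sim(0.0077, nw); x1 <- sim(0.0069, ns); y1 <- sim(0.0062, ns)
    d1 <- sim(0.0069 * 0.0062 / 0.0077, nd)                  # neutral in E1
    w2 <- sim(0.0069, nw); x2 <- sim(0.0060, ns); y2 <- sim(0.0055, ns)
    d2 <- sim(0.6 * 0.0060 * 0.0055 / 0.0069, nd)            # eps = -0.4 in E2
    b <- bootstrap_p_sscore(d1[1], d1[2], x1[1], x1[2], y1[1], y1[2],
                            w1[1], w1[2], d2[1], d2[2], x2[1], x2[2],
                            y2[1], y2[2], w2[1], w2[2],
                            cv2_e1 = 0.0075, cv2_e2 = 0.0075,
                            n_trials = 4000)
    hits <- hits + (b$p_value < 0.01)
  }
  expect_gte(hits, 18)  # >= 90% of datasets
})

test_that("Welch T-test matches its closed form and both input forms agree", {
  expect_equal(ttest_single_vs_wt(c(1, 2, 3), c(1, 2, 3)), 1)

  # large separation: P far below 1e-6
  set.seed(8)
  wt <- rnorm(19, 1, 0.02)
  mut <- rnorm(19, 1 - 5 * 0.02, 0.02)
  expect_lt(ttest_single_vs_wt(mut, wt), 1e-6)

  # summary-statistic path equals the replicate path
  p_rep <- ttest_single_vs_wt(mut, wt)
  p_sum <- ttest_single_vs_wt(list(mean = mean(mut), sd = sd(mut), n = 19),
                              list(mean = mean(wt), sd = sd(wt), n = 19))
  expect_equal(p_rep, p_sum)
  # and equals stats::t.test (Welch)
  expect_equal(p_rep, t.test(mut, wt)$p.value)

  expect_error(ttest_single_vs_wt(1, wt), "n >= 2")
})

test_that("environment assignment follows the four-way P rule", {
  expect_identical(assign_environment(0.005, 0.5), "E1-only")
  expect_identical(assign_environment(0.5, 0.005), "E2-only")
  expect_identical(assign_environment(0.005, 0.005), "both")
  expect_identical(assign_environment(0.5, 0.5), "none")
  # boundary: alpha itself is not significant (strict <)
  expect_identical(assign_environment(0.01, 0.005, alpha = 0.01), "E2-only")
  expect_identical(assign_environment(c(0.005, 0.5), c(0.5, 0.5)),
                   c("E1-only", "none"))
})

test_that("score_significance fills P-values consistently with the primitives", {
  ph <- tiny_phenotypes()
  sc <- score_library(ph, "E1", "E2")
  tested <- score_significance(sc, ph, n_trials = 2000, seed = 12)
  expect_true(all(!is.na(tested$p_value)))
  expect_true(all(tested$p_value >= 1 / 2001 & tested$p_value <= 1))
  # neutral-in-E1 F-score should be unremarkable; aggravating E2 one small
  expect_gt(tested$p_value[tested$family == "F" &
                             tested$environment == "E1"], 0.2)
  expect_lt(tested$p_value[tested$family == "F" &
                             tested$environment == "E2"], 0.05)
  # bit-reproducible under a fixed seed
  tested2 <- score_significance(sc, ph, n_trials = 2000, seed = 12)
  expect_identical(tested$p_value, tested2$p_value)
})
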