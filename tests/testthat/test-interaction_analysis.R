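test_that("threshold calling is strict and keeps the environment label", {
  sc <- make_scores(pair = c("A:B", "C:D", "E:F"),
                    gene1 = c("A", "C", "E"), gene2 = c("B", "D", "F"),
                    family = "S", environment = "cross",
                    epsilon = c(-0.4, 0.2, 0.01),
                    p_value = c(0.005, 0.02, 0.5))
  calls <- call_by_threshold(sc, alpha = 0.01, family = "S")
  expect_equal(nrow(calls), 1)
  expect_equal(calls$pair, "A:B")
  expect_equal(nrow(call_by_threshold(sc, alpha = 1, family = "S")), 3)

  # F family: union over environments, labelled by assignment
  fsc <- make_scores(pair = rep(c("A:B", "C:D"), each = 2),
                     gene1 = rep(c("A", "C"), each = 2),
                     gene2 = rep(c("B", "D"), each = 2),
                     family = "F", environment = rep(c("E1", "E2"), 2),
                     epsilon = c(0.3, 0.32, -0.2, -0.01),
                     p_value = c(0.002, 0.004, 0.5, 0.003))
  fcalls <- call_by_threshold(fsc, alpha = 0.01, family = "F")
  expect_equal(nrow(fcalls), 2)  # each significant pair appears once
  expect_identical(fcalls$environment[fcalls$pair == "A:B"], "both")
  expect_identical(fcalls$environment[fcalls$pair == "C:D"], "E2-only")
})

test_that("top-k selection is deterministic under ties", {
  sc <- make_scores(pair = c("A:B", "C:D", "E:F", "G:H"),
                    gene1 = c("A", "C", "E", "G"),
                    gene2 = c("B", "D", "F", "H"),
                    family = "S", environment = "cross",
                    epsilon = c(-0.10, 0.30, -0.30, 0.30),
                    p_value = c(0.02, 0.02, 0.02, 0.5))
  top2 <- call_top_k(sc, 2, family = "S")
  # tie at P = 0.02 broken by larger |eps|, then pair name
  expect_identical(top2$pair, c("C:D", "E:F"))
  expect_identical(call_top_k(sc, 2, family = "S")$pair, top2$pair)
  expect_equal(nrow(call_top_k(sc, 0, family = "S")), 0)
  expect_error(call_top_k(sc, 5, family = "S"), "exceeds")
})

test_that("call-set comparison partitions pairs symmetrically", {
  a <- data.frame(pair = c("A:B", "C:D", "E:F"))
  b <- data.frame(pair = c("C:D", "G:H"))
  cmp <- compare_call_sets(a, b)
  expect_equal(cmp$n_shared, 1)
  expect_equal(cmp$only_a, c("A:B", "E:F"))
  expect_equal(cmp$only_b, "G:H")
  rev <- compare_call_sets(b, a)
  expect_equal(rev$shared, cmp$shared)
  expect_equal(rev$only_a, cmp$only_b)
  expect_equal(cmp$n_shared + cmp$n_only_a + cmp$n_only_b,
               length(union(a$pair, b$pair)))
  same <- compare_call_sets(a, a)
  expect_equal(same$n_shared, 3)
  expect_length(same$only_a, 0)
})

test_that("|S| vs |dF| tabulation flags undefined correlations", {
  sc <- make_scores(
    pair = rep(c("A:B", "C:D", "E:F"), each = 3),
    gene1 = rep(c("A", "C", "E"), each = 3),
    gene2 = rep(c("B", "D", "F"), each = 3),
    family = rep(c("F", "F", "S"), 3),
    environment = rep(c("E1", "E2", "cross"), 3),
    epsilon = c(0.1, 0.4, 0.28, 0.0, 0.1, 0.095, 0.2, 0.21, 0.01))
  d <- delta_f_vs_s(sc)
  expect_equal(nrow(d$table), 3)
  expect_equal(d$table$abs_df[d$table$pair == "A:B"], 0.3)
  expect_true(is.finite(d$correlation))
  expect_gt(d$correlation, 0)

  one <- delta_f_vs_s(sc[sc$pair == "A:B", ], e1 = "E1", e2 = "E2")
  expect_true(is.na(one$correlation))
  expect_match(one$note, "undefined")
})

test_that("fold enrichment reproduces the frequency-ratio definition", {
  # 37 calls of which 9 carry evidence, 26 evidence pairs in a 316 universe
  calls <- data.frame(pair = sprintf("A%02d:B%02d", 1:37, 1:37))
  ev_pairs <- c(calls$pair[1:9], sprintf("C%02d:D%02d", 1:17, 1:17))
  ev <- make_evidence(ev_pairs, "buffering", 316)
  e <- enrichment_test(calls, ev, "buffering")
  expect_equal(e$hits_in_calls, 9)
  expect_equal(e$fold_R, (9 / 37) / (26 / 316))
  expect_equal(e$fold_R, 2.956, tolerance = 0.02)  # ~3-fold
  expect_lt(e$p_value, 0.01)

  # hits exactly at expectation -> fold 1
  calls2 <- data.frame(pair = c(ev_pairs[1:13], sprintf("X%d:Y%d", 1:145, 1:145)))
  e2 <- enrichment_test(calls2, make_evidence(ev_pairs, "buffering", 316),
                        "buffering")
  expect_equal(e2$fold_R, 1, tolerance = 1e-12)

  expect_error(enrichment_test(calls[0, , drop = FALSE], ev), "empty")
})

test_that("hypergeometric tails equal exhaustive enumeration on small universes", {
  for (N in c(10, 12, 15)) {
    K <- 4; n <- 5
    calls <- data.frame(pair = sprintf("P%02d:Q%02d", 1:n, 1:n))
    for (k in 0:min(K, n)) {
      # construct a call set with exactly k evidence hits
      ev_pairs <- c(calls$pair[seq_len(k)],
                    sprintf("R%02d:S%02d", seq_len(K - k), seq_len(K - k)))
      ev_pairs <- ev_pairs[seq_len(K)]
      e <- enrichment_test(calls, make_evidence(ev_pairs, "buffering", N),
                           "buffering")
      expect_equal(e$p_value, enum_hyper_tail(k, K, N, n), tolerance = 1e-12)
    }
  }
})

test_that("co-binding P-values behave at the extremes and match enumeration", {
  u <- sprintf("g%03d", 1:100)
  expect_gt(cobinding_test(u[1:10], u[11:20], u), 0.3)   # disjoint
  expect_lt(cobinding_test(u[1:10], u[1:10], u), 1e-10)  # identical

  u12 <- sprintf("g%02d", 1:12)
  a <- u12[1:5]; b <- u12[c(1:3, 6, 7)]
  k <- length(intersect(a, b))
  expect_equal(cobinding_test(a, b, u12),
               enum_hyper_tail(k, length(a), 12, length(b)),
               tolerance = 1e-12)
  expect_error(cobinding_test(u12[1:2], u12[1:2], character(0)), "empty")
})

test_that("predictive value and TPR/FPR respond to evidence coverage", {
  sc <- make_scores(pair = sprintf("A%d:B%d", 1:10, 1:10),
                    gene1 = sprintf("A%d", 1:10), gene2 = sprintf("B%d", 1:10),
                    family = "S", environment = "cross",
                    epsilon = seq(-0.5, 0.4, length.out = 10),
                    p_value = seq(0.001, 0.9, length.out = 10))
  all_ev <- make_evidence(sprintf("A%d:B%d", 1:10, 1:10), "buffering", 10)
  pv <- predictive_value_curve(sc, all_ev, alphas = c(0.01, 0.5),
                               families = "S")
  expect_true(all(pv$predictive_value == 1, na.rm = TRUE))

  some_ev <- make_evidence(sprintf("A%d:B%d", 1:3, 1:3), "buffering", 10)
  pv2 <- predictive_value_curve(sc, some_ev,
                                alphas = c(0.0005, 0.05, 0.3, 1.0),
                                families = "S")
  expect_true(all(diff(pv2$tpr) >= 0))  # monotone in alpha
  expect_true(all(diff(pv2$fpr) >= 0))
  expect_true(is.na(pv2$predictive_value[1]))  # alpha below every P: no calls
  expect_equal(pv2$tpr[4], 1)
})
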