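test_that("spec validation guards the generative invariants", {
  expect_error(synthetic_library_spec(1), "at least 2")
  expect_error(synthetic_library_spec(c("A", "A", "B")), "duplicate")
  expect_error(synthetic_library_spec(4, missing_fraction = 1), "missing_fraction")
  expect_error(synthetic_library_spec(
    4, planted = data.frame(gene1 = "G01", gene2 = "ZZ", eps_e1 = 0,
                            eps_e2 = 0)), "within the gene set")
  expect_error(synthetic_library_spec(
    4, planted = data.frame(gene1 = "G01", gene2 = "G02", eps_e1 = -1.2,
                            eps_e2 = 0)), "-1")
})

test_that("planted truth satisfies the score identity exactly", {
  spec <- standard_scenarios("modulated", seed = 3)
  lib <- generate_library(spec)
  tp <- lib$truth$pairs
  expect_equal(tp$eps_sen, (1 + tp$eps_fit_e1) / (1 + tp$eps_fit_e2) - 1,
               tolerance = 1e-15)
  # planted pair from the spec: eps (0, -0.4) implies eps_sen = 1/0.6 - 1
  planted <- pair_key(spec$planted$gene1[1], spec$planted$gene2[1])
  expect_equal(tp$eps_sen[tp$pair == planted], 1 / 0.6 - 1,
               tolerance = 1e-15)
})

test_that("library composition matches the design", {
  lib <- generate_library(synthetic_library_spec(26, seed = 2))
  nd <- n_deletions(unique(lib$phenotypes$strain))
  expect_equal(sum(nd == 0), 1)
  expect_equal(sum(nd == 1), 26)
  expect_equal(sum(nd == 2), 325)
  expect_equal(sum(lib$phenotypes$environment == "E1"), 352)

  # replicate counts per strain class
  reps <- lib$replicates
  n_by <- tapply(reps$replicate, paste(reps$strain, reps$environment), max)
  expect_true(all(n_by[names(n_by) == "WT E1"] == 19))
  expect_equal(unname(n_by[["G01:G02 E1"]]), 4)

  # unassayed doubles are absent rows, at about the missing fraction
  lib2 <- generate_library(synthetic_library_spec(26, missing_fraction = 0.028,
                                                  seed = 5))
  n_doubles <- sum(n_deletions(unique(lib2$phenotypes$strain)) == 2)
  expect_true(n_doubles >= 300 && n_doubles <= 325)
})

test_that("replicate noise has the requested scale and zero noise is exact", {
  spec <- synthetic_library_spec(3, replicate_cv = c(E1 = 0.05, E2 = 0.05),
                                 n_replicates = c(wt = 200, single = 200,
                                                  double = 200), seed = 9)
  lib <- generate_library(spec)
  cvs <- lib$phenotypes$cv
  expect_true(all(cvs > 0.03 & cvs < 0.07))

  lib0 <- generate_library(synthetic_library_spec(
    3, replicate_cv = c(E1 = 0, E2 = 0), seed = 9))
  truth <- lib0$truth$rates
  merged <- merge(as.data.frame(lib0$phenotypes), truth,
                  by = c("strain", "environment"))
  expect_equal(merged$rate.x, merged$rate.y, tolerance = 1e-15)
})

test_that("OD curves round-trip through the growth-rate fitter", {
  reps <- data.frame(gene1 = c("A", "B"), gene2 = NA, environment = "E1",
                     replicate = 1L, rate = c(0.0077, 0.005))
  curves <- generate_od_curves(reps, od_noise_cv = 0)
  rates <- fit_od_table(curves)
  expect_equal(sort(rates$rate), sort(reps$rate), tolerance = 1e-9)

  # default sampling leaves enough points in the default fit window
  one <- curves[curves$gene1 == "A", ]
  in_win <- one$od >= 0.1 & one$od <= 0.4 & one$time_min >= 60 &
    one$time_min <= 360
  expect_gte(sum(in_win), 10)

  # noisy curves: fitted-rate scatter within a sane envelope of the OD noise
  reps20 <- data.frame(gene1 = "A", gene2 = NA, environment = "E1",
                       replicate = 1:20, rate = 0.0077)
  noisy <- generate_od_curves(reps20, od_noise_cv = 0.02, seed = 14)
  fitted <- fit_od_table(noisy)$rate
  cv_hat <- sd(fitted) / mean(fitted)
  expect_gt(cv_hat, 0.1 * 0.02)
  expect_lt(cv_hat, 3 * 0.02)
})

test_that("scenario presets encode their designed contrasts", {
  expect_error(standard_scenarios("nonesuch"), "arg")

  null_spec <- standard_scenarios("null")
  expect_equal(nrow(null_spec$planted), 0)

  st <- standard_scenarios("static")
  expect_true(all(st$planted$eps_e1 == st$planted$eps_e2))
  lib_st <- generate_library(st)
  key_st <- pair_key(st$planted$gene1, st$planted$gene2)
  tp <- lib_st$truth$pairs
  expect_true(all(abs(tp$eps_sen[tp$pair %in% key_st]) < 1e-12))

  mod <- standard_scenarios("modulated")
  expect_true(all(mod$planted$eps_e1 == 0) && all(mod$planted$eps_e2 != 0))

  cx_spec <- standard_scenarios("complex")
  cxs <- attr(cx_spec, "complexes")
  expect_equal(lengths(cxs), c(C1 = 3L, C2 = 4L, C3 = 3L))
  # co-equivalence: within-complex true S-scores equal members' true ES-scores
  lib_cx <- generate_library(cx_spec)
  tg <- lib_cx$truth$genes
  tp_cx <- lib_cx$truth$pairs
  for (cx in names(cxs)) {
    members <- cxs[[cx]]
    prs <- pair_key(combn(members, 2)[1, ], combn(members, 2)[2, ])
    es <- tg$eps_env[tg$gene %in% members]
    expect_equal(length(unique(round(es, 12))), 1)
    expect_equal(tp_cx$eps_sen[tp_cx$pair %in% prs],
                 rep(es[1], length(prs)), tolerance = 1e-12)
    expect_lt(es[1], 0)  # alleviating (negative) S within complexes
  }
})

test_that("static versus modulated libraries separate the F and S methods", {
  score_and_test <- function(preset, seed) {
    spec <- standard_scenarios(preset, seed = seed)
    lib <- generate_library(spec)
    sc <- score_library(lib$phenotypes, "E1", "E2", families = c("F", "S"))
    sc <- score_significance(sc, lib$phenotypes, n_trials = 2000,
                             seed = seed + 1)
    list(scores = sc, planted = pair_key(spec$planted$gene1,
                                         spec$planted$gene2))
  }
  st <- score_and_test("static", 41)
  f_calls <- call_by_threshold(st$scores, 0.05, "F")
  s_calls <- call_by_threshold(st$scores, 0.05, "S")
  expect_gt(nrow(f_calls), nrow(s_calls))
  expect_gte(sum(st$planted %in% f_calls$pair), 18)  # F power >= 90%
  expect_lte(sum(st$planted %in% s_calls$pair), 8)   # S blind to static pairs

  md <- score_and_test("modulated", 43)
  s_calls2 <- call_by_threshold(md$scores, 0.05, "S")
  expect_gte(sum(md$planted %in% s_calls2$pair), 18)  # S power >= 90%
})
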