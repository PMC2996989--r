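# Truncated-normal draws by rejection: redraw non-positive values up to
# `max_redraw` times, then flag the trial for discarding. `mean` may be a
# vector (per-trial null means); `sd` is recycled against it.
draw_positive <- function(n, mean, sd, max_redraw = 100L) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= 0)
  tries <- 0L
  while (length(bad) > 0 && tries < max_redraw) {
    x[bad] <- stats::rnorm(length(bad),
                           if (length(mean) > 1) mean[bad] else mean,
                           if (length(sd) > 1) sd[bad] else sd)
    bad <- bad[x[bad] <= 0]
    tries <- tries + 1L
  }
  list(x = x, ok = !seq_len(n) %in% bad)
}

boot_result <- function(p, eps_obs, stat, n_trials, n_used, seed) {
  structure(list(p_value = p, epsilon = eps_obs, statistic = stat,
                 n_trials = n_trials, n_used = n_used,
                 n_discarded = n_trials - n_used, seed = seed),
            class = "bootstrap_test")
}

#' @export
print.bootstrap_test <- function(x, ...) {
  cat(sprintf("Parametric bootstrap (%s): epsilon = %.4g, P = %.4g (%d trials)\n",
              x$statistic, x$epsilon, x$p_value, x$n_used))
  invisible(x)
}

add_one_p <- function(eps_trials, eps_obs) {
  (1 + sum(abs(eps_trials) >= abs(eps_obs))) / (length(eps_trials) + 1)
}

#' Parametric-bootstrap P-value for an F-score
#'
#' Simulated rates are drawn from normal distributions matching the observed
#' means and variances (variance = `(cv * mean)^2`), with the double-mutant
#' rate drawn under the imposed null: mean `m0` equal to the multiplicative
#' expectation and variance `m0^2 * (cv_xy^2 + cv2^2)`, where `cv2` is the
#' library-median CV over all double mutants in the same environment. The
#' two-sided P-value is the add-one-corrected fraction of trials whose
#' |F-score| meets or exceeds the observed one; it is never exactly zero
#' (floor `1/(n_trials+1)`).
#'
#' The CVs supplied here should describe the uncertainty of the *mean* rate
#' estimates (replicate cv divided by sqrt(n)); [score_significance()] does
#' this conversion for whole score tables.
#'
#' @param m_xy,m_x,m_y,m_wt observed mean rates (double, singles, wildtype).
#' @param cv_xy,cv_x,cv_y,cv_wt CVs of those means.
#' @param cv2 library-median double-mutant CV for the environment.
#' @param n_trials bootstrap trials (default 300000).
#' @param seed optional integer; when `NULL` the current RNG stream is used.
#' @param null_mean_mode `"per-trial"` recomputes `m0` from each trial's
#'   drawn single/wildtype rates; `"fixed"` uses the observed means.
#' @return list of class `bootstrap_test`: `p_value`, `epsilon` (observed),
#'   `n_trials`, `n_used`, `n_discarded`, `seed`.
#' @export
bootstrap_p_fscore <- function(m_xy, cv_xy, m_x, cv_x, m_y, cv_y, m_wt, cv_wt,
                               cv2, n_trials = 300000L, seed = NULL,
                               null_mean_mode = c("per-trial", "fixed")) {
  mode <- match.arg(null_mean_mode)
  if (n_trials < 1000) stop("n_trials must be >= 1000")
  stopifnot(all(c(m_xy, m_x, m_y, m_wt) > 0),
            all(c(cv_xy, cv_x, cv_y, cv_wt, cv2) >= 0))
  if (!is.null(seed)) set.seed(seed)
  eps_obs <- f_score(m_xy, m_x, m_y, m_wt)
  wt <- draw_positive(n_trials, m_wt, cv_wt * m_wt)
  x <- draw_positive(n_trials, m_x, cv_x * m_x)
  y <- draw_positive(n_trials, m_y, cv_y * m_y)
  m0 <- if (mode == "per-trial") x$x * y$x / wt$x else
    rep(m_x * m_y / m_wt, n_trials)
  d <- draw_positive(n_trials, m0, m0 * sqrt(cv_xy^2 + cv2^2))
  ok <- wt$ok & x$ok & y$ok & d$ok
  eps <- d$x[ok] * wt$x[ok] / (x$x[ok] * y$x[ok]) - 1
  boot_result(add_one_p(eps, eps_obs), eps_obs, "F", n_trials, sum(ok), seed)
}

#' Parametric-bootstrap P-value for an S-score
#'
#' Same machinery as [bootstrap_p_fscore()] applied across both environments:
#' per trial, single and wildtype rates are drawn in each environment from
#' their observed distributions, and the double-mutant rate in *each*
#' environment is drawn around the multiplicative expectation for that
#' environment (jointly imposing the sensitivity neutrality) with variance
#' `m0^2 * (cv_xy^2 + cv2^2)` per environment. The trial statistic is the
#' S-score.
#'
#' @param m_xy_e1,cv_xy_e1,m_x_e1,cv_x_e1,m_y_e1,cv_y_e1,m_wt_e1,cv_wt_e1
#'   observed means/CVs in the reference environment.
#' @param m_xy_e2,cv_xy_e2,m_x_e2,cv_x_e2,m_y_e2,cv_y_e2,m_wt_e2,cv_wt_e2
#'   the same in the perturbed environment.
#' @param cv2_e1,cv2_e2 library-median double-mutant CV per environment.
#' @inheritParams bootstrap_p_fscore
#' @return a `bootstrap_test` list.
#' @export
bootstrap_p_sscore <- function(m_xy_e1, cv_xy_e1, m_x_e1, cv_x_e1, m_y_e1,
                               cv_y_e1, m_wt_e1, cv_wt_e1,
                               m_xy_e2, cv_xy_e2, m_x_e2, cv_x_e2, m_y_e2,
                               cv_y_e2, m_wt_e2, cv_wt_e2,
                               cv2_e1, cv2_e2, n_trials = 300000L,
                               seed = NULL,
                               null_mean_mode = c("per-trial", "fixed")) {
  mode <- match.arg(null_mean_mode)
  if (n_trials < 1000) stop("n_trials must be >= 1000")
  means <- c(m_xy_e1, m_x_e1, m_y_e1, m_wt_e1, m_xy_e2, m_x_e2, m_y_e2,
             m_wt_e2)
  stopifnot(all(means > 0))
  if (!is.null(seed)) set.seed(seed)
  eps_obs <- s_score(m_xy_e1 / m_xy_e2, m_x_e1 / m_x_e2, m_y_e1 / m_y_e2,
                     m_wt_e1 / m_wt_e2)
  one_env <- function(m_x, cv_x, m_y, cv_y, m_wt, cv_wt, cv_xy, cv2) {
    wt <- draw_positive(n_trials, m_wt, cv_wt * m_wt)
    x <- draw_positive(n_trials, m_x, cv_x * m_x)
    y <- draw_positive(n_trials, m_y, cv_y * m_y)
    m0 <- if (mode == "per-trial") x$x * y$x / wt$x else
      rep(m_x * m_y / m_wt, n_trials)
    d <- draw_positive(n_trials, m0, m0 * sqrt(cv_xy^2 + cv2^2))
    list(wt = wt, x = x, y = y, d = d, ok = wt$ok & x$ok & y$ok & d$ok)
  }
  e1 <- one_env(m_x_e1, cv_x_e1, m_y_e1, cv_y_e1, m_wt_e1, cv_wt_e1,
                cv_xy_e1, cv2_e1)
  e2 <- one_env(m_x_e2, cv_x_e2, m_y_e2, cv_y_e2, m_wt_e2, cv_wt_e2,
                cv_xy_e2, cv2_e2)
  ok <- e1$ok & e2$ok
  s_xy <- e1$d$x[ok] / e2$d$x[ok]
  s_x <- e1$x$x[ok] / e2$x$x[ok]
  s_y <- e1$y$x[ok] / e2$y$x[ok]
  s_wt <- e1$wt$x[ok] / e2$wt$x[ok]
  eps <- s_xy * s_wt / (s_x * s_y) - 1
  boot_result(add_one_p(eps, eps_obs), eps_obs, "S", n_trials, sum(ok), seed)
}

#' Parametric-bootstrap P-value for an ES-score
#'
#' Tests the null that a single mutant's environmental sensitivity equals the
#' wildtype's. Per trial, the wildtype rates (both environments) and the
#' mutant's reference-environment rate are drawn from their observed
#' distributions; the mutant's perturbed-environment rate is drawn around the
#' null mean that equalises the sensitivities,
#' `mu0 = m_x_e1 * m_wt_e2 / m_wt_e1`. By default `mu0` is built from the
#' *observed* means ("fixed"): with a per-trial `mu0` the constrained draw's
#' noise is the only term left in the trial statistic, the uncertainty of the
#' other three measurements cancelling exactly, which badly understates the
#' null variance.
#'
#' @param m_x_e1,cv_x_e1,m_x_e2,cv_x_e2 mutant means/CVs per environment.
#' @param m_wt_e1,cv_wt_e1,m_wt_e2,cv_wt_e2 wildtype means/CVs.
#' @inheritParams bootstrap_p_fscore
#' @return a `bootstrap_test` list.
#' @export
bootstrap_p_esscore <- function(m_x_e1, cv_x_e1, m_x_e2, cv_x_e2,
                                m_wt_e1, cv_wt_e1, m_wt_e2, cv_wt_e2,
                                n_trials = 300000L, seed = NULL,
                                null_mean_mode = c("fixed", "per-trial")) {
  mode <- match.arg(null_mean_mode)
  if (n_trials < 1000) stop("n_trials must be >= 1000")
  stopifnot(all(c(m_x_e1, m_x_e2, m_wt_e1, m_wt_e2) > 0))
  if (!is.null(seed)) set.seed(seed)
  eps_obs <- es_score(m_x_e1 / m_x_e2, m_wt_e1 / m_wt_e2)
  wt1 <- draw_positive(n_trials, m_wt_e1, cv_wt_e1 * m_wt_e1)
  wt2 <- draw_positive(n_trials, m_wt_e2, cv_wt_e2 * m_wt_e2)
  x1 <- draw_positive(n_trials, m_x_e1, cv_x_e1 * m_x_e1)
  mu0 <- if (mode == "per-trial") x1$x * wt2$x / wt1$x else
    rep(m_x_e1 * m_wt_e2 / m_wt_e1, n_trials)
  x2 <- draw_positive(n_trials, mu0, mu0 * cv_x_e2)
  ok <- wt1$ok & wt2$ok & x1$ok & x2$ok
  eps <- (wt1$x[ok] / wt2$x[ok]) / (x1$x[ok] / x2$x[ok]) - 1
  boot_result(add_one_p(eps, eps_obs), eps_obs, "ES", n_trials, sum(ok), seed)
}

# cv of the mean estimate, with library-median substitution for n = 1 strains
se_cv <- function(cv, n, fallback) {
  cv <- ifelse(is.na(cv), fallback, cv)
  cv / sqrt(n)
}

#' Attach bootstrap P-values to a score table
#'
#' Runs the appropriate bootstrap for every row of an `epistasis_scores`
#' table, pulling means, replicate CVs and replicate counts from the
#' phenotype table the scores were computed from. Replicate CVs are converted
#' to CVs of the mean (`cv / sqrt(n)`); strains with an unestimable CV
#' (single replicate) receive the library-median replicate CV of their
#' environment first. `cv2` is the per-environment median of the
#' double-mutant mean-CVs.
#'
#' @param scores an `epistasis_scores` table from [score_library()]. If the
#'   scores were computed with `estimate_singles` overrides, pass the same
#'   overridden phenotype table here (see [apply_estimated_singles()]).
#' @param phenotypes the `phenotype_table` used for scoring.
#' @param e1,e2 environment names (defaults from the score table attribute).
#' @param n_trials bootstrap trials per score.
#' @param seed integer seed for the whole pass; results are bit-reproducible
#'   for a fixed seed and row order.
#' @param null_mean_mode passed to the F/S bootstraps ("per-trial" default);
#'   the ES bootstrap always uses its own default ("fixed") unless
#'   `es_null_mean_mode` is given.
#' @param es_null_mean_mode optional override for the ES bootstrap.
#' @return the score table with `p_value` filled in.
#' @export
score_significance <- function(scores, phenotypes, e1 = NULL, e2 = NULL,
                               n_trials = 300000L, seed = NULL,
                               null_mean_mode = "per-trial",
                               es_null_mean_mode = "fixed") {
  envs <- attr(scores, "environments")
  if (is.null(e1)) e1 <- envs[["e1"]]
  if (is.null(e2)) e2 <- envs[["e2"]]
  if (is.null(e1) || is.null(e2)) stop("environment names e1/e2 required")
  if (!is.null(seed)) set.seed(seed)
  ph <- phenotypes
  ndel <- n_deletions(ph$strain)
  med_rep_cv <- stats::setNames(
    vapply(c(e1, e2), function(env)
      stats::median(ph$cv[ph$environment == env], na.rm = TRUE), numeric(1)),
    c(e1, e2))
  info <- function(strain, env) {
    i <- which(ph$strain == strain & ph$environment == env)
    if (length(i) != 1) return(NULL)
    list(m = ph$rate[i], cv = se_cv(ph$cv[i], ph$n[i], med_rep_cv[[env]]))
  }
  cv2 <- stats::setNames(vapply(c(e1, e2), function(env) {
    i <- which(ndel == 2 & ph$environment == env)
    if (length(i) == 0) return(0)
    stats::median(se_cv(ph$cv[i], ph$n[i], med_rep_cv[[env]]))
  }, numeric(1)), c(e1, e2))
  for (r in seq_len(nrow(scores))) {
    fam <- scores$family[r]
    if (fam == "F") {
      env <- scores$environment[r]
      g <- c(scores$gene1[r], scores$gene2[r])
      xy <- info(scores$pair[r], env); x <- info(g[1], env)
      y <- info(g[2], env); wt <- info("WT", env)
      if (any(vapply(list(xy, x, y, wt), is.null, logical(1)))) next
      b <- bootstrap_p_fscore(xy$m, xy$cv, x$m, x$cv, y$m, y$cv, wt$m, wt$cv,
                              cv2[[env]], n_trials = n_trials,
                              null_mean_mode = null_mean_mode)
    } else if (fam == "ES") {
      x1 <- info(scores$gene1[r], e1); x2 <- info(scores$gene1[r], e2)
      w1 <- info("WT", e1); w2 <- info("WT", e2)
      if (any(vapply(list(x1, x2, w1, w2), is.null, logical(1)))) next
      b <- bootstrap_p_esscore(x1$m, x1$cv, x2$m, x2$cv, w1$m, w1$cv,
                               w2$m, w2$cv, n_trials = n_trials,
                               null_mean_mode = es_null_mean_mode)
    } else {
      g <- c(scores$gene1[r], scores$gene2[r])
      a <- lapply(list(scores$pair[r], g[1], g[2], "WT"), info, env = e1)
      b2 <- lapply(list(scores$pair[r], g[1], g[2], "WT"), info, env = e2)
      if (any(vapply(c(a, b2), is.null, logical(1)))) next
      b <- bootstrap_p_sscore(
        a[[1]]$m, a[[1]]$cv, a[[2]]$m, a[[2]]$cv, a[[3]]$m, a[[3]]$cv,
        a[[4]]$m, a[[4]]$cv,
        b2[[1]]$m, b2[[1]]$cv, b2[[2]]$m, b2[[2]]$cv, b2[[3]]$m, b2[[3]]$cv,
        b2[[4]]$m, b2[[4]]$cv,
        cv2[[e1]], cv2[[e2]], n_trials = n_trials,
        null_mean_mode = null_mean_mode)
    }
    scores$p_value[r] <- b$p_value
  }
  scores
}

#' Welch T-test of a mutant against the wildtype
#'
#' Accepts either per-replicate rate vectors or summary statistics
#' (`list(mean=, sd=, n=)`); the two forms give identical results on the
#' same data.
#'
#' @param mutant,wt numeric replicate vectors (n >= 2) or summary lists.
#' @return two-sided P-value.
#' @export
ttest_single_vs_wt <- function(mutant, wt) {
  as_summary <- function(x) {
    if (is.list(x)) {
      stopifnot(all(c("mean", "sd", "n") %in% names(x)))
      if (x$n < 2) stop("need n >= 2 replicates")
      x
    } else {
      if (length(x) < 2) stop("need n >= 2 replicates")
      list(mean = mean(x), sd = stats::sd(x), n = length(x))
    }
  }
  a <- as_summary(mutant); b <- as_summary(wt)
  v1 <- a$sd^2 / a$n; v2 <- b$sd^2 / b$n
  se <- sqrt(v1 + v2)
  if (se == 0) return(if (a$mean == b$mean) 1 else 0)
  t <- (a$mean - b$mean) / se
  df <- (v1 + v2)^2 / (v1^2 / (a$n - 1) + v2^2 / (b$n - 1))
  2 * stats::pt(-abs(t), df)
}

#' Assign an interaction to environments from its two P-values
#'
#' The four-way rule: significant only in the reference environment
#' (`"E1-only"`), only in the perturbed one (`"E2-only"`), in `"both"`, or
#' `"none"`.
#'
#' @param p_e1,p_e2 P-values in the two environments (vectorised).
#' @param alpha significance threshold (strict `<`), default 0.01.
#' @return character vector in `{"E1-only","E2-only","both","none"}`.
#' @export
assign_environment <- function(p_e1, p_e2, alpha = 0.01) {
  stopifnot(all(p_e1 >= 0 & p_e1 <= 1, na.rm = TRUE),
            all(p_e2 >= 0 & p_e2 <= 1, na.rm = TRUE))
  ifelse(p_e1 < alpha & p_e2 >= alpha, "E1-only",
         ifelse(p_e1 >= alpha & p_e2 < alpha, "E2-only",
                ifelse(p_e1 < alpha & p_e2 < alpha, "both", "none")))
}

#' Type-I calibration experiment for the bootstrap tests
#'
#' Simulates independent null gene pairs under the library's replicate
#' design (wildtype + two singles + one multiplicative double in two
#' environments, replicate noise of the given CV), summarises each exactly
#' as the pipeline does (sample means, sample CVs converted to mean-CVs,
#' library-median `cv2` over the simulated doubles), and runs all three
#' bootstrap families on every pair. The empirical fraction of P-values
#' below alpha estimates each test's type-I error.
#'
#' @param n_pairs number of independent null pairs.
#' @param cv replicate noise CV (both environments).
#' @param n_reps named vector `c(wt=, single=, double=)` replicate counts.
#' @param n_trials bootstrap trials per test.
#' @param seed RNG seed.
#' @param null_mean_mode F/S bootstrap mode; ES uses its "fixed" default.
#' @return matrix `n_pairs` x 3 of P-values, columns `F`, `S`, `ES`.
#' @export
simulate_null_pair_tests <- function(n_pairs = 2000, cv = 0.03,
                                     n_reps = c(wt = 19, single = 19,
                                                double = 4),
                                     n_trials = 10000L, seed = 1L,
                                     null_mean_mode = "per-trial") {
  set.seed(seed)
  wt_rate <- c(0.0077, 0.0069)
  fx <- 0.9; fy <- 0.8
  sim <- function(m, n) {
    x <- m * (1 + stats::rnorm(n, 0, cv))
    while (any(x <= 0)) {
      x[x <= 0] <- m * (1 + stats::rnorm(sum(x <= 0), 0, cv))
    }
    c(mean = mean(x), cv = if (n > 1) stats::sd(x) / mean(x) else NA_real_,
      n = n)
  }
  dat <- lapply(seq_len(n_pairs), function(i) {
    lapply(1:2, function(e) {
      mw <- wt_rate[e]
      list(w = sim(mw, n_reps[["wt"]]), x = sim(fx * mw, n_reps[["single"]]),
           y = sim(fy * mw, n_reps[["single"]]),
           d = sim(fx * fy * mw, n_reps[["double"]]))
    })
  })
  mcv <- function(s) s[["cv"]] / sqrt(s[["n"]])
  cv2 <- vapply(1:2, function(e)
    stats::median(vapply(dat, function(p) mcv(p[[e]]$d), numeric(1))),
    numeric(1))
  p <- matrix(NA_real_, n_pairs, 3, dimnames = list(NULL, c("F", "S", "ES")))
  for (i in seq_len(n_pairs)) {
    e1 <- dat[[i]][[1]]; e2 <- dat[[i]][[2]]
    p[i, "F"] <- bootstrap_p_fscore(
      e1$d[["mean"]], mcv(e1$d), e1$x[["mean"]], mcv(e1$x),
      e1$y[["mean"]], mcv(e1$y), e1$w[["mean"]], mcv(e1$w), cv2[1],
      n_trials = n_trials, null_mean_mode = null_mean_mode)$p_value
    p[i, "S"] <- bootstrap_p_sscore(
      e1$d[["mean"]], mcv(e1$d), e1$x[["mean"]], mcv(e1$x),
      e1$y[["mean"]], mcv(e1$y), e1$w[["mean"]], mcv(e1$w),
      e2$d[["mean"]], mcv(e2$d), e2$x[["mean"]], mcv(e2$x),
      e2$y[["mean"]], mcv(e2$y), e2$w[["mean"]], mcv(e2$w),
      cv2[1], cv2[2], n_trials = n_trials,
      null_mean_mode = null_mean_mode)$p_value
    p[i, "ES"] <- bootstrap_p_esscore(
      e1$x[["mean"]], mcv(e1$x), e2$x[["mean"]], mcv(e2$x),
      e1$w[["mean"]], mcv(e1$w), e2$w[["mean"]], mcv(e2$w),
      n_trials = n_trials)$p_value
  }
  p
}
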