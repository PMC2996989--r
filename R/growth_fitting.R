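#' Fit window for exponential growth-rate estimation
#'
#' Points enter the log-linear fit only if the OD lies in `[od_min, od_max]`
#' AND the time lies in `[t_min, t_max]` (both filters applied conjunctively).
#' Defaults reflect common microplate practice for budding yeast: OD600
#' between 0.1 and 0.4 sampled between 60 and 360 minutes after inoculation,
#' with a minimum of 10 qualifying points.
#'
#' @param od_min,od_max OD600 bounds.
#' @param t_min,t_max time bounds, minutes.
#' @param min_points minimum qualifying points, >= 2.
#' @return list of class `fit_window`.
#' @export
fit_window <- function(od_min = 0.1, od_max = 0.4, t_min = 60, t_max = 360,
                       min_points = 10L) {
  if (!(od_min < od_max)) stop("od_min must be < od_max")
  if (!(t_min < t_max)) stop("t_min must be < t_max")
  if (min_points < 2) stop("min_points must be >= 2")
  structure(list(od_min = od_min, od_max = od_max, t_min = t_min,
                 t_max = t_max, min_points = as.integer(min_points)),
            class = "fit_window")
}

#' Estimate a logarithmic growth rate from one OD time course
#'
#' Ordinary least squares of `log(OD)` on time over the points surviving the
#' fit window. Non-positive OD readings inside the window are excluded before
#' the log and count against `min_points`. Rejection (too few points) is a
#' returned record, not an error, so library-scale fitting can proceed.
#'
#' @param times minutes, strictly increasing, length >= 2.
#' @param od OD600 readings, same length, >= 0.
#' @param window a [fit_window()].
#' @param r2_warn warn (but do not reject) when the fit R-squared falls below
#'   this value; a stand-in for manual curve inspection.
#' @return list of class `growth_fit` with fields `rate` (1/min, `NA` when
#'   rejected), `accepted`, `reason`, `n_points`, `r_squared`, `intercept`.
#' @examples
#' t <- seq(0, 600, by = 15)
#' fit_growth_rate(t, 0.05 * exp(0.0077 * t))$rate
#' @export
fit_growth_rate <- function(times, od, window = fit_window(),
                            r2_warn = 0.95) {
  times <- as.numeric(times); od <- as.numeric(od)
  if (length(times) < 2 || length(times) != length(od)) {
    stop("need >= 2 (time, od) pairs of equal length")
  }
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(od < 0, na.rm = TRUE)) stop("od must be non-negative")
  keep <- is.finite(od) & od >= window$od_min & od <= window$od_max &
    times >= window$t_min & times <= window$t_max & od > 0
  n <- sum(keep)
  if (n < window$min_points) {
    return(structure(list(rate = NA_real_, accepted = FALSE,
                          reason = sprintf("only %d qualifying points (min %d)",
                                           n, window$min_points),
                          n_points = n, r_squared = NA_real_,
                          intercept = NA_real_),
                     class = "growth_fit"))
  }
  x <- times[keep]; y <- log(od[keep])
  fit <- stats::lm.fit(cbind(1, x), y)
  rate <- unname(fit$coefficients[2])
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  if (is.finite(r2) && r2 < r2_warn) {
    warning(sprintf("growth fit R^2 = %.3f below %.2f", r2, r2_warn))
  }
  structure(list(rate = rate, accepted = TRUE, reason = "ok", n_points = n,
                 r_squared = r2, intercept = unname(fit$coefficients[1])),
            class = "growth_fit")
}

#' Fit growth rates for a long-format OD table
#'
#' Input columns: `gene1`, `gene2`, `environment`, `replicate`, `time_min`,
#' `od` (the layout written by [generate_od_curves()]). One fit per strain x
#' environment x replicate; rejected replicates are dropped from the rate
#' table and reported in the `rejections` attribute.
#'
#' @param curves data.frame of OD readings.
#' @param windows either a single [fit_window()] or a named list of windows
#'   keyed by environment (per-environment `min_points`, e.g. stricter in the
#'   drug environment).
#' @return data.frame `strain`, `gene1`, `gene2`, `environment`, `replicate`,
#'   `rate`, with attribute `rejections`.
#' @export
fit_od_table <- function(curves, windows = fit_window()) {
  stopifnot(all(c("gene1", "gene2", "environment", "replicate", "time_min",
                  "od") %in% names(curves)))
  win_for <- function(env) {
    if (inherits(windows, "fit_window")) return(windows)
    w <- windows[[env]]
    if (is.null(w)) stop("no fit window for environment ", env)
    w
  }
  curves$.strain <- pair_key(ifelse(is.na(curves$gene1), "", curves$gene1),
                             ifelse(is.na(curves$gene2), "", curves$gene2))
  parts <- split(curves, list(curves$.strain, curves$environment,
                              curves$replicate), drop = TRUE)
  rows <- vector("list", length(parts))
  rej <- list()
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    p <- p[order(p$time_min), ]
    f <- fit_growth_rate(p$time_min, p$od, win_for(p$environment[1]))
    if (f$accepted) {
      rows[[i]] <- data.frame(strain = p$.strain[1], gene1 = p$gene1[1],
                              gene2 = p$gene2[1],
                              environment = p$environment[1],
                              replicate = p$replicate[1], rate = f$rate,
                              stringsAsFactors = FALSE)
    } else {
      rej[[length(rej) + 1]] <- data.frame(strain = p$.strain[1],
                                           environment = p$environment[1],
                                           replicate = p$replicate[1],
                                           reason = f$reason,
                                           stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  attr(out, "rejections") <- if (length(rej)) do.call(rbind, rej) else NULL
  out
}

#' Summarise replicate growth rates
#'
#' @param rates numeric vector of accepted per-replicate rates, length >= 1.
#' @return list `mean`, `cv`, `n`, `cv_unestimable`. With a single replicate
#'   the cv is `NA` and flagged unestimable (never reported as 0); downstream
#'   significance testing substitutes the library-median cv.
#' @export
summarize_replicates <- function(rates) {
  rates <- as.numeric(rates)
  if (length(rates) == 0) stop("no accepted replicates to summarise")
  m <- mean(rates)
  if (m <= 0) stop("mean replicate rate must be positive")
  if (length(rates) == 1) {
    return(list(mean = m, cv = NA_real_, n = 1L, cv_unestimable = TRUE))
  }
  list(mean = m, cv = stats::sd(rates) / m, n = length(rates),
       cv_unestimable = FALSE)
}

#' Collapse a per-replicate rate table into a phenotype table
#'
#' @param rates data.frame with columns `gene1`, `gene2`, `environment`,
#'   `rate` (one row per replicate), as produced by [fit_od_table()] or
#'   [generate_library()].
#' @return a `phenotype_table`.
#' @export
summarize_rate_table <- function(rates) {
  stopifnot(all(c("gene1", "gene2", "environment", "rate") %in% names(rates)))
  strain <- pair_key(ifelse(is.na(rates$gene1), "", rates$gene1),
                     ifelse(is.na(rates$gene2), "", rates$gene2))
  parts <- split(rates, list(strain, rates$environment), drop = TRUE)
  rows <- lapply(parts, function(p) {
    s <- summarize_replicates(p$rate)
    data.frame(gene1 = p$gene1[1], gene2 = p$gene2[1],
               environment = p$environment[1], rate = s$mean, cv = s$cv,
               n = s$n, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  phenotype_table(df$gene1, df$gene2, df$environment, df$rate, df$cv, df$n)
}

#' Pooled estimation of a single-mutant growth rate from its double mutants
#'
#' For gene X with assayed double-mutant partners Y_i, each partner supplies
#' an estimate `mu_i = m(X,Y_i) * m(wt) / m(Y_i)` of the X single-mutant rate
#' under the hypothesis of no epistasis with Y_i; the estimate is the median
#' of the mu_i, which is robust to a minority of true interactions. Partners
#' whose own single-mutant rate is missing are skipped and reported.
#'
#' @param gene gene symbol.
#' @param phenotypes a `phenotype_table` containing the wildtype, partner
#'   singles and the doubles involving `gene`.
#' @param environment environment name to estimate in.
#' @param measured optional measured single-mutant rate; when supplied, the
#'   estimate is compared against it and `deviation_flag` set when the
#'   relative deviation exceeds `flag_threshold`.
#' @param flag_threshold relative deviation that raises the flag (default 5%).
#' @return list `gene`, `environment`, `mu` (named by partner), `estimate`,
#'   `n_partners`, `skipped`, `deviation`, `deviation_flag`.
#' @export
estimate_single_from_doubles <- function(gene, phenotypes, environment,
                                         measured = NULL,
                                         flag_threshold = 0.05) {
  gene <- toupper(gene)
  ph <- phenotypes[phenotypes$environment == environment, ]
  wt <- ph$rate[ph$strain == "WT"]
  if (length(wt) != 1) stop("wildtype rate missing in environment ",
                            environment)
  dbl <- ph[n_deletions(ph$strain) == 2 &
              (ph$gene1 == gene | ph$gene2 == gene), ]
  if (nrow(dbl) == 0) stop("gene ", gene, " has no assayed double-mutant ",
                           "partners in environment ", environment)
  partner <- ifelse(dbl$gene1 == gene, dbl$gene2, dbl$gene1)
  singles <- ph[n_deletions(ph$strain) == 1, ]
  mu <- numeric(0); skipped <- character(0)
  for (i in seq_along(partner)) {
    m_y <- singles$rate[singles$gene1 == partner[i]]
    if (length(m_y) != 1) { skipped <- c(skipped, partner[i]); next }
    mu <- c(mu, stats::setNames(dbl$rate[i] * wt / m_y, partner[i]))
  }
  if (length(mu) == 0) {
    stop("no partner of ", gene, " has a measured single-mutant rate")
  }
  est <- stats::median(mu)
  dev <- if (!is.null(measured)) abs(est - measured) / measured else NA_real_
  list(gene = gene, environment = environment, mu = mu, estimate = est,
       n_partners = length(mu), skipped = skipped, deviation = dev,
       deviation_flag = isTRUE(dev > flag_threshold))
}

#' Replace measured single-mutant rates by pooled estimates
#'
#' For each gene on the override list, the single-mutant mean rate in each
#' environment is replaced by [estimate_single_from_doubles()]; cv and n are
#' kept from the measured record (the estimate reuses the same replicate
#' structure). Used for strains whose directly measured rates are suspected
#' of carrying systematic bias.
#'
#' @param phenotypes a `phenotype_table`.
#' @param genes character vector of genes to override.
#' @return the modified `phenotype_table`.
#' @export
apply_estimated_singles <- function(phenotypes, genes) {
  for (g in toupper(genes)) {
    for (env in unique(phenotypes$environment)) {
      i <- which(phenotypes$strain == g & phenotypes$environment == env)
      if (length(i) != 1) next
      est <- estimate_single_from_doubles(g, phenotypes, env)
      phenotypes$rate[i] <- est$estimate
    }
  }
  phenotypes
}
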