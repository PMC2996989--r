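check_positive <- function(...) {
  vals <- c(...)
  if (any(!is.finite(vals) | vals <= 0)) {
    stop("growth rates and sensitivities must be positive and finite")
  }
  invisible(vals)
}

#' Multiplicative neutrality: expected double-mutant growth rate
#'
#' Under the multiplicative (Fisher) neutrality model the double mutant's
#' growth rate, absent epistasis, is `m_x * m_y / m_wt`.
#'
#' @param m_x,m_y,m_wt positive growth rates of the two singles and wildtype.
#' @return expected double-mutant rate (vectorised).
#' @export
expected_double_rate <- function(m_x, m_y, m_wt) {
  check_positive(m_x, m_y, m_wt)
  m_x * m_y / m_wt
}

#' Fitness-based epistasis score (F-score)
#'
#' Relative deviation of the observed double-mutant rate from the
#' multiplicative expectation within one environment:
#' `epsilon = m_xy * m_wt / (m_x * m_y) - 1`. Positive = alleviating,
#' negative = aggravating; symmetric in the two singles.
#'
#' @param m_xy observed double-mutant rate.
#' @param m_x,m_y,m_wt single-mutant and wildtype rates.
#' @return epsilon (vectorised).
#' @examples
#' f_score(0.72, 0.8, 0.9, 1.0)  # 0: exactly multiplicative
#' f_score(0.36, 0.8, 0.9, 1.0)  # -0.5: aggravating
#' @export
f_score <- function(m_xy, m_x, m_y, m_wt) {
  check_positive(m_xy, m_x, m_y, m_wt)
  m_xy * m_wt / (m_x * m_y) - 1
}

#' Environmental sensitivity of a strain
#'
#' `S = m(E1) / m(E2)`, the ratio of the strain's growth rate in the
#' reference environment to its rate in the perturbed environment; a strain
#' hurt by the perturbation has S > 1. Replicate CVs, when supplied, are
#' propagated to first order: `cv_S = sqrt(cv_e1^2 + cv_e2^2)`.
#'
#' @param m_e1,m_e2 positive rates in the reference and perturbed environment.
#' @param cv_e1,cv_e2 optional CVs of the two rates.
#' @return list of class `sensitivity_record`: `s`, `cv`.
#' @export
sensitivity <- function(m_e1, m_e2, cv_e1 = NA_real_, cv_e2 = NA_real_) {
  if (any(is.na(m_e1)) || any(is.na(m_e2))) {
    return(structure(list(s = NA_real_, cv = NA_real_),
                     class = "sensitivity_record"))
  }
  check_positive(m_e1, m_e2)
  cv <- if (all(is.na(c(cv_e1, cv_e2)))) NA_real_ else
    sqrt(ifelse(is.na(cv_e1), 0, cv_e1)^2 + ifelse(is.na(cv_e2), 0, cv_e2)^2)
  structure(list(s = m_e1 / m_e2, cv = cv), class = "sensitivity_record")
}

s_of <- function(x) if (inherits(x, "sensitivity_record")) x$s else x

#' Environmental sensitivity score (ES-score)
#'
#' `epsilon_env = S(reference) / S(mutant) - 1` quantifies the relative
#' change in environmental sensitivity caused by a deletion. The reference is
#' the wildtype for a single mutant, or the Y single mutant when scoring
#' deletion of X in a Y-deleted background. Zero iff the deletion leaves
#' sensitivity unchanged; a mutant hypersensitive to the perturbation (larger
#' S) gets a negative score.
#'
#' @param s_mutant,s_reference sensitivities (numbers or
#'   [sensitivity()] records).
#' @return epsilon, or `NA` if either sensitivity is undefined.
#' @export
es_score <- function(s_mutant, s_reference) {
  sm <- s_of(s_mutant); sr <- s_of(s_reference)
  if (any(is.na(sm)) || any(is.na(sr))) return(NA_real_)
  check_positive(sm, sr)
  sr / sm - 1
}

#' Multiplicative neutrality on sensitivities
#'
#' Expected double-mutant sensitivity absent epistasis:
#' `s_x * s_y / s_wt`, the direct analogue of [expected_double_rate()] with
#' the environmental perturbation treated as a third "mutation".
#'
#' @param s_x,s_y,s_wt positive sensitivities.
#' @export
expected_double_sensitivity <- function(s_x, s_y, s_wt) {
  s_x <- s_of(s_x); s_y <- s_of(s_y); s_wt <- s_of(s_wt)
  check_positive(s_x, s_y, s_wt)
  s_x * s_y / s_wt
}

#' Sensitivity-based epistasis score (S-score)
#'
#' `epsilon_sen = s_xy * s_wt / (s_x * s_y) - 1`: relative deviation of the
#' double mutant's sensitivity from the multiplicative sensitivity
#' expectation. Identically zero when the fitness interaction is the same in
#' both environments, so a nonzero S-score flags an interaction that is
#' modulated by the environmental change. Satisfies the identity
#' `epsilon_sen = (1 + epsilon_fit(E1)) / (1 + epsilon_fit(E2)) - 1`
#' when all scores are computed from the same mean rates.
#'
#' @param s_xy,s_x,s_y,s_wt positive sensitivities (numbers or records).
#' @return epsilon, `NA` if any input undefined.
#' @export
s_score <- function(s_xy, s_x, s_y, s_wt) {
  s_xy <- s_of(s_xy); s_x <- s_of(s_x); s_y <- s_of(s_y); s_wt <- s_of(s_wt)
  if (any(is.na(c(s_xy, s_x, s_y, s_wt)))) return(NA_real_)
  check_positive(s_xy, s_x, s_y, s_wt)
  s_xy * s_wt / (s_x * s_y) - 1
}

rate_lookup <- function(phenotypes) {
  function(strain, env) {
    r <- phenotypes$rate[phenotypes$strain == strain &
                           phenotypes$environment == env]
    if (length(r) == 1) r else NA_real_
  }
}

#' Score a deletion library
#'
#' Computes the requested score families over every assayable strain/pair of
#' a two-environment phenotype table. F-scores are computed per environment
#' for every double mutant with both singles and the wildtype present;
#' ES-scores per single mutant (cross-environment); S-scores per double
#' mutant (cross-environment). Pairs or genes with missing required rates are
#' skipped and listed in the `skipped` attribute. `p_value` is `NA` until
#' [score_significance()] fills it in.
#'
#' @param phenotypes a `phenotype_table` covering both environments.
#' @param e1,e2 names of the reference and perturbed environment.
#' @param families subset of `c("F", "ES", "S")`.
#' @param estimate_singles optional character vector of genes whose measured
#'   single-mutant rates are replaced by pooled estimates
#'   ([apply_estimated_singles()]) before scoring.
#' @return data.frame of class `epistasis_scores` with columns `pair`,
#'   `gene1`, `gene2`, `family`, `environment` (`e1`/`e2` for F, `"cross"`
#'   for ES and S), `epsilon`, `p_value`.
#' @export
score_library <- function(phenotypes, e1, e2, families = c("F", "ES", "S"),
                          estimate_singles = NULL) {
  if (length(families) > 0) {
    families <- match.arg(families, c("F", "ES", "S"), several.ok = TRUE)
  }
  envs <- unique(phenotypes$environment)
  if (!all(c(e1, e2) %in% envs)) {
    stop("environments ", e1, "/", e2, " not both present in the table")
  }
  if (!is.null(estimate_singles) && length(estimate_singles) > 0) {
    phenotypes <- apply_estimated_singles(phenotypes, estimate_singles)
  }
  rate <- rate_lookup(phenotypes)
  if (is.na(rate("WT", e1)) || is.na(rate("WT", e2))) {
    stop("wildtype missing: both environments require a WT row")
  }
  singles <- sort(unique(phenotypes$gene1[n_deletions(phenotypes$strain) == 1]))
  dbl_keys <- sort(unique(phenotypes$strain[n_deletions(phenotypes$strain) == 2]))
  rows <- list(); skipped <- list()
  add <- function(gene1, gene2, family, env, eps) {
    rows[[length(rows) + 1]] <<- data.frame(
      pair = strain_key(c(gene1, gene2)), gene1 = gene1,
      gene2 = if (is.na(gene2)) NA_character_ else gene2, family = family,
      environment = env, epsilon = eps, p_value = NA_real_,
      stringsAsFactors = FALSE)
  }
  skip <- function(what, family, why) {
    skipped[[length(skipped) + 1]] <<- data.frame(
      target = what, family = family, reason = why, stringsAsFactors = FALSE)
  }
  if ("F" %in% families) {
    for (key in dbl_keys) {
      g <- key_genes(key)
      for (env in c(e1, e2)) {
        m <- c(rate(key, env), rate(g[1], env), rate(g[2], env),
               rate("WT", env))
        if (any(is.na(m))) { skip(key, "F", paste("missing rate in", env)); next }
        add(g[1], g[2], "F", env, f_score(m[1], m[2], m[3], m[4]))
      }
    }
  }
  if ("ES" %in% families) {
    s_wt <- sensitivity(rate("WT", e1), rate("WT", e2))
    for (g in singles) {
      s_g <- sensitivity(rate(g, e1), rate(g, e2))
      if (is.na(s_g$s)) { skip(g, "ES", "missing rate in one environment"); next }
      add(g, NA_character_, "ES", "cross", es_score(s_g, s_wt))
    }
  }
  if ("S" %in% families) {
    s_wt <- sensitivity(rate("WT", e1), rate("WT", e2))
    for (key in dbl_keys) {
      g <- key_genes(key)
      s_xy <- sensitivity(rate(key, e1), rate(key, e2))
      s_x <- sensitivity(rate(g[1], e1), rate(g[1], e2))
      s_y <- sensitivity(rate(g[2], e1), rate(g[2], e2))
      eps <- s_score(s_xy, s_x, s_y, s_wt)
      if (is.na(eps)) { skip(key, "S", "undefined sensitivity"); next }
      add(g[1], g[2], "S", "cross", eps)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pair = character(0), gene1 = character(0),
               gene2 = character(0), family = character(0),
               environment = character(0), epsilon = numeric(0),
               p_value = numeric(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else NULL
  attr(out, "environments") <- c(e1 = e1, e2 = e2)
  class(out) <- c("epistasis_scores", "data.frame")
  out
}
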