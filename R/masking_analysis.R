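#' Phenotypic-masking equivalence statistic for one directed pair
#'
#' Masking of gene Y's phenotype by an upstream gene X shows up as the double
#' mutant resembling the X single mutant. With sensitivity phenotypes this
#' means the pair's S-score equals the ES-score of the *masked* gene:
#' `delta = |epsilon_sen - epsilon_env(Y)|`. With fitness phenotypes the
#' equivalent condition is `epsilon_fit = W_wt/W_Y - 1` (relative fitness W
#' measured in the chosen environment), so
#' `delta = |epsilon_fit - (m_wt/m_Y - 1)|`.
#'
#' @param masker,masked gene symbols (X upstream masking Y downstream).
#' @param scores an `epistasis_scores` table containing the required family
#'   rows (S and ES for the S family; F for the F family).
#' @param phenotypes the `phenotype_table` (needed for the F family's
#'   single-mutant fitness).
#' @param family `"S"` or `"F"`.
#' @param environment environment for the F family (typically the perturbed
#'   one).
#' @return list `delta` (`NA` when a required score is missing), `epsilon`
#'   (the pair score), `reference` (the equivalence target).
#' @export
masking_delta <- function(masker, masked, scores, phenotypes = NULL,
                          family = c("S", "F"), environment = NULL) {
  family <- match.arg(family)
  masker <- toupper(masker); masked <- toupper(masked)
  pr <- strain_key(c(masker, masked))
  if (family == "S") {
    eps <- scores$epsilon[scores$family == "S" & scores$pair == pr]
    ref <- scores$epsilon[scores$family == "ES" & scores$gene1 == masked]
    if (length(eps) != 1 || length(ref) != 1) {
      return(list(delta = NA_real_, epsilon = NA_real_,
                  reference = NA_real_))
    }
  } else {
    if (is.null(phenotypes) || is.null(environment)) {
      stop("F-family masking needs phenotypes and an environment")
    }
    eps <- scores$epsilon[scores$family == "F" & scores$pair == pr &
                            scores$environment == environment]
    m_wt <- phenotypes$rate[phenotypes$strain == "WT" &
                              phenotypes$environment == environment]
    m_y <- phenotypes$rate[phenotypes$strain == masked &
                             phenotypes$environment == environment]
    if (length(eps) != 1 || length(m_wt) != 1 || length(m_y) != 1) {
      return(list(delta = NA_real_, epsilon = NA_real_,
                  reference = NA_real_))
    }
    ref <- m_wt / m_y - 1
  }
  list(delta = abs(eps - ref), epsilon = eps, reference = ref)
}

default_alleviating_sign <- function(family) {
  # Within-complex masking shows up as environment-enhanced alleviating
  # interactions: negative S-scores; with fitness phenotypes the standard
  # convention is positive epsilon_fit = alleviating.
  if (family == "S") -1 else 1
}

#' Detect directional phenotypic masking within declared complexes
#'
#' Evaluates both directions of every assayed within-complex pair. A
#' direction is called masking when the pairwise interaction is alleviating
#' (sign per family convention, overridable), significant at `alpha`, and the
#' equivalence statistic [masking_delta()] falls strictly below `delta_thr`.
#'
#' @param complexes a `complex_list` (or named list of gene vectors).
#' @param scores an `epistasis_scores` table with P-values for the pair
#'   family.
#' @param phenotypes `phenotype_table` (F family only).
#' @param family `"S"` or `"F"`.
#' @param delta_thr equivalence threshold.
#' @param alpha significance gate on the pairwise interaction (strict `<`).
#' @param environment environment for the F family.
#' @param alleviating_sign `+1` or `-1`; the sign of epsilon that counts as
#'   alleviating for this family (default: -1 for S, +1 for F).
#' @return data.frame of class `masking_records`: `complex`, `masker`,
#'   `masked`, `family`, `delta`, `epsilon`, `p_value`, `is_masking`.
#'   Directions with missing scores are kept with `NA` delta and
#'   `is_masking = FALSE`.
#' @export
detect_masking <- function(complexes, scores, phenotypes = NULL,
                           family = c("S", "F"), delta_thr = 0.1,
                           alpha = 0.05, environment = NULL,
                           alleviating_sign = NULL) {
  family <- match.arg(family)
  if (is.null(alleviating_sign)) {
    alleviating_sign <- default_alleviating_sign(family)
  }
  rows <- list()
  for (cx in names(complexes)) {
    members <- toupper(complexes[[cx]])
    for (x in members) for (y in members) {
      if (x == y) next
      rows[[length(rows) + 1]] <- masking_record(
        cx, x, y, scores, phenotypes, family, delta_thr, alpha,
        environment, alleviating_sign)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("masking_records", "data.frame")
  out
}

masking_record <- function(cx, x, y, scores, phenotypes, family, delta_thr,
                           alpha, environment, alleviating_sign) {
  pr <- strain_key(c(x, y))
  md <- masking_delta(x, y, scores, phenotypes, family, environment)
  p <- if (family == "S") {
    scores$p_value[scores$family == "S" & scores$pair == pr]
  } else {
    scores$p_value[scores$family == "F" & scores$pair == pr &
                     scores$environment == environment]
  }
  p <- if (length(p) == 1) p else NA_real_
  is_mask <- !is.na(md$delta) && !is.na(p) &&
    sign(md$epsilon) == alleviating_sign && p < alpha && md$delta < delta_thr
  data.frame(complex = cx, masker = x, masked = y, family = family,
             delta = md$delta, epsilon = md$epsilon, p_value = p,
             is_masking = is_mask, stringsAsFactors = FALSE)
}

#' Masking recovery curve over the equivalence threshold
#'
#' Sweeps `delta_thr` over a grid and reports, per grid point, the true
#' positive rate over the expected within-complex directed interactions and
#' the false positive rate over all other assayed directed pairs. Unassayed
#' directions are excluded from numerator and denominator.
#'
#' @param complexes a `complex_list`; the expected set is every ordered pair
#'   within a complex that is assayed.
#' @param scores an `epistasis_scores` table with P-values covering the whole
#'   library (used both for the expected directions and the background).
#' @inheritParams detect_masking
#' @param delta_grid non-empty numeric grid of thresholds.
#' @return data.frame `delta_thr`, `tpr`, `fpr`, `family`,
#'   `n_expected`, `n_background`.
#' @export
recovery_curve <- function(complexes, scores, phenotypes = NULL,
                           family = c("S", "F"), delta_grid,
                           alpha = 0.05, environment = NULL,
                           alleviating_sign = NULL) {
  family <- match.arg(family)
  if (length(delta_grid) == 0) stop("empty delta_thr grid")
  if (is.null(alleviating_sign)) {
    alleviating_sign <- default_alleviating_sign(family)
  }
  pair_fam <- if (family == "S") "S" else "F"
  prows <- scores[scores$family == pair_fam, ]
  if (family == "F") prows <- prows[prows$environment == environment, ]
  expected_pairs <- character(0)
  for (cx in names(complexes)) {
    members <- toupper(complexes[[cx]])
    cmb <- utils::combn(members, 2)
    expected_pairs <- c(expected_pairs, pair_key(cmb[1, ], cmb[2, ]))
  }
  # directions: one row per ordered (masker, masked) over all assayed pairs
  dirs <- do.call(rbind, lapply(seq_len(nrow(prows)), function(i) {
    g <- key_genes(prows$pair[i])
    data.frame(masker = c(g[1], g[2]), masked = c(g[2], g[1]),
               pair = prows$pair[i], stringsAsFactors = FALSE)
  }))
  dirs$expected <- dirs$pair %in% expected_pairs
  stat <- lapply(seq_len(nrow(dirs)), function(i) {
    md <- masking_delta(dirs$masker[i], dirs$masked[i], scores, phenotypes,
                        family, environment)
    p <- prows$p_value[prows$pair == dirs$pair[i]]
    c(delta = md$delta, eps = md$epsilon,
      p = if (length(p) == 1) p else NA_real_)
  })
  stat <- do.call(rbind, stat)
  gate <- !is.na(stat[, "delta"]) & !is.na(stat[, "p"]) &
    sign(stat[, "eps"]) == alleviating_sign & stat[, "p"] < alpha
  n_exp <- sum(dirs$expected & !is.na(stat[, "delta"]))
  n_bg <- sum(!dirs$expected & !is.na(stat[, "delta"]))
  if (n_exp == 0) stop("no assayed expected directions")
  out <- do.call(rbind, lapply(sort(delta_grid), function(thr) {
    hit <- gate & stat[, "delta"] < thr
    data.frame(delta_thr = thr,
               tpr = sum(hit & dirs$expected) / n_exp,
               fpr = if (n_bg > 0) sum(hit & !dirs$expected) / n_bg else
                 NA_real_,
               family = family, n_expected = n_exp, n_background = n_bg,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
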