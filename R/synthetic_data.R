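#' Specification of a synthetic two-environment deletion library
#'
#' Defines the generative truth for a wildtype + single + double deletion
#' library in a reference (`E1`) and perturbed (`E2`) environment. Single
#' mutants have per-environment relative fitness; double-mutant true rates
#' follow the multiplicative expectation perturbed by planted interactions:
#' `m(X,Y,E) = (1 + eps_fit(E)) * m(X,E) * m(Y,E) / m(wt,E)`. Replicate
#' rates are drawn as `mean * (1 + Normal(0, cv))`, truncated positive
#' (lognormal noise available via `noise`).
#'
#' @param genes gene symbols, or an integer count (symbols `G01`, `G02`, ...).
#' @param wt_rate named vector `c(E1=, E2=)` of wildtype rates (1/min).
#' @param single_effects matrix (genes x 2, columns E1/E2) of relative
#'   fitness values in (0, 1]; default all 1.
#' @param planted data.frame `gene1`, `gene2`, `eps_e1`, `eps_e2` of planted
#'   fitness interactions (pairs not listed have eps 0).
#' @param replicate_cv named vector `c(E1=, E2=)` of replicate noise CVs.
#' @param n_replicates named vector `c(wt=, single=, double=)`; defaults to
#'   the screen floor of 19 replicates for wildtype/singles and 4 for
#'   doubles.
#' @param missing_fraction probability that a double mutant is unassayed.
#' @param noise `"normal"` (multiplicative normal, default) or
#'   `"lognormal"`.
#' @param seed integer seed used by [generate_library()].
#' @return list of class `synthetic_library_spec`.
#' @export
synthetic_library_spec <- function(genes = 26,
                                   wt_rate = c(E1 = 0.0077, E2 = 0.0069),
                                   single_effects = NULL, planted = NULL,
                                   replicate_cv = c(E1 = 0.03, E2 = 0.03),
                                   n_replicates = c(wt = 19, single = 19,
                                                    double = 4),
                                   missing_fraction = 0,
                                   noise = c("normal", "lognormal"),
                                   seed = 1L) {
  if (is.numeric(genes) && length(genes) == 1) {
    genes <- sprintf("G%02d", seq_len(genes))
  }
  genes <- toupper(genes)
  if (anyDuplicated(genes)) stop("duplicate gene symbols")
  if (length(genes) < 2) stop("need at least 2 genes")
  stopifnot(length(wt_rate) == 2, all(wt_rate > 0),
            length(replicate_cv) == 2, all(replicate_cv >= 0),
            all(n_replicates >= 1),
            missing_fraction >= 0, missing_fraction < 1)
  envs <- names(wt_rate)
  if (is.null(envs) || any(!nzchar(envs))) envs <- c("E1", "E2")
  names(wt_rate) <- envs
  names(replicate_cv) <- envs
  if (is.null(single_effects)) {
    single_effects <- matrix(1, length(genes), 2,
                             dimnames = list(genes, envs))
  }
  colnames(single_effects) <- envs
  if (!all(rownames(single_effects) == genes) ||
      any(single_effects <= 0)) {
    stop("single_effects must be a positive genes x 2 matrix")
  }
  if (is.null(planted)) {
    planted <- data.frame(gene1 = character(0), gene2 = character(0),
                          eps_e1 = numeric(0), eps_e2 = numeric(0),
                          stringsAsFactors = FALSE)
  }
  planted$gene1 <- toupper(planted$gene1)
  planted$gene2 <- toupper(planted$gene2)
  if (!all(c(planted$gene1, planted$gene2) %in% genes)) {
    stop("planted pairs must lie within the gene set")
  }
  if (any(planted$eps_e1 <= -1) || any(planted$eps_e2 <= -1)) {
    stop("planted eps must be > -1 (double rates must stay positive)")
  }
  structure(list(genes = genes, environments = envs, wt_rate = wt_rate,
                 single_effects = single_effects, planted = planted,
                 replicate_cv = replicate_cv, n_replicates = n_replicates,
                 missing_fraction = missing_fraction,
                 noise = match.arg(noise), seed = as.integer(seed)),
            class = "synthetic_library_spec")
}

draw_replicates <- function(n, mean, cv, noise) {
  if (cv == 0) return(rep(mean, n))
  if (noise == "lognormal") {
    sdlog <- sqrt(log(1 + cv^2))
    return(stats::rlnorm(n, log(mean) - sdlog^2 / 2, sdlog))
  }
  x <- mean * (1 + stats::rnorm(n, 0, cv))
  while (any(x <= 0)) {
    x[x <= 0] <- mean * (1 + stats::rnorm(sum(x <= 0), 0, cv))
  }
  x
}

#' Generate a synthetic deletion library with its planted truth
#'
#' @param spec a [synthetic_library_spec()].
#' @return list of class `synthetic_library`:
#'   * `replicates`: long data.frame `strain`, `gene1`, `gene2`,
#'     `environment`, `replicate`, `rate` (per-replicate rates);
#'   * `phenotypes`: the summarised `phenotype_table`;
#'   * `truth`: list with `pairs` (per assayed pair: `eps_fit_e1`,
#'     `eps_fit_e2`, and the implied `eps_sen`, which satisfies
#'     `eps_sen = (1+eps_fit_e1)/(1+eps_fit_e2) - 1` exactly), `genes`
#'     (true per-gene `eps_env`), and `rates` (true mean rates per strain
#'     and environment);
#'   * `spec`.
#' @export
generate_library <- function(spec) {
  stopifnot(inherits(spec, "synthetic_library_spec"))
  set.seed(spec$seed)
  envs <- spec$environments
  e1 <- envs[1]; e2 <- envs[2]
  genes <- spec$genes
  pairs <- utils::combn(genes, 2)
  assayed <- stats::runif(ncol(pairs)) >= spec$missing_fraction
  planted_key <- pair_key(spec$planted$gene1, spec$planted$gene2)
  eps_for <- function(key, env_idx) {
    i <- match(key, planted_key)
    if (is.na(i)) 0 else
      if (env_idx == 1) spec$planted$eps_e1[i] else spec$planted$eps_e2[i]
  }
  true_rate <- function(strain, env) {
    i <- match(env, envs)
    wt <- spec$wt_rate[[env]]
    g <- key_genes(strain)
    if (length(g) == 0) return(wt)
    if (length(g) == 1) return(spec$single_effects[g, i] * wt)
    mx <- spec$single_effects[g[1], i] * wt
    my <- spec$single_effects[g[2], i] * wt
    (1 + eps_for(strain, i)) * mx * my / wt
  }
  strains <- c("WT", genes, pair_key(pairs[1, assayed], pairs[2, assayed]))
  n_reps <- function(strain) {
    nd <- n_deletions(strain)
    if (nd == 0) spec$n_replicates[["wt"]]
    else if (nd == 1) spec$n_replicates[["single"]]
    else spec$n_replicates[["double"]]
  }
  rows <- list(); truth_rates <- list()
  for (s in strains) {
    g <- key_genes(s)
    for (env in envs) {
      m <- true_rate(s, env)
      reps <- draw_replicates(n_reps(s), m, spec$replicate_cv[[env]],
                              spec$noise)
      rows[[length(rows) + 1]] <- data.frame(
        strain = s, gene1 = if (length(g) >= 1) g[1] else NA_character_,
        gene2 = if (length(g) == 2) g[2] else NA_character_,
        environment = env, replicate = seq_along(reps), rate = reps,
        stringsAsFactors = FALSE)
      truth_rates[[length(truth_rates) + 1]] <- data.frame(
        strain = s, environment = env, rate = m, stringsAsFactors = FALSE)
    }
  }
  replicates <- do.call(rbind, rows)
  rownames(replicates) <- NULL
  phenotypes <- summarize_rate_table(replicates)
  akey <- pair_key(pairs[1, assayed], pairs[2, assayed])
  ef1 <- vapply(akey, eps_for, numeric(1), env_idx = 1)
  ef2 <- vapply(akey, eps_for, numeric(1), env_idx = 2)
  truth_pairs <- data.frame(
    pair = akey, gene1 = pairs[1, assayed], gene2 = pairs[2, assayed],
    eps_fit_e1 = ef1, eps_fit_e2 = ef2,
    eps_sen = (1 + ef1) / (1 + ef2) - 1, stringsAsFactors = FALSE)
  rownames(truth_pairs) <- NULL
  truth_genes <- data.frame(
    gene = genes,
    eps_env = spec$single_effects[, 2] / spec$single_effects[, 1] - 1,
    stringsAsFactors = FALSE)
  rownames(truth_genes) <- NULL
  structure(list(replicates = replicates, phenotypes = phenotypes,
                 truth = list(pairs = truth_pairs, genes = truth_genes,
                              rates = do.call(rbind, truth_rates)),
                 spec = spec),
            class = "synthetic_library")
}

#' @export
print.synthetic_library <- function(x, ...) {
  nd <- n_deletions(unique(x$phenotypes$strain))
  cat(sprintf(paste0("Synthetic library: %d genes, %d assayed doubles, ",
                     "%d planted interactions, environments %s\n"),
              length(x$spec$genes), sum(nd == 2),
              nrow(x$spec$planted),
              paste(x$spec$environments, collapse = "/")))
  invisible(x)
}

#' Generate OD600 time courses from a replicate rate table
#'
#' `OD(t) = od0 * exp(rate * t) * (1 + Normal(0, od_noise_cv))`, sampled on a
#' regular grid, emulating a microplate reader run. Fitting these curves with
#' [fit_growth_rate()] recovers the generating rates (exactly when
#' `od_noise_cv = 0`).
#'
#' @param replicates data.frame with `gene1`, `gene2`, `environment`,
#'   `replicate`, `rate` (e.g. from [generate_library()]).
#' @param od0 initial OD600.
#' @param sampling sampling interval, minutes.
#' @param duration run length, minutes.
#' @param od_noise_cv multiplicative measurement noise CV.
#' @param seed optional RNG seed.
#' @return long data.frame `strain`, `gene1`, `gene2`, `environment`,
#'   `replicate`, `time_min`, `od`.
#' @export
generate_od_curves <- function(replicates, od0 = 0.08, sampling = 15,
                               duration = 600, od_noise_cv = 0,
                               seed = NULL) {
  stopifnot(all(replicates$rate > 0), od0 > 0, sampling > 0)
  if (!is.null(seed)) set.seed(seed)
  tgrid <- seq(0, duration, by = sampling)
  out <- lapply(seq_len(nrow(replicates)), function(i) {
    r <- replicates[i, ]
    od <- od0 * exp(r$rate * tgrid)
    if (od_noise_cv > 0) {
      od <- od * (1 + stats::rnorm(length(od), 0, od_noise_cv))
      od[od < 0] <- 0
    }
    data.frame(strain = if ("strain" %in% names(r)) r$strain else
      pair_key(ifelse(is.na(r$gene1), "", r$gene1),
               ifelse(is.na(r$gene2), "", r$gene2)),
      gene1 = r$gene1, gene2 = r$gene2, environment = r$environment,
      replicate = r$replicate, time_min = tgrid, od = od,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Named synthetic-library presets
#'
#' Four designed study scenarios plus a clustering benchmark:
#' * `"null"`: 26 genes, graded single-mutant fitness defects, no
#'   gene-environment interactions, no planted pairs, ~2.8% of doubles
#'   unassayed. Every F/ES/S score is null.
#' * `"static"`: 20 planted pairs with equal fitness epistasis (+/-0.3) in
#'   both environments: detectable by F-scores, invisible to S-scores.
#' * `"modulated"`: the same 20 pairs with epistasis only in the perturbed
#'   environment (eps 0 in E1, -/+0.4 in E2): the S-score's target class.
#' * `"complex"`: three complexes (3 + 4 + 3 genes) whose members share a
#'   common environmental-sensitivity ratio and whose double mutants inherit
#'   the single-mutant sensitivity (co-equivalent phenotypic masking planted
#'   on sensitivity, alleviating negative S-scores); fitness masking does not
#'   hold. The complex membership is attached as attribute `complexes`.
#' * `"modules"`: 8 genes in two 4-gene modules, within-module S-score -0.4,
#'   between-module +0.3, replicate CV 0.02; attribute `modules` holds the
#'   planted partition.
#'
#' @param name preset name.
#' @param seed seed stored in the spec.
#' @param replicate_cv optional named vector overriding the preset's
#'   replicate noise CVs (e.g. `c(E1 = 0, E2 = 0)` for noiseless closure
#'   checks).
#' @return a `synthetic_library_spec`.
#' @export
standard_scenarios <- function(name = c("null", "static", "modulated",
                                        "complex", "modules"), seed = 1L,
                               replicate_cv = NULL) {
  name <- match.arg(name)
  if (!is.null(replicate_cv)) {
    spec <- standard_scenarios(name, seed = seed)
    cv <- spec$replicate_cv
    cv[] <- replicate_cv
    spec2 <- synthetic_library_spec(
      spec$genes, wt_rate = spec$wt_rate,
      single_effects = spec$single_effects, planted = spec$planted,
      replicate_cv = cv, n_replicates = spec$n_replicates,
      missing_fraction = spec$missing_fraction, noise = spec$noise,
      seed = spec$seed)
    for (a in c("complexes", "modules")) {
      if (!is.null(attr(spec, a))) attr(spec2, a) <- attr(spec, a)
    }
    return(spec2)
  }
  base_genes <- sprintf("G%02d", 1:26)
  graded <- function(genes, lo = 0.75, hi = 1.0) {
    f <- seq(lo, hi, length.out = length(genes))
    matrix(c(f, f), ncol = 2, dimnames = list(genes, c("E1", "E2")))
  }
  twenty_pairs <- function() {
    p1 <- cbind(sprintf("G%02d", seq(1, 25, 2)), sprintf("G%02d", seq(2, 26, 2)))
    p2 <- cbind(sprintf("G%02d", seq(2, 14, 2)), sprintf("G%02d", seq(3, 15, 2)))
    rbind(p1, p2)[1:20, ]
  }
  if (name == "null") {
    return(synthetic_library_spec(base_genes,
                                  single_effects = graded(base_genes),
                                  missing_fraction = 0.028, seed = seed))
  }
  if (name == "static") {
    pp <- twenty_pairs()
    eps <- rep(c(0.3, -0.3), 10)
    planted <- data.frame(gene1 = pp[, 1], gene2 = pp[, 2], eps_e1 = eps,
                          eps_e2 = eps, stringsAsFactors = FALSE)
    return(synthetic_library_spec(base_genes,
                                  single_effects = graded(base_genes),
                                  planted = planted, seed = seed))
  }
  if (name == "modulated") {
    pp <- twenty_pairs()
    eps2 <- rep(c(-0.4, 0.4), 10)
    planted <- data.frame(gene1 = pp[, 1], gene2 = pp[, 2], eps_e1 = 0,
                          eps_e2 = eps2, stringsAsFactors = FALSE)
    return(synthetic_library_spec(base_genes,
                                  single_effects = graded(base_genes),
                                  planted = planted, seed = seed))
  }
  if (name == "complex") {
    complexes <- list(C1 = sprintf("G%02d", 1:3),
                      C2 = sprintf("G%02d", 4:7),
                      C3 = sprintf("G%02d", 8:10))
    rho <- c(C1 = 1.5, C2 = 1.4, C3 = 1.6)
    se <- graded(base_genes)
    # complex members: moderate fitness defects and a shared sensitivity
    # ratio per complex (hypersensitive to the perturbation)
    member_f <- seq(0.80, 0.90, length.out = 10)
    for (cx in names(complexes)) {
      for (g in complexes[[cx]]) {
        i <- match(g, base_genes)
        se[g, "E1"] <- member_f[i]
        se[g, "E2"] <- member_f[i] / rho[[cx]]
      }
    }
    planted <- do.call(rbind, lapply(names(complexes), function(cx) {
      cmb <- utils::combn(complexes[[cx]], 2)
      data.frame(gene1 = cmb[1, ], gene2 = cmb[2, ], eps_e1 = 0,
                 eps_e2 = rho[[cx]] - 1, stringsAsFactors = FALSE)
    }))
    spec <- synthetic_library_spec(base_genes, single_effects = se,
                                   planted = planted, seed = seed)
    attr(spec, "complexes") <- complexes
    return(spec)
  }
  genes <- c(sprintf("M%d", 1:4), sprintf("N%d", 1:4))
  se <- graded(genes, 0.8, 0.95)
  cmb <- utils::combn(genes, 2)
  same <- substr(cmb[1, ], 1, 1) == substr(cmb[2, ], 1, 1)
  eps_sen <- ifelse(same, -0.4, 0.3)
  planted <- data.frame(gene1 = cmb[1, ], gene2 = cmb[2, ], eps_e1 = 0,
                        eps_e2 = 1 / (1 + eps_sen) - 1,
                        stringsAsFactors = FALSE)
  spec <- synthetic_library_spec(genes, single_effects = se,
                                 planted = planted,
                                 replicate_cv = c(E1 = 0.02, E2 = 0.02),
                                 seed = seed)
  attr(spec, "modules") <- list(M = genes[1:4], N = genes[5:8])
  spec
}
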