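order_calls <- function(df) {
  df[order(df$p_value, -abs(df$epsilon), df$pair), , drop = FALSE]
}

new_call_set <- function(df, method, rule) {
  rownames(df) <- NULL
  structure(df, method = method, selection_rule = rule,
            class = c("interaction_calls", "data.frame"))
}

#' @export
print.interaction_calls <- function(x, ...) {
  cat(sprintf("%d %s-score interaction calls (%s)\n", nrow(x),
              attr(x, "method"), attr(x, "selection_rule")))
  print.data.frame(utils::head(x, 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

family_rows <- function(scores, family) {
  rows <- scores[scores$family == family & !is.na(scores$p_value), ,
                 drop = FALSE]
  if (nrow(rows) == 0) stop("no ", family, "-scores with P-values present")
  rows
}

# F-scores come one row per environment; collapse to one row per pair with
# the four-way environment assignment attached.
collapse_f <- function(rows, e1, e2, alpha_assign = 0.01) {
  pairs <- unique(rows$pair)
  get <- function(pair, env) {
    i <- which(rows$pair == pair & rows$environment == env)
    if (length(i) == 1) rows[i, ] else NULL
  }
  out <- lapply(pairs, function(pr) {
    a <- get(pr, e1); b <- get(pr, e2)
    p1 <- if (is.null(a)) NA_real_ else a$p_value
    p2 <- if (is.null(b)) NA_real_ else b$p_value
    best <- if (is.na(p2) || (!is.na(p1) && p1 <= p2)) a else b
    data.frame(pair = pr, gene1 = best$gene1, gene2 = best$gene2,
               family = "F", epsilon = best$epsilon,
               p_value = min(p1, p2, na.rm = TRUE),
               p_e1 = p1, p_e2 = p2,
               environment = assign_environment(
                 ifelse(is.na(p1), 1, p1), ifelse(is.na(p2), 1, p2),
                 alpha_assign),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Call interactions by P-value threshold
#'
#' For the F family, a pair is called when its P-value is below `alpha` in
#' either environment (strict `<`); each call carries the four-way
#' environment assignment computed at `alpha`. For ES/S families the rows
#' are filtered directly. Calls are sorted by ascending P-value (ties by
#' larger |epsilon|, then pair name).
#'
#' @param scores an `epistasis_scores` table with P-values.
#' @param alpha threshold (strict).
#' @param family one of `"F"`, `"ES"`, `"S"`.
#' @param e1,e2 environment names (F family; defaults from the table).
#' @return an `interaction_calls` data.frame.
#' @export
call_by_threshold <- function(scores, alpha = 0.01, family = "S",
                              e1 = NULL, e2 = NULL) {
  rows <- family_rows(scores, family)
  if (family == "F") {
    envs <- attr(scores, "environments")
    if (is.null(e1)) e1 <- envs[["e1"]]
    if (is.null(e2)) e2 <- envs[["e2"]]
    coll <- collapse_f(rows, e1, e2, alpha_assign = alpha)
    calls <- coll[coll$environment != "none", , drop = FALSE]
  } else {
    calls <- rows[rows$p_value < alpha, , drop = FALSE]
  }
  new_call_set(order_calls(calls), family,
               sprintf("P < %g", alpha))
}

#' Call the k most likely interactions
#'
#' The k lowest P-values; ties broken by larger |epsilon|, then
#' lexicographic pair name, so the selection is deterministic.
#'
#' @inheritParams call_by_threshold
#' @param k number of calls, `0 <= k <=` number of scored pairs.
#' @export
call_top_k <- function(scores, k, family = "S", e1 = NULL, e2 = NULL) {
  rows <- family_rows(scores, family)
  if (family == "F") {
    envs <- attr(scores, "environments")
    if (is.null(e1)) e1 <- envs[["e1"]]
    if (is.null(e2)) e2 <- envs[["e2"]]
    rows <- collapse_f(rows, e1, e2)
  }
  if (k > nrow(rows)) {
    stop("k = ", k, " exceeds the ", nrow(rows), " scored pairs")
  }
  calls <- utils::head(order_calls(rows), k)
  new_call_set(calls, family, sprintf("top %d by P", k))
}

#' Overlap between two interaction call sets
#'
#' @param a,b `interaction_calls` over the same pair universe.
#' @return list `shared`, `only_a`, `only_b` (pair vectors) and
#'   `n_shared`, `n_only_a`, `n_only_b`.
#' @export
compare_call_sets <- function(a, b) {
  pa <- unique(a$pair); pb <- unique(b$pair)
  shared <- intersect(pa, pb)
  list(shared = sort(shared), only_a = sort(setdiff(pa, pb)),
       only_b = sort(setdiff(pb, pa)), n_shared = length(shared),
       n_only_a = length(setdiff(pa, pb)),
       n_only_b = length(setdiff(pb, pa)))
}

#' |S-score| versus |F-score difference| per pair
#'
#' For every pair scored by both families, tabulates `|epsilon_sen|` against
#' `|epsilon_fit(E2) - epsilon_fit(E1)|` and reports their Pearson
#' correlation. Because the S-score is (to first order) the relative change
#' in the fitness interaction across environments, pairs whose interaction is
#' environment-modulated populate the upper right of this relation.
#'
#' @param scores an `epistasis_scores` table containing F rows for both
#'   environments and S rows.
#' @param e1,e2 environment names (defaults from the table).
#' @return list `table` (pair, abs_s, abs_df), `correlation` (`NA` with a
#'   `note` when undefined), `n_excluded`.
#' @export
delta_f_vs_s <- function(scores, e1 = NULL, e2 = NULL) {
  envs <- attr(scores, "environments")
  if (is.null(e1)) e1 <- envs[["e1"]]
  if (is.null(e2)) e2 <- envs[["e2"]]
  s_rows <- scores[scores$family == "S", ]
  f1 <- scores[scores$family == "F" & scores$environment == e1, ]
  f2 <- scores[scores$family == "F" & scores$environment == e2, ]
  pairs <- intersect(s_rows$pair, intersect(f1$pair, f2$pair))
  n_excluded <- length(unique(c(s_rows$pair, f1$pair, f2$pair))) -
    length(pairs)
  tab <- data.frame(
    pair = pairs,
    abs_s = abs(s_rows$epsilon[match(pairs, s_rows$pair)]),
    abs_df = abs(f2$epsilon[match(pairs, f2$pair)] -
                   f1$epsilon[match(pairs, f1$pair)]),
    stringsAsFactors = FALSE)
  corr <- NA_real_; note <- NULL
  if (nrow(tab) >= 3 && stats::sd(tab$abs_s) > 0 && stats::sd(tab$abs_df) > 0) {
    corr <- stats::cor(tab$abs_s, tab$abs_df)
  } else {
    note <- "correlation undefined (fewer than 3 pairs or zero variance)"
  }
  list(table = tab, correlation = corr, note = note,
       n_excluded = n_excluded)
}

evidence_pairs <- function(evidence, category = "any") {
  ev <- evidence$evidence
  if (category == "any") unique(ev$pair)
  else {
    if (!category %in% evidence_categories) {
      stop("unknown evidence category: ", category)
    }
    unique(ev$pair[ev$category == category])
  }
}

#' Hypergeometric enrichment of evidence among interaction calls
#'
#' Upper-tail hypergeometric test (including the observed count) for drawing
#' at least `hits_in_calls` evidence-supported pairs in `n_calls` draws from
#' a universe of `universe_size` pairs of which `hits_in_universe` carry the
#' evidence. `fold_R` is the ratio of frequencies
#' `(hits_in_calls/n_calls) / (hits_in_universe/universe)`. The `"any"`
#' category counts a pair once regardless of how many categories support it.
#'
#' @param calls a non-empty `interaction_calls` set within the evidence
#'   universe.
#' @param evidence an `evidence_table`.
#' @param category one of the evidence categories or `"any"`.
#' @return list of class `enrichment_result`: `category`, `hits_in_calls`,
#'   `hits_in_universe`, `n_calls`, `universe`, `fold_R`, `p_value`.
#' @export
enrichment_test <- function(calls, evidence, category = "any") {
  if (nrow(calls) == 0) stop("empty call set")
  pairs <- unique(calls$pair)
  ev <- evidence_pairs(evidence, category)
  N <- evidence$universe_size
  k <- sum(pairs %in% ev); K <- length(ev); n <- length(pairs)
  if (n > N) stop("more calls than pairs in the evidence universe")
  fold <- (k / n) / (K / N)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  structure(list(category = category, hits_in_calls = k,
                 hits_in_universe = K, n_calls = n, universe = N,
                 fold_R = fold, p_value = p), class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("%-14s hits %d/%d (universe %d/%d)  R = %.2f  P = %.3g\n",
              x$category, x$hits_in_calls, x$n_calls, x$hits_in_universe,
              x$universe, x$fold_R, x$p_value))
  invisible(x)
}

#' Co-binding test for two regulators over a differentially expressed universe
#'
#' Upper-tail hypergeometric P-value for the number of genes bound by both
#' regulators, given the sizes of each target set within the universe of
#' differentially expressed genes.
#'
#' @param targets_a,targets_b character vectors of bound genes, subsets of
#'   `de_universe`.
#' @param de_universe character vector of differentially expressed genes.
#' @return P-value.
#' @export
cobinding_test <- function(targets_a, targets_b, de_universe) {
  if (length(de_universe) == 0) stop("empty differential-expression universe")
  u <- unique(toupper(de_universe))
  a <- unique(toupper(targets_a)); b <- unique(toupper(targets_b))
  if (!all(a %in% u) || !all(b %in% u)) {
    stop("target sets must lie within the declared universe")
  }
  k <- length(intersect(a, b))
  stats::phyper(k - 1, length(a), length(u) - length(a), length(b),
                lower.tail = FALSE)
}

#' Predictive value and TPR/FPR across P-value thresholds
#'
#' For each requested score family and each threshold, calls interactions at
#' that threshold and reports the fraction supported by at least one line of
#' evidence (predictive value), plus the true- and false-positive rates over
#' the evidence universe (TPR = evidence pairs called / evidence pairs;
#' FPR = non-evidence pairs called / non-evidence pairs). Thresholds
#' producing zero calls are flagged with `NA` predictive value.
#'
#' @param scores an `epistasis_scores` table with P-values.
#' @param evidence an `evidence_table` covering the scored pair universe.
#' @param alphas thresholds.
#' @param families subset of families present in `scores`.
#' @param e1,e2 environment names for the F family.
#' @return data.frame `family`, `alpha`, `n_calls`, `predictive_value`,
#'   `tpr`, `fpr`.
#' @export
predictive_value_curve <- function(scores, evidence, alphas,
                                   families = c("F", "S"),
                                   e1 = NULL, e2 = NULL) {
  ev_any <- evidence_pairs(evidence, "any")
  N <- evidence$universe_size
  rows <- list()
  for (fam in families) {
    all_pairs <- unique(scores$pair[scores$family == fam])
    n_neg <- N - length(ev_any)
    for (a in alphas) {
      calls <- tryCatch(call_by_threshold(scores, a, fam, e1, e2),
                        error = function(e) NULL)
      pairs <- if (is.null(calls)) character(0) else unique(calls$pair)
      hit <- sum(pairs %in% ev_any)
      rows[[length(rows) + 1]] <- data.frame(
        family = fam, alpha = a, n_calls = length(pairs),
        predictive_value = if (length(pairs) == 0) NA_real_ else
          hit / length(pairs),
        tpr = hit / length(ev_any),
        fpr = (length(pairs) - hit) / n_neg,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
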