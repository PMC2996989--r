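#' Build a gene-by-gene score profile matrix
#'
#' Symmetric matrix of pairwise epsilon values for one score family; the
#' diagonal and unassayed pairs are `NA`. Genes with no scored partner are
#' dropped with a warning; duplicate conflicting scores for a pair are an
#' error.
#'
#' @param scores an `epistasis_scores` table.
#' @param family score family to use (default `"S"`).
#' @return list of class `score_profile`: `genes`, `matrix`.
#' @export
build_profile_matrix <- function(scores, family = "S") {
  rows <- scores[scores$family == family, ]
  if (nrow(rows) == 0) stop("no ", family, "-scores in the table")
  if (anyDuplicated(rows$pair)) {
    dup <- rows$pair[duplicated(rows$pair)]
    bad <- rows[rows$pair %in% dup, ]
    conflict <- tapply(bad$epsilon, bad$pair,
                       function(e) length(unique(e)) > 1)
    if (any(conflict)) {
      stop("conflicting duplicate scores for pair(s): ",
           paste(names(conflict)[conflict], collapse = ", "))
    }
    rows <- rows[!duplicated(rows$pair), ]
  }
  genes <- sort(unique(c(rows$gene1, rows$gene2)))
  m <- matrix(NA_real_, length(genes), length(genes),
              dimnames = list(genes, genes))
  for (i in seq_len(nrow(rows))) {
    m[rows$gene1[i], rows$gene2[i]] <- rows$epsilon[i]
    m[rows$gene2[i], rows$gene1[i]] <- rows$epsilon[i]
  }
  scored <- rowSums(!is.na(m)) > 0
  if (any(!scored)) {
    warning("dropping gene(s) with no scored partner: ",
            paste(genes[!scored], collapse = ", "))
    m <- m[scored, scored, drop = FALSE]
    genes <- genes[scored]
  }
  structure(list(genes = genes, matrix = m), class = "score_profile")
}

#' Correlation-based dissimilarity between score profiles
#'
#' `d(i,j) = 1 - r(i,j)` with r the Pearson correlation of rows i and j of
#' the profile matrix, computed over the partners where both rows are
#' observed, excluding the mutual cells (columns i and j) so the distance is
#' driven by shared third-party profiles. Pairs sharing fewer than
#' `min_shared` partners are flagged unstable (warning); an undefined
#' correlation (fewer than 2 shared partners, or zero variance) is an error
#' naming the pair.
#'
#' @param profile a `score_profile`.
#' @param min_shared minimum shared partners before warning (default 3).
#' @return a `dist` object (values in `[0, 2]`).
#' @export
profile_dissimilarity <- function(profile, min_shared = 3L) {
  m <- profile$matrix
  genes <- profile$genes
  n <- length(genes)
  d <- matrix(0, n, n, dimnames = list(genes, genes))
  unstable <- character(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    use <- setdiff(seq_len(n), c(i, j))
    a <- m[i, use]; b <- m[j, use]
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < min_shared) {
      unstable <- c(unstable, paste0(genes[i], ":", genes[j]))
    }
    if (sum(ok) < 2 || stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) {
      stop("dissimilarity undefined for pair ", genes[i], ":", genes[j],
           " (", sum(ok), " shared partners)")
    }
    d[i, j] <- d[j, i] <- 1 - stats::cor(a[ok], b[ok])
  }
  if (length(unstable) > 0) {
    warning("correlation unstable (fewer than ", min_shared,
            " shared partners) for: ", paste(unstable, collapse = ", "))
  }
  stats::as.dist(d)
}

#' Average-linkage clustering of interaction profiles
#'
#' Hierarchical clustering (UPGMA) of the correlation-based profile
#' dissimilarities, optionally with bootstrap support per internal node
#' obtained by resampling profile columns (partners) with replacement and
#' counting how often each node's leaf set reappears.
#'
#' @param profile a `score_profile` with at least 3 genes.
#' @param n_bootstrap number of column resamples (0 = no support values).
#' @param seed optional RNG seed for the resampling.
#' @param min_shared passed to [profile_dissimilarity()].
#' @return list of class `profile_clust`: `hclust`, `dist`, `support`
#'   (fraction per internal node, `NULL` when `n_bootstrap = 0`),
#'   `n_bootstrap`, `n_failed` (resamples with undefined dissimilarities,
#'   skipped).
#' @export
cluster_profiles <- function(profile, n_bootstrap = 0L, seed = NULL,
                             min_shared = 3L) {
  if (length(profile$genes) < 3) stop("need at least 3 genes to cluster")
  d <- profile_dissimilarity(profile, min_shared)
  hc <- stats::hclust(d, method = "average")
  support <- NULL; n_failed <- 0L
  if (n_bootstrap > 0) {
    if (!is.null(seed)) set.seed(seed)
    target_sets <- node_leaf_sets(hc)
    counts <- numeric(length(target_sets))
    n <- length(profile$genes)
    for (b in seq_len(n_bootstrap)) {
      cols <- sample.int(n, n, replace = TRUE)
      db <- tryCatch(resampled_dissimilarity(profile, cols),
                     error = function(e) NULL)
      if (is.null(db)) { n_failed <- n_failed + 1L; next }
      hb <- stats::hclust(db, method = "average")
      sets <- node_leaf_sets(hb)
      counts <- counts + (target_sets %in% sets)
    }
    used <- n_bootstrap - n_failed
    support <- if (used > 0) counts / used else rep(NA_real_,
                                                    length(counts))
    names(support) <- target_sets
  }
  structure(list(hclust = hc, dist = d, support = support,
                 n_bootstrap = n_bootstrap, n_failed = n_failed),
            class = "profile_clust")
}

# leaf-set signature ("A|B|C", sorted) for every internal node of an hclust
node_leaf_sets <- function(hc) {
  n <- length(hc$labels)
  sets <- vector("list", n - 1)
  for (k in seq_len(n - 1)) {
    leaves <- c()
    for (side in hc$merge[k, ]) {
      leaves <- c(leaves, if (side < 0) hc$labels[-side] else
        strsplit(sets[[side]], "|", fixed = TRUE)[[1]])
    }
    sets[[k]] <- paste(sort(leaves), collapse = "|")
  }
  unlist(sets)
}

resampled_dissimilarity <- function(profile, cols) {
  m <- profile$matrix
  genes <- profile$genes
  n <- length(genes)
  d <- matrix(0, n, n, dimnames = list(genes, genes))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    use <- cols[!(cols %in% c(i, j))]
    a <- m[i, use]; b <- m[j, use]
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 2 || stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) {
      stop("undefined resampled dissimilarity")
    }
    d[i, j] <- d[j, i] <- 1 - stats::cor(a[ok], b[ok])
  }
  stats::as.dist(d)
}

#' @export
print.profile_clust <- function(x, ...) {
  cat("Average-linkage clustering of", length(x$hclust$labels),
      "interaction profiles\n")
  if (!is.null(x$support)) {
    cat(sprintf("bootstrap support over %d resamples (%d failed)\n",
                x$n_bootstrap, x$n_failed))
  }
  invisible(x)
}

#' Export a profile clustering as a Newick tree
#'
#' Branch lengths are the merge heights; bootstrap support values (when
#' present) become internal node labels.
#'
#' @param clust a `profile_clust`.
#' @param path optional file path; when given the tree is written there.
#' @return the Newick string, invisibly when writing to a file.
#' @export
as_newick <- function(clust, path = NULL) {
  phy <- ape::as.phylo(clust$hclust)
  if (!is.null(clust$support)) {
    sets <- node_leaf_sets(clust$hclust)
    phy$node.label <- vapply(seq_len(phy$Nnode), function(k) {
      tips <- ape::extract.clade(phy, k + ape::Ntip(phy))$tip.label
      sig <- paste(sort(tips), collapse = "|")
      i <- match(sig, sets)
      if (is.na(i)) "" else sprintf("%.2f", clust$support[i])
    }, character(1))
  }
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
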