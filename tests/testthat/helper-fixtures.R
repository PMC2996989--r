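# shared fixtures and independent oracles

# minimal two-environment library: wt, two singles, one double, multiplicative
# in E1, aggravating in E2
tiny_phenotypes <- function() {
  phenotype_table(
    gene1 = c(NA, NA, "gx", "gx", "gy", "gy", "gx", "gx"),
    gene2 = c(NA, NA, NA, NA, NA, NA, "gy", "gy"),
    environment = rep(c("E1", "E2"), 4),
    rate = c(1.0, 0.5, 0.8, 0.40, 0.9, 0.45, 0.72, 0.27),
    cv = rep(0.05, 8), n = rep(4L, 8))
}

# hand-built score table with environment attribute, for call/masking tests
make_scores <- function(pair, gene1, gene2, family, environment, epsilon,
                        p_value = NA_real_, e1 = "E1", e2 = "E2") {
  df <- data.frame(pair = pair, gene1 = gene1, gene2 = gene2,
                   family = family, environment = environment,
                   epsilon = epsilon, p_value = p_value,
                   stringsAsFactors = FALSE)
  attr(df, "environments") <- c(e1 = e1, e2 = e2)
  class(df) <- c("epistasis_scores", "data.frame")
  df
}

make_evidence <- function(pairs, categories, universe_size) {
  genes <- t(vapply(strsplit(pairs, ":", fixed = TRUE),
                    function(g) sort(g), character(2)))
  structure(list(
    evidence = data.frame(pair = pairs, gene1 = genes[, 1],
                          gene2 = genes[, 2], category = categories,
                          stringsAsFactors = FALSE),
    universe_size = as.integer(universe_size)),
    class = "evidence_table")
}

# exhaustive-enumeration oracle for the hypergeometric upper tail:
# probability of >= k successes when drawing n from a universe of N
# containing K successes, by enumerating all subsets
enum_hyper_tail <- function(k, K, N, n) {
  subsets <- utils::combn(N, n)
  hits <- colSums(subsets <= K)  # successes are items 1..K
  mean(hits >= k)
}

# adjusted Rand index between two label vectors (Hubert & Arabie)
ari <- function(a, b) {
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(sum(tab), 2)
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) return(1)
  (sum_ij - expected) / (maximum - expected)
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
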