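#' Canonical strain identifier
#'
#' A strain is identified by the set of deleted genes: none (wildtype), one
#' (single deletion) or two (double deletion). Keys are order-insensitive and
#' case-normalised to upper case, so `strain_key(c("swi6", "MSN4"))` and
#' `strain_key(c("MSN4", "SWI6"))` are identical.
#'
#' @param genes character vector of 0--2 gene symbols; `NA` and empty strings
#'   are dropped (a row with blank `gene1`/`gene2` fields is the wildtype).
#' @return a single string: `"WT"`, `"GENE"`, or `"GENEA:GENEB"` with the two
#'   symbols sorted.
#' @examples
#' strain_key(character(0))        # "WT"
#' strain_key(c("msn4", "SWI6"))   # "MSN4:SWI6"
#' @export
strain_key <- function(genes) {
  genes <- toupper(trimws(as.character(genes)))
  genes <- genes[!is.na(genes) & nzchar(genes) & genes != "NA"]
  genes <- unique(genes)
  if (length(genes) > 2) {
    stop("a strain carries at most two deletions, got: ",
         paste(genes, collapse = ", "))
  }
  if (length(genes) == 0) return("WT")
  paste(sort(genes), collapse = ":")
}

#' @rdname strain_key
#' @param g1,g2 vectors of gene symbols (recycled); used to key gene pairs.
#' @export
pair_key <- function(g1, g2) {
  mapply(function(a, b) strain_key(c(a, b)), g1, g2, USE.NAMES = FALSE)
}

key_genes <- function(key) {
  if (identical(key, "WT")) return(character(0))
  strsplit(key, ":", fixed = TRUE)[[1]]
}

is_wildtype_key <- function(key) key == "WT"
n_deletions <- function(key) {
  ifelse(key == "WT", 0L, lengths(strsplit(key, ":", fixed = TRUE)))
}

evidence_categories <- c("buffering", "direct_binding", "shared_target")

read_tsv_raw <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = c("NA", ""))
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop("format error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
  }
}

#' Read a growth-phenotype summary table
#'
#' Tab-delimited with a header and optional `#` comment lines. Required
#' columns: `gene1`, `gene2` (both blank for the wildtype, `gene2` blank for
#' singles), `environment`, `rate` (1/min), `n` (replicate count), and either
#' `cv` (sd/mean of replicate rates) or `sd` (converted to `cv = sd/rate` on
#' read). Gene symbols are upper-cased; a `strain` column, if present, is
#' ignored and recomputed from the gene fields. Missing double mutants are
#' simply absent rows.
#'
#' @param path file path.
#' @return a `phenotype_table`: data.frame with columns `strain`, `gene1`,
#'   `gene2`, `environment`, `rate`, `cv`, `n`.
#' @export
read_phenotype_table <- function(path) {
  df <- read_tsv_raw(path)
  require_columns(df, c("gene1", "gene2", "environment", "rate", "n"), path)
  if (!("cv" %in% names(df)) && !("sd" %in% names(df))) {
    stop("format error in ", path, ": missing column(s) cv (or sd)")
  }
  cv <- if ("cv" %in% names(df)) as.numeric(df$cv) else
    as.numeric(df$sd) / as.numeric(df$rate)
  out <- phenotype_table(
    gene1 = df$gene1, gene2 = df$gene2,
    environment = as.character(df$environment),
    rate = as.numeric(df$rate), cv = cv, n = as.integer(df$n)
  )
  out
}

#' Construct and validate a phenotype table
#'
#' @param gene1,gene2 gene symbols (NA/blank for absent deletions).
#' @param environment environment labels.
#' @param rate mean growth rates (1/min), positive.
#' @param cv coefficient of variation of replicate rates; `NA` allowed when
#'   `n == 1` (flagged unestimable; the significance layer substitutes the
#'   library median).
#' @param n replicate counts, >= 1.
#' @return data.frame of class `phenotype_table`.
#' @export
phenotype_table <- function(gene1, gene2, environment, rate, cv, n) {
  g1 <- toupper(trimws(ifelse(is.na(gene1), "", as.character(gene1))))
  g2 <- toupper(trimws(ifelse(is.na(gene2), "", as.character(gene2))))
  strain <- pair_key(g1, g2)
  out <- data.frame(strain = strain,
                    gene1 = ifelse(nzchar(g1), g1, NA_character_),
                    gene2 = ifelse(nzchar(g2), g2, NA_character_),
                    environment = as.character(environment),
                    rate = as.numeric(rate), cv = as.numeric(cv),
                    n = as.integer(n), stringsAsFactors = FALSE)
  bad_rate <- which(!is.finite(out$rate) | out$rate <= 0)
  if (length(bad_rate) > 0) {
    stop("validation error: non-positive growth rate at row(s) ",
         paste(bad_rate, collapse = ", "))
  }
  bad_cv <- which(!is.na(out$cv) & out$cv < 0)
  if (length(bad_cv) > 0) {
    stop("validation error: negative cv at row(s) ",
         paste(bad_cv, collapse = ", "))
  }
  bad_n <- which(is.na(out$n) | out$n < 1)
  if (length(bad_n) > 0) {
    stop("validation error: replicate count < 1 at row(s) ",
         paste(bad_n, collapse = ", "))
  }
  key <- paste(out$strain, out$environment)
  if (anyDuplicated(key)) {
    stop("validation error: duplicate (strain, environment) at row(s) ",
         paste(which(duplicated(key)), collapse = ", "))
  }
  class(out) <- c("phenotype_table", "data.frame")
  out
}

#' @rdname read_phenotype_table
#' @param x a `phenotype_table`.
#' @export
write_phenotype_table <- function(x, path) {
  stopifnot(inherits(x, "phenotype_table"))
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read an epistasis score table
#'
#' Tab-delimited with columns `gene1`, `gene2`, `score_type` (F/ES/S),
#' `environment` (an environment name for F rows, `cross` for ES/S rows),
#' `epsilon`, `p_value`. Round-trips losslessly at full double precision.
#'
#' @param scores a non-empty `epistasis_scores` data.frame (see
#'   [score_library()]).
#' @param path file path.
#' @export
write_score_table <- function(scores, path) {
  stopifnot(is.data.frame(scores))
  if (nrow(scores) == 0) stop("refusing to write an empty score table")
  out <- data.frame(
    gene1 = scores$gene1,
    gene2 = ifelse(is.na(scores$gene2), "", scores$gene2),
    score_type = scores$family,
    environment = scores$environment,
    epsilon = sprintf("%.17g", scores$epsilon),
    p_value = ifelse(is.na(scores$p_value), "NA",
                     sprintf("%.17g", scores$p_value)),
    stringsAsFactors = FALSE
  )
  con <- file(path, open = "wt")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  df <- read_tsv_raw(path)
  require_columns(df, c("gene1", "gene2", "score_type", "environment",
                        "epsilon", "p_value"), path)
  out <- data.frame(
    pair = pair_key(df$gene1, df$gene2),
    gene1 = toupper(as.character(df$gene1)),
    gene2 = toupper(ifelse(is.na(df$gene2) | df$gene2 == "", NA_character_,
                           as.character(df$gene2))),
    family = as.character(df$score_type),
    environment = as.character(df$environment),
    epsilon = as.numeric(df$epsilon),
    p_value = as.numeric(df$p_value),
    stringsAsFactors = FALSE
  )
  bad <- which(!out$family %in% c("F", "ES", "S"))
  if (length(bad) > 0) {
    stop("validation error: unknown score_type at row(s) ",
         paste(bad, collapse = ", "))
  }
  class(out) <- c("epistasis_scores", "data.frame")
  out
}

#' Read an evidence table of pairwise regulatory support
#'
#' Rows are `(gene1, gene2, category)` with category one of `buffering`,
#' `direct_binding`, `shared_target`. Pairs are keyed unordered, so rows for
#' (A,B) and (B,A) accumulate on the same pair. The universe size (number of
#' pairs tested) is taken from the `universe_size` argument, else from a
#' `# universe_size: <n>` pragma line in the file, else it defaults to the
#' number of distinct pairs listed (with a warning, since evidence files
#' normally list only the supported subset of the tested universe).
#'
#' @param path file path.
#' @param universe_size optional count of pairs tested.
#' @return an `evidence_table`: list with `evidence` (data.frame `pair`,
#'   `gene1`, `gene2`, `category`, deduplicated) and `universe_size`.
#' @export
read_evidence_table <- function(path, universe_size = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(universe_size)) {
    lines <- readLines(path, n = 50L)
    prag <- grep("^#\\s*universe_size\\s*:", lines, value = TRUE)
    if (length(prag) > 0) {
      universe_size <- as.integer(sub("^#\\s*universe_size\\s*:\\s*", "",
                                      prag[1]))
    }
  }
  df <- read_tsv_raw(path)
  require_columns(df, c("gene1", "gene2", "category"), path)
  cat <- as.character(df$category)
  bad <- which(!cat %in% evidence_categories)
  if (length(bad) > 0) {
    stop("validation error: unknown evidence category '", cat[bad[1]],
         "' at row ", bad[1], " (allowed: ",
         paste(evidence_categories, collapse = ", "), ")")
  }
  pair <- pair_key(df$gene1, df$gene2)
  ev <- unique(data.frame(pair = pair, category = cat,
                          stringsAsFactors = FALSE))
  genes <- t(vapply(ev$pair, function(p) key_genes(p), character(2)))
  ev$gene1 <- genes[, 1]
  ev$gene2 <- genes[, 2]
  ev <- ev[, c("pair", "gene1", "gene2", "category")]
  if (is.null(universe_size) || is.na(universe_size)) {
    universe_size <- length(unique(ev$pair))
    warning("universe_size not declared; defaulting to the ",
            universe_size, " distinct pairs listed")
  }
  if (length(unique(ev$pair)) > universe_size) {
    stop("validation error: more distinct pairs listed than universe_size")
  }
  structure(list(evidence = ev, universe_size = as.integer(universe_size)),
            class = "evidence_table")
}

#' @export
print.evidence_table <- function(x, ...) {
  cat("Evidence table:", length(unique(x$evidence$pair)),
      "supported pairs in a universe of", x$universe_size, "tested pairs\n")
  print(table(x$evidence$category))
  invisible(x)
}

#' Read a complex/pathway membership list
#'
#' Tab-delimited with columns `complex_name`, `gene`.
#'
#' @param path file path.
#' @return named list of upper-cased gene vectors, class `complex_list`.
#' @export
read_complex_table <- function(path) {
  df <- read_tsv_raw(path)
  require_columns(df, c("complex_name", "gene"), path)
  out <- lapply(split(toupper(as.character(df$gene)),
                      as.character(df$complex_name)), unique)
  small <- names(out)[lengths(out) < 2]
  if (length(small) > 0) {
    stop("validation error: complex(es) with fewer than 2 members: ",
         paste(small, collapse = ", "))
  }
  structure(out, class = "complex_list")
}
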