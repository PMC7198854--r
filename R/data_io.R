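# Readers and writers for the plain-text dialects the pipeline consumes:
# expression TSV (genes x samples), two-column edge lists, one-symbol-per-line
# gene sets, binary SNV tables (matrix or gene/sample pairs), GISTIC-coded CNV
# matrices, and the ranking TSV the pipeline emits.

read_tsv_quiet <- function(path, ...) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE, ...)
}

#' Read a gene-by-sample expression matrix
#'
#' Expects a TSV with a header row of sample identifiers and gene identifiers
#' in the first column. Values must be numeric, non-negative, and complete:
#' missing entries are a hard error (no imputation is attempted).
#'
#' @param path Path to the TSV file.
#' @param condition Condition label, `"tumor"` or `"normal"`.
#' @return An `expression_matrix` object.
#' @export
read_expression <- function(path, condition = c("tumor", "normal")) {
  condition <- match.arg(condition)
  tab <- read_tsv_quiet(path, col_types = readr::cols(.default = readr::col_character()))
  if (nrow(tab) == 0 || ncol(tab) < 2) {
    abort(sprintf("expression file '%s' has no data rows or no sample columns", path))
  }
  genes <- as.character(tab[[1]])
  if (anyDuplicated(genes)) {
    dups <- unique(genes[duplicated(genes)])
    abort(sprintf("duplicate gene identifier(s) in '%s': %s", path, paste(head(dups, 5), collapse = ", ")))
  }
  vals <- as.matrix(tab[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "non-numeric expression value at gene '%s', sample '%s'",
      genes[bad[1, 1]], colnames(vals)[bad[1, 2]]
    ))
  }
  if (anyNA(num)) {
    miss <- which(is.na(num), arr.ind = TRUE)
    abort(sprintf(
      "missing expression value at gene '%s', sample '%s' (missing values are rejected, not imputed)",
      genes[miss[1, 1]], colnames(vals)[miss[1, 2]]
    ))
  }
  if (any(num < 0)) {
    abort("expression values must be non-negative normalized abundances")
  }
  dimnames(num) <- list(genes, colnames(vals))
  new_expression_matrix(num, condition)
}

#' Write an expression matrix as TSV
#'
#' @param expr An `expression_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  df <- tibble(gene = expr$genes)
  df <- dplyr::bind_cols(df, as_tibble(expr$values))
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a directed edge list
#'
#' Each line holds `source<TAB>target`. Duplicate edges collapse (the
#' adjacency is 0/1) and self-loops are dropped with a warning, since the walk
#' is defined over transitions to distinct neighbors.
#'
#' @param path Path to the two-column TSV edge list (no header).
#' @param directed Must be `TRUE`; the reference network is directed.
#' @return A `directed_network`.
#' @export
read_network <- function(path, directed = TRUE) {
  stopifnot(isTRUE(directed))
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(sprintf("edge list '%s' is empty", path))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 2)) {
    i <- which(nf != 2)[1]
    abort(sprintf("line %d of '%s' has %d field(s); expected 2 (source<TAB>target)", i, path, nf[i]))
  }
  edges <- tibble(
    from = vapply(parts, `[[`, character(1), 1),
    to = vapply(parts, `[[`, character(1), 2)
  )
  directed_network(edges)
}

#' Write a directed network as a two-column edge list
#'
#' @param net A `directed_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  readr::write_tsv(tidy(net), path, col_names = FALSE)
  invisible(path)
}

#' Read a gene set (one symbol per line)
#'
#' Blank lines are ignored and duplicates removed. Identifiers are opaque,
#' case-sensitive strings; no aliasing is applied.
#'
#' @param path Path to the file.
#' @param name Label for the resulting set.
#' @return A `gene_set`.
#' @export
read_gene_set <- function(path, name = basename(path)) {
  lines <- trimws(readr::read_lines(path, progress = FALSE))
  genes <- lines[nzchar(lines)]
  gs <- gene_set(genes, name = name)
  inform(sprintf("gene set '%s': %d unique genes", name, length(gs$genes)))
  gs
}

#' Write a gene set, one symbol per line
#'
#' @param gs A `gene_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_set <- function(gs, path) {
  readr::write_lines(gs$genes, path)
  invisible(path)
}

read_numeric_matrix <- function(path, what) {
  tab <- read_tsv_quiet(path)
  if (nrow(tab) == 0 || ncol(tab) < 2) abort(sprintf("%s file '%s' is empty", what, path))
  genes <- as.character(tab[[1]])
  if (anyDuplicated(genes)) abort(sprintf("duplicate gene identifier(s) in %s file '%s'", what, path))
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  m
}

#' Read a binary SNV table
#'
#' Two dialects are accepted: a gene-by-sample 0/1 matrix (TSV with a header of
#' sample identifiers), or a headerless two-column `gene<TAB>sample` pair list
#' (the reduction of a MAF) which is expanded to the matrix form.
#'
#' @param path Path to the file.
#' @return Binary gene-by-sample matrix.
#' @export
read_snv <- function(path) {
  first <- readr::read_lines(path, n_max = 1, progress = FALSE)
  nfields <- length(strsplit(first, "\t", fixed = TRUE)[[1]])
  peek <- read_tsv_quiet(path, col_names = FALSE, n_max = 5,
                         col_types = readr::cols(.default = readr::col_character()))
  pairlike <- nfields == 2 &&
    all(is.na(suppressWarnings(as.numeric(unlist(peek[, 2])))))
  if (pairlike) {
    pairs <- read_tsv_quiet(path, col_names = c("gene", "sample"),
                            col_types = "cc")
    genes <- sort(unique(pairs$gene))
    samples <- sort(unique(pairs$sample))
    m <- matrix(0, length(genes), length(samples), dimnames = list(genes, samples))
    m[cbind(pairs$gene, pairs$sample)] <- 1
    return(m)
  }
  m <- read_numeric_matrix(path, "SNV")
  if (!all(m %in% c(0, 1))) abort(sprintf("SNV matrix '%s' must be binary 0/1", path))
  m
}

#' Read a GISTIC-thresholded copy-number matrix
#'
#' @param path Path to the TSV; integer values in \{-2, -1, 0, 1, 2\}
#'   (homozygous deletion to high-level amplification).
#' @return Integer gene-by-sample matrix.
#' @export
read_cnv <- function(path) {
  m <- read_numeric_matrix(path, "CNV")
  if (!all(m %in% -2:2)) {
    abort(sprintf("CNV matrix '%s' contains values outside the GISTIC thresholds {-2,...,2}", path))
  }
  m
}

#' Cohort-level mutation status from SNV and CNV tables
#'
#' A gene counts as mutated in a sample if it carries an SNV there, or a
#' copy-number call of +2 (high-level amplification) or -2 (homozygous
#' deletion). Low-level gains/losses (+1/-1) do not count. Status is
#' cohort-level: a gene is mutated if it is mutated in at least one sample.
#'
#' @param snv Binary gene-by-sample matrix (or `NULL`).
#' @param cnv Integer gene-by-sample matrix with values in \{-2,...,2\}
#'   (or `NULL`). Gene/sample universes may differ; absent cells count 0.
#' @return A `mutation_status` tibble with columns `gene`, `mutated`,
#'   `mutated_sample_count`.
#' @export
build_mutation_status <- function(snv = NULL, cnv = NULL) {
  if (is.null(snv) && is.null(cnv)) abort("at least one of snv, cnv is required")
  check_binary <- function(m) {
    if (!is.null(m) && !all(m %in% c(0, 1))) abort("SNV table must be binary 0/1")
  }
  check_binary(snv)
  if (!is.null(cnv) && !all(cnv %in% -2:2)) {
    abort("CNV values must lie in the GISTIC thresholded range {-2,...,2}")
  }
  genes <- sort(union(rownames(snv), rownames(cnv)))
  samples <- sort(union(colnames(snv), colnames(cnv)))
  expand <- function(m) {
    out <- matrix(0, length(genes), length(samples), dimnames = list(genes, samples))
    if (!is.null(m)) out[rownames(m), colnames(m)] <- m
    out
  }
  hit <- (expand(snv) == 1) | (abs(expand(cnv)) == 2)
  counts <- unname(rowSums(hit))
  out <- tibble(
    gene = genes,
    mutated = counts >= 1,
    mutated_sample_count = as.integer(counts)
  )
  class(out) <- c("mutation_status", class(out))
  out
}

#' Write a ranked driver-gene list as TSV
#'
#' Columns: `rank`, `gene`, `score` (12 printed decimals), and
#' `mutated_sample_count`. Reading the file back reproduces the ranking.
#'
#' @param ranked A `ranked_list` tibble from [filter_and_rank()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranked, path) {
  stopifnot(all(c("rank", "gene", "score", "mutated_sample_count") %in% names(ranked)))
  df <- tibble(
    rank = as.integer(ranked$rank),
    gene = ranked$gene,
    score = sprintf("%.12f", ranked$score),
    mutated_sample_count = as.integer(ranked$mutated_sample_count)
  )
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a ranking written by [write_ranking()]
#'
#' @param path Path to the ranking TSV.
#' @return A `ranked_list` tibble.
#' @export
read_ranking <- function(path) {
  tab <- read_tsv_quiet(path, col_types = "icdi")
  out <- tibble(
    rank = as.integer(tab$rank),
    gene = tab$gene,
    score = tab$score,
    mutated_sample_count = as.integer(tab$mutated_sample_count)
  )
  class(out) <- c("ranked_list", class(out))
  out
}
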