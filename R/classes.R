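# Light S3 containers for the non-tabular objects the pipeline moves around.
# Tabular results (rankings, PR curves, summaries) are tibble subclasses and
# live with the functions that build them.

new_expression_matrix <- function(values, condition) {
  stopifnot(is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)))
  structure(
    list(
      genes = rownames(values),
      samples = colnames(values),
      values = values,
      condition = condition
    ),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf(
    "<expression_matrix> %d genes x %d samples, condition = %s\n",
    length(x$genes), length(x$samples), x$condition
  ))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

new_directed_network <- function(A) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  stopifnot(all(A %in% c(0, 1)))
  if (nrow(A) > 0) {
    stopifnot(!is.null(rownames(A)), identical(rownames(A), colnames(A)))
    stopifnot(all(diag(A) == 0))
  }
  structure(
    list(genes = rownames(A) %||% character(0), A = A, n = nrow(A)),
    class = "directed_network"
  )
}

#' Build a directed network from an edge table
#'
#' @param edges Data frame with columns `from` and `to` (gene identifiers).
#'   Duplicate edges collapse to a single 0/1 adjacency entry; self-loops are
#'   dropped with a warning.
#' @param genes Optional character vector fixing the node universe (and its
#'   order). Defaults to the sorted union of genes appearing in `edges`.
#' @return A `directed_network`: adjacency matrix `A` with `A[i, j] = 1` iff
#'   the directed edge i -> j is present, plus `genes` and node count `n`.
#' @export
directed_network <- function(edges, genes = NULL) {
  stopifnot(is.data.frame(edges), all(c("from", "to") %in% names(edges)))
  from <- as.character(edges$from)
  to <- as.character(edges$to)
  loops <- from == to
  if (any(loops)) {
    warn(sprintf("dropping %d self-loop(s)", sum(loops)))
    from <- from[!loops]
    to <- to[!loops]
  }
  if (is.null(genes)) genes <- sort(unique(c(from, to)))
  stopifnot(!anyDuplicated(genes))
  missing <- setdiff(unique(c(from, to)), genes)
  if (length(missing) > 0) {
    abort(sprintf("edge gene(s) not in node universe: %s", paste(head(missing, 5), collapse = ", ")))
  }
  n <- length(genes)
  A <- matrix(0, n, n, dimnames = list(genes, genes))
  if (length(from) > 0) A[cbind(from, to)] <- 1
  new_directed_network(A)
}

#' @export
print.directed_network <- function(x, ...) {
  cat(sprintf("<directed_network> %d nodes, %d edges\n", x$n, sum(x$A)))
  invisible(x)
}

#' Edge table of a directed network
#'
#' @param x A `directed_network`.
#' @param ... Unused.
#' @return Tibble with one row per directed edge, columns `from`, `to`.
#' @export
tidy.directed_network <- function(x, ...) {
  idx <- which(x$A == 1, arr.ind = TRUE)
  tibble(from = x$genes[idx[, 1]], to = x$genes[idx[, 2]]) |>
    dplyr::arrange(.data$from, .data$to)
}

#' @export
glance.directed_network <- function(x, ...) {
  tibble(n_nodes = x$n, n_edges = sum(x$A), density = if (x$n > 1) sum(x$A) / (x$n * (x$n - 1)) else NA_real_)
}

as_igraph <- function(net) {
  igraph::graph_from_adjacency_matrix(net$A, mode = "directed")
}

#' Construct a named gene set
#'
#' @param genes Character vector of gene identifiers; duplicates are removed.
#' @param name Label for the set.
#' @return A `gene_set` object.
#' @export
gene_set <- function(genes, name = "gene_set") {
  structure(list(name = name, genes = unique(as.character(genes))), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$genes)
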