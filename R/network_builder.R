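# Cancer-specific network construction: condition-wise Pearson coexpression
# with p-values, strict p < 0.05 significance masks, the tumor-XOR-normal
# differential edge rule, and intersection with the directed reference
# network (which contributes the edge directions).

#' Pairwise Pearson correlation with p-values
#'
#' Computes, for every gene pair, the Pearson coefficient across samples and a
#' two-sided p-value from the t transform `t = r * sqrt((m - 2) / (1 - r^2))`
#' with `m - 2` degrees of freedom (`m` = sample count). Pairs involving a
#' zero-variance gene have no defined correlation and are flagged `NA`; they
#' never become significant.
#'
#' @param expr An `expression_matrix` (genes x samples) for one condition.
#' @return A `coexpression` object with symmetric matrices `r` and `p`.
#' @export
pearson_with_pvalues <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  m <- length(expr$samples)
  if (m < 3) abort("at least 3 samples are required for correlation p-values")
  x <- t(expr$values)                       # samples x genes
  sds <- apply(x, 2, sd)
  r <- suppressWarnings(cor(x))             # zero-variance genes give NA
  r[sds == 0, ] <- NA_real_
  r[, sds == 0] <- NA_real_
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt((m - 2) / pmax(1 - r^2, 0))
  p <- 2 * pt(abs(tstat), df = m - 2, lower.tail = FALSE)
  p[which(abs(r) == 1)] <- 0                # t -> Inf
  diag(r) <- 1
  diag(p) <- 0
  dimnames(r) <- dimnames(p) <- list(expr$genes, expr$genes)
  structure(
    list(genes = expr$genes, r = r, p = p, condition = expr$condition),
    class = "coexpression"
  )
}

#' @export
print.coexpression <- function(x, ...) {
  cat(sprintf(
    "<coexpression> %d genes, condition = %s (%d undefined pairs)\n",
    length(x$genes), x$condition, sum(is.na(x$r[upper.tri(x$r)]))
  ))
  invisible(x)
}

#' Long-form gene-pair correlations
#'
#' @param x A `coexpression` object.
#' @param ... Unused.
#' @return Tibble with one row per unordered gene pair: `gene1`, `gene2`,
#'   `r`, `p`.
#' @export
tidy.coexpression <- function(x, ...) {
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble(
    gene1 = x$genes[idx[, 1]],
    gene2 = x$genes[idx[, 2]],
    r = x$r[idx],
    p = x$p[idx]
  ) |>
    dplyr::arrange(.data$gene1, .data$gene2)
}

#' Significance mask at a strict p-value threshold
#'
#' An unordered pair is marked 1 iff its correlation p-value is strictly below
#' the threshold. Boundary values (`p == threshold`) and undefined
#' (zero-variance) pairs are 0. The diagonal is always 0.
#'
#' @param corr A `coexpression` object.
#' @param threshold Significance level in (0, 1); default 0.05.
#' @return A `significance_mask` object with a symmetric 0/1 `mask`.
#' @export
significance_mask <- function(corr, threshold = 0.05) {
  stopifnot(inherits(corr, "coexpression"))
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold >= 1) {
    abort("threshold must be a single probability strictly inside (0, 1)")
  }
  mask <- (corr$p < threshold) * 1
  mask[is.na(mask)] <- 0
  diag(mask) <- 0
  structure(
    list(genes = corr$genes, mask = mask, threshold = threshold, condition = corr$condition),
    class = "significance_mask"
  )
}

#' Differential coexpression edges (tumor XOR normal)
#'
#' Keeps the unordered gene pairs significantly correlated in exactly one of
#' the two conditions; pairs significant in both, or in neither ("consistent
#' edges"), are removed. The rule is symmetric in its two arguments.
#'
#' @param tumor_mask,normal_mask `significance_mask` objects over the same
#'   gene universe.
#' @return A `differential_edges` object: the XOR mask plus a tibble of pairs.
#' @export
differential_edges <- function(tumor_mask, normal_mask) {
  stopifnot(inherits(tumor_mask, "significance_mask"),
            inherits(normal_mask, "significance_mask"))
  if (!identical(tumor_mask$genes, normal_mask$genes)) {
    abort("significance masks are over different gene universes")
  }
  mask <- (tumor_mask$mask != normal_mask$mask) * 1
  diag(mask) <- 0
  idx <- which(upper.tri(mask) & mask == 1, arr.ind = TRUE)
  pairs <- tibble(
    gene1 = tumor_mask$genes[idx[, 1]],
    gene2 = tumor_mask$genes[idx[, 2]]
  ) |>
    dplyr::arrange(.data$gene1, .data$gene2)
  structure(
    list(genes = tumor_mask$genes, mask = mask, pairs = pairs),
    class = "differential_edges"
  )
}

#' @export
print.differential_edges <- function(x, ...) {
  cat(sprintf("<differential_edges> %d pairs over %d genes\n", nrow(x$pairs), length(x$genes)))
  invisible(x)
}

#' @export
tidy.differential_edges <- function(x, ...) x$pairs

#' Intersect differential pairs with the directed reference network
#'
#' The node set is the intersection of the reference nodes with the
#' expression-derived gene universe; a directed edge i -> j survives iff it is
#' in the reference AND the unordered pair \{i, j\} is a differential edge.
#' Direction comes solely from the reference (correlation is symmetric).
#' Nodes left without edges are kept: the walk handles them through its
#' uniform dangling-row rule.
#'
#' @param diff A `differential_edges` object.
#' @param reference A `directed_network` reference interaction network.
#' @return A `directed_network` over the common nodes.
#' @export
intersect_with_reference <- function(diff, reference) {
  stopifnot(inherits(diff, "differential_edges"), inherits(reference, "directed_network"))
  common <- intersect(reference$genes, diff$genes)
  A <- reference$A[common, common, drop = FALSE] * diff$mask[common, common, drop = FALSE]
  net <- new_directed_network(A)
  if (sum(A) == 0) warn("constructed network has no edges; walk rows will be uniform")
  net
}

#' Build the cancer-specific network from expression and a reference
#'
#' Convenience wrapper chaining [pearson_with_pvalues()] on each condition,
#' [significance_mask()], [differential_edges()], and
#' [intersect_with_reference()].
#'
#' @param tumor_expr,normal_expr `expression_matrix` objects over the same
#'   genes.
#' @param reference A `directed_network`.
#' @param threshold Significance level for both conditions; default 0.05.
#' @param restrict_to_reference If `TRUE` (default) correlations are computed
#'   only on genes also present in the reference network; the final network is
#'   identical either way, this only avoids wasted work.
#' @return List with the constructed `network` plus the intermediate
#'   `differential` edge object.
#' @export
build_cancer_network <- function(tumor_expr, normal_expr, reference,
                                 threshold = 0.05, restrict_to_reference = TRUE) {
  stopifnot(inherits(tumor_expr, "expression_matrix"),
            inherits(normal_expr, "expression_matrix"))
  if (!identical(sort(tumor_expr$genes), sort(normal_expr$genes))) {
    abort("tumor and normal expression matrices must share one gene universe")
  }
  keep <- tumor_expr$genes
  if (restrict_to_reference) keep <- intersect(keep, reference$genes)
  subset_expr <- function(e) new_expression_matrix(e$values[keep, , drop = FALSE], e$condition)
  tm <- significance_mask(pearson_with_pvalues(subset_expr(tumor_expr)), threshold)
  nm <- significance_mask(pearson_with_pvalues(subset_expr(normal_expr)), threshold)
  diff <- differential_edges(tm, nm)
  list(network = intersect_with_reference(diff, reference), differential = diff)
}
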