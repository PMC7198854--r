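# Node centralities on the constructed directed network: out-degree (used to
# bias the walk's transitions), betweenness (shortest-path load), and Katz
# (damped walk counts), the latter two feeding the seed restart vector.

new_centrality <- function(values, genes, kind) {
  structure(
    list(genes = genes, values = setNames(as.numeric(values), genes), kind = kind),
    class = "centrality_vector"
  )
}

#' @export
print.centrality_vector <- function(x, ...) {
  cat(sprintf("<centrality_vector> %s over %d nodes\n", x$kind, length(x$genes)))
  invisible(x)
}

#' @export
tidy.centrality_vector <- function(x, ...) {
  tibble(gene = x$genes, kind = x$kind, value = unname(x$values))
}

#' Out-degree centrality
#'
#' Row sums of the adjacency matrix: the number of edges leaving each node.
#' This is the degree that biases the walk's transition probabilities.
#'
#' @param net A `directed_network`.
#' @return A `centrality_vector` of kind `"degree_out"`.
#' @export
out_degree <- function(net) {
  stopifnot(inherits(net, "directed_network"))
  new_centrality(rowSums(net$A), net$genes, "degree_out")
}

#' Betweenness centrality
#'
#' Directed betweenness: for node i, the sum over ordered pairs (s, t) with
#' s != t, both different from i, of the fraction of shortest s -> t paths
#' passing through i, scaled by `2 / (n^2 - 3n + 2)`. Unreachable pairs
#' contribute 0. Graphs with fewer than 3 nodes return zeros with a warning
#' (the scale factor is undefined there).
#'
#' @param net A `directed_network`.
#' @param undirected Treat edges as undirected when computing shortest paths
#'   (escape hatch; default `FALSE`).
#' @return A `centrality_vector` of kind `"betweenness"`.
#' @export
betweenness_centrality <- function(net, undirected = FALSE) {
  stopifnot(inherits(net, "directed_network"))
  n <- net$n
  if (n < 3) {
    warn("betweenness normalization requires at least 3 nodes; returning zeros")
    return(new_centrality(rep(0, n), net$genes, "betweenness"))
  }
  g <- as_igraph(net)
  raw <- igraph::betweenness(g, directed = !undirected, normalized = FALSE)
  new_centrality(2 / (n^2 - 3 * n + 2) * raw, net$genes, "betweenness")
}

#' Spectral radius of the adjacency matrix
#'
#' Largest eigenvalue modulus of `A`; the Katz damping must stay strictly
#' below its reciprocal for the walk-count series to converge.
#'
#' @param net A `directed_network`.
#' @return Non-negative scalar.
#' @export
spectral_radius <- function(net) {
  stopifnot(inherits(net, "directed_network"))
  if (net$n == 0 || sum(net$A) == 0) return(0)
  l <- max(Mod(eigen(net$A, only.values = TRUE)$values))
  # a 0/1 adjacency has lambda1 = 0 (acyclic) or >= 1 (contains a cycle);
  # anything in between is eigensolver noise on a nilpotent matrix
  if (l < 0.5) 0 else l
}

#' Katz centrality
#'
#' Damped count of all directed walks arriving at each node,
#' `KC = (I - alpha * t(A))^{-1} 1`. The effective damping is
#' `damping_fraction / lambda1` (or `damping_fraction` itself on an edgeless
#' graph, where lambda1 = 0), which keeps it strictly below `1 / lambda1` so
#' the series converges by construction.
#'
#' @param net A `directed_network`.
#' @param damping_fraction Fraction of the convergence limit `1 / lambda1` to
#'   use as damping; in (0, 1), default 0.85.
#' @return A `centrality_vector` of kind `"katz"`; the effective damping is
#'   attached as attribute `alpha`.
#' @export
katz_centrality <- function(net, damping_fraction = 0.85) {
  stopifnot(inherits(net, "directed_network"))
  if (!is.numeric(damping_fraction) || length(damping_fraction) != 1 ||
      damping_fraction <= 0 || damping_fraction >= 1) {
    abort("damping_fraction must lie strictly inside (0, 1)")
  }
  n <- net$n
  lambda1 <- spectral_radius(net)
  alpha <- if (lambda1 > 0) damping_fraction / lambda1 else damping_fraction
  kc <- solve(diag(n) - alpha * t(net$A), rep(1, n))
  out <- new_centrality(kc, net$genes, "katz")
  attr(out, "alpha") <- alpha
  attr(out, "lambda1") <- lambda1
  out
}

#' All three centralities as one table
#'
#' @param net A `directed_network`.
#' @param damping_fraction Katz damping fraction, see [katz_centrality()].
#' @param bc_undirected Passed to [betweenness_centrality()].
#' @return Tibble with columns `gene`, `degree_out`, `betweenness`, `katz`.
#' @export
centrality_table <- function(net, damping_fraction = 0.85, bc_undirected = FALSE) {
  tibble(
    gene = net$genes,
    degree_out = unname(out_degree(net)$values),
    betweenness = unname(betweenness_centrality(net, undirected = bc_undirected)$values),
    katz = unname(katz_centrality(net, damping_fraction)$values)
  )
}
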