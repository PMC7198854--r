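# The improved random walk: a degree-biased transition matrix (transition
# probability to an out-neighbor proportional to that neighbor's out-degree,
# mixed with uniform teleportation), a restart vector concentrated on seed
# genes and weighted by their betweenness and Katz centralities, and the
# damped iteration r <- d * t(P) r + (1 - d) * prior run to convergence.

new_transition_matrix <- function(P, alpha_mix, kind) {
  structure(
    list(genes = rownames(P), P = P, alpha_mix = alpha_mix, kind = kind),
    class = "transition_matrix"
  )
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf(
    "<transition_matrix> %s, %d nodes, alpha = %g\n",
    x$kind, nrow(x$P), x$alpha_mix
  ))
  invisible(x)
}

#' @export
tidy.transition_matrix <- function(x, ...) {
  as_tibble(x$P, rownames = "from") |>
    tidyr::pivot_longer(-"from", names_to = "to", values_to = "probability")
}

mix_transition <- function(net, weights, alpha_mix, kind) {
  if (!is.numeric(alpha_mix) || length(alpha_mix) != 1 ||
      alpha_mix < 0 || alpha_mix > 1) {
    abort("alpha_mix must lie in [0, 1]")
  }
  n <- net$n
  S <- rowSums(weights)
  P <- matrix(1 / n, n, n, dimnames = list(net$genes, net$genes))
  ok <- S > 0
  if (any(ok)) {
    P[ok, ] <- alpha_mix * weights[ok, , drop = FALSE] / S[ok] + (1 - alpha_mix) / n
  }
  new_transition_matrix(P, alpha_mix, kind)
}

#' Degree-biased transition matrix
#'
#' Row i distributes probability over its out-neighbors proportionally to the
#' neighbors' own out-degree: with `S = sum of out-degrees of i's
#' out-neighbors`, `P[i, j] = alpha * deg_out(j) * A[i, j] / S + (1 - alpha) / n`
#' for every column j (non-neighbors receive the teleport share
#' `(1 - alpha) / n` alone). Rows with `S = 0` — dangling nodes, or nodes all
#' of whose out-neighbors are sinks — are uniform `1 / n`. Every row sums to
#' 1 for any `alpha` in \[0, 1\].
#'
#' @param net A `directed_network`.
#' @param alpha_mix Mixing weight of the degree-biased part; default 0.85.
#' @return A `transition_matrix`.
#' @export
build_transition_matrix <- function(net, alpha_mix = 0.85) {
  stopifnot(inherits(net, "directed_network"))
  deg <- rowSums(net$A)
  weights <- net$A * rep(deg, each = net$n)   # weights[i, j] = A[i, j] * deg_out(j)
  mix_transition(net, weights, alpha_mix, "degree_biased")
}

#' Uniform-neighbor transition matrix (ablation baseline)
#'
#' Same teleportation mix as [build_transition_matrix()] but every
#' out-neighbor is weighted equally: `P[i, j] = alpha * A[i, j] / deg_out(i) +
#' (1 - alpha) / n`, uniform `1 / n` on dangling rows. On out-regular graphs
#' this coincides with the degree-biased matrix.
#'
#' @inheritParams build_transition_matrix
#' @return A `transition_matrix`.
#' @export
build_uniform_transition <- function(net, alpha_mix = 0.85) {
  stopifnot(inherits(net, "directed_network"))
  mix_transition(net, net$A, alpha_mix, "uniform_neighbor")
}

new_prior <- function(prior_p, genes, seed_genes) {
  structure(
    list(genes = genes, prior_p = setNames(as.numeric(prior_p), genes), seed_genes = seed_genes),
    class = "prior_vector"
  )
}

#' @export
print.prior_vector <- function(x, ...) {
  cat(sprintf(
    "<prior_vector> %d nodes, %d seed(s) carrying mass\n",
    length(x$genes), length(x$seed_genes)
  ))
  invisible(x)
}

#' @export
tidy.prior_vector <- function(x, ...) {
  tibble(gene = x$genes, prior = unname(x$prior_p), is_seed = x$genes %in% x$seed_genes)
}

normalize_to_sum1 <- function(v) {
  s <- sum(v)
  if (s > 0) v / s else v
}

#' Centrality-weighted restart vector over seed genes
#'
#' Betweenness and Katz centralities are each normalized to sum 1 over all
#' network genes; every seed gene receives the mean of its two normalized
#' values, non-seeds receive 0, and the vector is renormalized to sum 1.
#' Seeds absent from the network are dropped with a warning; if no usable
#' seed remains (or all seed mass is zero) the prior falls back to uniform
#' `1 / n` with a warning.
#'
#' @param seeds A `gene_set` of known cancer genes.
#' @param bc,kc `centrality_vector`s (betweenness and Katz) over the network
#'   genes.
#' @param net The `directed_network` the walk runs on.
#' @return A `prior_vector` summing to 1.
#' @export
build_prior <- function(seeds, bc, kc, net) {
  stopifnot(inherits(seeds, "gene_set"), inherits(net, "directed_network"))
  stopifnot(identical(bc$genes, net$genes), identical(kc$genes, net$genes))
  if (length(seeds$genes) == 0) abort("seed gene set is empty")
  usable <- intersect(seeds$genes, net$genes)
  dropped <- setdiff(seeds$genes, net$genes)
  if (length(dropped) > 0) {
    warn(sprintf("%d seed gene(s) absent from the network were dropped", length(dropped)))
  }
  n <- net$n
  if (length(usable) == 0) {
    warn("no seed gene present in the network; falling back to a uniform prior")
    return(new_prior(rep(1 / n, n), net$genes, character(0)))
  }
  bcn <- normalize_to_sum1(bc$values)
  kcn <- normalize_to_sum1(kc$values)
  prior <- setNames(rep(0, n), net$genes)
  prior[usable] <- (bcn[usable] + kcn[usable]) / 2
  if (sum(prior) == 0) {
    warn("all usable seeds have zero centrality mass; falling back to a uniform prior")
    return(new_prior(rep(1 / n, n), net$genes, character(0)))
  }
  new_prior(prior / sum(prior), net$genes, usable)
}

#' Uniform restart vector (seedless ablation)
#'
#' Every node gets restart probability `1 / n`.
#'
#' @param net A `directed_network`.
#' @return A `prior_vector`.
#' @export
uniform_prior <- function(net) {
  stopifnot(inherits(net, "directed_network"))
  new_prior(rep(1 / net$n, net$n), net$genes, character(0))
}

new_scores <- function(r, genes, iterations, converged, final_diff) {
  structure(
    list(
      genes = genes, r = setNames(as.numeric(r), genes),
      iterations = iterations, converged = converged, final_diff = final_diff
    ),
    class = "irw_scores"
  )
}

#' @export
print.irw_scores <- function(x, ...) {
  cat(sprintf(
    "<irw_scores> %d genes; %s in %d iteration(s), final diff %.3g\n",
    length(x$genes), if (x$converged) "converged" else "NOT converged",
    x$iterations, x$final_diff
  ))
  invisible(x)
}

#' @export
tidy.irw_scores <- function(x, ...) {
  tibble(gene = x$genes, score = unname(x$r)) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$gene)
}

#' @export
glance.irw_scores <- function(x, ...) {
  tibble(
    n_genes = length(x$genes), iterations = x$iterations,
    converged = x$converged, final_diff = x$final_diff
  )
}

#' Initial walk scores from tumor expression
#'
#' The starting vector is each network gene's mean tumor expression,
#' normalized to sum 1 over the network genes. Every network gene must be
#' present in the expression matrix (the walk is undefined otherwise), and
#' abundances must be non-negative. If all means are zero the start falls
#' back to uniform with a warning. For a damping factor below 1 the walk's
#' fixed point does not depend on the start; it only shapes the transient.
#'
#' @param tumor_expr An `expression_matrix` with condition `"tumor"`.
#' @param net A `directed_network`.
#' @return An `irw_scores` object holding r(0) (0 iterations).
#' @export
initial_scores <- function(tumor_expr, net) {
  stopifnot(inherits(tumor_expr, "expression_matrix"), inherits(net, "directed_network"))
  missing <- setdiff(net$genes, tumor_expr$genes)
  if (length(missing) > 0) {
    abort(sprintf(
      "network gene(s) missing from tumor expression: %s",
      paste(head(missing, 5), collapse = ", ")
    ))
  }
  vals <- tumor_expr$values[net$genes, , drop = FALSE]
  if (any(vals < 0)) abort("tumor expression must be non-negative")
  means <- rowMeans(vals)
  if (sum(means) == 0) {
    warn("all tumor means are zero; using a uniform start")
    means <- rep(1, net$n)
  }
  new_scores(means / sum(means), net$genes, 0L, FALSE, Inf)
}

#' Run the random walk with restart to convergence
#'
#' Iterates `r(t+1) = d * t(P) %*% r(t) + (1 - d) * prior` and stops when the
#' squared-difference sum `sum((r(t+1) - r(t))^2)` falls below `eps`, or after
#' `max_iter` iterations. Because the columns of `t(P)` sum to 1, total score
#' mass is conserved: if `r(0)` and the prior each sum to 1, so does every
#' iterate. With `d = 0` the iteration returns the prior exactly.
#'
#' @param P A `transition_matrix` (row-stochastic).
#' @param prior A `prior_vector` summing to 1.
#' @param r0 An `irw_scores` start vector summing to 1.
#' @param d Damping factor in \[0, 1); default 0.85 (the classical PageRank
#'   value). `1 - d` is the restart probability.
#' @param eps Convergence threshold on the squared-difference sum; default
#'   1e-8.
#' @param max_iter Iteration cap; default 1000.
#' @return An `irw_scores` object with the stationary scores, iteration
#'   count, convergence flag, and final difference.
#' @export
random_walk <- function(P, prior, r0, d = 0.85, eps = 1e-8, max_iter = 1000L) {
  stopifnot(inherits(P, "transition_matrix"), inherits(prior, "prior_vector"),
            inherits(r0, "irw_scores"))
  if (!is.numeric(d) || length(d) != 1 || d < 0 || d >= 1) {
    abort("damping factor d must lie in [0, 1)")
  }
  if (max(abs(rowSums(P$P) - 1)) > 1e-12 || any(P$P < 0)) {
    abort("transition matrix is not row-stochastic")
  }
  stopifnot(identical(P$genes, prior$genes), identical(P$genes, r0$genes))
  Pt <- t(P$P)
  restart <- (1 - d) * unname(prior$prior_p)
  r <- unname(r0$r)
  converged <- FALSE
  diff <- Inf
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    r_new <- d * as.vector(Pt %*% r) + restart
    if (anyNA(r_new)) abort("walk produced NaN scores")
    diff <- sum((r_new - r)^2)
    r <- r_new
    if (diff < eps) {
      converged <- TRUE
      break
    }
  }
  new_scores(r, P$genes, iter, converged, diff)
}
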