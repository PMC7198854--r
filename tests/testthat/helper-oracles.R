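# Independent oracles, deliberately written against different primitives than
# the implementation: explicit sums for Pearson, matrix-power shortest-path
# counting for betweenness, truncated series for Katz, dense linear solve for
# the walk's fixed point.

# Pearson r and two-sided p for one gene pair, from explicit sums.
oracle_pearson_pair <- function(x, y) {
  m <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- sum(x * y) - sx * sy / m
  den <- sqrt((sum(x^2) - sx^2 / m) * (sum(y^2) - sy^2 / m))
  if (den == 0) return(list(r = NA_real_, p = NA_real_))
  r <- num / den
  if (abs(r) >= 1) return(list(r = sign(r), p = 0))
  tt <- r * sqrt((m - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tt), df = m - 2))
}

# All-pairs shortest-path distances and path counts by matrix powers:
# sigma(s, t) = (A^k)[s, t] at the first k with a nonzero entry.
oracle_path_counts <- function(A) {
  n <- nrow(A)
  dist <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n)
  diag(dist) <- 0
  diag(sigma) <- 1
  Ak <- diag(n)
  for (k in seq_len(n - 1)) {
    Ak <- Ak %*% A
    newly <- is.infinite(dist) & Ak > 0
    dist[newly] <- k
    sigma[newly] <- Ak[newly]
  }
  list(dist = dist, sigma = sigma)
}

# Betweenness via the pair-dependency definition: for each ordered (s, t)
# with finite distance, node i (distinct from both) contributes
# sigma(s,i) * sigma(i,t) / sigma(s,t) when d(s,i) + d(i,t) = d(s,t).
oracle_betweenness <- function(A, scale = TRUE) {
  n <- nrow(A)
  pc <- oracle_path_counts(A)
  bc <- numeric(n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t || is.infinite(pc$dist[s, t])) next
    for (i in seq_len(n)) {
      if (i == s || i == t) next
      if (is.finite(pc$dist[s, i]) && is.finite(pc$dist[i, t]) &&
          pc$dist[s, i] + pc$dist[i, t] == pc$dist[s, t]) {
        bc[i] <- bc[i] + pc$sigma[s, i] * pc$sigma[i, t] / pc$sigma[s, t]
      }
    }
  }
  if (scale) bc <- 2 / (n^2 - 3 * n + 2) * bc
  bc
}

# Katz by truncated power series sum_{k>=0} alpha^k (A^T)^k 1.
oracle_katz_series <- function(A, alpha, k_max = 60) {
  n <- nrow(A)
  term <- rep(1, n)
  total <- term
  At <- t(A)
  for (k in seq_len(k_max)) {
    term <- alpha * (At %*% term)
    total <- total + term
  }
  as.vector(total)
}

# Stationary point of the walk by direct linear solve.
oracle_walk_solve <- function(P, prior, d) {
  n <- nrow(P)
  as.vector(solve(diag(n) - d * t(P), (1 - d) * prior))
}

# Random directed 0/1 graph (no self-loops) as a directed_network.
random_network <- function(n, p = 0.2, rng_seed = 1) {
  withr::with_seed(rng_seed, {
    A <- matrix(rbinom(n * n, 1, p), n, n)
    diag(A) <- 0
    genes <- sprintf("n%02d", seq_len(n))
    dimnames(A) <- list(genes, genes)
    driverwalk:::new_directed_network(A)
  })
}

# Tiny expression matrix from a genes x samples value matrix.
make_expr <- function(values, condition = "tumor",
                      genes = sprintf("g%d", seq_len(nrow(values))),
                      samples = sprintf("s%d", seq_len(ncol(values)))) {
  dimnames(values) <- list(genes, samples)
  driverwalk:::new_expression_matrix(values, condition)
}

# Small fixture config used where full size is not needed; ... overrides.
small_cfg <- function(...) {
  defaults <- list(n_genes = 60L, n_tumor = 40L, n_normal = 40L,
                   n_modules = 2L, block_size = 5L, n_decoy_seeds = 3L)
  do.call(fixture_config, utils::modifyList(defaults, list(...)))
}
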