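net4 <- function() {
  directed_network(tibble::tibble(
    from = c("v1", "v1", "v2", "v3"),
    to = c("v2", "v3", "v3", "v1")
  ), genes = c("v1", "v2", "v3", "v4"))
}

test_that("degree-biased transition reproduces the hand-derived 4-node matrix", {
  # out-degrees (2, 1, 1, 0); alpha = 0.85
  P <- build_transition_matrix(net4(), alpha_mix = 0.85)$P
  expected <- rbind(
    c(0.0375, 0.4625, 0.4625, 0.0375),
    c(0.0375, 0.0375, 0.8875, 0.0375),
    c(0.8875, 0.0375, 0.0375, 0.0375),
    c(0.2500, 0.2500, 0.2500, 0.2500)
  )
  expect_equal(unname(P), expected, tolerance = 1e-12)
})

test_that("transition rows are stochastic for any alpha, with uniform degenerate rows", {
  withr::with_seed(5, {
    for (alpha in c(0, 0.5, 0.85, 1)) {
      for (rep in 1:5) {
        net <- random_network(sample(2:40, 1), runif(1, 0.05, 0.5),
                              rng_seed = sample.int(1e6, 1))
        for (builder in list(build_transition_matrix, build_uniform_transition)) {
          P <- builder(net, alpha)$P
          expect_equal(unname(rowSums(P)), rep(1, net$n), tolerance = 1e-12)
          expect_true(all(P >= 0 & P <= 1))
        }
      }
    }
  })

  # a node whose only out-neighbor is a sink hits the S = 0 uniform branch
  chain <- directed_network(tibble::tibble(from = "a", to = "b"),
                            genes = c("a", "b", "c"))
  P <- build_transition_matrix(chain, 0.85)$P
  expect_equal(unname(P["a", ]), rep(1 / 3, 3))   # b has out-degree 0
  expect_equal(unname(P["b", ]), rep(1 / 3, 3))   # dangling
})

test_that("uniform-neighbor transition weights neighbors equally and matches on regular graphs", {
  net <- net4()
  P <- build_uniform_transition(net, 0.85)$P
  expect_equal(unname(P["v1", ]), c(0.0375, 0.4625, 0.4625, 0.0375))
  expect_equal(unname(P["v4", ]), rep(0.25, 4))

  # 4-cycle is out-regular: both constructions coincide
  cyc <- directed_network(tibble::tibble(
    from = c("a", "b", "c", "d"), to = c("b", "c", "d", "a")
  ))
  expect_equal(build_transition_matrix(cyc, 0.85)$P,
               build_uniform_transition(cyc, 0.85)$P)
})

test_that("seed prior averages normalized centralities and falls back gracefully", {
  net <- net4()
  bc <- betweenness_centrality(net)
  kc <- katz_centrality(net)

  one <- build_prior(gene_set("v3", "s"), bc, kc, net)
  expect_equal(unname(one$prior_p), c(0, 0, 1, 0))
  expect_equal(sum(one$prior_p), 1)

  # symmetric seeds in a symmetric structure share the mass equally
  cyc <- directed_network(tibble::tibble(
    from = c("a", "b", "c"), to = c("b", "c", "a")
  ))
  two <- build_prior(gene_set(c("a", "b"), "s"),
                     betweenness_centrality(cyc), katz_centrality(cyc), cyc)
  expect_equal(unname(two$prior_p), c(0.5, 0.5, 0))

  expect_warning(
    expect_warning(out <- build_prior(gene_set("zz", "s"), bc, kc, net), "dropped"),
    "uniform"
  )
  expect_equal(unname(out$prior_p), rep(0.25, 4))

  expect_warning(mix <- build_prior(gene_set(c("v3", "zz"), "s"), bc, kc, net),
                 "dropped")
  expect_equal(unname(mix$prior_p), c(0, 0, 1, 0))

  expect_equal(unname(uniform_prior(net)$prior_p), rep(0.25, 4))
})

test_that("initial scores are normalized tumor means restricted to network genes", {
  net <- directed_network(tibble::tibble(from = "g1", to = "g2"))
  expr <- make_expr(rbind(c(2, 4), c(1, 1)), genes = c("g1", "g2"))
  r0 <- initial_scores(expr, net)
  expect_equal(unname(r0$r), c(0.75, 0.25))

  flat <- make_expr(rbind(c(1, 1), c(1, 1)), genes = c("g1", "g2"))
  expect_equal(unname(initial_scores(flat, net)$r), c(0.5, 0.5))

  small <- make_expr(matrix(1, 1, 2), genes = "g1")
  expect_error(initial_scores(small, net), "g2")

  neg <- driverwalk:::new_expression_matrix(
    matrix(c(1, -1, 2, 3), 2, 2, dimnames = list(c("g1", "g2"), c("s1", "s2"))),
    "tumor"
  )
  expect_error(initial_scores(neg, net), "non-negative")
})

test_that("the walk matches the direct linear solve and conserves mass", {
  withr::with_seed(41, {
    for (rep in 1:5) {
      n <- sample(20:200, 1)
      net <- random_network(n, runif(1, 0.02, 0.2), rng_seed = sample.int(1e6, 1))
      P <- build_transition_matrix(net, 0.85)
      prior <- uniform_prior(net)
      r0 <- driverwalk:::new_scores(rep(1 / n, n), net$genes, 0L, FALSE, Inf)
      res <- random_walk(P, prior, r0, d = 0.85, eps = 1e-16, max_iter = 2000)
      expect_true(res$converged)
      expect_equal(sum(res$r), 1, tolerance = 1e-9)
      expect_equal(unname(res$r), oracle_walk_solve(P$P, unname(prior$prior_p), 0.85),
                   tolerance = 1e-6)
    }
  })
})

test_that("d = 0 returns the prior and a uniform system fixes the uniform vector", {
  net <- net4()
  P <- build_transition_matrix(net, 0.85)
  bc <- betweenness_centrality(net)
  kc <- katz_centrality(net)
  prior <- build_prior(gene_set(c("v1", "v3"), "s"), bc, kc, net)
  r0 <- initial_scores(make_expr(matrix(1:8, 4, 2), genes = net$genes), net)

  expect_equal(random_walk(P, prior, r0, d = 0)$r, prior$prior_p)

  uni <- random_walk(build_transition_matrix(
    directed_network(tibble::tibble(from = character(0), to = character(0)),
                     genes = net$genes)
  ), uniform_prior(net), driverwalk:::new_scores(rep(0.25, 4), net$genes, 0L, FALSE, Inf))
  expect_equal(unname(uni$r), rep(0.25, 4))
  expect_equal(uni$iterations, 1L)
})

test_that("the stationary point does not depend on the start vector", {
  withr::with_seed(47, {
    net <- random_network(60, 0.1, rng_seed = 17)
    P <- build_transition_matrix(net, 0.85)
    prior <- uniform_prior(net)
    mk <- function(v) driverwalk:::new_scores(v / sum(v), net$genes, 0L, FALSE, Inf)
    a <- random_walk(P, prior, mk(runif(60)), eps = 1e-16)
    b <- random_walk(P, prior, mk(runif(60)), eps = 1e-16)
    expect_equal(a$r, b$r, tolerance = 1e-6)
  })
})

test_that("mass is conserved at every iteration", {
  withr::with_seed(53, {
    net <- random_network(30, 0.15, rng_seed = 29)
    P <- build_transition_matrix(net, 0.85)
    prior <- uniform_prior(net)
    r <- rep(1 / 30, 30)
    Pt <- t(P$P)
    for (t in 1:50) {
      r <- 0.85 * as.vector(Pt %*% r) + 0.15 * unname(prior$prior_p)
      expect_equal(sum(r), 1, tolerance = 1e-9)
    }
  })
})

test_that("raising a seed's restart mass never lowers its stationary score", {
  net <- random_network(25, 0.2, rng_seed = 61)
  P <- build_transition_matrix(net, 0.85)
  n <- net$n
  r0 <- driverwalk:::new_scores(rep(1 / n, n), net$genes, 0L, FALSE, Inf)
  target <- net$genes[5]
  score_for <- function(w) {
    p <- rep(1, n); p[5] <- w
    prior <- driverwalk:::new_prior(p / sum(p), net$genes, target)
    random_walk(P, prior, r0, eps = 1e-16)$r[target]
  }
  scores <- vapply(c(1, 2, 5, 10, 50), score_for, numeric(1))
  expect_true(all(diff(scores) >= -1e-12))
})
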