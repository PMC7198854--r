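scores_of <- function(v) {
  driverwalk:::new_scores(v / sum(v), names(v), 1L, TRUE, 0)
}

mut_of <- function(genes, mutated, counts = as.integer(mutated)) {
  out <- tibble::tibble(gene = genes, mutated = mutated,
                        mutated_sample_count = as.integer(counts))
  class(out) <- c("mutation_status", class(out))
  out
}

test_that("filter_and_rank keeps mutated genes sorted by score then identifier", {
  sc <- scores_of(c(a = 0.4, b = 0.3, c = 0.2, d = 0.1))
  ms <- mut_of(c("a", "b", "c", "d"), c(FALSE, TRUE, FALSE, TRUE), c(0, 3, 0, 1))
  r <- filter_and_rank(sc, ms)
  expect_identical(r$gene, c("b", "d"))
  expect_identical(r$rank, 1:2)
  expect_identical(r$mutated_sample_count, c(3L, 1L))
  expect_true(all(diff(r$score) <= 0))

  # equal scores break ties alphabetically
  tie <- scores_of(c(z = 0.25, m = 0.25, a = 0.25, q = 0.25))
  rt <- filter_and_rank(tie, mut_of(c("z", "m", "a", "q"), rep(TRUE, 4)))
  expect_identical(rt$gene, c("a", "m", "q", "z"))

  expect_warning(
    empty <- filter_and_rank(sc, mut_of(c("a", "b", "c", "d"), rep(FALSE, 4))),
    "empty"
  )
  expect_equal(nrow(empty), 0)

  # input ordering of the score vector is immaterial
  sc2 <- scores_of(c(d = 0.1, c = 0.2, a = 0.4, b = 0.3))
  r2 <- filter_and_rank(sc2, ms)
  expect_identical(r2$gene, r$gene)
  expect_equal(r2$score, r$score)
})

test_that("precision/recall arithmetic matches the 20-of-138 hand example", {
  # 100-gene ranking whose hits are exactly 20 members of a 138-gene benchmark
  bench <- gene_set(sprintf("b%03d", 1:138), "benchmark")
  genes <- c(sprintf("b%03d", 1:20), sprintf("x%03d", 1:80))
  ranked <- filter_and_rank(
    scores_of(setNames(seq(100, 1), genes)),
    mut_of(genes, rep(TRUE, 100))
  )
  pr <- precision_recall_at(ranked, bench, 100)
  expect_equal(pr$precision[pr$n == 100], 0.20)
  expect_equal(pr$recall[pr$n == 100], 20 / 138)
  expect_equal(pr$hits[pr$n == 100], 20L)

  # shared hit count: precision(N) * N = recall(N) * |benchmark| for all N
  expect_equal(pr$precision * pr$n, pr$recall * 138)
  expect_true(all(diff(pr$recall) >= 0))

  # benchmark superset of the ranking: precision 1 everywhere
  all_in <- precision_recall_at(ranked, gene_set(genes, "all"), 100)
  expect_true(all(all_in$precision == 1))

  # disjoint benchmark: flat zero
  none <- precision_recall_at(ranked, gene_set("nope", "none"), 100)
  expect_true(all(none$precision == 0) && all(none$recall == 0))

  # short rankings end early instead of padding
  short <- precision_recall_at(head(ranked, 7), bench, 100)
  expect_equal(max(short$n), 7)

  expect_error(precision_recall_at(ranked, gene_set(character(0), "e"), 100),
               "empty")
})

test_that("ablation arms differ only as designed", {
  cfg <- small_cfg()
  b <- simulate_fixture(cfg)
  prep <- suppressWarnings(driver_irw_prepare(b$tumor, b$normal, b$reference, b$snv, b$cnv))

  full <- run_ablation(prep, b$seeds, b$benchmark, "full")
  uni <- run_ablation(prep, b$seeds, b$benchmark, "uniform_transition")
  nosd <- run_ablation(prep, b$seeds, b$benchmark, "no_seeds")

  # seedless arm restarts uniformly at exactly 1/n
  expect_equal(unname(nosd$result$prior$prior_p),
               rep(1 / prep$network$n, prep$network$n))
  # the seeded arms share the same prior but different transitions
  expect_equal(full$result$prior$prior_p, uni$result$prior$prior_p)
  expect_identical(full$result$transition$kind, "degree_biased")
  expect_identical(uni$result$transition$kind, "uniform_neighbor")

  # reruns are deterministic
  full2 <- run_ablation(prep, b$seeds, b$benchmark, "full")
  expect_identical(full$result$ranking, full2$result$ranking)
  expect_error(driver_irw(seeds = b$seeds, mode = "nope", prepared = prep))
})

test_that("full and uniform-transition arms coincide on an out-regular network", {
  # directed ring: every node has out-degree 1
  g <- sprintf("r%02d", 1:8)
  ring <- directed_network(tibble::tibble(from = g, to = c(g[-1], g[1])))
  P1 <- build_transition_matrix(ring, 0.85)
  P2 <- build_uniform_transition(ring, 0.85)
  expect_equal(P1$P, P2$P)

  bc <- betweenness_centrality(ring)
  kc <- katz_centrality(ring)
  prior <- build_prior(gene_set(g[1:2], "s"), bc, kc, ring)
  r0 <- driverwalk:::new_scores(rep(1 / 8, 8), g, 0L, FALSE, Inf)
  ms <- mut_of(g, rep(TRUE, 8))
  r_full <- filter_and_rank(random_walk(P1, prior, r0), ms)
  r_uni <- filter_and_rank(random_walk(P2, prior, r0), ms)
  expect_identical(r_full$gene, r_uni$gene)
})

test_that("seed subsampling is reproducible and keeps the full run at fraction 1", {
  cfg <- small_cfg()
  b <- simulate_fixture(cfg)
  prep <- suppressWarnings(driver_irw_prepare(b$tumor, b$normal, b$reference, b$snv, b$cnv))

  s1 <- seed_subsampling(prep, b$seeds, b$benchmark,
                         fractions = c(1, 0.5), repeats = 3, rng_seed = 7)
  s2 <- seed_subsampling(prep, b$seeds, b$benchmark,
                         fractions = c(1, 0.5), repeats = 3, rng_seed = 7)
  expect_equal(as.data.frame(s1), as.data.frame(s2))

  full <- run_ablation(prep, b$seeds, b$benchmark, "full")
  last <- full$pr[nrow(full$pr), ]
  expect_equal(s1$mean_precision[s1$fraction == 1], last$precision)
  expect_equal(s1$mean_recall[s1$fraction == 1], last$recall)
  expect_equal(s1$sd_precision[s1$fraction == 1], 0)
  expect_identical(s1$n_seeds_kept[s1$fraction == 0.5],
                   as.integer(ceiling(0.5 * length(b$seeds$genes))))
})

test_that("mutation-frequency baseline ranks by count with alphabetical ties", {
  ms <- mut_of(c("a", "b", "c", "d"), c(TRUE, TRUE, FALSE, TRUE), c(2, 5, 0, 2))
  r <- mutation_frequency_ranking(ms)
  expect_identical(r$gene, c("b", "a", "d"))
  expect_equal(r$score, c(5, 2, 2))
})

test_that("result tables render as ggplot objects", {
  bench <- gene_set(c("a", "b"), "bench")
  ranked <- filter_and_rank(
    scores_of(c(a = 0.5, b = 0.3, c = 0.2)),
    mut_of(c("a", "b", "c"), rep(TRUE, 3))
  )
  pr <- precision_recall_at(ranked, bench, 3)
  expect_s3_class(autoplot(pr), "ggplot")
  expect_s3_class(plot_pr_comparison(list(full = pr, ablation = pr), "recall"),
                  "ggplot")

  sub <- tibble::new_tibble(
    tibble::tibble(fraction = c(1, 0.5), n_seeds_kept = c(4L, 2L),
                   mean_precision = c(0.6, 0.5), mean_recall = c(0.9, 0.8),
                   sd_precision = c(0, 0.1), sd_recall = c(0, 0.1),
                   n_uniform_fallback = c(0L, 0L)),
    n_max = 100L, repeats = 10L, class = "seed_subsample_summary"
  )
  expect_s3_class(autoplot(sub), "ggplot")
})
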