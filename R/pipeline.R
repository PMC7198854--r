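# End-to-end orchestration: build the cancer-specific network once, then run
# the walk under the full model or either ablation, and the seed-subsampling
# experiment. Every step is deterministic given the inputs (and, for
# subsampling, the RNG seed).

#' Prepare shared pipeline state
#'
#' Builds the cancer-specific network from expression and the reference,
#' computes the centralities, the mutation status, and the r(0) start vector.
#' The result feeds [driver_irw()] (directly or through its `prepared`
#' argument) and [seed_subsampling()], which rerun only the walk.
#'
#' @param tumor_expr,normal_expr `expression_matrix` objects.
#' @param reference A `directed_network`.
#' @param snv,cnv Mutation tables for [build_mutation_status()] (either may
#'   be `NULL`, not both).
#' @param threshold Coexpression significance level; default 0.05.
#' @param katz_fraction Katz damping as a fraction of 1/lambda1; default 0.85.
#' @param bc_undirected Compute betweenness on the undirected skeleton;
#'   default `FALSE`.
#' @return A `driver_irw_prep` list: `network`, `bc`, `kc`, `mutation`, `r0`,
#'   `differential`, `params`.
#' @export
driver_irw_prepare <- function(tumor_expr, normal_expr, reference, snv, cnv,
                               threshold = 0.05, katz_fraction = 0.85,
                               bc_undirected = FALSE) {
  built <- build_cancer_network(tumor_expr, normal_expr, reference, threshold)
  net <- built$network
  structure(
    list(
      network = net,
      differential = built$differential,
      bc = betweenness_centrality(net, undirected = bc_undirected),
      kc = katz_centrality(net, katz_fraction),
      mutation = build_mutation_status(snv, cnv),
      r0 = initial_scores(tumor_expr, net),
      params = list(threshold = threshold, katz_fraction = katz_fraction,
                    bc_undirected = bc_undirected)
    ),
    class = "driver_irw_prep"
  )
}

#' @export
print.driver_irw_prep <- function(x, ...) {
  cat(sprintf(
    "<driver_irw_prep> network: %d nodes / %d edges; %d mutated gene(s)\n",
    x$network$n, sum(x$network$A), sum(x$mutation$mutated)
  ))
  invisible(x)
}

#' Run the driver-gene prioritization pipeline
#'
#' Chains network construction, centralities, the degree-biased (or, for the
#' ablation, uniform-neighbor) transition matrix, the centrality-weighted
#' seed restart vector (or the seedless uniform one), the walk, and the
#' mutation post-filter.
#'
#' @param tumor_expr,normal_expr,reference,snv,cnv,threshold,katz_fraction,bc_undirected
#'   As in [driver_irw_prepare()]; ignored when `prepared` is given.
#' @param seeds A `gene_set` of known cancer genes (ignored under
#'   `mode = "no_seeds"`).
#' @param mode `"full"` (degree-biased transition + seed prior),
#'   `"uniform_transition"` (uniform-neighbor transition + seed prior), or
#'   `"no_seeds"` (degree-biased transition + uniform prior).
#' @param alpha_mix Transition mixing weight; default 0.85.
#' @param d Walk damping factor; default 0.85.
#' @param eps Convergence threshold (squared-difference sum); default 1e-8.
#' @param max_iter Walk iteration cap; default 1000.
#' @param prepared Optional `driver_irw_prep` to reuse.
#' @return A `driver_irw_result` list: `network`, `centralities` (tibble),
#'   `transition`, `prior`, `scores`, `mutation`, `ranking`, `params`.
#' @export
driver_irw <- function(tumor_expr = NULL, normal_expr = NULL, reference = NULL,
                       snv = NULL, cnv = NULL, seeds = NULL,
                       mode = c("full", "uniform_transition", "no_seeds"),
                       alpha_mix = 0.85, d = 0.85, eps = 1e-8, max_iter = 1000L,
                       threshold = 0.05, katz_fraction = 0.85,
                       bc_undirected = FALSE, prepared = NULL) {
  mode <- match.arg(mode)
  if (is.null(prepared)) {
    prepared <- driver_irw_prepare(tumor_expr, normal_expr, reference, snv, cnv,
                                   threshold, katz_fraction, bc_undirected)
  }
  stopifnot(inherits(prepared, "driver_irw_prep"))
  net <- prepared$network
  P <- if (mode == "uniform_transition") {
    build_uniform_transition(net, alpha_mix)
  } else {
    build_transition_matrix(net, alpha_mix)
  }
  prior <- if (mode == "no_seeds") {
    uniform_prior(net)
  } else {
    if (is.null(seeds)) abort("seeds are required unless mode = 'no_seeds'")
    build_prior(seeds, prepared$bc, prepared$kc, net)
  }
  scores <- random_walk(P, prior, prepared$r0, d = d, eps = eps, max_iter = max_iter)
  ranking <- filter_and_rank(scores, prepared$mutation)
  structure(
    list(
      network = net,
      centralities = tibble(
        gene = net$genes,
        degree_out = unname(out_degree(net)$values),
        betweenness = unname(prepared$bc$values),
        katz = unname(prepared$kc$values)
      ),
      transition = P,
      prior = prior,
      scores = scores,
      mutation = prepared$mutation,
      ranking = ranking,
      params = c(prepared$params, list(
        mode = mode, alpha_mix = alpha_mix, d = d, eps = eps,
        max_iter = as.integer(max_iter),
        prior_mode = if (mode == "no_seeds") "uniform" else "seed_centrality",
        katz_series_offset = "closed form (I - alpha A^T)^-1 1, k-from-0 series"
      ))
    ),
    class = "driver_irw_result"
  )
}

#' @export
print.driver_irw_result <- function(x, ...) {
  cat(sprintf(
    "<driver_irw_result> mode = %s; %d-node network; %d ranked gene(s)\n",
    x$params$mode, x$network$n, nrow(x$ranking)
  ))
  print(head(as_tibble(x$ranking), 5))
  invisible(x)
}

#' @export
tidy.driver_irw_result <- function(x, ...) as_tibble(x$ranking)

#' @export
glance.driver_irw_result <- function(x, ...) {
  dplyr::bind_cols(
    tibble(mode = x$params$mode, n_nodes = x$network$n,
           n_edges = sum(x$network$A), n_ranked = nrow(x$ranking)),
    glance(x$scores)[, c("iterations", "converged", "final_diff")]
  )
}

#' Run one ablation arm and evaluate it
#'
#' @param prepared A `driver_irw_prep` (shared network state).
#' @param seeds Seed `gene_set`.
#' @param benchmark Benchmark `gene_set` for the PR curve.
#' @param mode One of `"full"`, `"uniform_transition"`, `"no_seeds"`.
#' @param n_max PR cutoff; default 100.
#' @param ... Passed to [driver_irw()] (`alpha_mix`, `d`, `eps`, `max_iter`).
#' @return List with `result` (a `driver_irw_result`) and `pr` (a
#'   `pr_curve`).
#' @export
run_ablation <- function(prepared, seeds, benchmark,
                         mode = c("full", "uniform_transition", "no_seeds"),
                         n_max = 100L, ...) {
  mode <- match.arg(mode)
  res <- driver_irw(seeds = seeds, mode = mode, prepared = prepared, ...)
  list(result = res, pr = precision_recall_at(res$ranking, benchmark, n_max))
}

#' Seed-subsampling robustness experiment
#'
#' Randomly deletes a fraction of the seed genes (uniformly, without
#' replacement), reruns prior + walk + filter + evaluation, and repeats;
#' reports mean and standard deviation of top-`n_max` precision ("accuracy")
#' and recall per retention fraction, alongside the full-seed run. A repeat
#' whose surviving seeds all fall outside the network runs with the uniform
#' fallback prior and is counted in `n_uniform_fallback`.
#'
#' @param prepared A `driver_irw_prep`.
#' @param seeds Full seed `gene_set`.
#' @param benchmark Benchmark `gene_set`.
#' @param fractions Retention fractions in (0, 1]; default `c(1, 0.9, 0.7,
#'   0.5)` (the full run plus 10/30/50% deletion).
#' @param repeats Repeats per fraction below 1; default 10.
#' @param rng_seed Integer seed making the draws reproducible.
#' @param n_max PR cutoff; default 100.
#' @param ... Passed to [driver_irw()].
#' @return A `seed_subsample_summary` tibble: `fraction`, `n_seeds_kept`,
#'   `mean_precision`, `mean_recall`, `sd_precision`, `sd_recall`,
#'   `n_uniform_fallback`.
#' @export
seed_subsampling <- function(prepared, seeds, benchmark,
                             fractions = c(1, 0.9, 0.7, 0.5), repeats = 10L,
                             rng_seed = 1L, n_max = 100L, ...) {
  stopifnot(all(fractions > 0), all(fractions <= 1), repeats >= 1)
  one_run <- function(seed_subset) {
    res <- driver_irw(seeds = gene_set(seed_subset, name = seeds$name),
                      mode = "full", prepared = prepared, ...)
    pr <- precision_recall_at(res$ranking, benchmark, n_max)
    tibble(
      precision = pr$precision[nrow(pr)],
      recall = pr$recall[nrow(pr)],
      fallback = length(res$prior$seed_genes) == 0
    )
  }
  rows <- withr::with_seed(rng_seed, {
    purrr::map(fractions, function(f) {
      k <- ceiling(f * length(seeds$genes))
      reps <- if (f == 1) 1L else as.integer(repeats)
      runs <- purrr::map(seq_len(reps), function(i) {
        kept <- if (f == 1) seeds$genes else sample(seeds$genes, k, replace = FALSE)
        suppressWarnings(one_run(kept))
      }) |> purrr::list_rbind()
      tibble(
        fraction = f,
        n_seeds_kept = as.integer(k),
        mean_precision = mean(runs$precision),
        mean_recall = mean(runs$recall),
        sd_precision = if (nrow(runs) > 1) sd(runs$precision) else 0,
        sd_recall = if (nrow(runs) > 1) sd(runs$recall) else 0,
        n_uniform_fallback = sum(runs$fallback)
      )
    }) |> purrr::list_rbind()
  })
  new_tibble(rows, n_max = as.integer(n_max), repeats = as.integer(repeats),
             class = "seed_subsample_summary")
}

#' Write pipeline outputs to a directory
#'
#' Emits the ranking (`ranking.tsv`), the walk scores
#' (`scores.tsv`: gene, score, iterations, converged), the centrality table
#' (`centralities.tsv`), and a JSON-like sidecar of run parameters
#' (`run_metadata.json`). Output is byte-identical across reruns on
#' identical inputs.
#'
#' @param result A `driver_irw_result`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_run <- function(result, dir) {
  stopifnot(inherits(result, "driver_irw_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_ranking(result$ranking, file.path(dir, "ranking.tsv"))
  sc <- tidy(result$scores) |>
    dplyr::mutate(
      score = sprintf("%.12f", .data$score),
      iterations = result$scores$iterations,
      converged = result$scores$converged
    )
  readr::write_tsv(sc, file.path(dir, "scores.tsv"))
  cent <- result$centralities |>
    dplyr::mutate(dplyr::across(dplyr::where(is.numeric), ~ sprintf("%.12g", .x)))
  readr::write_tsv(cent, file.path(dir, "centralities.tsv"))
  meta <- result$params
  json <- paste0(
    "{\n",
    paste(sprintf('  "%s": %s', names(meta), vapply(meta, function(v) {
      if (is.character(v)) sprintf('"%s"', v)
      else if (is.logical(v)) tolower(as.character(v))
      else format(v, digits = 15)
    }, character(1))), collapse = ",\n"),
    "\n}\n"
  )
  writeLines(json, file.path(dir, "run_metadata.json"))
  invisible(dir)
}
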