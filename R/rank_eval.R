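# Mutation post-filter, final ranking, and the evaluation protocol:
# top-N precision/recall against a benchmark gene set, plus the
# mutation-frequency sanity baseline.

#' Mutation-filter walk scores into a final ranking
#'
#' Keeps only genes mutated somewhere in the cohort (an SNV or a +2/-2
#' copy-number call in at least one sample), sorts by walk score descending
#' with ties broken by gene identifier ascending, and attaches the
#' per-gene mutated-sample counts.
#'
#' @param scores An `irw_scores` object.
#' @param mutation A `mutation_status` tibble from [build_mutation_status()].
#' @return A `ranked_list` tibble: `rank`, `gene`, `score`,
#'   `mutated_sample_count`. Empty (with a warning) if no scored gene is
#'   mutated.
#' @export
filter_and_rank <- function(scores, mutation) {
  stopifnot(inherits(scores, "irw_scores"), inherits(mutation, "mutation_status"))
  mut <- dplyr::filter(as_tibble(mutation), .data$mutated)
  out <- tibble(gene = scores$genes, score = unname(scores$r)) |>
    dplyr::inner_join(mut[, c("gene", "mutated_sample_count")], by = "gene") |>
    dplyr::arrange(dplyr::desc(.data$score), .data$gene) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1)
  if (nrow(out) == 0) warn("no mutated gene carries a walk score; ranking is empty")
  class(out) <- c("ranked_list", class(out))
  out
}

#' Rank genes by mutation frequency alone
#'
#' Naive baseline: mutated genes sorted by mutated-sample count (ties by gene
#' identifier). Useful as a sanity reference, not as the method.
#'
#' @param mutation A `mutation_status` tibble.
#' @return A `ranked_list` tibble whose `score` is the mutated-sample count.
#' @export
mutation_frequency_ranking <- function(mutation) {
  stopifnot(inherits(mutation, "mutation_status"))
  out <- as_tibble(mutation) |>
    dplyr::filter(.data$mutated) |>
    dplyr::arrange(dplyr::desc(.data$mutated_sample_count), .data$gene) |>
    dplyr::transmute(
      gene = .data$gene,
      score = as.numeric(.data$mutated_sample_count),
      mutated_sample_count = .data$mutated_sample_count
    ) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1)
  class(out) <- c("ranked_list", class(out))
  out
}

#' Top-N precision/recall curve against a benchmark set
#'
#' For every cutoff `N` up to `n_max` (or the ranking length, whichever is
#' smaller): `hits = |top-N genes ∩ benchmark|`, `precision = hits / N`,
#' `recall = hits / |benchmark|`. Benchmark genes absent from the ranking
#' still count in the recall denominator. If the ranking is shorter than
#' `n_max` the curve simply ends early.
#'
#' @param ranked A `ranked_list` tibble.
#' @param benchmark A non-empty `gene_set`.
#' @param n_max Largest cutoff to evaluate; default 100.
#' @return A `pr_curve` tibble with columns `n`, `hits`, `precision`,
#'   `recall` and attributes `benchmark_name`, `benchmark_size`.
#' @export
precision_recall_at <- function(ranked, benchmark, n_max = 100L) {
  stopifnot(inherits(benchmark, "gene_set"))
  if (length(benchmark$genes) == 0) abort("benchmark gene set is empty")
  stopifnot(is.numeric(n_max), length(n_max) == 1, n_max >= 1)
  n_top <- min(as.integer(n_max), nrow(ranked))
  genes <- ranked$gene[seq_len(n_top)]
  hits <- cumsum(genes %in% benchmark$genes)
  out <- tibble(
    n = seq_len(n_top),
    hits = as.integer(hits),
    precision = hits / seq_len(n_top),
    recall = hits / length(benchmark$genes)
  )
  out <- new_tibble(out, benchmark_name = benchmark$name,
                    benchmark_size = length(benchmark$genes),
                    class = "pr_curve")
  out
}

#' @export
glance.pr_curve <- function(x, ...) {
  tibble(
    benchmark = attr(x, "benchmark_name"),
    benchmark_size = attr(x, "benchmark_size"),
    n_max = max(x$n),
    precision_at_max = x$precision[nrow(x)],
    recall_at_max = x$recall[nrow(x)]
  )
}

#' Write a precision/recall curve as TSV
#'
#' @param pr A `pr_curve` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pr_curve <- function(pr, path) {
  readr::write_tsv(as_tibble(pr), path)
  invisible(path)
}
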