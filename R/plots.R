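# ggplot2 views of the tabular results.

#' Plot a precision/recall curve over top-N cutoffs
#'
#' @param object A `pr_curve` tibble.
#' @param ... Unused.
#' @return A ggplot: precision and recall as functions of the cutoff N.
#' @export
autoplot.pr_curve <- function(object, ...) {
  long <- as_tibble(object) |>
    tidyr::pivot_longer(c("precision", "recall"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n, y = .data$value,
                                     color = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "top N genes", y = NULL, color = NULL,
      title = sprintf("Top-N performance vs %s (%d genes)",
                      attr(object, "benchmark_name"), attr(object, "benchmark_size"))
    ) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Compare several precision/recall curves
#'
#' @param curves Named list of `pr_curve` tibbles (e.g. the three ablation
#'   arms).
#' @param metric `"precision"` or `"recall"`.
#' @return A ggplot with one line per curve.
#' @export
plot_pr_comparison <- function(curves, metric = c("precision", "recall")) {
  metric <- match.arg(metric)
  stopifnot(length(curves) > 0, !is.null(names(curves)))
  long <- purrr::imap(curves, function(cu, nm) {
    dplyr::mutate(as_tibble(cu), run = nm)
  }) |> purrr::list_rbind()
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n, y = .data[[metric]],
                                     color = .data$run)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "top N genes", y = metric, color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the seed-subsampling summary
#'
#' @param object A `seed_subsample_summary` tibble.
#' @param ... Unused.
#' @return A ggplot: mean precision and recall (±1 sd) per retention
#'   fraction.
#' @export
autoplot.seed_subsample_summary <- function(object, ...) {
  long <- as_tibble(object) |>
    dplyr::select("fraction", "mean_precision", "mean_recall",
                  "sd_precision", "sd_recall") |>
    tidyr::pivot_longer(-"fraction",
                        names_to = c("stat", "metric"), names_sep = "_",
                        values_to = "value") |>
    tidyr::pivot_wider(names_from = "stat", values_from = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$fraction), y = .data$mean,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$mean - .data$sd, 0),
                   ymax = pmin(.data$mean + .data$sd, 1)),
      position = ggplot2::position_dodge(width = 0.9), width = 0.2
    ) +
    ggplot2::labs(x = "seed retention fraction", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
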