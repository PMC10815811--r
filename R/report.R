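#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d classifier(s), %d run(s), base seed %d\n",
              length(x$classifiers), x$n_runs, as.integer(x$base_seed)))
  wide <- x$summary |>
    dplyr::mutate(cell = sprintf("%.3f ± %.3f", .data$mean, .data$sd)) |>
    dplyr::select("classifier", "metric", "cell") |>
    tidyr::pivot_wider(names_from = "metric", values_from = "cell")
  print(wide, n = Inf)
  invisible(x)
}

#' Tidy an evaluation report into per-run metric rows
#'
#' @param x An `eval_report` from [repeat_experiment()].
#' @param ... Unused.
#' @return A long tibble: `classifier`, `run`, `seed`, `metric`, `value`.
#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) {
  x$runs |>
    tidyr::pivot_longer(-c("classifier", "run", "seed"),
                        names_to = "metric", values_to = "value")
}

#' Summarize an evaluation report, one row per classifier
#'
#' @param x An `eval_report` from [repeat_experiment()].
#' @param ... Unused.
#' @return A tibble with `<metric>_mean` and `<metric>_sd` columns per
#'   classifier, plus `n_runs`.
#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  x$summary |>
    tidyr::pivot_wider(names_from = "metric", values_from = c("mean", "sd"),
                       names_glue = "{metric}_{.value}") |>
    dplyr::mutate(n_runs = x$n_runs)
}

#' Plot classifier performance with run-to-run spread
#'
#' Point-range plot of mean +/- one standard deviation over runs, faceted
#' by metric (training runtime excluded).
#'
#' @param object An `eval_report` from [repeat_experiment()].
#' @param metrics Metrics to show (default the six quality metrics).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot eval_report
#' @export
autoplot.eval_report <- function(object,
                                 metrics = c("accuracy", "precision", "recall",
                                             "f1_weighted", "f1_macro", "roc_auc"),
                                 ...) {
  dat <- dplyr::filter(object$summary, .data$metric %in% metrics)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$classifier, y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = pmax(0, .data$mean - .data$sd),
                                          ymax = pmin(1, .data$mean + .data$sd))) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = NULL, y = sprintf("mean ± sd over %d runs", object$n_runs)) +
    ggplot2::theme_bw()
}

#' Heatmap of a contact map
#'
#' @param map A contact map from [contact_map()].
#' @return A ggplot tile plot with residue indices on both axes.
#' @export
plot_contact_map <- function(map) {
  stopifnot(is.matrix(map))
  df <- expand.grid(i = seq_len(nrow(map)), j = seq_len(ncol(map)))
  df$contact <- as.vector(map)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i,
                                   fill = factor(.data$contact))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(`0` = "grey95", `1` = "grey15"),
                               name = "contact") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "residue j", y = "residue i") +
    ggplot2::theme_minimal()
}
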