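# ggplot2 presentation helpers for the pipeline's result types.

#' Stacked composition bars for an "Others"-aggregated table
#'
#' @param composition A composition tibble from [aggregate_others()].
#' @param metadata Optional sample metadata (`sample_id`, `batch_id`, `day`)
#'   used to order and facet the bars.
#' @return A ggplot object.
#' @export
plot_composition <- function(composition, metadata = NULL) {
  long <- tidyr::pivot_longer(composition, -"taxon_id",
                              names_to = "sample_id", values_to = "proportion")
  if (!is.null(metadata)) {
    long <- dplyr::left_join(long, metadata, by = "sample_id")
    p <- ggplot2::ggplot(long, ggplot2::aes(
      x = factor(.data$day), y = .data$proportion, fill = .data$taxon_id
    )) +
      ggplot2::facet_wrap(~batch_id, nrow = 1) +
      ggplot2::labs(x = "day")
  } else {
    p <- ggplot2::ggplot(long, ggplot2::aes(
      x = .data$sample_id, y = .data$proportion, fill = .data$taxon_id
    )) +
      ggplot2::labs(x = NULL)
  }
  p +
    ggplot2::geom_col(width = 0.9) +
    ggplot2::scale_y_continuous(labels = function(v) 100 * v) +
    ggplot2::labs(y = "relative abundance (%)", fill = "taxon") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Dyeing intensity, pH and ORP over fermentation time
#'
#' @param dataset An `indigo_dataset`.
#' @return A ggplot object with one panel per measured series.
#' @export
plot_fermentation <- function(dataset) {
  dye <- dplyr::select(dataset$dye, "batch_id", "day", value = "intensity") %>%
    dplyr::mutate(series = "dyeing intensity")
  env <- dataset$environment %>%
    dplyr::filter(.data$day %in% dataset$dye$day) %>%
    tidyr::pivot_longer(c("ph", "orp"), names_to = "series", values_to = "value") %>%
    dplyr::select("batch_id", "day", "series", "value")
  both <- dplyr::bind_rows(dye, env)
  ggplot2::ggplot(both, ggplot2::aes(
    x = .data$day, y = .data$value, colour = .data$batch_id
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "day", y = NULL, colour = "batch") +
    ggplot2::theme_minimal()
}

#' Alpha-diversity trajectories
#'
#' @param alpha The tibble returned by [alpha_diversity()] (joined with
#'   metadata so `batch_id` and `day` are present).
#' @return A ggplot object.
#' @export
plot_alpha_diversity <- function(alpha) {
  long <- tidyr::pivot_longer(alpha, c("observed", "shannon"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$day, y = .data$value, colour = .data$batch_id
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "day", y = NULL, colour = "batch") +
    ggplot2::theme_minimal()
}

#' @rdname ko_phenotype_correlation
#' @param x An `indigo_ko_screen`.
#' @param ... Unused.
#' @export
tidy.indigo_ko_screen <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("ko_id", "r", "n_pairs", "hit")])
}

#' @rdname ko_phenotype_correlation
#' @export
glance.indigo_ko_screen <- function(x, ...) {
  tibble(
    n_tested = nrow(x), n_hits = sum(x$hit),
    min_r = attr(x, "min_r"), mode = attr(x, "mode"), method = attr(x, "method")
  )
}

#' @rdname ko_phenotype_correlation
#' @param object An `indigo_ko_screen`.
#' @export
autoplot.indigo_ko_screen <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$r, fill = .data$hit)) +
    ggplot2::geom_histogram(bins = 40, boundary = 0) +
    ggplot2::geom_vline(xintercept = attr(object, "min_r"), linetype = 2) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "correlation with dyeing-intensity change", y = "KO count",
                  fill = "hit") +
    ggplot2::theme_minimal()
}
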