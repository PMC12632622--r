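# ggplot2 helpers for the main result types.

#' Plot barcode frequency trajectories
#'
#' Log-scale frequency over transfers, one line per strain, faceted by
#' replicate. Strains passing `highlight` (e.g. the finalists) are
#' coloured; the rest are grey.
#'
#' @param freq Frequency table (`strain_id`, `replicate`, `timepoint`,
#'   `freq`).
#' @param highlight Optional strain ids to colour.
#' @param min_freq Floor for the log axis.
#' @return A ggplot.
#' @export
plot_trajectories <- function(freq, highlight = NULL, min_freq = 1e-6) {
  assert_columns(freq, c("strain_id", "replicate", "timepoint", "freq"), "freq")
  df <- dplyr::mutate(freq, freq = pmax(.data$freq, min_freq))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$timepoint, y = .data$freq,
                                        group = .data$strain_id))
  if (is.null(highlight)) {
    p <- p + ggplot2::geom_line(alpha = 0.4)
  } else {
    p <- p +
      ggplot2::geom_line(data = df[!df$strain_id %in% highlight, ],
                         colour = "grey70", alpha = 0.4) +
      ggplot2::geom_line(data = df[df$strain_id %in% highlight, ],
                         ggplot2::aes(colour = .data$strain_id),
                         linewidth = 0.8)
  }
  p +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$replicate)) +
    ggplot2::labs(x = "transfer", y = "barcode frequency",
                  colour = "strain")
}

#' @describeIn infer_fitness Starting-position plot: inferred selection
#'   coefficient against initial frequency, with standard-error bars.
#' @param object A `fitness_fit`.
#' @param highlight Optional strain ids to colour.
#' @method autoplot fitness_fit
#' @export
autoplot.fitness_fit <- function(object, highlight = NULL, ...) {
  e <- dplyr::filter(object$estimates, .data$flag %in% c("ok", "boundary"))
  e$highlight <- if (is.null(highlight)) "strain" else
    ifelse(e$strain_id %in% highlight, "highlighted", "other")
  ggplot2::ggplot(e, ggplot2::aes(x = .data$f0_hat, y = .data$s_hat)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$s_hat - .data$se,
                                        ymax = .data$s_hat + .data$se),
                           width = 0, colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$highlight)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "initial frequency", y = "selection coefficient (per generation)",
                  colour = NULL)
}

#' @describeIn coverage_profile Genome-wide binned coverage, normalised to
#'   the genome median, faceted by chromosome.
#' @param object A `coverage_profile`.
#' @param ... Unused.
#' @method autoplot coverage_profile
#' @export
autoplot.coverage_profile <- function(object, ...) {
  b <- object$bins
  b$ratio <- b$mean_depth / object$genome_median
  ggplot2::ggplot(b, ggplot2::aes(x = .data$start / 1000, y = .data$ratio)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.5) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "red") +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), scales = "free_x") +
    ggplot2::labs(x = "position (kb)", y = "depth / genome median")
}

#' Plot diversity decay (N99 over time)
#'
#' Median and interquartile ribbon across replicates.
#'
#' @param diversity Output of [diversity_series()].
#' @return A ggplot.
#' @export
plot_diversity <- function(diversity) {
  s <- diversity$summary
  ggplot2::ggplot(s, ggplot2::aes(x = .data$timepoint, y = .data$median)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "transfer", y = "strains composing 99% of the pool")
}
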