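#' Plot a positional distance profile
#'
#' Shows the observed normalised functional-SNP density around exon
#' boundaries against the resampled null profiles.
#'
#' @param object A `distance_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.distance_profile <- function(object, ...) {
  ggplot2::ggplot() +
    ggplot2::geom_line(
      data = object$random,
      ggplot2::aes(x = .data$bin_mid, y = .data$density,
                   group = .data$set),
      colour = "grey70", alpha = 0.4, na.rm = TRUE
    ) +
    ggplot2::geom_line(
      data = object$observed,
      ggplot2::aes(x = .data$bin_mid, y = .data$density),
      colour = "darkgreen", linewidth = 1, na.rm = TRUE
    ) +
    ggplot2::labs(
      x = "distance to ASAS exon boundary (bp)",
      y = "SNP density / testable SNP density",
      title = "Functional-SNP positional profile",
      subtitle = sprintf("%d resampled testable-SNP sets in grey",
                         object$n_random_sets)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a differential allelic-imbalance scan
#'
#' Effect size (difference in group mean allelic ratios) against
#' significance for every tested tag SNP.
#'
#' @param object A `differential_scan` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.differential_scan <- function(object, ...) {
  dat <- object %>% filter(!is.na(.data$p_value))
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$mean_ad - .data$mean_control,
    y = -log10(pmax(.data$p_value, 1e-300)),
    colour = .data$significant
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = c(-0.1, 0.1), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey50")) +
    ggplot2::labs(x = "mean allelic ratio difference (AD - control)",
                  y = expression(-log[10] ~ p),
                  colour = "significant") +
    ggplot2::theme_minimal()
}

#' Plot an empirical enrichment result
#'
#' Observed term counts against their null means, coloured by
#' significance.
#'
#' @param object An `enrichment_result` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enrichment_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$null_mean, y = .data$query_count,
    colour = .data$significant
  )) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey50")) +
    ggplot2::labs(x = "mean count in matched background sets",
                  y = "count in query set", colour = "significant") +
    ggplot2::theme_minimal()
}

#' Plot event-type proportions of an ASAS summary
#'
#' @param object An `asas_event_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.asas_event_summary <- function(object, ...) {
  ggplot2::ggplot(object$type_proportions,
                  ggplot2::aes(x = .data$type, y = .data$proportion)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "event type", y = "proportion of ASAS events") +
    ggplot2::theme_minimal()
}
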