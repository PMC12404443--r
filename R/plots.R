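# ggplot2 displays for the main result types.

#' Plot a burial profile
#'
#' Bars of smoothed variant-type counts along the burial (rank) axis with
#' the per-residue raw type counts overlaid as points — the standard
#' burial-versus-variability display in which a buried outlier such as
#' TRPV1 M308 appears as a high point at a low rank.
#'
#' @param object A [burial_profile()] (optionally after [discordance()]).
#' @param highlight Optional residue position(s) to label.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.burial_profile <- function(object, highlight = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$rank)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$smoothed), fill = "goldenrod",
                      width = 1, alpha = 0.8) +
    ggplot2::geom_point(ggplot2::aes(y = .data$n_types), size = 0.8) +
    ggplot2::labs(
      x = "residue rank by fractional SASA (buried → exposed)",
      y = "missense variant types (points: raw; bars: smoothed)"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(highlight)) {
    hl <- object %>% filter(.data$position %in% highlight)
    p <- p +
      ggplot2::geom_point(data = hl, ggplot2::aes(y = .data$n_types),
                          colour = "magenta", size = 2) +
      ggplot2::geom_text(
        data = hl,
        ggplot2::aes(y = .data$n_types,
                     label = paste0(.data$restype, .data$position)),
        vjust = -0.8, size = 3
      )
  }
  p
}

#' Plot a Hill dose-response fit
#'
#' Normalized responses on a log concentration axis with the fitted Hill
#' curve and the EC50 marked.
#'
#' @param object A [hill_fit()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hill_fit <- function(object, ...) {
  rng <- range(object$data$conc_uM)
  grid <- tibble(
    conc_uM = exp(seq(log(rng[1]), log(rng[2]), length.out = 200))
  )
  grid$fit <- predict(object, grid)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$conc_uM)) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fit), colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(y = .data$norm_current)) +
    ggplot2::geom_vline(xintercept = object$EC50, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "capsaicin (µM)", y = "normalized current",
      subtitle = sprintf("EC50 = %.3g µM, n = %.2f", object$EC50, object$n)
    ) +
    ggplot2::theme_minimal()
}

#' Plot an idealized single-channel trace
#'
#' The current trace with the idealized occupancy path overlaid at the
#' unitary-current scale.
#'
#' @param object An [idealize_half_amplitude()] result.
#' @param max_points Downsample the display to at most this many samples
#'   (default 20000) so long recordings stay plottable.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.idealized_trace <- function(object, max_points = 20000, ...) {
  tr <- object$trace
  if (nrow(tr) > max_points) {
    tr <- tr[seq(1, nrow(tr), length.out = max_points), ]
  }
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$time_s)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$current_pA), colour = "grey55",
                       linewidth = 0.2) +
    ggplot2::geom_step(ggplot2::aes(y = .data$state * object$unitary_current),
                       colour = "firebrick") +
    ggplot2::labs(
      x = "time (s)", y = "current (pA)",
      subtitle = sprintf("Po = %.3f (k = %d)", object$po, object$n_channels)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a binned current-temperature relation
#'
#' @param relation Output of [temperature_relation()].
#' @return A ggplot object.
#' @export
plot_temperature_relation <- function(relation) {
  assert_columns(relation, c("temp_bin", "median_norm", "sem"), "`relation`")
  ggplot2::ggplot(relation, ggplot2::aes(x = .data$temp_bin, y = .data$median_norm)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$median_norm - .data$sem,
                                        ymax = .data$median_norm + .data$sem),
                           width = 0.6) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "temperature (°C)",
                  y = "current normalized to room temperature") +
    ggplot2::theme_minimal()
}
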