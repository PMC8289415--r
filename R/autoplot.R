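#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a topology-weighting profile
#'
#' One line per topology (or the single tracked one) across window
#' positions; the association signal is a run of near-1 weights for the
#' phenotype topology.
#'
#' @param object a [weighting_profile()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.weight_profile <- function(object, ...) {
  mid <- (object$start + object$end) / 2
  ggplot2::ggplot(dplyr::mutate(object, mid = mid),
                  ggplot2::aes(x = mid, y = .data$weight,
                               colour = .data$topology)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "window midpoint (bp)", y = "topology weight") +
    ggplot2::theme_minimal()
}

#' Plot per-group normalized depth profiles
#'
#' @param profiles output of [group_mean_depth()].
#' @param drops optional drop calls from [detect_drops()] to shade.
#' @return a ggplot.
#' @export
plot_group_depth <- function(profiles, drops = NULL) {
  p <- ggplot2::ggplot(profiles,
                       ggplot2::aes(x = (.data$start + .data$end) / 2,
                                    y = .data$mean_norm,
                                    colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "position (bp)", y = "normalized depth") +
    ggplot2::theme_minimal()
  if (!is.null(drops) && nrow(drops))
    p <- p + ggplot2::annotate("rect", xmin = drops$start, xmax = drops$end,
                               ymin = -Inf, ymax = Inf, alpha = 0.15,
                               fill = "orange")
  p
}

#' Plot a virtual-4C profile
#'
#' @param profile output of [virtual_profile()].
#' @return a ggplot.
#' @export
plot_virtual_4c <- function(profile) {
  ggplot2::ggplot(profile[!profile$is_anchor, ],
                  ggplot2::aes(x = (.data$start + .data$end) / 2,
                               y = .data$count)) +
    ggplot2::geom_col(width = profile$end[1] - profile$start[1]) +
    ggplot2::geom_vline(xintercept = mean(c(profile$start[profile$is_anchor],
                                            profile$end[profile$is_anchor])),
                        colour = "red", linetype = 2) +
    ggplot2::labs(x = "position (bp)", y = "contacts with anchor") +
    ggplot2::theme_minimal()
}

#' Plot a coverage track with called peaks
#'
#' @param track per-base tibble (`pos`, `coverage`).
#' @param peaks optional [call_peaks()] intervals to shade.
#' @return a ggplot.
#' @export
plot_track <- function(track, peaks = NULL) {
  p <- ggplot2::ggplot(track, ggplot2::aes(x = .data$pos, y = .data$coverage)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "position (bp)", y = "coverage") +
    ggplot2::theme_minimal()
  if (!is.null(peaks) && nrow(peaks))
    p <- p + ggplot2::annotate("rect", xmin = peaks$start, xmax = peaks$end,
                               ymin = -Inf, ymax = Inf, alpha = 0.15,
                               fill = "steelblue")
  p
}

#' Plot the power spectrum behind a spacing estimate
#'
#' @param object a [ridge_spacing()] estimate.
#' @param trace the trace the estimate came from.
#' @param pixel micrometres per point (defaults to the trace attribute).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.spacing_estimate <- function(object, trace, pixel = NULL, ...) {
  if (is.data.frame(trace)) {
    pixel <- pixel %||% attr(trace, "pixel")
    trace <- trace$intensity
  }
  n <- length(trace)
  y <- trace - fitted(lm(trace ~ seq_len(n)))
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  p <- Mod(fft(y * w))^2
  freq <- (seq_len(n) - 1) / (n * pixel)
  half <- 2:(n %/% 2)
  df <- tibble::tibble(frequency = freq[half], power = p[half])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frequency, y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$frequency, colour = "red",
                        linetype = 2) +
    ggplot2::coord_cartesian(xlim = c(0, 2 * object$frequency)) +
    ggplot2::labs(x = "spatial frequency (1/um)", y = "power") +
    ggplot2::theme_minimal()
}
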