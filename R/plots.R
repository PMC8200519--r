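#' Plot a stimulus trace
#'
#' @param object a `stim_trace`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.stim_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_s, .data$intensity)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "intensity (drive units)",
                  title = paste0("stimulus: ", attr(object, "kind"))) +
    ggplot2::theme_minimal()
}

#' Raster + population-rate view of a simulation
#'
#' @param object a `sim_result`.
#' @param max_units number of units drawn in the raster panel.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.sim_result <- function(object, max_units = 100, ...) {
  r <- object$raster
  keep <- sort(unique(r$unit))
  if (length(keep) > max_units) keep <- keep[seq_len(max_units)]
  r <- dplyr::filter(r, .data$unit %in% keep)
  ggplot2::ggplot(r, ggplot2::aes(.data$time_s, .data$unit,
                                  colour = .data$pool)) +
    ggplot2::geom_point(shape = ".", alpha = 0.6) +
    ggplot2::labs(x = "time (s)", y = "unit",
                  title = sprintf("%s raster (%d of %d units)",
                                  object$model, length(keep),
                                  length(unique(object$raster$unit)))) +
    ggplot2::theme_minimal()
}

#' Time-frequency power plot
#'
#' @param object a `tfr`.
#' @param trans power transform for display, default `log10`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.tfr <- function(object, trans = log10, ...) {
  d <- tidy(object)
  d$power <- trans(pmax(d$power, .Machine$double.xmin))
  ggplot2::ggplot(d, ggplot2::aes(.data$time_s, .data$freq,
                                  fill = .data$power)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "power") +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)") +
    ggplot2::theme_minimal()
}

#' Hysteresis loop plot
#'
#' @param object a `hysteresis_curve`.
#' @param what `"freq"` or `"power"`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.hysteresis_curve <- function(object, what = c("freq", "power"),
                                      ...) {
  what <- match.arg(what)
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$intensity, .data[[what]],
                                  colour = .data$phase)) +
    ggplot2::geom_path() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "stimulus intensity (drive units)",
                  y = if (what == "freq") "peak frequency (Hz)"
                      else "band power") +
    ggplot2::theme_minimal()
}

#' Spike-triggered average plot with null band
#'
#' @param object an `sta_result`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.sta_result <- function(object, ...) {
  mu <- attr(object, "signal_mean")
  nb <- attr(object, "null_band")
  ggplot2::ggplot(object, ggplot2::aes(.data$lag_s * 1000,
                                       .data$mean_signal)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf, ymin = mu - nb,
                      ymax = mu + nb, alpha = 0.15) +
    ggplot2::geom_hline(yintercept = mu, linetype = 2, linewidth = 0.3) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::labs(x = "lag (ms, negative = before spike)",
                  y = "mean signal",
                  subtitle = sprintf("%d triggers; shaded: +/-3 SE null band",
                                     attr(object, "n_triggers"))) +
    ggplot2::theme_minimal()
}

#' PPC spectrum plot
#'
#' @param object a `ppc_spectrum`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.ppc_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$freq, .data$ppc)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "frequency (Hz)", y = "pairwise phase consistency") +
    ggplot2::theme_minimal()
}

#' Granger-causality spectrum plot
#'
#' @param object a `gc_result`.
#' @param boot optional [bootstrap_gc()] tibble for the uncertainty ribbon.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.gc_result <- function(object, boot = NULL, ...) {
  d <- tidyr::pivot_longer(as_tibble(object), c("gc_xy", "gc_yx"),
                           names_to = "direction", values_to = "gc")
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$freq, .data$gc,
                                       colour = .data$direction))
  if (!is.null(boot)) {
    p <- p +
      ggplot2::geom_ribbon(data = boot,
                           ggplot2::aes(.data$freq, ymin = .data$lo_xy,
                                        ymax = .data$hi_xy),
                           inherit.aes = FALSE, alpha = 0.2) +
      ggplot2::geom_ribbon(data = boot,
                           ggplot2::aes(.data$freq, ymin = .data$lo_yx,
                                        ymax = .data$hi_yx),
                           inherit.aes = FALSE, alpha = 0.2)
  }
  p + ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(gc_xy = "#c23b22",
                                            gc_yx = "#4477aa"),
                                 labels = c(gc_xy = "input to output",
                                            gc_yx = "output to input")) +
    ggplot2::labs(x = "frequency (Hz)", y = "Granger causality") +
    ggplot2::theme_minimal()
}

#' Latency-fit plot: relative phase versus frequency
#'
#' @param object a `latency_estimate`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.latency_estimate <- function(object, ...) {
  ggplot2::ggplot(object$phases,
                  ggplot2::aes(.data$freq, .data$phase_unwrapped)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4) +
    ggplot2::labs(x = "stimulation frequency (Hz)",
                  y = "relative phase (rad)",
                  subtitle = sprintf("slope implies latency %.2f ms",
                                     object$latency_ms)) +
    ggplot2::theme_minimal()
}
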