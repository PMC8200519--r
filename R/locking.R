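#' Spike-triggered average of a continuous signal
#'
#' Averages signal segments centered on spike times (reverse correlation).
#' With a white-noise input signal, the average reveals the input pattern
#' that causally precedes spikes. Spikes whose window does not fit inside the
#' signal are dropped and counted. The `null_band` attribute is the +/- 3
#' standard-error band expected for a signal unrelated to the spikes
#' (`3 * sd(signal) / sqrt(n_triggers)`).
#'
#' @param signal tibble with `time_s` and a value column, or numeric vector
#'   (then `fs` is required and time starts at 0).
#' @param spike_times trigger times (s).
#' @param window_halfwidth half-width of the lag window (s), default 0.1.
#' @param fs sampling rate for bare numeric signals.
#' @return An `sta_result`: tibble `lag_s`, `mean_signal` with attributes
#'   `n_triggers`, `n_dropped`, `null_band`, `signal_mean`.
#' @export
spike_triggered_average <- function(signal, spike_times,
                                    window_halfwidth = 0.1, fs = NULL) {
  xs <- extract_signal(signal, fs)
  x <- xs$x; fs <- xs$fs; t0 <- xs$t0
  half <- round(window_halfwidth * fs)
  idx <- round((spike_times - t0) * fs) + 1L
  ok <- idx - half >= 1L & idx + half <= length(x)
  n_drop <- sum(!ok)
  idx <- idx[ok]
  if (!length(idx)) abort("zero usable triggers (all windows fall outside)")
  acc <- numeric(2L * half + 1L)
  for (i in idx) acc <- acc + x[(i - half):(i + half)]
  m <- acc / length(idx)
  out <- tibble(lag_s = (-half:half) / fs, mean_signal = m)
  structure(out, class = c("sta_result", class(out)),
            n_triggers = length(idx), n_dropped = n_drop,
            null_band = 3 * sd(x) / sqrt(length(idx)),
            signal_mean = mean(x))
}

#' @export
print.sta_result <- function(x, ...) {
  cat(sprintf("<sta_result> %d triggers (%d dropped), +/-%.0f ms, null band %.4g\n",
              attr(x, "n_triggers"), attr(x, "n_dropped"),
              1000 * max(x$lag_s), attr(x, "null_band")))
  NextMethod()
}

#' Oscillatory structure of a spike-triggered average
#'
#' `sta_side_lobes()` counts local maxima of the demeaned STA that exceed
#' the +/-3 SE null band inside a lag range (default the 60 ms before the
#' spike): a white-noise STA with no transmission has none, while
#' gamma-resonant transmission produces one lobe per resonance cycle.
#' `sta_band_amplitude()` measures the amplitude of the STA's component at
#' one frequency over a lag range, the quantitative version of "the STA is
#' modulated at frequency f".
#'
#' @param sta an [spike_triggered_average()] result.
#' @param lag_range `c(lo, hi)` lags (s) examined.
#' @return `sta_side_lobes()`: integer count; `sta_band_amplitude()`:
#'   amplitude in signal units.
#' @export
sta_side_lobes <- function(sta, lag_range = c(-0.06, 0)) {
  d <- sta$mean_signal - attr(sta, "signal_mean")
  keep <- sta$lag_s >= lag_range[1] & sta$lag_s <= lag_range[2]
  d <- d[keep]
  nb <- attr(sta, "null_band")
  n <- length(d)
  if (n < 3) return(0L)
  pk <- which(d[2:(n - 1)] > d[1:(n - 2)] & d[2:(n - 1)] >= d[3:n]) + 1L
  sum(d[pk] > nb)
}

#' @rdname sta_side_lobes
#' @param freq frequency (Hz) at which the modulation is measured.
#' @export
sta_band_amplitude <- function(sta, freq, lag_range = c(-0.05, -0.002)) {
  k <- sta$lag_s >= lag_range[1] & sta$lag_s <= lag_range[2]
  x <- sta$mean_signal[k] - mean(sta$mean_signal[k])
  2 * Mod(sum(x * exp(-2i * pi * freq * sta$lag_s[k]))) / sum(k)
}

#' @rdname sta_side_lobes
#' @export
sta_band_phase <- function(sta, freq, lag_range = c(-0.05, 0)) {
  k <- sta$lag_s >= lag_range[1] & sta$lag_s <= lag_range[2]
  x <- sta$mean_signal[k] - mean(sta$mean_signal[k])
  Arg(sum(x * exp(-2i * pi * freq * sta$lag_s[k])))
}

#' Pairwise phase consistency (PPC) between spikes and a field signal
#'
#' For each spike, the surrounding field epoch is Hann tapered and Fourier
#' transformed at each frequency, giving the spike's field phase. PPC is the
#' average cosine of the phase difference across all unordered spike pairs,
#' computed in closed form as `(|sum e^{i theta}|^2 - n) / (n (n - 1))`. Its
#' expectation does not depend on the number of spikes, which is what makes
#' it preferable to resultant-length measures for comparing conditions with
#' different spike counts. Epochs are +/- 0.5 s for frequencies up to 20 Hz
#' and +/- 0.25 s above 20 Hz; spikes whose epoch does not fit are dropped
#' per frequency.
#'
#' @param spike_times spike times (s); at least 2 with valid epochs.
#' @param lfp field signal: tibble with `time_s` + value column, or numeric
#'   vector with `fs`.
#' @param freqs frequencies (Hz).
#' @param fs sampling rate for bare numeric signals.
#' @return A `ppc_spectrum` tibble: `freq`, `ppc`, `n_spikes`,
#'   `epoch_halfwidth` (s).
#' @export
ppc <- function(spike_times, lfp, freqs, fs = NULL) {
  xs <- extract_signal(lfp, fs)
  x <- xs$x; fs <- xs$fs; t0 <- xs$t0
  idx <- round((spike_times - t0) * fs) + 1L
  out <- purrr::map_dfr(freqs, function(f) {
    hw <- if (f <= 20) 0.5 else 0.25
    half <- round(hw * fs)
    ok <- idx - half >= 1L & idx + half <= length(x)
    n <- sum(ok)
    if (n < 2L)
      return(tibble(freq = f, ppc = NA_real_, n_spikes = n,
                    epoch_halfwidth = hw))
    taper <- hann_window(2L * half + 1L)
    carr <- taper * exp(-2i * pi * f * (-half:half) / fs)
    z <- vapply(idx[ok], function(i) {
      v <- sum(x[(i - half):(i + half)] * carr)
      v / Mod(v)
    }, complex(1))
    R2 <- Mod(sum(z))^2
    tibble(freq = f, ppc = (R2 - n) / (n * (n - 1)), n_spikes = n,
           epoch_halfwidth = hw)
  })
  if (all(is.na(out$ppc))) abort("fewer than 2 spikes with valid epochs")
  class(out) <- c("ppc_spectrum", class(out))
  out
}

#' Cross-correlation between a spike density and a stimulus
#'
#' Pearson correlation coefficient as a function of the time shift of the
#' stimulus relative to the response. Entrainment strength is summarized as
#' the modulation depth, the peak-to-trough distance of the correlation
#' function; `peak_lag` is the shift maximizing the correlation (positive =
#' response lags the stimulus).
#'
#' @param density response signal (tibble with `time_s` or numeric).
#' @param stimulus stimulus signal on the same grid (`stim_trace`, tibble, or
#'   numeric).
#' @param max_lag maximum shift examined (s).
#' @param fs sampling rate if both inputs are bare vectors.
#' @return List with `correlation` (tibble `lag_s`, `r`), `modulation_depth`,
#'   `peak_lag` (s).
#' @export
xcorr_modulation <- function(density, stimulus, max_lag = 0.05, fs = NULL) {
  a <- extract_signal(density, fs)
  b <- extract_signal(stimulus, a$fs)
  if (sd(a$x) == 0 || sd(b$x) == 0)
    abort("constant input: correlation undefined")
  n <- min(length(a$x), length(b$x))
  x <- a$x[seq_len(n)]; y <- b$x[seq_len(n)]
  L <- round(max_lag * a$fs)
  lags <- -L:L
  r <- vapply(lags, function(l) {
    # correlate response(t) with stimulus(t - l)
    if (l >= 0) stats::cor(x[(1 + l):n], y[seq_len(n - l)])
    else stats::cor(x[seq_len(n + l)], y[(1 - l):n])
  }, numeric(1))
  list(correlation = tibble(lag_s = lags / a$fs, r = r),
       modulation_depth = max(r) - min(r),
       peak_lag = lags[which.max(r)] / a$fs)
}

#' Response latency from the slope of the relative-phase spectrum
#'
#' A fixed conduction delay produces a relative phase between drive and
#' response that grows linearly with stimulation frequency; the latency is
#' read off the slope of that line. Per stimulation frequency, the relative
#' phase is the argument of the cross-spectrum (response relative to
#' stimulus) over the analyzed period; phases are unwrapped across increasing
#' frequency by progressively fitting a line and choosing, for each new
#' frequency, the 2 pi branch closest to the prediction, which also handles
#' delays long enough to wrap by more than pi between adjacent frequencies.
#' The fitted line has a free intercept (non-delay phase offsets are absorbed
#' there) and latency = -slope / (2 pi) * 1000 ms.
#'
#' @param stimuli list of sinusoidal `stim_trace`s, one per frequency.
#' @param responses list of responses on the same grids (tibbles or vectors).
#' @param freqs stimulation frequencies (Hz), default c(5, 10, 20, 40, 80).
#' @param analysis_window `c(t0, t1)` (s) of the steady-state period used;
#'   default drops the first 0.5 s.
#' @return A `latency_estimate`: list with `phases` (tibble `freq`,
#'   `phase_raw`, `phase_unwrapped`), `slope` (rad/Hz), `latency_ms`,
#'   `fit_residual` (RMS rad), `wrap_flag`.
#' @export
phase_slope_latency <- function(stimuli, responses,
                                freqs = c(5, 10, 20, 40, 80),
                                analysis_window = NULL) {
  if (length(freqs) < 2L) abort("need at least 2 stimulation frequencies")
  stopifnot(length(stimuli) == length(freqs),
            length(responses) == length(freqs))
  ord <- order(freqs)
  ph <- vapply(seq_along(freqs), function(i) {
    s <- extract_signal(stimuli[[i]], NULL)
    r <- extract_signal(responses[[i]], s$fs)
    n <- min(length(s$x), length(r$x))
    win <- if (is.null(analysis_window)) c(0.5, n / s$fs)
           else analysis_window
    keep <- seq_len(n)[(seq_len(n) - 1) / s$fs >= win[1] &
                       (seq_len(n) - 1) / s$fs <= win[2]]
    xs <- s$x[keep] - mean(s$x[keep])
    xr <- r$x[keep] - mean(r$x[keep])
    if (sd(xr) == 0 || sd(xs) == 0) return(NA_real_)
    carr <- exp(-2i * pi * freqs[i] * (seq_along(keep) - 1) / s$fs)
    # cross-spectrum response x conj(stimulus): delay tau -> phase -2 pi f tau
    Arg(sum(xr * carr) * Conj(sum(xs * carr)))
  }, numeric(1))
  if (any(is.na(ph))) abort("undefined fit: a response carries no signal")
  f_ord <- freqs[ord]; p_raw <- ph[ord]
  # progressive unwrap: project each phase onto the branch nearest the
  # prediction of the line fitted through the frequencies handled so far
  p_un <- p_raw
  wrap_flag <- FALSE
  for (i in seq_along(f_ord)[-1]) {
    pred <- if (i == 2L) p_un[1] else {
      ft <- lm(p ~ f, data = data.frame(f = f_ord[1:(i - 1)],
                                        p = p_un[1:(i - 1)]))
      unname(stats::predict(ft, data.frame(f = f_ord[i])))
    }
    k <- round((pred - p_raw[i]) / (2 * pi))
    p_un[i] <- p_raw[i] + 2 * pi * k
    if (abs(p_un[i] - p_un[i - 1]) > pi) wrap_flag <- TRUE
  }
  fit <- lm(p ~ f, data = data.frame(f = f_ord, p = p_un))
  slope <- unname(coef(fit)[2])
  structure(list(
    phases = tibble(freq = f_ord, phase_raw = p_raw, phase_unwrapped = p_un),
    slope = slope,
    latency_ms = -slope / (2 * pi) * 1000,
    fit_residual = sqrt(mean(stats::residuals(fit)^2)),
    wrap_flag = wrap_flag
  ), class = "latency_estimate")
}

#' @export
print.latency_estimate <- function(x, ...) {
  cat(sprintf("<latency_estimate> %.3f ms (slope %.4f rad/Hz, RMS resid %.3g%s)\n",
              x$latency_ms, x$slope, x$fit_residual,
              if (x$wrap_flag) ", phase steps wrapped" else ""))
  invisible(x)
}

#' @rdname phase_slope_latency
#' @param x a `latency_estimate`.
#' @param ... unused.
#' @export
tidy.latency_estimate <- function(x, ...) x$phases

#' @rdname phase_slope_latency
#' @export
glance.latency_estimate <- function(x, ...) {
  tibble(latency_ms = x$latency_ms, slope = x$slope,
         fit_residual = x$fit_residual, wrap_flag = x$wrap_flag)
}
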