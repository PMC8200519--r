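#' Optogenetic-style stimulus protocols
#'
#' `generate_stimulus()` builds the discrete-time intensity trace of one of the
#' six stimulation protocols used to probe network resonance: constant light,
#' a linear ramp, a single slow sine (half-period raised cosine), a slow
#' Gaussian intensity profile, a fast sinusoid oscillating between zero and a
#' maximum, and Gaussian white noise. Intensities are in abstract drive units
#' (the mapping to model input current is the simulator's `drive_gain`).
#'
#' A stimulus trace is a tibble with columns `time_s` and `intensity` and
#' attributes `fs` (sampling rate, Hz), `kind`, and `params`. The default
#' sampling rate of 1017.1 Hz matches the update rate of the laser control
#' system the protocols emulate.
#'
#' Protocol parameters (all optional, with protocol-specific defaults):
#' \describe{
#'   \item{level}{constant: intensity (default 1).}
#'   \item{from, to}{ramp: start and end intensity (defaults 0, 1).}
#'   \item{peak}{slow_sine / gauss_profile: maximum intensity (default 1).}
#'   \item{sd_s}{gauss_profile: width in seconds (default `duration/6`).}
#'   \item{freq, max}{sinusoid: frequency in Hz (must be below Nyquist) and
#'     maximum intensity; the waveform is `max/2 * (1 - cos(2 pi f t))`, so it
#'     oscillates between 0 and `max` with mean `max/2`.}
#'   \item{mean}{white_noise: mean intensity; see [generate_white_noise()].}
#' }
#'
#' @param kind one of `"constant"`, `"ramp"`, `"slow_sine"`, `"gauss_profile"`,
#'   `"sinusoid"`, `"white_noise"`.
#' @param duration trace duration (s).
#' @param fs sampling rate (Hz); default 1017.1.
#' @param seed integer seed, used only by `white_noise`.
#' @param ... protocol parameters, see Details.
#' @return A `stim_trace` tibble (`time_s`, `intensity`).
#' @examples
#' ramp <- generate_stimulus("ramp", duration = 3, from = 0, to = 1)
#' sine <- generate_stimulus("sinusoid", duration = 2, freq = 40, max = 1)
#' @export
generate_stimulus <- function(kind, duration, fs = 1017.1, seed = 1L, ...) {
  kinds <- c("constant", "ramp", "slow_sine", "gauss_profile", "sinusoid",
             "white_noise")
  if (!is.character(kind) || length(kind) != 1L || !kind %in% kinds) {
    abort(paste0("unknown stimulus kind; must be one of: ",
                 paste(kinds, collapse = ", ")))
  }
  if (!is.numeric(duration) || duration <= 0) abort("duration must be > 0")
  if (!is.numeric(fs) || fs <= 0) abort("fs must be > 0")
  params <- list(...)
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs

  p <- function(name, default) if (!is.null(params[[name]])) params[[name]] else default

  x <- switch(kind,
    constant = {
      level <- p("level", 1)
      if (level < 0) abort("negative levels are not allowed")
      rep(level, n)
    },
    ramp = {
      from <- p("from", 0); to <- p("to", 1)
      if (from < 0 || to < 0) abort("negative levels are not allowed")
      if (n == 1L) from else from + (to - from) * (t / duration)
    },
    slow_sine = {
      peak <- p("peak", 1)
      if (peak < 0) abort("negative levels are not allowed")
      # half-period raised cosine: 0 at both ends, peak at duration/2
      peak * 0.5 * (1 - cos(2 * pi * t / duration))
    },
    gauss_profile = {
      peak <- p("peak", 1)
      sd_s <- p("sd_s", duration / 6)
      if (peak < 0) abort("negative levels are not allowed")
      peak * exp(-(t - duration / 2)^2 / (2 * sd_s^2))
    },
    sinusoid = {
      freq <- p("freq", 40); mx <- p("max", 1)
      if (mx < 0) abort("negative levels are not allowed")
      if (freq >= fs / 2) abort("sinusoid frequency must be below Nyquist (fs/2)")
      mx * 0.5 * (1 - cos(2 * pi * freq * t))
    },
    white_noise = {
      tr <- generate_white_noise(mean = p("mean", 1), fs = fs,
                                 duration = duration, seed = seed,
                                 max_level = p("max_level", Inf))
      return(tr)
    }
  )
  new_stim_trace(x, fs = fs, kind = kind,
                 params = c(params, list(duration = duration, seed = seed)))
}

#' Truncated Gaussian white-noise stimulus
#'
#' Intensities are i.i.d. Gaussian with standard deviation equal to half the
#' mean, updated at `fs` (default 1017.1 Hz). Samples falling outside
#' mean +/- 3.5 sd, at or below zero, or at or above `max_level` are redrawn
#' (rejection resampling, not clipping), so the delivered intensity range
#' strictly excludes both zero and the maximum, and no point masses appear at
#' the truncation bounds.
#'
#' @param mean mean intensity (> 0); the sd is `mean/2`.
#' @param fs sampling (update) rate in Hz.
#' @param duration duration (s).
#' @param seed integer seed; the trace is reproducible bit-for-bit.
#' @param max_level optional hard upper intensity bound (default `Inf`, in
#'   which case the upper bound is `mean + 3.5 sd`).
#' @return A `stim_trace` tibble.
#' @export
generate_white_noise <- function(mean, fs = 1017.1, duration = 1, seed = 1L,
                                 max_level = Inf) {
  if (!is.numeric(mean) || mean <= 0) abort("white-noise mean must be > 0")
  if (duration <= 0) abort("duration must be > 0")
  s <- mean / 2
  lo <- max(0, mean - 3.5 * s)
  hi <- min(max_level, mean + 3.5 * s)
  n <- round(duration * fs)
  x <- withr_seed(seed, {
    out <- rnorm(n, mean, s)
    bad <- which(out <= lo | out >= hi)
    while (length(bad) > 0L) {
      out[bad] <- rnorm(length(bad), mean, s)
      bad <- bad[out[bad] <= lo | out[bad] >= hi]
    }
    out
  })
  new_stim_trace(x, fs = fs, kind = "white_noise",
                 params = list(mean = mean, sd = s, duration = duration,
                               seed = seed, max_level = max_level))
}

new_stim_trace <- function(x, fs, kind, params) {
  out <- tibble(time_s = (seq_along(x) - 1) / fs, intensity = as.numeric(x))
  class(out) <- c("stim_trace", class(out))
  attr(out, "fs") <- fs
  attr(out, "kind") <- kind
  attr(out, "params") <- params
  out
}

#' @export
print.stim_trace <- function(x, ...) {
  cat(sprintf("<stim_trace> kind=%s fs=%g Hz n=%d (%.3f s)\n",
              attr(x, "kind"), attr(x, "fs"), nrow(x),
              nrow(x) / attr(x, "fs")))
  NextMethod()
}

#' Sampling rate of a stimulus trace
#' @param x a `stim_trace`.
#' @return Sampling rate in Hz.
#' @export
stim_fs <- function(x) attr(x, "fs")

#' Resample a stimulus trace by zero-order hold
#'
#' Holds each intensity value constant between update ticks, which is how the
#' control hardware delivers a coarse command sequence on a finer physical
#' time base. Per-tick values are preserved exactly.
#'
#' @param x a `stim_trace`.
#' @param fs_new target sampling rate (Hz), normally finer than `stim_fs(x)`.
#' @return A `stim_trace` at `fs_new`.
#' @export
stim_resample <- function(x, fs_new) {
  fs <- stim_fs(x)
  n_new <- round(nrow(x) / fs * fs_new)
  idx <- pmin(nrow(x), floor((seq_len(n_new) - 1) / fs_new * fs + 1e-9) + 1L)
  new_stim_trace(x$intensity[idx], fs = fs_new, kind = attr(x, "kind"),
                 params = attr(x, "params"))
}

#' Stimulus intensity at arbitrary times (zero-order hold)
#' @param x a `stim_trace`.
#' @param times times (s) at which to evaluate.
#' @return Intensities at `times`, holding each tick's value.
#' @export
stim_at <- function(x, times) {
  fs <- stim_fs(x)
  idx <- pmin(nrow(x), pmax(1L, floor(times * fs + 1e-9) + 1L))
  x$intensity[idx]
}

#' Write / read a stimulus trace as two-column CSV
#'
#' The CSV holds `time_s,intensity`; sampling rate, kind and parameters go to
#' a JSON sidecar `<path>.json`.
#'
#' @param x a `stim_trace`.
#' @param path CSV file path.
#' @return `write_stim_csv()` returns `path` invisibly; `read_stim_csv()`
#'   returns the `stim_trace`.
#' @export
write_stim_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x[, c("time_s", "intensity")]), path,
                   row.names = FALSE)
  meta <- list(fs = stim_fs(x), kind = attr(x, "kind"),
               params = attr(x, "params"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_stim_csv
#' @export
read_stim_csv <- function(path) {
  d <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new_stim_trace(d$intensity, fs = meta$fs, kind = meta$kind,
                 params = meta$params)
}

# run expr with a local RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
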