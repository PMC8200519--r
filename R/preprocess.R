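#' Gaussian spike density
#'
#' Convolves spike times with a Gaussian kernel truncated at +/- 2 sd and
#' renormalized to unit mass, so the integral of the density equals the spike
#' count exactly. The conventional widths are sd = 12.5 ms for constant and
#' slowly varying stimulation and sd = 1.25 ms for pulse-train and sinusoidal
#' stimulation.
#'
#' @param spike_times numeric vector of spike times (s); may be empty.
#' @param sigma_ms kernel standard deviation (ms).
#' @param fs_out output sampling rate (Hz).
#' @param t_range output window `c(t0, t1)` (s); defaults to `[0, max spike]`.
#' @return Tibble `time_s`, `density` (spikes/s).
#' @export
spike_density <- function(spike_times, sigma_ms = 12.5, fs_out = 1000,
                          t_range = NULL) {
  if (is.null(t_range)) {
    t_range <- c(0, if (length(spike_times)) max(spike_times) else 1)
  }
  n <- max(1L, round((t_range[2] - t_range[1]) * fs_out))
  tt <- t_range[1] + (seq_len(n) - 1) / fs_out
  dens <- numeric(n)
  if (length(spike_times)) {
    sig <- sigma_ms / 1000
    half <- ceiling(2 * sig * fs_out)           # kernel support: +/- 2 sd
    kt <- (-half:half) / fs_out
    kern <- exp(-kt^2 / (2 * sig^2))
    kern[abs(kt) > 2 * sig] <- 0
    kern <- kern / sum(kern) * fs_out           # unit mass after truncation
    counts <- numeric(n + 2L * half)
    idx <- round((spike_times - t_range[1]) * fs_out) + 1L + half
    keep <- idx >= 1L & idx <= length(counts)
    for (i in idx[keep]) counts[i] <- counts[i] + 1
    dens <- as.numeric(stats::convolve(counts, rev(kern), type = "filter"))
    dens <- dens[seq_len(n)]
  }
  tibble(time_s = tt, density = dens)
}

#' Sliding-window time-frequency power
#'
#' For each frequency the analysis window is 4 cycles long
#' (`round(4 fs / f)` samples), moved across the signal in steps of `step_ms`.
#' Each windowed epoch is Hann tapered, Fourier transformed at the window's
#' own frequency, squared and divided by the window length, giving power
#' density per (time, frequency). Windows are interior-only (no padding); the
#' common time axis is the intersection of the per-frequency valid ranges, so
#' it is set by the lowest frequency's window.
#'
#' @param signal numeric vector, or tibble with a `value`/`density`/`field`
#'   column and `time_s`.
#' @param fs sampling rate (Hz); taken from `time_s` if `signal` is a tibble.
#' @param freqs frequencies (Hz) to evaluate.
#' @param step_ms sliding step (ms), default 1.
#' @param cycles taper length in cycles per window, default 4.
#' @return A `tfr` object: list with `times` (s), `freqs` (Hz), and a
#'   `power` matrix (time x frequency). Use [tidy.tfr()] for a long tibble.
#' @export
tf_power <- function(signal, fs = NULL, freqs = 25:95, step_ms = 1,
                     cycles = 4) {
  xs <- extract_signal(signal, fs)
  x <- xs$x; fs <- xs$fs; t0 <- xs$t0
  n <- length(x)
  wins <- round(cycles * fs / freqs)
  ok <- wins <= n & wins >= 4
  if (!all(ok)) {
    warn(sprintf("%d frequencies dropped: 4-cycle window exceeds the signal",
                 sum(!ok)))
    freqs <- freqs[ok]; wins <- wins[ok]
  }
  if (!length(freqs)) abort("no frequency has a window that fits the signal")
  step <- max(1L, round(step_ms / 1000 * fs))
  # common interior grid: centers valid for the longest window
  wmax <- max(wins)
  c_lo <- ceiling((wmax + 1) / 2)
  c_hi <- n - floor(wmax / 2)
  centers <- seq.int(c_lo, c_hi, by = step)
  if (!length(centers)) abort("signal too short for the requested frequencies")
  P <- matrix(NA_real_, length(centers), length(freqs))
  for (j in seq_along(freqs)) {
    w <- wins[j]
    taper <- hann_window(w)
    carr <- exp(-2i * pi * freqs[j] * (0:(w - 1)) / fs)
    kern <- taper * carr
    starts <- centers - ceiling((w + 1) / 2) + 1L
    # sliding inner products via FFT convolution
    conv <- fft_filter(x, kern)
    P[, j] <- Mod(conv[starts])^2 / w
  }
  structure(list(times = t0 + (centers - 1) / fs, freqs = freqs, power = P,
                 window_spec = list(cycles = cycles, taper = "hann",
                                    step_ms = step_ms, fs = fs)),
            class = "tfr")
}

# valid ("filter") complex convolution of x with kernel k; element i is
# sum(x[i..i+len(k)-1] * k)
fft_filter <- function(x, k) {
  n <- length(x); m <- length(k)
  N <- stats::nextn(n + m, 2)
  full <- fft(fft(c(x, rep(0, N - n))) * fft(c(rev(k), rep(0, N - m))),
              inverse = TRUE) / N
  full[m:n]
}

hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))

extract_signal <- function(signal, fs) {
  if (is.data.frame(signal)) {
    col <- intersect(c("value", "density", "field", "intensity", "rate"),
                     names(signal))[1]
    if (is.na(col)) abort("no signal column found")
    x <- signal[[col]]
    if ("time_s" %in% names(signal)) {
      fs <- 1 / median(diff(signal$time_s))
      t0 <- signal$time_s[1]
    } else t0 <- 0
  } else {
    x <- as.numeric(signal); t0 <- 0
  }
  if (is.null(fs)) abort("fs must be given for bare numeric signals")
  list(x = x, fs = fs, t0 = t0)
}

#' @export
print.tfr <- function(x, ...) {
  cat(sprintf("<tfr> %d times x %d freqs (%.1f-%.1f Hz), 4-cycle Hann\n",
              length(x$times), length(x$freqs), min(x$freqs), max(x$freqs)))
  invisible(x)
}

#' Tidy a time-frequency object into a long tibble
#' @param x a `tfr`.
#' @param ... unused.
#' @return Tibble `time_s`, `freq`, `power`.
#' @export
tidy.tfr <- function(x, ...) {
  tibble(time_s = rep(x$times, times = length(x$freqs)),
         freq = rep(x$freqs, each = length(x$times)),
         power = as.numeric(x$power))
}

#' Stimulation/baseline power ratio spectrum
#'
#' Mean power during the stimulation period divided by mean power in a
#' pre-onset baseline window, per frequency. The conventional baseline is
#' -0.5 s to -0.2 s relative to stimulation onset.
#'
#' @param tfr a [tf_power()] result whose time axis includes the baseline.
#' @param baseline_window `c(t0, t1)` (s) relative to the same clock as
#'   `tfr$times`.
#' @param stim_window `c(t0, t1)` of the stimulation period; default: all
#'   times after 0.
#' @return Tibble `freq`, `ratio`, `flagged` (TRUE where baseline power was
#'   zero and the ratio is undefined).
#' @export
power_ratio <- function(tfr, baseline_window = c(-0.5, -0.2),
                        stim_window = NULL) {
  bl <- tfr$times >= baseline_window[1] & tfr$times <= baseline_window[2]
  if (!any(bl)) abort("baseline window not inside the recording")
  if (is.null(stim_window)) st <- tfr$times > 0
  else st <- tfr$times >= stim_window[1] & tfr$times <= stim_window[2]
  if (!any(st)) abort("stimulation window not inside the recording")
  base <- colMeans(tfr$power[bl, , drop = FALSE])
  stim <- colMeans(tfr$power[st, , drop = FALSE])
  bad <- base <= 0
  tibble(freq = tfr$freqs, ratio = ifelse(bad, NA_real_, stim / base),
         flagged = bad)
}

#' Track the within-band spectral peak over time
#'
#' Per time step, the frequency of maximal power inside `band` and that
#' power. Times whose band power stays below a floor are marked absent
#' (`NA`): the floor is 5x the median band power inside `baseline_window`
#' when one is given, otherwise 5x the median band power of the whole
#' recording (for protocols, like the slow unimodal sweeps, that contain
#' extended sub-resonance periods and no designated baseline).
#'
#' @param tfr a [tf_power()] result.
#' @param band `c(lo, hi)` Hz, default the 25-95 Hz gamma band.
#' @param baseline_window optional `c(t0, t1)` (s) defining pre-onset noise.
#' @return Tibble `time_s`, `peak_freq`, `peak_power` (`NA` when absent).
#' @export
track_peak <- function(tfr, band = c(25, 95), baseline_window = NULL) {
  sel <- tfr$freqs >= band[1] & tfr$freqs <= band[2]
  if (!any(sel)) abort("band contains no frequencies of the tfr")
  P <- tfr$power[, sel, drop = FALSE]
  fr <- tfr$freqs[sel]
  pk_i <- max.col(P, ties.method = "first")
  pk_p <- P[cbind(seq_len(nrow(P)), pk_i)]
  if (!is.null(baseline_window)) {
    bl <- tfr$times >= baseline_window[1] & tfr$times <= baseline_window[2]
    floor_p <- 5 * median(P[bl, , drop = FALSE])
  } else {
    floor_p <- 5 * median(P)
  }
  absent <- pk_p < floor_p
  tibble(time_s = tfr$times,
         peak_freq = ifelse(absent, NA_real_, fr[pk_i]),
         peak_power = ifelse(absent, NA_real_, pk_p))
}

#' Rising- versus falling-phase response curves under a slow unimodal drive
#'
#' Splits the recording into the rising and the falling phase of a slow
#' unimodal stimulus (by the sign of the stimulus derivative; the single
#' extremal sample belongs to neither phase), then bins tracked gamma power
#' and peak frequency against instantaneous stimulus intensity separately per
#' phase. A memoryless circuit yields coincident curves; slow adaptive state
#' variables open a loop between them (hysteresis). `onset_threshold` is the
#' lowest rising-phase intensity whose band power clears the tracking floor.
#'
#' @param tfr a [tf_power()] result for the response signal.
#' @param stimulus the slow `stim_trace` that drove it (must rise then fall).
#' @param band gamma band for peak tracking.
#' @param n_bins number of equal-width intensity bins over the visited range.
#' @param baseline_window optional pre-onset window for the power floor.
#' @return A `hysteresis_curve`: tibble `phase` ("rising"/"falling"),
#'   `intensity` (bin center), `power`, `freq`, with attribute
#'   `onset_threshold`.
#' @export
hysteresis_curves <- function(tfr, stimulus, band = c(25, 95), n_bins = 20,
                              baseline_window = NULL) {
  inten <- stim_at(stimulus, tfr$times)
  ipk <- which.max(stimulus$intensity)
  if (ipk <= 2 || ipk >= nrow(stimulus) - 1)
    abort("stimulus must rise and then fall (unimodal)")
  d <- diff(stimulus$intensity)
  if (any(d[seq_len(ipk - 1L)] < -1e-9 * max(stimulus$intensity)) ||
      any(d[ipk:length(d)] > 1e-9 * max(stimulus$intensity)))
    abort("stimulus must be monotone on each half (non-unimodal input)")
  t_peak <- stimulus$time_s[ipk]
  trk <- track_peak(tfr, band, baseline_window)
  phase <- ifelse(tfr$times < t_peak, "rising",
                  ifelse(tfr$times > t_peak, "falling", NA_character_))
  rng <- range(inten)
  brk <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin <- pmin(n_bins, pmax(1L, findInterval(inten, brk)))
  centers <- (brk[-1] + brk[-length(brk)]) / 2
  df <- tibble(phase = phase, bin = bin,
               power = trk$peak_power, freq = trk$peak_freq) |>
    filter(!is.na(.data$phase)) |>
    group_by(.data$phase, .data$bin) |>
    summarise(power = mean(.data$power, na.rm = TRUE),
              freq = mean(.data$freq, na.rm = TRUE), .groups = "drop") |>
    mutate(intensity = centers[.data$bin]) |>
    select("phase", "intensity", "power", "freq") |>
    arrange(.data$phase, .data$intensity)
  rising_ok <- !is.na(trk$peak_power) & phase %in% "rising"
  onset <- if (any(rising_ok)) min(inten[rising_ok]) else NA_real_
  structure(df, class = c("hysteresis_curve", class(df)),
            onset_threshold = onset)
}

#' Area of the frequency (or power) hysteresis loop
#'
#' Mean rising-minus-falling gap of the chosen quantity at matched
#' intensity, over the mid-range bins where the resonance is established in
#' both phases (binned power at least `power_frac` of the maximum binned
#' power); near onset the tracked peak is noise-dominated and a gap there is
#' not evidence of memory. Positive when the rising branch runs higher, the
#' signature of slow adaptation; zero in expectation for a memoryless
#' system.
#'
#' @param hc a [hysteresis_curves()] result.
#' @param what `"freq"` or `"power"`.
#' @param signed if `FALSE`, return the mean absolute gap instead.
#' @param power_frac resonance-established threshold as a fraction of the
#'   maximum binned power (default 0.1).
#' @return Single number (Hz or power units).
#' @export
hysteresis_area <- function(hc, what = c("freq", "power"), signed = TRUE,
                            power_frac = 0.1) {
  what <- match.arg(what)
  d <- as_tibble(hc)[, c("phase", "intensity", "power", "freq")]
  w <- tidyr::pivot_wider(d, names_from = "phase",
                          values_from = c("power", "freq"))
  need <- c("power_rising", "power_falling", "freq_rising", "freq_falling")
  if (!all(need %in% names(w))) return(NA_real_)
  pmax_bin <- max(c(w$power_rising, w$power_falling), na.rm = TRUE)
  ok <- is.finite(w$power_rising) & is.finite(w$power_falling) &
    w$power_rising >= power_frac * pmax_bin &
    w$power_falling >= power_frac * pmax_bin
  gap <- if (what == "freq") w$freq_rising - w$freq_falling
         else w$power_rising - w$power_falling
  gap <- gap[ok & is.finite(gap)]
  if (!length(gap)) return(NA_real_)
  if (signed) mean(gap) else mean(abs(gap))
}
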