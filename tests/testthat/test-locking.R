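test_that("spike-triggered averaging recovers constructed structure", {
  fs <- 1000
  tt <- seq(0, 20, by = 1 / fs)
  x <- sin(2 * pi * 25 * tt)
  # spikes at the peaks of the sinusoid (index i corresponds to time (i-1)/fs)
  spk <- which(diff(sign(diff(x))) == -2) / fs
  sta <- spike_triggered_average(x, spk, window_halfwidth = 0.08, fs = fs)
  expect_equal(sta$mean_signal[sta$lag_s == 0], 1, tolerance = 1e-3)
  # the STA is the sinusoid itself
  expect_equal(sta$mean_signal,
               cos(2 * pi * 25 * sta$lag_s), tolerance = 1e-2)
  # linearity in the signal
  sta2 <- spike_triggered_average(2 * x, spk, 0.08, fs = fs)
  expect_equal(sta2$mean_signal, 2 * sta$mean_signal, tolerance = 1e-12)
})

test_that("independent spikes give an STA inside the null band", {
  set.seed(42)
  fs <- 1000
  x <- rnorm(120000)
  spk <- sort(runif(250, 0.2, 119.8))   # sparse: windows barely overlap
  sta <- spike_triggered_average(x, spk, 0.1, fs = fs)
  dev <- abs(sta$mean_signal - mean(x))
  expect_gt(mean(dev < attr(sta, "null_band")), 0.95)
  expect_lte(gammaflow::sta_side_lobes(sta), 1L)
  expect_error(spike_triggered_average(x, 1e5, 0.1, fs = fs), "trigger")
})

test_that("PPC hits its closed forms and epoch-width rules", {
  # all phases identical -> PPC exactly 1: spikes at oscillation peaks
  fs <- 1017.1
  dur <- 30
  tt <- (seq_len(round(dur * fs)) - 1) / fs
  lfp <- tibble::tibble(time_s = tt, value = cos(2 * pi * 10 * tt))
  spk <- seq(1, dur - 1, by = 0.1)           # every peak of the 10 Hz cycle
  p1 <- ppc(spk, lfp, freqs = 10)
  expect_equal(p1$ppc, 1, tolerance = 1e-3)  # grid rounding jitters phases
  expect_identical(p1$epoch_halfwidth, 0.5)  # low-frequency rule

  p40 <- ppc(spk, lfp, freqs = 40)
  expect_identical(p40$epoch_halfwidth, 0.25)

  # uniform phases: PPC near zero
  set.seed(11)
  spk_u <- sort(runif(10000, 1, dur - 1))
  pu <- ppc(spk_u, lfp, freqs = 10)
  expect_lt(abs(pu$ppc), 3 / sqrt(pu$n_spikes))

  expect_error(ppc(0.5, lfp, freqs = 10), "2 spikes")
})

test_that("PPC is unbiased by spike count", {
  # mean PPC at n = 50 vs n = 500 spikes agrees closely (the design
  # property of the pairwise estimator); moderate replicate count here,
  # the full calibration runs in the acceptance suite
  fs <- 1017.1
  reps <- 60
  est <- vapply(seq_len(reps), function(r) {
    g_small <- gen_locked_spikes(40, 1, rate = 50, duration = 1.2,
                                 seed = 1000 + r, fs = fs)
    g_big <- gen_locked_spikes(40, 1, rate = 500, duration = 1.2,
                               seed = 3000 + r, fs = fs)
    c(ppc(g_small$spike_times, g_small$signal, 40)$ppc,
      ppc(g_big$spike_times, g_big$signal, 40)$ppc)
  }, numeric(2))
  expect_lt(abs(mean(est[1, ]) - mean(est[2, ])), 0.03)
})

test_that("cross-correlation modulation matches shifted-sinusoid expectations", {
  st <- generate_stimulus("sinusoid", duration = 4, freq = 10, max = 1)
  resp <- gen_lagged_response(st, latency_ms = 5)
  xc <- xcorr_modulation(resp, st, max_lag = 0.06)
  expect_lt(abs(xc$peak_lag - 0.005), 1.5 / stim_fs(st))
  expect_equal(xc$modulation_depth, 2, tolerance = 1e-3)

  same <- xcorr_modulation(st, st, max_lag = 0.02)
  expect_equal(same$correlation$r[same$correlation$lag_s == 0], 1,
               tolerance = 1e-12)

  set.seed(3)
  a <- rnorm(20000); b <- rnorm(20000)
  ind <- xcorr_modulation(a, b, max_lag = 0.02, fs = 1000)
  expect_lt(ind$modulation_depth, 6 / sqrt(20000))
})

test_that("phase-slope latency recovers imposed delays including wrapped ones", {
  freqs <- c(5, 10, 20, 40, 80)
  run <- function(lat) {
    stim <- lapply(freqs, function(f)
      generate_stimulus("sinusoid", duration = 2, freq = f, max = 1))
    resp <- lapply(stim, function(s)
      gen_lagged_response(s, lat, gain = 1.5, noise_sd = 0.05, seed = 21))
    phase_slope_latency(stim, resp, freqs)
  }
  e0 <- run(0)
  expect_lt(abs(e0$latency_ms), 0.05)
  expect_lt(e0$fit_residual, 0.05)

  e5 <- run(5.5)
  expect_lt(abs(e5$latency_ms - 5.5), 0.05)

  e20 <- run(20)                    # wraps between 40 and 80 Hz
  expect_lt(abs(e20$latency_ms - 20), 0.05)
  expect_true(e20$wrap_flag)
  # oracle: time-domain cross-correlation peak agrees
  st40 <- generate_stimulus("sinusoid", duration = 2, freq = 10, max = 1)
  r40 <- gen_lagged_response(st40, 20)
  expect_equal(xcorr_modulation(r40, st40, 0.04)$peak_lag * 1000, 20,
               tolerance = 1)

  expect_error(phase_slope_latency(list(), list(), freqs = 5), "2 stim")
  # a zero response leaves the fit undefined
  stim1 <- lapply(c(5, 10), function(f)
    generate_stimulus("sinusoid", duration = 1, freq = f, max = 1))
  resp1 <- list(gen_lagged_response(stim1[[1]], 1),
                tibble::tibble(time_s = stim1[[2]]$time_s,
                               value = rep(0, nrow(stim1[[2]]))))
  expect_error(phase_slope_latency(stim1, resp1, c(5, 10)), "undefined")
})
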