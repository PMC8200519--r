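test_that("spike density conserves mass, support and linearity", {
  spk <- c(0.2, 0.45, 0.71)
  d <- spike_density(spk, sigma_ms = 12.5, fs_out = 2000, t_range = c(0, 1))
  dt <- 1 / 2000
  expect_equal(sum(d$density) * dt, 3, tolerance = 1e-9)

  one <- spike_density(0.5, sigma_ms = 12.5, fs_out = 2000,
                       t_range = c(0, 1))
  expect_equal(one$time_s[which.max(one$density)], 0.5, tolerance = dt)
  # truncated at +/- 2 sd = 25 ms
  expect_true(all(abs(one$density[one$time_s < 0.5 - 0.0255]) < 1e-8))
  expect_true(all(abs(one$density[one$time_s > 0.5 + 0.0255]) < 1e-8))
  expect_gt(one$density[which.min(abs(one$time_s - (0.5 - 0.024)))], 0)

  a <- spike_density(c(0.2, 0.45), 12.5, 2000, c(0, 1))
  b <- spike_density(0.71, 12.5, 2000, c(0, 1))
  expect_equal(a$density + b$density, d$density, tolerance = 1e-9)

  empty <- spike_density(numeric(0), 12.5, 1000, c(0, 1))
  expect_true(all(empty$density == 0))
})

test_that("tf_power follows the 4-cycle Hann window rule", {
  fs <- 1000
  x <- sin(2 * pi * 40 * seq(0, 2, by = 1 / fs))
  tfr <- tf_power(x, fs, freqs = c(20, 40, 50, 80))
  # 4-cycle windows: 50 Hz -> 80 ms -> 80 samples at 1 kHz
  expect_equal(round(4 * fs / 50), 80)
  # pure 40 Hz tone: argmax at 40 everywhere
  peaks <- tfr$freqs[max.col(tfr$power)]
  expect_true(all(peaks == 40))
  # quadratic amplitude scaling
  tfr2 <- tf_power(2 * x, fs, freqs = c(20, 40, 50, 80))
  i40 <- which(tfr$freqs == 40)
  expect_equal(tfr2$power[, i40] / tfr$power[, i40],
               rep(4, nrow(tfr$power)), tolerance = 1e-9)
  # over-long windows are dropped with a warning
  expect_warning(tf_power(x[1:300], fs, freqs = c(2, 40)), "dropped")
  expect_error(suppressWarnings(tf_power(x[1:10], fs, freqs = 2)), "fits|fit")
})

test_that("power ratio is 1 for identical periods and scales quadratically", {
  fs <- 1000
  tt <- seq(-1, 2, by = 1 / fs)
  amp <- ifelse(tt > 0, 3, 1)
  x <- amp * sin(2 * pi * 50 * tt)
  tfr <- tf_power(tibble::tibble(time_s = tt, value = x),
                  freqs = seq(30, 70, 5))
  pr <- power_ratio(tfr, baseline_window = c(-0.5, -0.2),
                    stim_window = c(0.2, 1.8))
  expect_equal(pr$ratio[pr$freq == 50], 9, tolerance = 0.05)

  same <- power_ratio(tfr, baseline_window = c(-0.9, -0.4),
                      stim_window = c(-0.9, -0.4))
  expect_true(all(abs(same$ratio[!same$flagged] - 1) < 1e-9))
})

test_that("peak tracking follows a chirp and stays silent in silence", {
  fs <- 1000
  tt <- seq(0, 4, by = 1 / fs)
  finst <- 30 + 10 * tt                      # 30 -> 70 Hz chirp
  x <- sin(2 * pi * cumsum(finst) / fs)
  x[tt < 0.5] <- 0                           # silent head
  tfr <- tf_power(x, fs, freqs = seq(20, 90, 1))
  trk <- track_peak(tfr, band = c(25, 95))
  mid <- !is.na(trk$peak_freq) & trk$time_s > 1 & trk$time_s < 3.5
  # tracked frequency increases along the chirp
  expect_gt(cor(trk$time_s[mid], trk$peak_freq[mid]), 0.98)
  # silent head marked absent, not spurious peaks
  expect_true(all(is.na(trk$peak_freq[trk$time_s < 0.4])))
})

test_that("hysteresis area separates memoryless from adapting responses", {
  fs <- 1000
  st <- generate_stimulus("slow_sine", duration = 10, peak = 1, fs = fs)
  inten <- st$intensity
  # memoryless: instantaneous frequency is a pure function of intensity
  f_mless <- 40 + 30 * inten
  x1 <- sin(2 * pi * cumsum(f_mless) / fs) * (inten > 0.1)
  tfr1 <- tf_power(x1, fs, freqs = seq(30, 80, 1))
  hc1 <- hysteresis_curves(tfr1, st, band = c(30, 80))
  a1 <- hysteresis_area(hc1, "freq")

  # adapting: a slow first-order state subtracts from the drive, so the
  # falling branch runs at lower frequency at matched intensity
  adapt <- stats::filter(inten, 1 - 1 / (fs * 0.5), "recursive") / (fs * 0.5)
  f_ad <- 40 + 30 * pmax(0, inten - 0.8 * as.numeric(adapt))
  x2 <- sin(2 * pi * cumsum(f_ad) / fs) * (inten > 0.1)
  tfr2 <- tf_power(x2, fs, freqs = seq(30, 80, 1))
  hc2 <- hysteresis_curves(tfr2, st, band = c(30, 80))
  a2 <- hysteresis_area(hc2, "freq")

  expect_lt(abs(a1), 1)          # no memory, no loop (within bin noise)
  expect_gt(a2, 2)               # adaptation opens a positive loop
  expect_gt(a2, 5 * abs(a1))

  # onset threshold: resonance starts where the gate opens
  expect_gt(attr(hc1, "onset_threshold"), 0.05)
  # non-unimodal stimulus is rejected
  ramp <- generate_stimulus("ramp", duration = 2, fs = fs)
  expect_error(hysteresis_curves(tfr1, ramp), "unimodal|rise")
})
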