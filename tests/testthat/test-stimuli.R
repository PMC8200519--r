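test_that("deterministic protocols have their defining shapes", {
  ramp <- generate_stimulus("ramp", duration = 3, from = 0, to = 1)
  expect_equal(stim_at(ramp, 1.5), 0.5, tolerance = 1e-3)
  expect_true(all(diff(ramp$intensity) >= 0))

  ss <- generate_stimulus("slow_sine", duration = 10, peak = 2)
  x <- ss$intensity
  # symmetric about the midpoint, zero ends, peak at duration/2
  expect_lt(max(abs(x - rev(x))) / max(x), 0.01)
  expect_equal(ss$time_s[which.max(x)], 5, tolerance = 0.01)
  expect_lt(x[1] / max(x), 1e-5)

  sin40 <- generate_stimulus("sinusoid", duration = 2, freq = 40, max = 1)
  expect_equal(mean(sin40$intensity), 0.5, tolerance = 1e-3)
  expect_lt(min(sin40$intensity), 1e-4)
  expect_equal(max(sin40$intensity), 1, tolerance = 1e-4)

  gp <- generate_stimulus("gauss_profile", duration = 6, peak = 1)
  expect_equal(gp$time_s[which.max(gp$intensity)], 3, tolerance = 0.01)

  # seed invariance of deterministic kinds
  expect_identical(generate_stimulus("ramp", 3, seed = 1)$intensity,
                   generate_stimulus("ramp", 3, seed = 99)$intensity)
})

test_that("trace length and errors follow the contract", {
  tr <- generate_stimulus("constant", duration = 2, fs = 1017.1)
  expect_equal(nrow(tr), round(2 * 1017.1))
  expect_error(generate_stimulus("laser_pulse", 1), "unknown")
  expect_error(generate_stimulus("ramp", -1), "duration")
  expect_error(generate_stimulus("ramp", 1, from = -2), "negative")
  expect_error(generate_stimulus("sinusoid", 1, fs = 100, freq = 60),
               "Nyquist")
  expect_error(generate_white_noise(mean = 0), "mean")
})

test_that("white noise follows the mean/2 sd, truncation and positivity rules", {
  wn <- generate_white_noise(mean = 8, duration = 100, seed = 3)
  x <- wn$intensity
  n <- length(x)
  expect_gt(n, 1e5 - 1)
  # the generating sd is mean/2; the delivered samples are doubly truncated
  # (positivity cuts at 2 sd below the mean), whose sd has a closed form
  a <- (0 - 8) / 4; b <- (8 + 3.5 * 4 - 8) / 4
  Z <- pnorm(b) - pnorm(a)
  mu_t <- (dnorm(a) - dnorm(b)) / Z
  sd_t <- 4 * sqrt(1 + (a * dnorm(a) - b * dnorm(b)) / Z - mu_t^2)
  expect_lt(abs(sd(x) - sd_t) / (sd_t / sqrt(2 * (n - 1))), 4)
  expect_lt(abs(sd(x) - 4) / 4, 0.15)   # still close to the nominal mean/2
  expect_gt(min(x), 0)                      # strictly positive
  expect_lt(max(x), 8 + 3.5 * 4)            # truncated, never at the bound
  expect_gt(min(x), 8 - 3.5 * 4)
  # rejection-resampling, not clipping: no mass at the bounds
  expect_equal(sum(abs(x - (8 + 3.5 * 4)) < 1e-6), 0)
  # whiteness: lag-k autocorrelation small
  r <- acf(x, lag.max = 5, plot = FALSE)$acf[-1]
  expect_lt(max(abs(r)), 3 / sqrt(n))
  # reproducibility
  expect_identical(x, generate_white_noise(mean = 8, duration = 100,
                                           seed = 3)$intensity)
})

test_that("white-noise periodogram is flat across bands", {
  wn <- generate_white_noise(mean = 2, fs = 1000, duration = 1000, seed = 9)
  p <- welch_psd(wn$intensity, 1000, seg_s = 0.5)
  b1 <- mean(p$power[p$freq > 50 & p$freq <= 200])
  b2 <- mean(p$power[p$freq > 300 & p$freq <= 450])
  expect_lt(abs(b1 - b2) / b1, 0.1)
})

test_that("zero-order-hold resampling preserves per-tick values", {
  wn <- generate_white_noise(mean = 2, fs = 1017.1, duration = 0.5, seed = 4)
  fine <- stim_resample(wn, 50000)
  # first fine sample at or after each tick start carries that tick's value
  idx <- ceiling(wn$time_s * 50000 - 1e-6) + 1L
  expect_identical(fine$intensity[idx], wn$intensity)
})

test_that("traces round-trip through the CSV writer", {
  wn <- generate_white_noise(mean = 2, duration = 0.2, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_stim_csv(wn, path)
  back <- read_stim_csv(path)
  expect_equal(back$intensity, wn$intensity, tolerance = 1e-12)
  expect_equal(stim_fs(back), stim_fs(wn))
  expect_identical(attr(back, "kind"), "white_noise")
})
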