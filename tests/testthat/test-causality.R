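test_that("CSD estimation follows the epoch/padding contract", {
  fs <- 200
  x <- rnorm(10 * fs)
  csd <- estimate_csd(x, x, fs = fs)
  expect_equal(diff(csd$freqs)[1], 1)        # 1-Hz grid from 1-s padding
  expect_identical(csd$n_epochs, 20L)
  # x = y: coherence identically 1
  coh <- Mod(csd$S[1, 2, ])^2 / (Re(csd$S[1, 1, ]) * Re(csd$S[2, 2, ]))
  expect_true(all(abs(coh[-1] - 1) < 1e-10))
  expect_error(estimate_csd(x[1:50], x[1:50], fs = fs), "shorter")
})

test_that("independent channels show null coherence at 500 epochs", {
  set.seed(5)
  fs <- 200
  xs <- lapply(1:50, function(i) rnorm(10 * fs))
  ys <- lapply(1:50, function(i) rnorm(10 * fs))
  csd <- estimate_csd(xs, ys, fs = fs)
  expect_identical(csd$n_epochs, 1000L)
  coh <- Mod(csd$S[1, 2, ])^2 / (Re(csd$S[1, 1, ]) * Re(csd$S[2, 2, ]))
  expect_gt(mean(coh < 0.05), 0.95)
})

test_that("white spectra factorize into themselves", {
  S <- array(0i, c(2, 2, 65))
  for (k in 1:65) S[, , k] <- diag(2) * 2.5
  f <- factorize_spectral_matrix(S)
  expect_true(f$converged)
  expect_equal(f$Sigma, diag(2) * 2.5, tolerance = 1e-10)
  expect_lt(max(Mod(f$H[, , 10] - diag(2))), 1e-10)
  # converged runs reconstruct to well below 1e-6
  expect_lt(f$rel_err, 1e-6)
})

test_that("factorizing the analytic VAR spectrum recovers the transfer function", {
  spec <- gc_fixture_spec()
  freqs <- 0:100
  S <- var_spectral_matrix(spec, freqs)
  fac <- factorize_spectral_matrix(S)
  H_true <- gammaflow:::var_transfer(spec, freqs)
  # H is identified up to the innovation normalization; compare the
  # rotation-invariant quantity H Sigma H* against S (reconstruction) and
  # the Geweke influence against the closed form
  truth <- var_granger(spec, freqs)
  gc <- vapply(seq_along(freqs), function(k)
    gammaflow:::geweke_pair(Re(diag(S[, , k])), fac$H[, , k], fac$Sigma),
    numeric(2))
  expect_lt(max(abs(gc[1, ] - truth$gc_xy)), 1e-4)
  expect_lt(max(abs(gc[2, ] - truth$gc_yx)), 1e-4)
  # minimum-phase normalization: |H| relative error against the truth
  relerr <- max(vapply(seq_along(freqs), function(k)
    max(Mod(Mod(fac$H[, , k]) - Mod(H_true[[k]]))) /
      max(Mod(H_true[[k]])), numeric(1)))
  expect_lt(relerr, 1e-3)
})

test_that("nonparametric GC matches the parametric oracle and is nonnegative", {
  spec <- gc_fixture_spec()
  truth <- var_granger(spec, 1:100)
  d <- gen_var_process(spec, n = 300 * 100, seed = 8)
  csd <- estimate_csd(d$x, d$y, fs = 200)
  gc <- suppressWarnings(granger_from_csd(csd, fmin = 1, fmax = 100))
  expect_true(all(gc$gc_xy >= 0) && all(gc$gc_yx >= 0))
  cmp <- merge(as.data.frame(gc), as.data.frame(truth), by = "freq")
  expect_lt(max(abs(cmp$gc_xy.x - cmp$gc_xy.y)), 0.03)   # 300 epochs here
  expect_lt(max(cmp$gc_yx.x), 0.02)
  # the influence peaks at the coupling resonance
  expect_lt(abs(cmp$freq[which.max(cmp$gc_xy.x)] -
                truth$freq[which.max(truth$gc_xy)]), 10)
})

test_that("time reversal swaps the directions of influence", {
  spec <- gc_fixture_spec()
  d <- gen_var_process(spec, n = 200 * 100, seed = 13)
  fwd <- suppressWarnings(granger_from_csd(
    estimate_csd(d$x, d$y, fs = 200), fmin = 1, fmax = 100))
  rev_ <- suppressWarnings(granger_from_csd(
    estimate_csd(rev(d$x), rev(d$y), fs = 200), fmin = 1, fmax = 100))
  # forward: x drives y; reversed: y "drives" x (integrated over frequency,
  # which averages out single-bin noise spikes of the null direction)
  expect_gt(sum(fwd$gc_xy), 2 * sum(fwd$gc_yx))
  expect_gt(sum(rev_$gc_yx), 2 * sum(rev_$gc_xy))
  expect_equal(sum(rev_$gc_yx), sum(fwd$gc_xy), tolerance = 0.05)
})

test_that("the trial bootstrap is reproducible and degenerate for identical trials", {
  spec <- gc_fixture_spec()
  d <- gen_var_process(spec, n = 40 * 100, seed = 3)
  one <- d$x[1:2000]; two <- d$y[1:2000]
  same_x <- replicate(12, one, simplify = FALSE)
  same_y <- replicate(12, two, simplify = FALSE)
  br <- bootstrap_gc(same_x, same_y, fs = 200, n_iter = 10, seed = 4,
                     fmax = 100)
  expect_lt(max(br$hi_xy - br$lo_xy), 1e-12)   # no resampling variance

  xs <- lapply(0:11, function(i) d$x[i * 300 + 1:300])
  ys <- lapply(0:11, function(i) d$y[i * 300 + 1:300])
  b1 <- bootstrap_gc(xs, ys, fs = 200, n_iter = 15, seed = 9, fmax = 100)
  b2 <- bootstrap_gc(xs, ys, fs = 200, n_iter = 15, seed = 9, fmax = 100)
  expect_identical(b1, b2)
  expect_error(bootstrap_gc(xs[1:3], ys[1:3], fs = 200, frac = 0.3),
               "at least 2")
})

test_that("bootstrap regions cover the parametric oracle spectrum", {
  spec <- gc_fixture_spec()
  truth <- var_granger(spec, 1:100)
  d <- gen_var_process(spec, n = 100 * 200, seed = 17)
  len <- 2 * 200                                  # 2-s trials
  xs <- lapply(0:49, function(i) d$x[i * len + seq_len(len)])
  ys <- lapply(0:49, function(i) d$y[i * len + seq_len(len)])
  br <- bootstrap_gc(xs, ys, fs = 200, n_iter = 60, frac = 0.3, seed = 2,
                     fmax = 100)
  m <- merge(as.data.frame(br), as.data.frame(truth), by = "freq")
  cover <- mean(m$gc_xy >= m$lo_xy - 1e-12 & m$gc_xy <= m$hi_xy + 1e-12)
  expect_gte(cover, 0.90)
})
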