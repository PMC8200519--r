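make_paired <- function(seed, n_site = 20, n_freq = 60, effect = 0,
                        band = 30:50) {
  set.seed(seed)
  A <- matrix(rnorm(n_site * n_freq), n_site, n_freq)
  B <- matrix(rnorm(n_site * n_freq), n_site, n_freq)
  A[, band] <- A[, band] + effect
  list(A = A, B = B)
}

test_that("an overwhelming localized effect yields exactly one covering cluster", {
  d <- make_paired(1, effect = 10)
  r <- cluster_permutation_test(d$A, d$B, n_perm = 1000, seed = 2,
                                freqs = 1:60)
  sig <- r[r$significant, ]
  expect_identical(nrow(sig), 1L)
  expect_identical(sig$sign, 1L)
  expect_lte(abs(sig$freq_lo - 30), 1)
  expect_lte(abs(sig$freq_hi - 50), 1)
  expect_lte(sig$p_value, 0.05)
})

test_that("fixed seeds reproduce cluster p-values exactly", {
  d <- make_paired(3, effect = 1.2)
  r1 <- cluster_permutation_test(d$A, d$B, n_perm = 400, seed = 7,
                                 freqs = 1:60)
  r2 <- cluster_permutation_test(d$A, d$B, n_perm = 400, seed = 7,
                                 freqs = 1:60)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
})

test_that("negating all differences mirrors signs and keeps p-values", {
  d <- make_paired(5, effect = 3, band = 20:28)
  r_ab <- cluster_permutation_test(d$A, d$B, n_perm = 600, seed = 11,
                                   freqs = 1:60)
  r_ba <- cluster_permutation_test(d$B, d$A, n_perm = 600, seed = 11,
                                   freqs = 1:60)
  expect_identical(r_ab$freq_lo, r_ba$freq_lo)
  expect_identical(r_ab$sign, -r_ba$sign)
  expect_equal(r_ab$summed_t, -r_ba$summed_t, tolerance = 1e-12)
  expect_equal(r_ab$p_value, r_ba$p_value, tolerance = 1e-12)
})

test_that("scaling a localized effect up cannot weaken its cluster", {
  ps <- vapply(c(1, 2.5, 6), function(eff) {
    d <- make_paired(9, effect = eff, band = 35:45)
    r <- cluster_permutation_test(d$A, d$B, n_perm = 500, seed = 13,
                                  freqs = 1:60)
    in_band <- r$freq_lo <= 45 & r$freq_hi >= 35
    if (any(in_band)) min(r$p_value[in_band]) else 1
  }, numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("null data keep the family-wise error near its nominal level", {
  # reduced-size calibration (the full 500 x 500 run is in the acceptance
  # suite): any significant cluster on exchangeable data is a family error
  hits <- vapply(1:120, function(i) {
    d <- make_paired(1000 + i, effect = 0)
    r <- cluster_permutation_test(d$A, d$B, n_perm = 250, seed = i,
                                  freqs = 1:60)
    any(r$significant)
  }, logical(1))
  expect_gte(mean(hits), 0.0)
  expect_lte(mean(hits), 0.13)
})

test_that("degenerate inputs are rejected", {
  d <- make_paired(2)
  expect_error(cluster_permutation_test(d$A, d$B[, 1:30]), "mismatch")
  expect_error(cluster_permutation_test(d$A[1, , drop = FALSE],
                                        d$B[1, , drop = FALSE]), "2 sites")
})
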