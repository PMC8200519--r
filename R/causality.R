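#' Cross-spectral density of an input signal and an output spike train
#'
#' Each trial is segmented into non-overlapping 500-ms epochs; per epoch both
#' channels are demeaned, multiplied with a Hann taper, zero-padded to
#' 1000 ms and Fourier transformed, and the power- and cross-spectral
#' densities are averaged over all epochs of all trials, giving a Hermitian
#' 2x2 spectral matrix on an (approximately) 1-Hz frequency grid. Spike
#' trains must be binned to the continuous channel's grid beforehand (see
#' [bin_spikes()]).
#'
#' @param x input (continuous) channel: list of per-trial numeric vectors, or
#'   a single vector treated as one trial.
#' @param y output channel on the same grid, same structure as `x`.
#' @param fs sampling rate (Hz).
#' @param epoch_ms epoch length (ms), default 500.
#' @param pad_ms length after zero-padding (ms), default 1000.
#' @param demean demean each epoch before tapering (default TRUE; avoids DC
#'   leakage through the taper).
#' @return A `csd_estimate`: list with `freqs`, `S` (2 x 2 x nfreq complex),
#'   `n_epochs`, `fs`, `epoch_spec`.
#' @export
estimate_csd <- function(x, y, fs, epoch_ms = 500, pad_ms = 1000,
                         demean = TRUE) {
  if (!is.list(x)) x <- list(x)
  if (!is.list(y)) y <- list(y)
  stopifnot(length(x) == length(y))
  n_ep <- round(epoch_ms / 1000 * fs)
  n_pad <- round(pad_ms / 1000 * fs)
  if (any(vapply(x, length, 1L) < n_ep))
    abort("a trial is shorter than one epoch")
  taper <- hann_window(n_ep)
  nf <- floor(n_pad / 2) + 1L
  Sxx <- Syy <- numeric(nf); Sxy <- complex(nf)
  m <- 0L
  for (tr in seq_along(x)) {
    xt <- x[[tr]]; yt <- y[[tr]]
    n_seg <- floor(min(length(xt), length(yt)) / n_ep)
    for (s in seq_len(n_seg)) {
      i0 <- (s - 1L) * n_ep
      xe <- xt[i0 + seq_len(n_ep)]; ye <- yt[i0 + seq_len(n_ep)]
      if (demean) { xe <- xe - mean(xe); ye <- ye - mean(ye) }
      X <- fft(c(xe * taper, rep(0, n_pad - n_ep)))[seq_len(nf)]
      Y <- fft(c(ye * taper, rep(0, n_pad - n_ep)))[seq_len(nf)]
      Sxx <- Sxx + Mod(X)^2
      Syy <- Syy + Mod(Y)^2
      Sxy <- Sxy + X * Conj(Y)
      m <- m + 1L
    }
  }
  # taper power normalization; overall scale cancels in coherence and GC
  norm <- m * sum(taper^2) * fs
  S <- array(0i, c(2, 2, nf))
  S[1, 1, ] <- Sxx / norm
  S[2, 2, ] <- Syy / norm
  S[1, 2, ] <- Sxy / norm
  S[2, 1, ] <- Conj(Sxy) / norm
  structure(list(freqs = (seq_len(nf) - 1) * fs / n_pad, S = S,
                 n_epochs = m, fs = fs,
                 epoch_spec = list(epoch_ms = epoch_ms, pad_ms = pad_ms,
                                   taper = "hann", demean = demean)),
            class = "csd_estimate")
}

#' Bin spike times onto a regular grid
#'
#' @param spike_times spike times (s).
#' @param fs grid rate (Hz).
#' @param duration grid length (s).
#' @return Integer vector of counts per bin, length `round(duration * fs)`.
#' @export
bin_spikes <- function(spike_times, fs, duration) {
  n <- round(duration * fs)
  idx <- floor(spike_times * fs) + 1L
  idx <- idx[idx >= 1L & idx <= n]
  tabulate(idx, nbins = n)
}

#' Wilson spectral matrix factorization
#'
#' Iteratively factorizes a Hermitian positive semi-definite spectral matrix
#' into `S(f) = H(f) Sigma H(f)*` with `H` minimum-phase and normalized so
#' that `H(0)` carries no instantaneous mixing (`Sigma` real positive
#' definite). This is the nonparametric route to spectral Granger causality:
#' no autoregressive model is fitted. The iteration starts from the Cholesky
#' factor of the frequency-averaged spectrum and stops when the relative
#' reconstruction error falls below `tol` or after `max_iter` iterations
#' (non-convergence is flagged but the result is still returned with the
#' achieved error).
#'
#' @param S 2 x 2 x nfreq complex array on a uniform grid from 0 to Nyquist.
#' @param tol relative reconstruction tolerance, default 1e-8.
#' @param max_iter iteration cap, default 100.
#' @return List with `H` (2 x 2 x nfreq), `Sigma` (2 x 2), `converged`,
#'   `rel_err`, `n_iter`.
#' @export
factorize_spectral_matrix <- function(S, tol = 1e-8, max_iter = 100) {
  nf <- dim(S)[3]
  m <- dim(S)[1]
  # two-sided extension: nfft = 2 (nf - 1), frequencies 0 .. fs (mod)
  nfft <- 2L * (nf - 1L)
  Sfull <- array(0i, c(m, m, nfft))
  Sfull[, , seq_len(nf)] <- S
  if (nf > 2L)
    for (k in 2:(nf - 1L)) Sfull[, , nfft - k + 2L] <- t(S[, , k])  # conj sym
  # lag-domain covariance sequence
  gam <- apply_ifft(Sfull)
  gam0 <- Re(gam[, , 1])
  h0 <- tryCatch(chol(gam0), error = function(e)
    chol(gam0 + diag(m) * max(diag(gam0)) * 1e-10))
  psi <- array(0i, c(m, m, nfft))
  for (k in seq_len(nfft)) psi[, , k] <- h0
  I2 <- diag(m)
  rel_err <- Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    g <- array(0i, c(m, m, nfft))
    for (k in seq_len(nfft)) {
      pinv <- solve(psi[, , k])
      g[, , k] <- pinv %*% Sfull[, , k] %*% Conj(t(pinv)) + I2
    }
    gp <- plus_operator(g)
    psi_old <- psi
    for (k in seq_len(nfft)) psi[, , k] <- psi[, , k] %*% gp[, , k]
    rel_err <- recon_error(psi, Sfull, nf)
    if (rel_err < tol) break
    if (max(Mod(psi - psi_old)) < 1e-14) break
  }
  A0 <- Re(apply_ifft(psi)[, , 1])
  Sigma <- A0 %*% t(A0)
  H <- array(0i, c(m, m, nf))
  A0inv <- solve(A0)
  for (k in seq_len(nf)) H[, , k] <- psi[, , k] %*% A0inv
  if (rel_err >= tol)
    warn(sprintf("spectral factorization did not converge: rel err %.3g after %d iterations",
                 rel_err, it))
  list(H = H, Sigma = Sigma, converged = rel_err < tol, rel_err = rel_err,
       n_iter = it)
}

# elementwise inverse FFT along the third dimension
apply_ifft <- function(A) {
  nfft <- dim(A)[3]
  out <- array(0i, dim(A))
  for (i in 1:dim(A)[1]) for (j in 1:dim(A)[2])
    out[i, j, ] <- fft(A[i, j, ], inverse = TRUE) / nfft
  out
}

apply_fft <- function(A) {
  out <- array(0i, dim(A))
  for (i in 1:dim(A)[1]) for (j in 1:dim(A)[2])
    out[i, j, ] <- fft(A[i, j, ])
  out
}

# causal-part projection of a two-sided spectral function: zero negative
# lags, halve lag zero keeping its upper triangle. The lag-domain
# coefficients of a Hermitian, conjugate-symmetric spectral function are
# real; enforcing that kills accumulated rounding asymmetry.
plus_operator <- function(g) {
  nfft <- dim(g)[3]
  gam <- Re(apply_ifft(g))
  dim(gam) <- dim(g)
  beta0 <- 0.5 * gam[, , 1]
  beta0[lower.tri(beta0)] <- 0
  gam[, , 1] <- beta0
  half <- floor(nfft / 2)
  if (half + 2L <= nfft) gam[, , (half + 2L):nfft] <- 0i
  apply_fft(gam)
}

recon_error <- function(psi, Sfull, nf) {
  num <- 0; den <- 0
  for (k in seq_len(nf)) {
    R <- psi[, , k] %*% Conj(t(psi[, , k]))
    num <- max(num, max(Mod(R - Sfull[, , k])))
    den <- max(den, max(Mod(Sfull[, , k])))
  }
  num / den
}

#' Spectral Granger causality from a cross-spectral density estimate
#'
#' Factorizes the spectral matrix (Wilson iteration) and evaluates the Geweke
#' frequency-resolved directed influence in both directions. Influence is
#' nonnegative at every frequency by construction.
#'
#' @param csd a [estimate_csd()] result (channel 1 = x/input, channel 2 =
#'   y/output).
#' @param fmax highest frequency reported (Hz), default 150.
#' @param fmin lowest frequency reported (Hz), default 1.
#' @return A `gc_result` tibble: `freq`, `gc_xy` (x to y), `gc_yx`, with
#'   attributes `factorization` (H, Sigma, convergence) and `n_epochs`.
#' @export
granger_from_csd <- function(csd, fmin = 1, fmax = 150) {
  fac <- factorize_spectral_matrix(csd$S)
  nf <- length(csd$freqs)
  gc <- vapply(seq_len(nf), function(k) {
    Sd <- Re(diag(csd$S[, , k]))
    if (all(Sd <= 0)) return(c(NA_real_, NA_real_))
    geweke_pair(Sd, fac$H[, , k], fac$Sigma)
  }, numeric(2))
  keep <- csd$freqs >= fmin & csd$freqs <= fmax
  out <- tibble(freq = csd$freqs[keep],
                gc_xy = pmax(0, gc[1, keep]),
                gc_yx = pmax(0, gc[2, keep]))
  structure(out, class = c("gc_result", class(out)),
            factorization = fac[c("Sigma", "converged", "rel_err", "n_iter")],
            n_epochs = csd$n_epochs)
}

#' @export
print.gc_result <- function(x, ...) {
  fac <- attr(x, "factorization")
  cat(sprintf("<gc_result> %d freqs (%.0f-%.0f Hz), %d epochs, factorization %s\n",
              nrow(x), min(x$freq), max(x$freq), attr(x, "n_epochs"),
              if (fac$converged) "converged" else
                sprintf("NOT converged (err %.2g)", fac$rel_err)))
  NextMethod()
}

#' Bootstrap uncertainty region for a Granger-causality spectrum
#'
#' Re-estimates the GC spectrum `n_iter` times, each time from a random 30%
#' of the trials (drawn without replacement within each iteration), and
#' returns, per frequency and direction, the region containing the central
#' 95% of the bootstrapped estimates.
#'
#' @param x,y per-trial channel lists as in [estimate_csd()].
#' @param fs sampling rate (Hz).
#' @param n_iter bootstrap iterations, default 100.
#' @param frac fraction of trials per iteration, default 0.30.
#' @param seed integer seed (regions are reproducible).
#' @param replace draw trials with replacement instead (default FALSE).
#' @param level central coverage, default 0.95.
#' @param ... passed to [estimate_csd()] / [granger_from_csd()].
#' @return Tibble `freq`, `lo_xy`, `hi_xy`, `lo_yx`, `hi_yx`.
#' @export
bootstrap_gc <- function(x, y, fs, n_iter = 100, frac = 0.30, seed = 1L,
                         replace = FALSE, level = 0.95, ...) {
  if (!is.list(x)) x <- list(x)
  if (!is.list(y)) y <- list(y)
  n_tr <- length(x)
  k <- max(1L, round(frac * n_tr))
  if (k < 2L) abort("frac * n_trials must be at least 2")
  dots <- list(...)
  csd_args <- dots[names(dots) %in% c("epoch_ms", "pad_ms", "demean")]
  gc_args <- dots[names(dots) %in% c("fmin", "fmax")]
  est <- withr_seed(seed, {
    lapply(seq_len(n_iter), function(i) {
      pick <- sample.int(n_tr, k, replace = replace)
      csd <- do.call(estimate_csd, c(list(x[pick], y[pick], fs), csd_args))
      suppressWarnings(do.call(granger_from_csd, c(list(csd), gc_args)))
    })
  })
  freqs <- est[[1]]$freq
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  xy <- vapply(est, function(e) e$gc_xy, numeric(length(freqs)))
  yx <- vapply(est, function(e) e$gc_yx, numeric(length(freqs)))
  tibble(freq = freqs,
         lo_xy = apply(xy, 1, stats::quantile, qs[1]),
         hi_xy = apply(xy, 1, stats::quantile, qs[2]),
         lo_yx = apply(yx, 1, stats::quantile, qs[1]),
         hi_yx = apply(yx, 1, stats::quantile, qs[2]))
}
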