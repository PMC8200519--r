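#' Specify a stationary bivariate vector-autoregressive (VAR) process
#'
#' A VAR fixture provides a stochastic process whose spectral matrix and
#' directed (Geweke) influence are known in closed form, so the nonparametric
#' Granger-causality chain can be validated against an analytic answer.
#'
#' @param A list of 2x2 lag-coefficient matrices (lag 1, 2, ...).
#' @param Sigma 2x2 innovation covariance (positive definite).
#' @param fs nominal sampling rate (Hz) used to place the spectrum on a
#'   physical frequency axis; default 1017.1 to match the stimulus grid.
#' @return A `var_spec` object.
#' @export
var_spec <- function(A, Sigma = diag(2), fs = 1017.1) {
  A <- lapply(A, function(m) matrix(as.numeric(m), 2, 2))
  Sigma <- matrix(as.numeric(Sigma), 2, 2)
  if (any(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values <= 0))
    abort("Sigma must be positive definite")
  # companion-matrix stationarity check
  p <- length(A)
  comp <- matrix(0, 2 * p, 2 * p)
  for (k in seq_len(p)) comp[1:2, (2 * k - 1):(2 * k)] <- A[[k]]
  if (p > 1L) comp[3:(2 * p), 1:(2 * (p - 1))] <- diag(2 * (p - 1))
  rho <- max(Mod(eigen(comp, only.values = TRUE)$values))
  if (rho >= 1) abort(sprintf("VAR spec is unstable (spectral radius %.3f)", rho))
  structure(list(A = A, Sigma = Sigma, fs = fs, spectral_radius = rho),
            class = "var_spec")
}

#' Simulate a realization of a VAR fixture
#'
#' @param spec a [var_spec()].
#' @param n number of samples.
#' @param seed integer seed (bit-for-bit reproducible).
#' @param burn burn-in samples discarded before returning.
#' @return Tibble with columns `time_s`, `x`, `y`.
#' @export
gen_var_process <- function(spec, n, seed = 1L, burn = 500L) {
  stopifnot(inherits(spec, "var_spec"))
  p <- length(spec$A)
  L <- chol(spec$Sigma)
  withr_seed(seed, {
    eps <- matrix(rnorm(2 * (n + burn)), ncol = 2) %*% L
    X <- matrix(0, n + burn, 2)
    for (t in (p + 1):(n + burn)) {
      acc <- eps[t, ]
      for (k in seq_len(p)) acc <- acc + spec$A[[k]] %*% X[t - k, ]
      X[t, ] <- acc
    }
    tibble(time_s = (seq_len(n) - 1) / spec$fs,
           x = X[burn + seq_len(n), 1], y = X[burn + seq_len(n), 2])
  })
}

# transfer function H(f) = (I - sum_k A_k e^{-i 2 pi f k / fs})^{-1}
var_transfer <- function(spec, freqs) {
  lapply(freqs, function(f) {
    Af <- diag(2) + 0i
    for (k in seq_along(spec$A))
      Af <- Af - spec$A[[k]] * exp(-2i * pi * f * k / spec$fs)
    solve(Af)
  })
}

#' Analytic spectral matrix of a VAR fixture
#'
#' @param spec a [var_spec()].
#' @param freqs frequencies (Hz) at which to evaluate.
#' @return A 2 x 2 x length(freqs) complex array, S(f) = H Sigma H* / fs.
#' @export
var_spectral_matrix <- function(spec, freqs) {
  H <- var_transfer(spec, freqs)
  S <- array(0i, c(2, 2, length(freqs)))
  for (i in seq_along(freqs)) S[, , i] <- H[[i]] %*% spec$Sigma %*% Conj(t(H[[i]]))
  S / spec$fs
}

#' Parametric Geweke spectral influence of a VAR fixture (test oracle)
#'
#' Computes the frequency-resolved directed influence in both directions
#' directly from the true coefficients, the closed-form answer the
#' nonparametric estimator must reproduce.
#'
#' @inheritParams var_spectral_matrix
#' @return Tibble with `freq`, `gc_xy` (x to y), `gc_yx` (y to x).
#' @export
var_granger <- function(spec, freqs) {
  H <- var_transfer(spec, freqs)
  Sg <- spec$Sigma
  gc <- vapply(seq_along(freqs), function(i) {
    Hf <- H[[i]]
    S <- Hf %*% Sg %*% Conj(t(Hf))
    geweke_pair(Re(diag(S)), Hf, Sg)
  }, numeric(2))
  tibble(freq = freqs, gc_xy = gc[1, ], gc_yx = gc[2, ])
}

# Geweke influence for one frequency from S diagonal, transfer H, innovations
# Sigma; returns c(x->y, y->x). Channel 1 = x, channel 2 = y.
geweke_pair <- function(Sdiag, H, Sigma) {
  # x -> y: uses H_yx and Sigma_xx conditioned on y's innovations
  sxx_c <- Sigma[1, 1] - Sigma[1, 2]^2 / Sigma[2, 2]
  syy_c <- Sigma[2, 2] - Sigma[1, 2]^2 / Sigma[1, 1]
  gxy <- log(Sdiag[2] / pmax(Sdiag[2] - sxx_c * Mod(H[2, 1])^2,
                             .Machine$double.eps))
  gyx <- log(Sdiag[1] / pmax(Sdiag[1] - syy_c * Mod(H[1, 2])^2,
                             .Machine$double.eps))
  c(gxy, gyx)
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler; used by the phase-locked spike fixture.
#'
#' @param n number of draws.
#' @param mu mean direction (rad).
#' @param kappa concentration (>= 0); 0 gives the uniform circle.
#' @return Numeric vector of angles in (-pi, pi].
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 0) abort("kappa must be >= 0")
  if (kappa == 0) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      out[i] <- sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  ((out + mu + pi) %% (2 * pi)) - pi
}

#' Spikes phase-locked to an oscillation with known concentration
#'
#' Generates an oscillatory "field" `cos(2 pi f t)` and spikes whose phases
#' relative to that oscillation are von Mises with concentration `kappa`
#' around phase 0 (the oscillation peak). The squared mean resultant length
#' `(I1(kappa)/I0(kappa))^2` is the analytic pairwise-phase-consistency
#' ground truth; `kappa = 0` gives phase-independent spiking.
#'
#' @param f_gamma oscillation frequency (Hz).
#' @param kappa von Mises concentration (>= 0).
#' @param rate mean spike rate (spikes/s).
#' @param duration duration (s).
#' @param seed integer seed.
#' @param fs sampling rate of the returned field signal (Hz).
#' @return List with `spike_times` (s), `signal` (tibble `time_s`, `value`),
#'   `fs`, and `ppc_true`.
#' @export
gen_locked_spikes <- function(f_gamma, kappa, rate, duration, seed = 1L,
                              fs = 1017.1) {
  if (rate <= 0) abort("rate must be > 0")
  if (kappa < 0) abort("kappa must be >= 0")
  n_spk <- max(2L, round(rate * duration))
  withr_seed(seed, {
    # pick a cycle uniformly, then a phase within the cycle
    cyc <- sample.int(max(1L, floor(f_gamma * duration) - 2L), n_spk,
                      replace = TRUE)
    ph <- rvonmises(n_spk, 0, kappa)
    st <- sort((cyc + ph / (2 * pi)) / f_gamma)
    st <- st[st > 0 & st < duration]
    tt <- (seq_len(round(duration * fs)) - 1) / fs
    list(spike_times = st,
         signal = tibble(time_s = tt, value = cos(2 * pi * f_gamma * tt)),
         fs = fs,
         ppc_true = (besselI(kappa, 1) / besselI(kappa, 0))^2)
  })
}

#' Delayed, scaled, noisy copy of a stimulus
#'
#' Ground truth for latency and cross-correlation estimators: the response is
#' `gain * stimulus(t - latency) + noise`. Fractional-sample delays are
#' applied in the frequency domain (circular shift), which is exact for the
#' steady-state periodic stimuli this fixture is used with.
#'
#' @param stimulus a `stim_trace`.
#' @param latency_ms imposed delay (ms); must be shorter than the trace.
#' @param gain multiplicative gain; `gain = 0` yields a pure-noise response.
#' @param noise_sd additive Gaussian noise sd.
#' @param seed integer seed.
#' @return Tibble `time_s`, `value` at the stimulus sampling rate.
#' @export
gen_lagged_response <- function(stimulus, latency_ms, gain = 1, noise_sd = 0,
                                seed = 1L) {
  fs <- stim_fs(stimulus)
  x <- stimulus$intensity
  n <- length(x)
  if (abs(latency_ms) / 1000 >= n / fs)
    abort("latency exceeds the trace length")
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n        # signed DFT bin index
  shift <- exp(-2i * pi * k * (latency_ms / 1000) * fs / n)
  y <- Re(fft(fft(x) * shift, inverse = TRUE)) / n * gain
  if (noise_sd > 0) y <- y + withr_seed(seed, rnorm(n, 0, noise_sd))
  tibble(time_s = stimulus$time_s, value = y)
}
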