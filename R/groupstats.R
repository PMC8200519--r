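#' Cluster-based permutation test for paired spectra
#'
#' Compares two paired sets of per-site spectra (e.g., two stimulation
#' conditions recorded at the same sites) with a nonparametric cluster-level
#' permutation test that corrects for the multiple comparisons across
#' frequencies. Per frequency, a paired t-value across sites serves purely as
#' a normalized difference metric; runs of adjacent frequencies whose t-value
#' is significant at the cluster-forming `alpha` are merged into clusters and
#' their t-values summed. For each permutation the two conditions are
#' exchanged or not, independently per site, and the maximum and minimum
#' cluster sums enter the max/min randomization distributions (zero when a
#' permutation produces no cluster). An observed cluster is significant when
#' its sum lies strictly above the 97.5th percentile of the maximum
#' distribution or strictly below the 2.5th percentile of the minimum
#' distribution (ties count as non-significant); this is a two-sided test at
#' the 5% family-wise level.
#'
#' @param spectra_a,spectra_b numeric site x frequency matrices on the same
#'   grid (>= 2 sites), or tibbles with columns `site`, `freq`, `value`.
#' @param n_perm number of permutations, default 10000.
#' @param alpha cluster-forming alpha for the per-frequency t-values.
#' @param seed integer seed; p-values are reproducible.
#' @param freqs optional frequency axis (Hz) for matrix input.
#' @return A `cluster_result` tibble: one row per observed cluster with
#'   `freq_lo`, `freq_hi`, `summed_t`, `sign`, `p_value`, `significant`;
#'   attributes `n_permutations`, `alpha_cluster_forming`,
#'   `percentile_bounds`, and `thresholds` (the 2.5th/97.5th percentile
#'   cluster-sum bounds).
#' @export
cluster_permutation_test <- function(spectra_a, spectra_b, n_perm = 10000,
                                     alpha = 0.05, seed = 1L, freqs = NULL) {
  A <- as_spectra_matrix(spectra_a)
  B <- as_spectra_matrix(spectra_b)
  if (!all(dim(A) == dim(B))) abort("mismatched spectra grids")
  n <- nrow(A)
  if (n < 2L) abort("need at least 2 sites")
  nf <- ncol(A)
  if (is.null(freqs)) freqs <- attr(spectra_a, "freqs") %||% seq_len(nf)
  D <- A - B
  tcrit <- qt(1 - alpha / 2, df = n - 1L)
  ssq <- colSums(D^2)                       # invariant under sign flips
  t_of <- function(signs) {                 # signs: n_perm x n of +/-1
    mns <- signs %*% D / n
    s2 <- (rep(ssq, each = nrow(signs)) - n * mns^2) / (n - 1L)
    s2[s2 < .Machine$double.eps] <- .Machine$double.eps
    mns / sqrt(s2 / n)
  }
  obs_t <- drop(t_of(matrix(1, 1, n)))
  obs_cl <- find_clusters(obs_t, tcrit)
  mx <- numeric(n_perm); mn <- numeric(n_perm)
  signs <- withr_seed(seed,
    matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n))
  Tp <- t_of(signs)
  for (p in seq_len(n_perm)) {
    cl <- find_clusters(Tp[p, ], tcrit)
    mx[p] <- if (nrow(cl)) max(cl$summed_t, 0) else 0
    mn[p] <- if (nrow(cl)) min(cl$summed_t, 0) else 0
  }
  hi <- stats::quantile(mx, 0.975, names = FALSE)
  lo <- stats::quantile(mn, 0.025, names = FALSE)
  if (nrow(obs_cl)) {
    p_val <- vapply(obs_cl$summed_t, function(s) {
      if (s > 0) max(1, sum(mx >= s)) / n_perm
      else max(1, sum(mn <= s)) / n_perm
    }, numeric(1))
    out <- tibble(freq_lo = freqs[obs_cl$lo], freq_hi = freqs[obs_cl$hi],
                  summed_t = obs_cl$summed_t,
                  sign = ifelse(obs_cl$summed_t > 0, 1L, -1L),
                  p_value = pmin(1, p_val),
                  significant = obs_cl$summed_t > hi | obs_cl$summed_t < lo)
  } else {
    out <- tibble(freq_lo = numeric(), freq_hi = numeric(),
                  summed_t = numeric(), sign = integer(),
                  p_value = numeric(), significant = logical())
  }
  structure(out, class = c("cluster_result", class(out)),
            n_permutations = n_perm, alpha_cluster_forming = alpha,
            percentile_bounds = c(2.5, 97.5),
            thresholds = c(lo = lo, hi = hi))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# maximal runs of adjacent frequencies with |t| > tcrit and a common sign
find_clusters <- function(tv, tcrit) {
  sig <- abs(tv) > tcrit
  if (!any(sig)) return(data.frame(lo = integer(), hi = integer(),
                                   summed_t = numeric()))
  lab <- sig * sign(tv)
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0
  data.frame(lo = starts[keep], hi = ends[keep],
             summed_t = vapply(which(keep), function(i)
               sum(tv[starts[i]:ends[i]]), numeric(1)))
}

as_spectra_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  if (is.data.frame(x) && all(c("site", "freq", "value") %in% names(x))) {
    w <- tidyr::pivot_wider(x, names_from = "freq", values_from = "value")
    m <- as.matrix(w[, setdiff(names(w), "site")])
    attr(m, "freqs") <- as.numeric(setdiff(names(w), "site"))
    return(m)
  }
  abort("spectra must be a site x frequency matrix or a site/freq/value tibble")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d cluster(s), %d permutations\n",
              nrow(x), attr(x, "n_permutations")))
  NextMethod()
}
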