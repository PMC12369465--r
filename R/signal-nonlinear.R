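# Nonlinear heart-rate-variability estimators: approximate / sample
# entropy, correlation dimension, Hurst exponent, largest Lyapunov
# exponent. All operate on plain numeric series.

# Chebyshev distance matrix between all m-length templates of x
cheb_dist <- function(x, m) {
  n <- length(x)
  N <- n - m + 1L
  D <- matrix(0, N, N)
  for (k in 0:(m - 1L)) {
    xk <- x[(1L + k):(N + k)]
    D <- pmax(D, abs(outer(xk, xk, "-")))
  }
  D
}

#' Approximate entropy (Pincus)
#'
#' \eqn{ApEn(m, r) = \Phi_m - \Phi_{m+1}} with
#' \eqn{\Phi_m = \mathrm{mean}_i \log(C_i^m(r))}, where \eqn{C_i^m} is the
#' fraction of templates (self-matches included) within Chebyshev distance
#' `r` of template `i`. The tolerance is `r_frac` times the series SD; a
#' constant series has ApEn 0 by convention.
#'
#' @param x Numeric series (`length(x) > m + 1`).
#' @param m Embedding dimension (default 2).
#' @param r_frac Tolerance as a fraction of `sd(x)` (default 0.2).
#' @param r Absolute tolerance, overriding `r_frac`.
#' @return Approximate entropy (nats).
#' @export
#' @examples
#' approximate_entropy(rep(5, 100))           # 0
#' approximate_entropy(sin(1:200 / 5), r_frac = 0.2)
approximate_entropy <- function(x, m = 2L, r_frac = 0.2, r = NULL) {
  x <- as.numeric(x)
  if (length(x) <= m + 1L) return(NA_real_)
  s <- sd(x)
  if (is.null(r)) {
    if (s == 0) return(0)
    r <- r_frac * s
  }
  phi <- function(mm) {
    D <- cheb_dist(x, mm)
    mean(log(rowMeans(D <= r)))
  }
  phi(m) - phi(m + 1L)
}

#' Sample entropy (Richman-Moorman)
#'
#' \eqn{SampEn(m, r) = -\log(A/B)} where `B` counts template pairs within
#' `r` at length `m` and `A` at length `m + 1`, excluding self-matches.
#' Returns `NA` when no pairs match.
#'
#' @inheritParams approximate_entropy
#' @return Sample entropy (nats).
#' @export
sample_entropy <- function(x, m = 2L, r_frac = 0.2, r = NULL) {
  x <- as.numeric(x)
  n <- length(x)
  if (n <= m + 1L) return(NA_real_)
  s <- sd(x)
  if (is.null(r)) {
    if (s == 0) return(0)
    r <- r_frac * s
  }
  # both counts use the first n - m templates so lengths are comparable
  Dm <- cheb_dist(x, m)[seq_len(n - m), seq_len(n - m), drop = FALSE]
  tail_d <- abs(outer(x[(m + 1L):n], x[(m + 1L):n], "-"))
  B <- (sum(Dm <= r) - (n - m)) / 2
  A <- (sum(pmax(Dm, tail_d) <= r) - (n - m)) / 2
  if (B == 0 || A == 0) return(NA_real_)
  -log(A / B)
}

#' Correlation dimension (Grassberger-Procaccia)
#'
#' Time-delay embedding (delay 1) at dimensions `m_range`; for each `m`
#' the slope of `log C(r)` versus `log r` is fitted over radii spanning
#' the 5th-50th percentile of pairwise template distances, and the slopes
#' are averaged.
#'
#' @param x Numeric series.
#' @param m_range Embedding dimensions to sweep (default `2:6`).
#' @param n_r Number of radii in the fit (default 8).
#' @return Estimated correlation dimension, `NA` for short or degenerate
#'   series.
#' @export
correlation_dimension <- function(x, m_range = 2:6, n_r = 8L) {
  x <- as.numeric(x)
  if (length(x) < max(m_range) + 10L || sd(x) == 0) return(NA_real_)
  slopes <- vapply(m_range, function(m) {
    D <- cheb_dist(x, m)
    d <- D[upper.tri(D)]
    d <- d[d > 0]
    if (length(d) < 20L) return(NA_real_)
    rs <- exp(seq(log(quantile(d, 0.05)), log(quantile(d, 0.5)),
                  length.out = n_r))
    cr <- vapply(rs, function(r) mean(d <= r), numeric(1))
    keep <- cr > 0
    if (sum(keep) < 3L) return(NA_real_)
    unname(coef(lm(log(cr[keep]) ~ log(rs[keep])))[2])
  }, numeric(1))
  if (all(is.na(slopes))) NA_real_ else mean(slopes, na.rm = TRUE)
}

#' Hurst exponent by rescaled-range analysis
#'
#' Classical R/S estimate: block sizes log-spaced between 8 and half the
#' series length; within each block the range of cumulative mean-deviations
#' is divided by the block SD, and the Hurst exponent is the slope of
#' `log(mean R/S)` against `log(block size)`.
#'
#' @param x Numeric series (needs at least 32 points).
#' @return Hurst exponent estimate, `NA` if too short/degenerate.
#' @export
hurst_exponent <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 32L || sd(x) == 0) return(NA_real_)
  sizes <- unique(round(exp(seq(log(8), log(n / 2), length.out = 6))))
  rs <- vapply(sizes, function(w) {
    nb <- n %/% w
    vals <- vapply(seq_len(nb), function(b) {
      seg <- x[((b - 1L) * w + 1L):(b * w)]
      s <- sd(seg)
      if (s == 0) return(NA_real_)
      dev <- cumsum(seg - mean(seg))
      (max(dev) - min(dev)) / s
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  keep <- is.finite(rs) & rs > 0
  if (sum(keep) < 3L) return(NA_real_)
  unname(coef(lm(log(rs[keep]) ~ log(sizes[keep])))[2])
}

#' Largest Lyapunov exponent (Rosenstein)
#'
#' Delay embedding (dimension `m`, delay 1); each template is paired with
#' its nearest neighbour at temporal separation greater than `min_sep`,
#' and the average log-divergence curve is fitted over the first
#' `fit_steps` steps. Units: nats per sample.
#'
#' @param x Numeric series.
#' @param m Embedding dimension (default 3).
#' @param min_sep Minimum temporal separation of neighbour pairs.
#' @param fit_steps Steps of divergence used in the linear fit.
#' @return Estimated largest Lyapunov exponent, `NA` if undefined.
#' @export
lyapunov_exponent <- function(x, m = 3L, min_sep = 10L, fit_steps = 10L) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < m + min_sep + fit_steps + 10L || sd(x) == 0) return(NA_real_)
  D <- cheb_dist(x, m)
  N <- nrow(D)
  sep <- abs(outer(seq_len(N), seq_len(N), "-"))
  D[sep <= min_sep] <- Inf
  nn <- apply(D, 1, which.min)
  usable <- which(is.finite(D[cbind(seq_len(N), nn)]))
  div <- matrix(NA_real_, length(usable), fit_steps)
  for (r in seq_along(usable)) {
    i <- usable[r]; j <- nn[i]
    for (s in seq_len(fit_steps)) {
      if (i + s <= N && j + s <= N) {
        d <- max(abs(x[(i + s):(i + s + m - 1L)] - x[(j + s):(j + s + m - 1L)]))
        if (d > 0) div[r, s] <- log(d)
      }
    }
  }
  curve <- colMeans(div, na.rm = TRUE)
  keep <- is.finite(curve)
  if (sum(keep) < 3L) return(NA_real_)
  unname(coef(lm(curve[keep] ~ seq_len(fit_steps)[keep]))[2])
}
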