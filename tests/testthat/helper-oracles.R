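# Independent brute-force oracles used across the suite. These deliberately
# mirror the textbook definitions with explicit loops, not the package's
# vectorised implementations.

brute_entropy <- function(p, base = 2) {
  h <- 0
  for (pi in p) if (pi > 0) h <- h - pi * log(pi, base)
  unname(h)
}

brute_mi <- function(p, base = 2) {
  px <- rowSums(p); py <- colSums(p)
  acc <- 0
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(ncol(p))) {
      if (p[i, j] > 0) {
        acc <- acc + p[i, j] * log(p[i, j] / (px[i] * py[j]), base)
      }
    }
  }
  unname(acc)
}

brute_cmi <- function(p, base = 2) {
  # chain rule through conditional entropies: H(X,Z) + H(Y,Z) - H(Z) - H(X,Y,Z)
  hxz <- brute_entropy(as.vector(apply(p, c(1, 3), sum)), base)
  hyz <- brute_entropy(as.vector(apply(p, c(2, 3), sum)), base)
  hz <- brute_entropy(as.vector(apply(p, 3, sum)), base)
  hxyz <- brute_entropy(as.vector(p), base)
  hxz + hyz - hz - hxyz
}

random_pmf <- function(dims, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- array(runif(prod(dims)), dims)
  p / sum(p)
}

# O(n^2) double-loop approximate entropy (Pincus definition)
brute_apen <- function(x, m, r) {
  n <- length(x)
  phi <- function(mm) {
    N <- n - mm + 1
    cs <- numeric(N)
    for (i in seq_len(N)) {
      cnt <- 0
      for (j in seq_len(N)) {
        if (max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)])) <= r) cnt <- cnt + 1
      }
      cs[i] <- cnt / N
    }
    mean(log(cs))
  }
  phi(m) - phi(m + 1)
}

brute_sampen <- function(x, m, r) {
  n <- length(x)
  A <- 0; B <- 0
  for (i in seq_len(n - m)) {
    for (j in seq_len(n - m)) {
      if (j <= i) next
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
        B <- B + 1
        if (max(abs(x[i:(i + m)] - x[j:(j + m)])) <= r) A <- A + 1
      }
    }
  }
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

# exhaustive breakpoint scan for the two-sample KS statistic
brute_ks <- function(a, b) {
  best_d <- -1; best_x <- NA_real_
  for (x in sort(unique(c(a, b)))) {
    d <- abs(mean(a <= x) - mean(b <= x))
    if (d > best_d + 1e-12) { best_d <- d; best_x <- x }
  }
  list(d_ks = best_d, threshold = best_x)
}

# tiny deterministic feature table used by several association tests
toy_table <- function() {
  set.seed(99)
  grid <- 6:1
  rows <- list()
  infants <- tibble::tibble(
    infant_id = sprintf("i%02d", 1:12),
    hospital_id = rep(c("hospA", "hospB", "hospC"), each = 4),
    class = rep(c("healthy", "healthy", "acidosis", "hie"), times = 3))
  for (k in seq_len(nrow(infants))) {
    rows[[k]] <- tibble::tibble(
      infant_id = infants$infant_id[k],
      hospital_id = infants$hospital_id[k],
      class = infants$class[k],
      ttd_epoch = grid,
      f_trend = grid + rnorm(6, 0, 0.2),
      f_noise = rnorm(6))
  }
  dplyr::bind_rows(rows)
}
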