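# Binary healthy-vs-pathological discriminability via the two-sample
# Kolmogorov-Smirnov statistic, time-invariant and per TTD epoch.

#' Two-sample KS statistic and optimal threshold
#'
#' Scans every breakpoint (pooled observed value) for the maximum absolute
#' difference between the two empirical CDFs. The returned `threshold` is
#' the value at which the distance is maximal — the cutoff giving the
#' greatest separability of the two samples; ties are broken toward the
#' smallest value.
#'
#' @param sample_a,sample_b Non-empty numeric vectors (NAs dropped).
#' @return List with `d_ks` and `threshold`.
#' @export
#' @examples
#' ks_statistic(c(1, 2, 3), c(4, 5, 6))  # d_ks = 1
#' ks_statistic(c(1, 2), c(1, 3))        # d_ks = 0.5 at threshold 2
ks_statistic <- function(sample_a, sample_b) {
  sample_a <- sample_a[is.finite(sample_a)]
  sample_b <- sample_b[is.finite(sample_b)]
  if (!length(sample_a) || !length(sample_b)) abort("Empty sample.")
  br <- sort(unique(c(sample_a, sample_b)))
  fa <- ecdf(sample_a); fb <- ecdf(sample_b)
  d <- abs(fa(br) - fb(br))
  # first maximiser up to floating-point noise: ties break toward the
  # smallest breakpoint value
  i <- which(d >= max(d) - 1e-12)[1]
  list(d_ks = max(d), threshold = br[i])
}

#' Bootstrap variability of the KS statistic and threshold
#'
#' Resamples both groups with replacement (same sizes, epoch-level) and
#' recomputes the KS statistic and optimal threshold for each iteration.
#'
#' @inheritParams ks_statistic
#' @param n_boot Number of bootstrap iterations (default 10000).
#' @param seed Optional integer seed.
#' @return List with `d_ks_mean`, `d_ks_sd`, `threshold_mean`,
#'   `threshold_sd`, and the replicate tibble in `$replicates`.
#' @export
bootstrap_ks <- function(sample_a, sample_b, n_boot = 10000L, seed = NULL) {
  sample_a <- sample_a[is.finite(sample_a)]
  sample_b <- sample_b[is.finite(sample_b)]
  if (!length(sample_a) || !length(sample_b)) abort("Empty sample.")
  if (n_boot < 1L) abort("`n_boot` must be >= 1.")
  run <- function() {
    d <- numeric(n_boot); thr <- numeric(n_boot)
    na <- length(sample_a); nb <- length(sample_b)
    for (i in seq_len(n_boot)) {
      ks <- ks_statistic(sample_a[sample.int(na, na, replace = TRUE)],
                         sample_b[sample.int(nb, nb, replace = TRUE)])
      d[i] <- ks$d_ks; thr[i] <- ks$threshold
    }
    tibble::tibble(d_ks = d, threshold = thr)
  }
  reps <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  list(d_ks_mean = mean(reps$d_ks), d_ks_sd = sd(reps$d_ks),
       threshold_mean = mean(reps$threshold),
       threshold_sd = sd(reps$threshold), replicates = reps)
}

ks_pvalue <- function(sample_a, sample_b) {
  suppressWarnings(ks.test(sample_a, sample_b)$p.value)
}

#' Time-resolved KS discriminability of one feature
#'
#' Splits the cohort into healthy versus pathological (acidosis or HIE) and
#' computes the two-sample KS statistic and optimal threshold pooled over
#' all epochs (the time-invariant result, scope `"TI"`) and separately at
#' every TTD epoch (scope `t`). Per-epoch significance flags come from the
#' asymptotic two-sample KS test, BH-corrected across epochs. Optional
#' bootstrap resampling (epoch-level, with replacement) gives the
#' variability of both statistics.
#'
#' @param tbl Feature table (see [ctg_association()] for the layout).
#' @param feature Feature column name.
#' @param n_boot Bootstrap iterations per scope; 0 disables bootstrapping.
#' @param alpha Significance level for the per-epoch flags (default 0.05).
#' @param seed Optional integer seed for the bootstrap.
#' @return A `ctg_ks` tibble: `scope` ("TI" or the epoch index),
#'   `ttd_epoch`, `d_ks`, `threshold`, group sizes, `p`, `q`,
#'   `significant`, `available`, and bootstrap columns when requested.
#' @export
time_resolved_ks <- function(tbl, feature, n_boot = 0L, alpha = 0.05,
                             seed = NULL) {
  validate_feature_table(tbl)
  if (!feature %in% names(tbl)) abort(sprintf("No column `%s`.", feature))
  v <- tbl[[feature]]
  patho <- as.character(tbl$class) %in% c("acidosis", "hie")
  scopes <- c(NA_integer_, sort(unique(tbl$ttd_epoch), decreasing = TRUE))
  seeds <- if (!is.null(seed)) seed + seq_along(scopes) else
    vector("list", length(scopes))
  rows <- purrr::map_dfr(seq_along(scopes), function(i) {
    t <- scopes[i]
    sel <- if (is.na(t)) rep(TRUE, nrow(tbl)) else tbl$ttd_epoch == t
    a <- v[sel & !patho]; b <- v[sel & patho]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    out <- tibble::tibble(
      scope = if (is.na(t)) "TI" else as.character(t),
      ttd_epoch = t, n_healthy = length(a), n_pathological = length(b),
      available = length(a) > 0 && length(b) > 0,
      d_ks = NA_real_, threshold = NA_real_, p = NA_real_)
    if (!out$available) return(out)
    ks <- ks_statistic(a, b)
    out$d_ks <- ks$d_ks; out$threshold <- ks$threshold
    out$p <- ks_pvalue(a, b)
    if (n_boot > 0L) {
      bt <- bootstrap_ks(a, b, n_boot = n_boot, seed = seeds[[i]])
      out$d_ks_boot_mean <- bt$d_ks_mean; out$d_ks_boot_sd <- bt$d_ks_sd
      out$threshold_boot_mean <- bt$threshold_mean
      out$threshold_boot_sd <- bt$threshold_sd
    }
    out
  })
  per_epoch <- !is.na(rows$ttd_epoch) & rows$available
  rows$q <- NA_real_
  rows$q[per_epoch] <- bh_adjust(rows$p[per_epoch])
  rows$q[rows$scope == "TI"] <- rows$p[rows$scope == "TI"]
  rows$significant <- !is.na(rows$q) & rows$q < alpha
  attr(rows, "feature") <- feature
  class(rows) <- c("ctg_ks", class(rows))
  rows
}
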