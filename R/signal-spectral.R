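# Frequency-band power and phase-rectified signal averaging.

#' Spectral band powers of a heart-rate segment
#'
#' Integrated periodogram power in the conventional fetal HRV bands:
#' low frequency (LF) 0.03-0.15 Hz, movement frequency (MF) 0.15-0.5 Hz,
#' high frequency (HF) 0.5-1.0 Hz, plus the sympatho-vagal balance ratio
#' LF/(MF+HF). The segment is linearly detrended before the periodogram.
#' Segments shorter than `min_duration_s` (two cycles of the lowest LF
#' edge by default) return `NA` for every band.
#'
#' @param x Numeric samples.
#' @param fs Sampling rate in Hz (default 4).
#' @param bands Named list of `c(lo, hi)` band edges in Hz.
#' @param min_duration_s Minimum segment duration in seconds.
#' @return List with `lf`, `mf`, `hf` and `ratio`.
#' @export
#' @examples
#' t <- seq(0, 300, by = 0.25)
#' bp <- band_powers(sin(2 * pi * 0.1 * t))
#' bp$lf / (bp$lf + bp$mf + bp$hf)  # ~1: a 0.1 Hz tone is pure LF
band_powers <- function(x, fs = 4,
                        bands = list(lf = c(0.03, 0.15), mf = c(0.15, 0.5),
                                     hf = c(0.5, 1.0)),
                        min_duration_s = 2 / 0.03) {
  x <- as.numeric(x)
  empty <- list(lf = NA_real_, mf = NA_real_, hf = NA_real_, ratio = NA_real_)
  if (length(x) < ceiling(min_duration_s * fs) || sd(x) == 0) return(empty)
  pg <- spec.pgram(stats::ts(x, frequency = fs), detrend = TRUE, taper = 0,
                   fast = TRUE, plot = FALSE)
  bp <- lapply(bands, function(b) {
    sum(pg$spec[pg$freq >= b[1] & pg$freq < b[2]])
  })
  denom <- bp$mf + bp$hf
  list(lf = bp$lf, mf = bp$mf, hf = bp$hf,
       ratio = if (denom > 0) bp$lf / denom else NA_real_)
}

#' Phase-rectified signal averaging capacity
#'
#' Anchors are samples that increase (`sign = +1`, acceleration capacity)
#' or decrease (`sign = -1`, deceleration capacity) relative to the
#' previous sample. Windows of `2L` samples around each anchor are
#' averaged and the capacity is the Haar-wavelet coefficient at the
#' anchor: `(xbar(0) + xbar(1) - xbar(-1) - xbar(-2)) / 4`. Series with no
#' anchors (e.g. constant, or strictly monotone against the chosen sign)
#' give `NA`.
#'
#' @param x Numeric series (`length(x) > 2L + 2`).
#' @param sign `+1` for acceleration anchors, `-1` for deceleration.
#' @param L Half window width in samples (default 5).
#' @return PRSA capacity value, `NA` when no anchors exist.
#' @export
prsa_capacity <- function(x, sign = 1, L = 5L) {
  x <- as.numeric(x)
  n <- length(x)
  if (n <= 2L * L + 2L) return(NA_real_)
  d <- diff(x)
  anchors <- which(if (sign >= 0) d > 0 else d < 0) + 1L
  anchors <- anchors[anchors > L & anchors + L - 1L <= n]
  if (!length(anchors)) return(NA_real_)
  offs <- (-L):(L - 1L)
  win <- vapply(offs, function(k) mean(x[anchors + k]), numeric(1))
  names(win) <- offs
  unname((win["0"] + win["1"] - win["-1"] - win["-2"]) / 4)
}

#' Deceleration reserve
#'
#' Signed combination of the acceleration and deceleration capacities
#' (their sum by default: a negative-dominant value signals that
#' decelerations outweigh accelerations).
#'
#' @inheritParams prsa_capacity
#' @return `AC + DC`, or `NA` when either capacity is undefined.
#' @export
deceleration_reserve <- function(x, L = 5L) {
  ac <- prsa_capacity(x, sign = 1, L = L)
  dc <- prsa_capacity(x, sign = -1, L = L)
  ac + dc
}
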