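# Raw trace container, gap filling, epoch segmentation.

#' Construct a signal trace
#'
#' One row per 4-Hz sample, aligned so the last row is the moment of
#' delivery. `missing` marks gaps / uninterpretable samples; `fhr_bpm` is
#' `NA` wherever missing.
#'
#' @param fhr Fetal heart rate samples (bpm), `NA` allowed.
#' @param up Uterine pressure samples (mmHg), optional.
#' @param missing Logical mask; defaults to `is.na(fhr)`.
#' @param fs Sampling rate (Hz).
#' @return Tibble with `time_s`, `fhr_bpm`, `up_mmHg`, `missing`.
#' @export
signal_trace <- function(fhr, up = NULL, missing = NULL, fs = FS_HZ) {
  n <- length(fhr)
  if (is.null(missing)) missing <- is.na(fhr)
  if (length(missing) != n) abort("`missing` must match `fhr` in length.")
  if (!is.null(up) && length(up) != n) abort("`up` must match `fhr` in length.")
  if (any(!is.finite(fhr[!missing]))) {
    abort("`fhr` must be finite wherever not missing.")
  }
  fhr[missing] <- NA_real_
  tibble::tibble(time_s = (seq_len(n) - 1L) / fs,
                 fhr_bpm = as.numeric(fhr),
                 up_mmHg = if (is.null(up)) NA_real_ else as.numeric(up),
                 missing = as.logical(missing))
}

#' Fill short gaps by linear interpolation
#'
#' Gaps strictly shorter than `max_gap` samples (60, i.e. 15 s at 4 Hz)
#' with valid samples on both sides are filled by a linear ramp between
#' the flanking values; longer gaps, and gaps touching either end of the
#' trace, remain missing (no extrapolation).
#'
#' @param trace A [signal_trace()] tibble.
#' @param max_gap Strict gap-length threshold in samples.
#' @return The trace with eligible gaps filled and `missing` updated.
#' @export
fill_gaps <- function(trace, max_gap = 60L) {
  m <- trace$missing
  if (!any(m)) return(trace)
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  n <- length(m)
  x <- trace$fhr_bpm
  for (i in which(r$values)) {
    len <- r$lengths[i]
    s <- starts[i]; e <- ends[i]
    if (len >= max_gap || s == 1L || e == n) next
    left <- x[s - 1L]; right <- x[e + 1L]
    x[s:e] <- left + (right - left) * seq_len(len) / (len + 1L)
    m[s:e] <- FALSE
  }
  trace$fhr_bpm <- x
  trace$missing <- m
  trace
}

#' Segment a trace into 20-minute epochs
#'
#' Tiles non-overlapping 4800-sample windows backward from delivery (the
#' end of the trace). Epoch `t = 1` is the final pre-delivery window;
#' windows beyond `max_epochs` (12 h) are discarded, as is any incomplete
#' leading window. An epoch is accepted when at most 20% of its samples
#' are missing (strictly more than 20% rejects).
#'
#' @param trace A [signal_trace()] tibble.
#' @param epoch_samples Samples per epoch (default 4800).
#' @param max_epochs Maximum number of epochs (default 36).
#' @param max_missing_frac Acceptance threshold on the missing fraction.
#' @return Tibble with `ttd_epoch`, 0-based half-open `start`/`end`
#'   sample indices, `fraction_missing`, `accepted`. Empty when the trace
#'   is shorter than one epoch.
#' @export
segment_epochs <- function(trace, epoch_samples = EPOCH_SAMPLES,
                           max_epochs = N_EPOCHS_MAX,
                           max_missing_frac = 0.20) {
  n <- nrow(trace)
  n_full <- min(n %/% epoch_samples, max_epochs)
  if (n_full < 1L) {
    return(tibble::tibble(ttd_epoch = integer(), start = integer(),
                          end = integer(), fraction_missing = numeric(),
                          accepted = logical()))
  }
  t <- seq_len(n_full)
  start <- n - t * epoch_samples
  end <- n - (t - 1L) * epoch_samples
  frac <- vapply(t, function(k) mean(trace$missing[(start[k] + 1L):end[k]]),
                 numeric(1))
  tibble::tibble(ttd_epoch = t, start = as.integer(start),
                 end = as.integer(end), fraction_missing = frac,
                 accepted = frac <= max_missing_frac)
}
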