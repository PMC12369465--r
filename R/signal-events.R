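# Rule-based detection of FHR baselines, accelerations, decelerations and
# uterine contractions, and deceleration subtype classification.

#' Event-detector configuration
#'
#' @param threshold_bpm Excursion threshold from the local baseline
#'   (clinical rule: more than 15 bpm).
#' @param min_duration_s Minimum sustained excursion (strictly more than
#'   15 s).
#' @param baseline_window_s Width of the rolling-median local baseline.
#' @param up_threshold Uterine-pressure excursion above resting tone
#'   (mmHg) marking a contraction.
#' @param up_min_duration_s Minimum contraction duration.
#' @param fs Sampling rate (Hz).
#' @return A configuration list.
#' @export
event_config <- function(threshold_bpm = 15, min_duration_s = 15,
                         baseline_window_s = 240, up_threshold = 15,
                         up_min_duration_s = 30, fs = FS_HZ) {
  list(threshold_bpm = threshold_bpm, min_duration_s = min_duration_s,
       baseline_window_s = baseline_window_s, up_threshold = up_threshold,
       up_min_duration_s = up_min_duration_s, fs = fs)
}

# odd rolling-median window in samples
odd_window <- function(seconds, fs, n) {
  k <- min(round(seconds * fs), n - (1 - n %% 2))
  k <- max(3L, as.integer(k))
  if (k %% 2L == 0L) k <- k - 1L
  k
}

# NA-tolerant slow reference: interpolate across NAs, then runmed
slow_reference <- function(x, window_s, fs) {
  n <- length(x)
  if (all(is.na(x))) return(rep(NA_real_, n))
  idx <- which(!is.na(x))
  xf <- approx(idx, x[idx], xout = seq_len(n), rule = 2)$y
  as.numeric(runmed(xf, odd_window(window_s, fs, n)))
}

runs_where <- function(flag, min_len) {
  flag[is.na(flag)] <- FALSE
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths > min_len
  tibble::tibble(start = starts[keep] - 1L, end = ends[keep]) # 0-based half-open
}

event_tibble <- function(start = integer(), end = integer(),
                         type = character(), subtype = NA_character_) {
  tibble::tibble(start = as.integer(start), end = as.integer(end),
                 type = type,
                 subtype = if (length(start)) rep_len(subtype, length(start))
                           else character())
}

#' Detect CTG events in a (gap-filled) trace
#'
#' Rule-based detector. The local FHR baseline is a slow rolling median;
#' accelerations are excursions above it by more than `threshold_bpm`
#' sustained for more than `min_duration_s`, decelerations are the
#' mirrored rule, and the remaining interpretable samples form baseline
#' segments. Contractions are uterine-pressure excursions above a
#' rolling resting tone sustained for at least `up_min_duration_s`.
#'
#' @param trace A [signal_trace()] tibble, ideally after [fill_gaps()].
#' @param config An [event_config()] list.
#' @return Event tibble with 0-based half-open `start`/`end`, `type`
#'   (`baseline`, `acceleration`, `deceleration`, `contraction`) and
#'   `subtype` (`NA` until [classify_decelerations()] is applied).
#' @export
detect_events <- function(trace, config = event_config()) {
  x <- trace$fhr_bpm
  x[trace$missing] <- NA_real_
  n <- length(x)
  if (all(is.na(x))) return(event_tibble())
  ref <- slow_reference(x, config$baseline_window_s, config$fs)
  dev <- x - ref
  min_len <- as.integer(round(config$min_duration_s * config$fs))
  acc <- runs_where(dev > config$threshold_bpm, min_len)
  dec <- runs_where(dev < -config$threshold_bpm, min_len)
  in_event <- rep(FALSE, n)
  for (i in seq_len(nrow(acc))) in_event[(acc$start[i] + 1L):acc$end[i]] <- TRUE
  for (i in seq_len(nrow(dec))) in_event[(dec$start[i] + 1L):dec$end[i]] <- TRUE
  base <- runs_where(!is.na(x) & !in_event, 0L)
  ev <- dplyr::bind_rows(
    dplyr::mutate(base, type = "baseline", subtype = NA_character_),
    dplyr::mutate(acc, type = "acceleration", subtype = NA_character_),
    dplyr::mutate(dec, type = "deceleration", subtype = NA_character_))
  up <- trace$up_mmHg
  if (any(is.finite(up))) {
    tone <- slow_reference(up, config$baseline_window_s, config$fs)
    ctr <- runs_where(up - tone > config$up_threshold,
                      as.integer(round(config$up_min_duration_s * config$fs)))
    if (nrow(ctr)) {
      ev <- dplyr::bind_rows(ev, dplyr::mutate(ctr, type = "contraction",
                                               subtype = NA_character_))
    }
  }
  dplyr::arrange(ev, .data$start)
}

#' Deceleration-classifier configuration
#'
#' @param variable_rate_bpm_s Descent-rate threshold: decelerations whose
#'   initial descent is at least this fast are `variable` (abrupt onset).
#' @param late_lag_s Minimum lag of the deceleration nadir behind the
#'   paired contraction peak for a gradual deceleration to be `late`.
#' @param pair_window_s Maximum nadir-to-peak lag considered pairable.
#' @param fs Sampling rate (Hz).
#' @return A configuration list.
#' @export
decel_config <- function(variable_rate_bpm_s = 2, late_lag_s = 20,
                         pair_window_s = 150, fs = FS_HZ) {
  list(variable_rate_bpm_s = variable_rate_bpm_s, late_lag_s = late_lag_s,
       pair_window_s = pair_window_s, fs = fs)
}

#' Classify deceleration subtypes
#'
#' `variable` decelerations have an abrupt onset (descent rate from the
#' event start to the nadir at least `variable_rate_bpm_s`). Gradual
#' decelerations whose nadir lags a preceding contraction peak by more
#' than `late_lag_s` (within `pair_window_s`) are `late`; everything else
#' — including every gradual deceleration when no contractions are
#' available, which makes `late` impossible — is `other`.
#'
#' @param events Event tibble from [detect_events()] (or ground-truth
#'   annotations converted to events); decelerations get their `subtype`
#'   filled, other rows pass through.
#' @param trace The [signal_trace()] the events refer to.
#' @param config A [decel_config()] list.
#' @return The event tibble with deceleration subtypes
#'   (`late` / `variable` / `other`).
#' @export
classify_decelerations <- function(events, trace, config = decel_config()) {
  dec_idx <- which(events$type == "deceleration")
  if (!length(dec_idx)) return(events)
  x <- trace$fhr_bpm
  peaks <- numeric(0)
  ctr <- events[events$type == "contraction", ]
  up <- trace$up_mmHg
  if (nrow(ctr) && any(is.finite(up))) {
    peaks <- vapply(seq_len(nrow(ctr)), function(i) {
      lo <- ctr$start[i] + 1L; hi <- ctr$end[i]
      (lo - 1L) + which.max(up[lo:hi]) - 1L # 0-based peak sample
    }, numeric(1))
  }
  for (i in dec_idx) {
    # analyse from 10 s before the detected run: the onset descent begins
    # before the excursion crosses the detection threshold
    lo <- max(1L, events$start[i] + 1L - as.integer(10 * config$fs))
    hi <- events$end[i]
    seg <- x[lo:hi]
    if (all(is.na(seg))) { events$subtype[i] <- "other"; next }
    seg_ok <- !is.na(seg)
    if (sum(seg_ok) > 21L) { # median filter against noise spikes
      seg[seg_ok] <- as.numeric(runmed(seg[seg_ok], 21L))
    }
    bottom <- min(seg, na.rm = TRUE)
    # centre of the bottom region (within 2 bpm of the minimum) is the
    # nadir used for contraction pairing
    in_bottom <- which(!is.na(seg) & seg <= bottom + 2)
    nadir <- (lo - 1L) + as.integer(round(mean(in_bottom))) - 1L
    # abruptness: steepest sustained (8-s span) descent anywhere in the event
    span_s <- 8
    span <- as.integer(span_s * config$fs)
    rate <- if (length(seg) > span) {
      max((seg[seq_len(length(seg) - span)] -
             seg[(span + 1L):length(seg)]) / span_s, na.rm = TRUE)
    } else 0
    if (rate >= config$variable_rate_bpm_s) {
      events$subtype[i] <- "variable"
      next
    }
    lag_s <- NA_real_
    if (length(peaks)) {
      before <- peaks[peaks <= nadir]
      if (length(before)) lag_s <- (nadir - max(before)) / config$fs
    }
    events$subtype[i] <-
      if (!is.na(lag_s) && lag_s > config$late_lag_s &&
          lag_s <= config$pair_window_s) "late" else "other"
  }
  events
}
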