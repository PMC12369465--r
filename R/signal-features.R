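# Per-epoch CTG feature extraction over the baseline / acceleration /
# deceleration / contraction event grid (88 features).

#' Classical fetal HRV indices
#'
#' Computed from 2.5-s segment means `v` of the FHR, following the
#' classical fetal monitoring definitions: short-term variability (STV) is
#' the mean absolute successive difference of `v`; the interval index (II)
#' is STV divided by the SD of those differences; long-term irregularity
#' (LTI) is the mean interquartile range of `v` over 3-min windows; delta
#' is the per-minute (max - min) averaged over minutes.
#'
#' @param x FHR samples (bpm).
#' @param fs Sampling rate (Hz).
#' @param coarse_s Segment-mean width in seconds (default 2.5).
#' @return List with `stv`, `ii`, `lti`, `delta`.
#' @export
hrv_classical <- function(x, fs = FS_HZ, coarse_s = 2.5) {
  out <- list(stv = NA_real_, ii = NA_real_, lti = NA_real_,
              delta = NA_real_)
  x <- x[is.finite(x)]
  if (length(x) < 2 * coarse_s * fs) return(out)
  v <- coarse_means(x, round(coarse_s * fs))
  if (length(v) >= 2) {
    d <- diff(v)
    out$stv <- mean(abs(d))
    sdd <- sd(d)
    out$ii <- if (is.finite(sdd) && sdd > 0) out$stv / sdd else NA_real_
  }
  win <- round(180 / coarse_s) # 3 min of coarse samples
  if (length(v) >= win) {
    nb <- length(v) %/% win
    iqrs <- vapply(seq_len(nb), function(b) {
      seg <- v[((b - 1L) * win + 1L):(b * win)]
      diff(unname(quantile(seg, c(0.25, 0.75))))
    }, numeric(1))
    out$lti <- mean(iqrs)
  }
  mwin <- round(60 * fs)
  if (length(x) >= mwin) {
    nb <- length(x) %/% mwin
    rng <- vapply(seq_len(nb), function(b) {
      seg <- x[((b - 1L) * mwin + 1L):(b * mwin)]
      max(seg) - min(seg)
    }, numeric(1))
    out$delta <- mean(rng)
  }
  out
}

coarse_means <- function(x, w) {
  nb <- length(x) %/% w
  if (nb < 1L) return(numeric(0))
  colMeans(matrix(x[seq_len(nb * w)], nrow = w))
}

#' Feature-extraction configuration
#'
#' @param r_fracs Tolerance fractions for ApEn / SampEn.
#' @param apen_m Embedding dimension for the entropies.
#' @param prsa_L PRSA half-window (coarse samples).
#' @param coarse_s Coarse-graining width (s) for the nonlinear estimators
#'   and PRSA (2.5-s means).
#' @param min_spectral_s Minimum segment duration for band powers.
#' @param bands Spectral bands, see [band_powers()].
#' @param fs Sampling rate (Hz).
#' @return A configuration list.
#' @export
feature_config <- function(r_fracs = c(0.1, 0.2, 0.3), apen_m = 2L,
                           prsa_L = 5L, coarse_s = 2.5,
                           min_spectral_s = 120,
                           bands = list(lf = c(0.03, 0.15),
                                        mf = c(0.15, 0.5),
                                        hf = c(0.5, 1.0)),
                           fs = FS_HZ) {
  list(r_fracs = r_fracs, apen_m = apen_m, prsa_L = prsa_L,
       coarse_s = coarse_s, min_spectral_s = min_spectral_s, bands = bands,
       fs = fs)
}

#' The CTG feature grid
#'
#' The feature-by-event grid implemented by [extract_features()]:
#' 26 baseline (`bl_`), 28 acceleration (`ac_`), 31 deceleration (`dc_`)
#' and 3 contraction (`ct_`) features — 88 in total.
#'
#' @return Tibble with `name`, `event`, `measure`.
#' @export
ctg_feature_grid <- function() {
  shared <- c("level", "delta", "stv", "lti", "ii", "sd",
              "lf_power", "mf_power", "hf_power", "lf_ratio",
              "apen_r010", "apen_r020", "apen_r030",
              "sampen_r010", "sampen_r020", "sampen_r030",
              "corr_dim", "hurst", "lyapunov",
              "acc_capacity", "dec_capacity", "dec_reserve", "dwell_time")
  grid <- list(
    baseline = c(shared, "slope", "trans_accel", "trans_decel"),
    acceleration = c(shared, "trans_decel", "trans_baseline", "area",
                     "height", "count"),
    deceleration = c(shared, "trans_accel", "trans_baseline", "area",
                     "height", "count", "n_late", "n_variable", "n_other"),
    contraction = c("count", "dwell_time", "resting_time"))
  prefix <- c(baseline = "bl", acceleration = "ac", deceleration = "dc",
              contraction = "ct")
  purrr::map_dfr(names(grid), function(ev) {
    tibble::tibble(name = paste(prefix[[ev]], grid[[ev]], sep = "_"),
                   event = ev, measure = grid[[ev]])
  })
}

# sample-based measures on the concatenated samples of one event type
sample_measures <- function(x, t_s, config) {
  out <- list(level = NA_real_, slope = NA_real_, delta = NA_real_,
              stv = NA_real_, lti = NA_real_, ii = NA_real_, sd = NA_real_,
              lf_power = NA_real_, mf_power = NA_real_, hf_power = NA_real_,
              lf_ratio = NA_real_,
              apen_r010 = NA_real_, apen_r020 = NA_real_,
              apen_r030 = NA_real_,
              sampen_r010 = NA_real_, sampen_r020 = NA_real_,
              sampen_r030 = NA_real_,
              corr_dim = NA_real_, hurst = NA_real_, lyapunov = NA_real_,
              acc_capacity = NA_real_, dec_capacity = NA_real_,
              dec_reserve = NA_real_)
  ok <- is.finite(x)
  x <- x[ok]; t_s <- t_s[ok]
  if (!length(x)) return(out)
  fs <- config$fs
  out$level <- mean(x)
  if (length(x) >= 8) out$slope <- unname(coef(lm(x ~ t_s))[2])
  hv <- hrv_classical(x, fs = fs, coarse_s = config$coarse_s)
  out[c("stv", "ii", "lti", "delta")] <- hv[c("stv", "ii", "lti", "delta")]
  # high-pass by removing a slow rolling median, then SD
  if (length(x) >= 16) {
    k <- odd_window(30, fs, length(x))
    out$sd <- sd(x - as.numeric(runmed(x, k)))
  }
  bp <- band_powers(x, fs = fs, bands = config$bands,
                    min_duration_s = config$min_spectral_s)
  out[c("lf_power", "mf_power", "hf_power", "lf_ratio")] <-
    bp[c("lf", "mf", "hf", "ratio")]
  v <- coarse_means(x, round(config$coarse_s * fs))
  if (length(v) > config$apen_m + 1) {
    rn <- c("r010", "r020", "r030")
    for (i in seq_along(config$r_fracs)) {
      out[[paste0("apen_", rn[i])]] <-
        approximate_entropy(v, m = config$apen_m, r_frac = config$r_fracs[i])
      out[[paste0("sampen_", rn[i])]] <-
        sample_entropy(v, m = config$apen_m, r_frac = config$r_fracs[i])
    }
    out$corr_dim <- correlation_dimension(v)
    out$hurst <- hurst_exponent(v)
    out$lyapunov <- lyapunov_exponent(v)
    out$acc_capacity <- prsa_capacity(v, sign = 1, L = config$prsa_L)
    out$dec_capacity <- prsa_capacity(v, sign = -1, L = config$prsa_L)
    out$dec_reserve <- if (is.na(out$acc_capacity) || is.na(out$dec_capacity))
      NA_real_ else out$acc_capacity + out$dec_capacity
  }
  out
}

clip_events <- function(events, lo, hi) {
  ev <- events[events$end > lo & events$start < hi, , drop = FALSE]
  ev$start <- pmax(ev$start, lo)
  ev$end <- pmin(ev$end, hi)
  ev
}

#' Extract the per-epoch CTG feature set
#'
#' For every accepted epoch, computes the [ctg_feature_grid()] features
#' from the concatenated samples of each event type (baseline /
#' acceleration / deceleration) plus the event-geometry features (dwell,
#' resting, area, height, transition and subtype counts). Event types
#' absent from an epoch yield `NA` (missing, never zero) for their
#' sample-based features, while their event counts are 0.
#'
#' @param trace A gap-filled [signal_trace()].
#' @param epochs Epoch tibble from [segment_epochs()] (computed when
#'   `NULL`); only accepted epochs are extracted.
#' @param events Event tibble from [detect_events()] or ground-truth
#'   annotations; detected when `NULL`. Deceleration subtypes are
#'   classified on the fly when absent.
#' @param config A [feature_config()] list.
#' @return Tibble: one row per accepted epoch (`ttd_epoch`,
#'   `fraction_missing`, then the 88 feature columns).
#' @export
extract_features <- function(trace, epochs = NULL, events = NULL,
                             config = feature_config()) {
  if (is.null(epochs)) epochs <- segment_epochs(trace)
  if (is.null(events)) events <- detect_events(trace)
  if (any(events$type == "deceleration" & is.na(events$subtype))) {
    events <- classify_decelerations(events, trace)
  }
  epochs <- epochs[epochs$accepted, , drop = FALSE]
  grid <- ctg_feature_grid()
  x_all <- trace$fhr_bpm
  ref <- if (any(!is.na(x_all))) {
    slow_reference(ifelse(trace$missing, NA, x_all), 240, config$fs)
  } else rep(NA_real_, length(x_all))
  fs <- config$fs
  rows <- purrr::map_dfr(seq_len(nrow(epochs)), function(k) {
    lo <- epochs$start[k]; hi <- epochs$end[k]
    ev <- clip_events(events, lo, hi)
    fhr_ev <- ev[ev$type %in% c("baseline", "acceleration", "deceleration"), ]
    fhr_ev <- fhr_ev[order(fhr_ev$start), ]
    vals <- setNames(rep(NA_real_, nrow(grid)), grid$name)
    for (etype in c("baseline", "acceleration", "deceleration")) {
      pre <- c(baseline = "bl", acceleration = "ac", deceleration = "dc")[[etype]]
      sub <- fhr_ev[fhr_ev$type == etype, ]
      keys <- grid$measure[grid$event == etype]
      # geometry first (counts are 0, not NA, when the type is absent)
      if ("count" %in% keys) vals[paste0(pre, "_count")] <- nrow(sub)
      vals[paste0(pre, "_dwell_time")] <-
        if (nrow(sub)) sum(sub$end - sub$start) / fs else 0
      nxt <- fhr_ev$type[match(sub$end, fhr_ev$start)]
      for (tt in c("accel", "decel", "baseline")) {
        key <- paste0(pre, "_trans_", tt)
        if (key %in% grid$name) {
          full <- c(accel = "acceleration", decel = "deceleration",
                    baseline = "baseline")[[tt]]
          vals[key] <- sum(nxt == full, na.rm = TRUE)
        }
      }
      if (etype == "deceleration") {
        vals["dc_n_late"] <- sum(sub$subtype == "late", na.rm = TRUE)
        vals["dc_n_variable"] <- sum(sub$subtype == "variable", na.rm = TRUE)
        vals["dc_n_other"] <- sum(sub$subtype == "other", na.rm = TRUE)
      }
      if (!nrow(sub)) next
      idx <- unlist(purrr::map2(sub$start, sub$end,
                                function(s, e) (s + 1L):e))
      xs <- x_all[idx]
      if (etype != "baseline") {
        dev <- abs(xs - ref[idx])
        vals[paste0(pre, "_area")] <- sum(dev, na.rm = TRUE) / fs
        vals[paste0(pre, "_height")] <- max(dev, na.rm = TRUE)
      }
      sm <- sample_measures(xs, (idx - 1L) / fs, config)
      for (ky in intersect(keys, names(sm))) {
        vals[paste0(pre, "_", ky)] <- sm[[ky]]
      }
    }
    ctr <- ev[ev$type == "contraction", ]
    vals["ct_count"] <- nrow(ctr)
    dwell <- if (nrow(ctr)) sum(ctr$end - ctr$start) / fs else 0
    vals["ct_dwell_time"] <- dwell
    vals["ct_resting_time"] <- (hi - lo) / fs - dwell
    dplyr::bind_cols(
      tibble::tibble(ttd_epoch = epochs$ttd_epoch[k],
                     fraction_missing = epochs$fraction_missing[k]),
      tibble::as_tibble(as.list(vals)))
  })
  rows
}
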