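# Synthetic raw CTG traces (FHR + uterine pressure) with ground-truth
# event annotations, for exercising the detector and extractor.

#' Trace-generator specification
#'
#' Event rates are expected counts per 20-min epoch; deceleration rates
#' are split by subtype so the generator can emit ground truth. `late`
#' decelerations are tied to a contraction (nadir 30-50 s after the
#' peak, gradual onset), `variable` decelerations are abrupt, `other`
#' decelerations are gradual and kept away from contraction peaks. The
#' gap process drops samples in lognormally sized runs.
#'
#' @param baseline_bpm,baseline_sd FHR baseline level and noise SD (bpm).
#' @param drift_amp,drift_period_s Slow sinusoidal baseline wander.
#' @param rates Named per-epoch event rates (`accel`, `decel_late`,
#'   `decel_variable`, `decel_other`, `contraction`).
#' @param class_decel_mult Per-class multiplier on the deceleration rates
#'   (pathological classes have more decelerations).
#' @param accel_amp,decel_amp `c(lo, hi)` amplitude ranges (bpm).
#' @param up_resting,up_amp Uterine resting tone and contraction
#'   amplitude (mmHg).
#' @param contraction_dur_s Mean contraction duration (s).
#' @param gap_rate_per_h,gap_meanlog,gap_sdlog Gap process: Poisson rate
#'   and lognormal length parameters (log-seconds). A rate of 0 disables
#'   gaps.
#' @return An object of class `trace_spec`.
#' @export
trace_spec <- function(baseline_bpm = 140, baseline_sd = 2.5,
                       drift_amp = 3, drift_period_s = 600,
                       rates = c(accel = 2, decel_late = 0.5,
                                 decel_variable = 0.5, decel_other = 0.5,
                                 contraction = 3),
                       class_decel_mult = c(healthy = 1, acidosis = 1.4,
                                            hie = 1.8),
                       accel_amp = c(18, 26), decel_amp = c(20, 32),
                       up_resting = 12, up_amp = 45,
                       contraction_dur_s = 70,
                       gap_rate_per_h = 6, gap_meanlog = log(8),
                       gap_sdlog = 0.8) {
  if (any(rates < 0)) abort("Event rates must be >= 0.")
  structure(list(baseline_bpm = baseline_bpm, baseline_sd = baseline_sd,
                 drift_amp = drift_amp, drift_period_s = drift_period_s,
                 rates = rates, class_decel_mult = class_decel_mult,
                 accel_amp = accel_amp, decel_amp = decel_amp,
                 up_resting = up_resting, up_amp = up_amp,
                 contraction_dur_s = contraction_dur_s,
                 gap_rate_per_h = gap_rate_per_h, gap_meanlog = gap_meanlog,
                 gap_sdlog = gap_sdlog), class = "trace_spec")
}

# trapezoidal bump over [0, 1] with given ramp fractions
trapezoid <- function(n, ramp_up_frac, ramp_down_frac) {
  u <- seq(0, 1, length.out = n)
  up <- pmin(u / ramp_up_frac, 1)
  down <- pmin((1 - u) / ramp_down_frac, 1)
  pmin(up, down)
}

place_interval <- function(occupied, n, len, margin, lo = 1L, hi = n - len,
                           tries = 200L) {
  if (hi < lo) return(NA_integer_)
  for (i in seq_len(tries)) {
    s <- sample.int(hi - lo + 1L, 1L) + lo - 1L
    span <- max(1L, s - margin):min(n, s + len + margin)
    if (!any(occupied[span])) return(s)
  }
  NA_integer_
}

simulate_one_trace <- function(n, cls, ts) {
  fs <- FS_HZ
  n_ep <- n / EPOCH_SAMPLES
  t_s <- (seq_len(n) - 1L) / fs
  ann <- list()

  # uterine pressure with contractions
  up <- ts$up_resting + rnorm(n, 0, 1.5)
  occ_up <- rep(FALSE, n)
  n_ctr <- rpois(1, ts$rates[["contraction"]] * n_ep)
  ctr_len <- as.integer(round(ts$contraction_dur_s * fs))
  ctr_peaks <- integer(0)
  for (i in seq_len(n_ctr)) {
    s <- place_interval(occ_up, n, ctr_len, margin = 30L * fs)
    if (is.na(s)) abort("Contraction rate too high: cannot place events without overlap.")
    occ_up[s:(s + ctr_len - 1L)] <- TRUE
    peak <- s + ctr_len %/% 2L
    ctr_peaks <- c(ctr_peaks, peak)
    bump <- ts$up_amp * exp(-0.5 * ((seq_len(n) - peak) / (ctr_len / 5))^2)
    up <- up + bump
    ann[[length(ann) + 1L]] <- tibble::tibble(
      start = s - 1L, end = s + ctr_len - 1L, type = "contraction",
      subtype = NA_character_)
  }

  # FHR: baseline + drift + AR(1) noise
  ar <- as.numeric(stats::filter(rnorm(n, 0, ts$baseline_sd * sqrt(1 - 0.9^2)),
                                 0.9, method = "recursive"))
  fhr <- ts$baseline_bpm + ts$drift_amp * sin(2 * pi * t_s / ts$drift_period_s) + ar
  occ <- rep(FALSE, n)
  mult <- ts$class_decel_mult[[cls]]

  add_fhr_event <- function(s, len, amp, type, subtype, ramp_up, ramp_down) {
    shape <- amp * trapezoid(len, ramp_up, ramp_down)
    idx <- s:(s + len - 1L)
    fhr[idx] <<- fhr[idx] + if (type == "acceleration") shape else -shape
    occ[max(1L, s - 40L):min(n, s + len + 40L)] <<- TRUE
    ann[[length(ann) + 1L]] <<- tibble::tibble(
      start = s - 1L, end = s + len - 1L, type = type, subtype = subtype)
  }

  # late decelerations ride on contractions
  n_late <- min(rpois(1, ts$rates[["decel_late"]] * mult * n_ep),
                length(ctr_peaks))
  if (n_late > 0) {
    for (peak in sample(ctr_peaks, n_late)) {
      len <- as.integer(round(runif(1, 60, 100) * fs))
      lag <- as.integer(round(runif(1, 30, 50) * fs))
      s <- peak + lag - len %/% 2L # nadir (centre) lags the peak
      if (s < 1L || s + len > n || any(occ[s:(s + len - 1L)])) next
      add_fhr_event(s, len, runif(1, ts$decel_amp[1], ts$decel_amp[2]),
                    "deceleration", "late", 0.45, 0.45)
    }
  }
  # variable decelerations: abrupt onset, anywhere
  for (i in seq_len(rpois(1, ts$rates[["decel_variable"]] * mult * n_ep))) {
    len <- as.integer(round(runif(1, 30, 60) * fs))
    s <- place_interval(occ, n, len, margin = 40L)
    if (is.na(s)) abort("Deceleration rate too high: cannot place events without overlap.")
    amp <- runif(1, ts$decel_amp[1] + 8, ts$decel_amp[2] + 8)
    add_fhr_event(s, len, amp, "deceleration", "variable",
                  ramp_up = (8 * fs) / len, ramp_down = (15 * fs) / len)
  }
  # other decelerations: gradual, away from contraction peaks
  for (i in seq_len(rpois(1, ts$rates[["decel_other"]] * mult * n_ep))) {
    len <- as.integer(round(runif(1, 60, 100) * fs))
    placed <- FALSE
    for (try in 1:100) {
      s <- place_interval(occ, n, len, margin = 40L, tries = 20L)
      if (is.na(s)) break
      nadir <- s + len %/% 2L
      lags <- (nadir - ctr_peaks) / fs
      if (!any(lags > 0 & lags <= 160)) { # keep clear of "late" territory
        add_fhr_event(s, len, runif(1, ts$decel_amp[1], ts$decel_amp[2]),
                      "deceleration", "other", 0.45, 0.45)
        placed <- TRUE
        break
      }
      occ_try <- TRUE # reject and retry elsewhere
    }
    if (!placed) next
  }
  # accelerations
  for (i in seq_len(rpois(1, ts$rates[["accel"]] * n_ep))) {
    len <- as.integer(round(runif(1, 30, 60) * fs))
    s <- place_interval(occ, n, len, margin = 40L)
    if (is.na(s)) abort("Acceleration rate too high: cannot place events without overlap.")
    add_fhr_event(s, len, runif(1, ts$accel_amp[1], ts$accel_amp[2]),
                  "acceleration", NA_character_, 0.25, 0.25)
  }

  # gap process
  miss <- rep(FALSE, n)
  if (ts$gap_rate_per_h > 0) {
    n_gaps <- rpois(1, ts$gap_rate_per_h * n / (3600 * fs))
    for (i in seq_len(n_gaps)) {
      len <- max(2L, as.integer(round(rlnorm(1, ts$gap_meanlog, ts$gap_sdlog) * fs)))
      s <- sample.int(max(1L, n - len), 1L)
      miss[s:(s + len - 1L)] <- TRUE
    }
  }

  ann <- if (length(ann)) dplyr::arrange(dplyr::bind_rows(ann), .data$start)
         else tibble::tibble(start = 0L, end = n, type = "baseline",
                             subtype = NA_character_)
  list(trace = signal_trace(ifelse(miss, NA_real_, fhr), up = up,
                            missing = miss),
       annotations = ann)
}

#' Generate a synthetic signal cohort
#'
#' For each infant in the cohort spec, simulates an FHR/uterine-pressure
#' trace at 4 Hz covering `min(labor length, 12 h)` (whole epochs), with
#' inserted accelerations, subtype-labelled decelerations, contractions
#' and missing-sample gaps, plus the ground-truth annotation of every
#' inserted event. Seeding is hierarchical exactly as in
#' [generate_feature_table()].
#'
#' @param spec A [cohort_spec()] (class sizes, labor lengths, seed).
#' @param trace A [trace_spec()].
#' @param max_epochs Cap on epochs per infant (keeps test cohorts small).
#' @return List with `traces` (named list of [signal_trace()] tibbles),
#'   `annotations` (tibble with `infant_id`, 0-based half-open sample
#'   `start`/`end`, `type`, `subtype`) and `meta` (infant, hospital,
#'   class).
#' @export
generate_signal_cohort <- function(spec, trace = trace_spec(),
                                   max_epochs = N_EPOCHS_MAX) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(trace, "trace_spec"))
  class_prefix <- c(healthy = "h", acidosis = "a", hie = "e")
  traces <- list(); anns <- list(); meta <- list()
  for (k in seq_along(spec$counts)) {
    cls <- names(spec$counts)[k]
    n_c <- spec$counts[[k]]
    lp <- labor_lognorm_params(spec$labor_length, cls)
    infant_seeds <- withr::with_seed(derive_seed(spec$seed, 100L + k),
                                     sample.int(2147483646L, n_c))
    for (i in seq_len(n_c)) {
      id <- sprintf("%s%05d", class_prefix[[cls]], i)
      res <- withr::with_seed(infant_seeds[i], {
        hospital <- sample.int(spec$n_hospitals, 1L)
        labor_h <- if (lp$sdlog == 0) exp(lp$meanlog) else
          rlnorm(1L, lp$meanlog, lp$sdlog)
        n_ep <- max(1L, min(max_epochs, floor(labor_h * 3)))
        out <- simulate_one_trace(n_ep * EPOCH_SAMPLES, cls, trace)
        out$hospital <- hospital
        out
      })
      traces[[id]] <- res$trace
      anns[[id]] <- dplyr::mutate(res$annotations, infant_id = id,
                                  .before = 1)
      meta[[id]] <- tibble::tibble(
        infant_id = id, hospital_id = sprintf("hosp%02d", res$hospital),
        class = cls)
    }
  }
  list(traces = traces, annotations = dplyr::bind_rows(anns),
       meta = dplyr::bind_rows(meta))
}

#' Write event annotations as JSON records
#'
#' @param annotations Annotation tibble (sample coordinates at 4 Hz).
#' @param path Output file.
#' @param fs Sampling rate used to convert samples to seconds.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path, fs = FS_HZ) {
  recs <- dplyr::mutate(annotations, start_s = .data$start / fs,
                        end_s = .data$end / fs)
  recs <- recs[, intersect(c("infant_id", "start_s", "end_s", "type",
                             "subtype"), names(recs))]
  jsonlite::write_json(recs, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' Extract a feature table from a signal cohort
#'
#' Runs the preprocessing chain (gap fill, epoch segmentation) and feature
#' extraction for every infant, using either the detector or the
#' ground-truth annotations, and assembles the long-format feature table.
#'
#' @param cohort Output of [generate_signal_cohort()].
#' @param use_annotations Use the ground-truth events instead of
#'   [detect_events()].
#' @param config A [feature_config()].
#' @return A feature table (infant, hospital, class, ttd_epoch, features).
#' @export
extract_cohort_features <- function(cohort, use_annotations = FALSE,
                                    config = feature_config()) {
  purrr::map_dfr(names(cohort$traces), function(id) {
    tr <- fill_gaps(cohort$traces[[id]])
    ep <- segment_epochs(tr)
    ev <- if (use_annotations) {
      ann_to_events(cohort$annotations[cohort$annotations$infant_id == id, ],
                    tr)
    } else NULL
    ft <- extract_features(tr, epochs = ep, events = ev, config = config)
    if (!nrow(ft)) return(NULL)
    m <- cohort$meta[cohort$meta$infant_id == id, ]
    dplyr::bind_cols(
      tibble::tibble(infant_id = id, hospital_id = m$hospital_id,
                     class = m$class),
      ft)
  })
}

# ground-truth annotations -> detector-style event tibble (adds the
# baseline complement over valid samples)
ann_to_events <- function(ann, trace) {
  ev <- ann[ann$type != "baseline",
            c("start", "end", "type", "subtype"), drop = FALSE]
  n <- nrow(trace)
  in_ev <- rep(FALSE, n)
  fhr_ev <- ev[ev$type %in% c("acceleration", "deceleration"), ]
  for (i in seq_len(nrow(fhr_ev))) {
    in_ev[(fhr_ev$start[i] + 1L):fhr_ev$end[i]] <- TRUE
  }
  base <- runs_where(!trace$missing & !in_ev, 0L)
  dplyr::arrange(
    dplyr::bind_rows(
      dplyr::mutate(base, type = "baseline", subtype = NA_character_), ev),
    .data$start)
}
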