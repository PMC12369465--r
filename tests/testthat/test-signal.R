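# helpers to build small deterministic traces
flat_trace <- function(n, level = 140, up = NULL) {
  signal_trace(rep(level, n), up = up)
}

# trapezoidal excursion written into a numeric vector (1-based samples)
add_bump <- function(x, start, dur, amp, ramp = 8) {
  idx <- start:(start + dur - 1)
  u <- seq_along(idx)
  shape <- pmin(u / ramp, pmin(1, (length(idx) - u + 1) / ramp))
  x[idx] <- x[idx] + amp * shape
  x
}

test_that("short gaps are linearly interpolated, long and edge gaps kept", {
  x <- rep(120, 300)
  x[101:159] <- NA  # 59-sample gap between 120 and 126
  x[100] <- 120; x[160] <- 126
  tr <- fill_gaps(signal_trace(x))
  expect_false(any(tr$missing[101:159]))
  expect_equal(tr$fhr_bpm[101:159], 120 + 6 * (1:59) / 60)
  # 60-sample gap: untouched (strictly "shorter than")
  y <- rep(120, 300); y[101:160] <- NA
  tr2 <- fill_gaps(signal_trace(y))
  expect_true(all(tr2$missing[101:160]))
  # gap touching the boundary: no extrapolation
  z <- rep(120, 300); z[1:10] <- NA
  tr3 <- fill_gaps(signal_trace(z))
  expect_true(all(tr3$missing[1:10]))
  # no gaps: identity
  w <- signal_trace(rep(130, 100))
  expect_identical(fill_gaps(w)$fhr_bpm, w$fhr_bpm)
})

test_that("epoch acceptance applies the strict 20% missing rule", {
  x <- rep(140, EPOCH_SAMPLES)
  x[seq_len(961)] <- NA
  expect_false(segment_epochs(signal_trace(x))$accepted)
  x <- rep(140, EPOCH_SAMPLES)
  x[seq_len(960)] <- NA # exactly 20%
  expect_true(segment_epochs(signal_trace(x))$accepted)
})

test_that("a fully valid 12-h trace gives 36 accepted epochs and no more", {
  tr <- flat_trace(EPOCH_SAMPLES * 40) # 40 tiled epochs available
  ep <- segment_epochs(tr)
  expect_identical(nrow(ep), 36L)
  expect_true(all(ep$accepted))
  expect_identical(ep$ttd_epoch, 1:36)
  expect_identical(nrow(segment_epochs(flat_trace(100))), 0L)
})

test_that("the detector applies the 15 bpm / 15 s excursion rules", {
  n <- EPOCH_SAMPLES
  x <- rep(140, n)
  x <- add_bump(x, 2000, 120, 20) # +20 bpm for 30 s
  ev <- detect_events(signal_trace(x))
  expect_identical(sum(ev$type == "acceleration"), 1L)
  expect_identical(sum(ev$type == "deceleration"), 0L)
  # +10 bpm: below threshold
  ev2 <- detect_events(signal_trace(add_bump(rep(140, n), 2000, 120, 10)))
  expect_identical(sum(ev2$type == "acceleration"), 0L)
  # mirrored rule for decelerations
  ev3 <- detect_events(signal_trace(add_bump(rep(140, n), 2000, 120, -20)))
  expect_identical(sum(ev3$type == "deceleration"), 1L)
  expect_identical(nrow(detect_events(signal_trace(rep(NA_real_, n)))), 0L)
})

test_that("deceleration subtypes follow the timing and abruptness rules", {
  n <- EPOCH_SAMPLES * 4
  fs <- 4
  up <- rep(12, n)
  peak <- 3000
  up <- up + 45 * exp(-0.5 * ((seq_len(n) - peak) / 56)^2)
  x <- rep(140, n)
  # gradual decel, nadir 40 s after the contraction peak -> late
  dur1 <- 80 * fs
  s1 <- peak + 40 * fs - dur1 %/% 2
  x <- add_bump(x, s1, dur1, -30, ramp = 0.45 * dur1)
  # abrupt dip far from the contraction -> variable
  s2 <- 11000; dur2 <- 40 * fs
  x <- add_bump(x, s2, dur2, -30, ramp = 6 * fs)
  # gradual decel with no contraction nearby -> other
  s3 <- 16000; dur3 <- 80 * fs
  x <- add_bump(x, s3, dur3, -30, ramp = 0.45 * dur3)
  tr <- signal_trace(x, up = up)
  ev <- classify_decelerations(detect_events(tr), tr)
  dec <- ev[ev$type == "deceleration", ]
  dec <- dec[order(dec$start), ]
  expect_identical(nrow(dec), 3L)
  expect_identical(dec$subtype, c("late", "variable", "other"))
  # without contractions, late is impossible
  tr_nc <- signal_trace(x)
  ev_nc <- classify_decelerations(detect_events(tr_nc), tr_nc)
  expect_setequal(ev_nc$subtype[ev_nc$type == "deceleration"],
                  c("variable", "other"))
})

test_that("detected subtypes agree with generator ground truth", {
  spec <- cohort_spec(
    n_healthy = 3, n_acidosis = 2, n_hie = 2,
    labor_length = labor_length_spec(
      median_h = c(healthy = 3, acidosis = 3, hie = 3),
      iqr_h = c(healthy = 0, acidosis = 0, hie = 0)),
    archetypes = default_archetypes(1), seed = 11)
  co <- generate_signal_cohort(spec)
  matched <- 0L; agree <- 0L; truth_n <- 0L
  for (id in names(co$traces)) {
    tr <- fill_gaps(co$traces[[id]])
    ev <- classify_decelerations(detect_events(tr), tr)
    det <- ev[ev$type == "deceleration", ]
    ann <- co$annotations[co$annotations$infant_id == id &
                            co$annotations$type == "deceleration", ]
    truth_n <- truth_n + nrow(ann)
    for (i in seq_len(nrow(ann))) {
      if (!nrow(det)) next
      ov <- pmin(det$end, ann$end[i]) - pmax(det$start, ann$start[i])
      j <- which.max(ov)
      if (ov[j] > 0) {
        matched <- matched + 1L
        if (det$subtype[j] == ann$subtype[i]) agree <- agree + 1L
      }
    }
  }
  expect_gt(matched / truth_n, 0.85)  # most true events are recovered
  expect_gte(agree / matched, 0.90)   # and their subtype agrees
})

test_that("a constant baseline-only epoch yields the trivial feature values", {
  ft <- extract_features(flat_trace(EPOCH_SAMPLES))
  expect_identical(nrow(ft), 1L)
  expect_equal(ft$bl_level, 140)
  expect_equal(ft$bl_slope, 0, tolerance = 1e-10)
  expect_equal(ft$bl_delta, 0)
  expect_equal(ft$bl_stv, 0)
  expect_equal(ft$ac_count, 0)
  expect_equal(ft$dc_count, 0)
  expect_equal(ft$ct_count, 0)
  expect_equal(ft$bl_dwell_time, 1200)
  expect_equal(ft$ct_resting_time, 1200)
  # no acceleration samples: sample-based acceleration features are missing
  expect_true(is.na(ft$ac_level))
  expect_true(is.na(ft$dc_apen_r020))
})

test_that("two inserted accelerations are counted and transitioned to", {
  x <- rep(140, EPOCH_SAMPLES)
  x <- add_bump(x, 500, 120, 20)
  x <- add_bump(x, 3000, 120, 20)
  ft <- extract_features(signal_trace(x))
  expect_equal(ft$ac_count, 2)
  expect_equal(ft$bl_trans_accel, 2)
  expect_equal(ft$ac_trans_baseline, 2)
  expect_true(ft$bl_dwell_time + ft$ac_dwell_time + ft$dc_dwell_time <= 1200)
})

test_that("peak-to-peak variability is 3.92 standard deviations", {
  expect_equal(round(ptp_from_sd(1), 2), 3.92)
  expect_equal(ptp_from_sd(2.5), 2 * qnorm(0.975) * 2.5)
})

test_that("approximate and sample entropy match the double-loop oracle", {
  x <- rep(c(1, 2), 50)
  r <- 0.3 * sd(x)
  expect_equal(approximate_entropy(x, m = 2, r_frac = 0.3),
               brute_apen(x, 2, r), tolerance = 1e-10)
  set.seed(8)
  y <- rnorm(60)
  expect_equal(approximate_entropy(y, m = 2, r_frac = 0.2),
               brute_apen(y, 2, 0.2 * sd(y)), tolerance = 1e-10)
  expect_equal(sample_entropy(y, m = 2, r_frac = 0.2),
               brute_sampen(y, 2, 0.2 * sd(y)), tolerance = 1e-10)
  expect_equal(approximate_entropy(rep(7, 100)), 0)
})

test_that("noise is more entropic than a sine of equal SD", {
  set.seed(5)
  noise <- rnorm(500)
  sine <- sin(2 * pi * (1:500) / 50)
  sine <- sine * sd(noise) / sd(sine)
  expect_gt(approximate_entropy(noise, r_frac = 0.2),
            approximate_entropy(sine, r_frac = 0.2))
})

test_that("band powers localise pure tones and spread white noise", {
  t <- seq(0, 600, by = 0.25)
  lf_tone <- band_powers(sin(2 * pi * 0.1 * t))
  expect_gt(lf_tone$lf / (lf_tone$lf + lf_tone$mf + lf_tone$hf), 0.95)
  hf_tone <- band_powers(sin(2 * pi * 0.7 * t))
  expect_gt(hf_tone$hf, hf_tone$lf + hf_tone$mf)
  set.seed(12)
  agg <- c(lf = 0, mf = 0, hf = 0)
  for (i in 1:20) {
    bp <- band_powers(rnorm(2400))
    agg <- agg + c(bp$lf, bp$mf, bp$hf)
  }
  widths <- c(lf = 0.12, mf = 0.35, hf = 0.5)
  ratio <- (agg / sum(agg)) / (widths / sum(widths))
  expect_true(all(abs(ratio - 1) < 0.15))
  expect_true(is.na(band_powers(rnorm(100))$lf)) # shorter than 2 LF cycles
})

test_that("PRSA capacities behave at the degenerate anchors", {
  expect_true(is.na(prsa_capacity(1:100, sign = -1))) # no decel anchors
  expect_true(is.na(prsa_capacity(rep(3, 100))))      # constant: no anchors
  alt <- rep(c(0, 1), 50)
  expect_equal(prsa_capacity(alt, 1), -prsa_capacity(alt, -1))
  expect_equal(deceleration_reserve(alt), 0)
})

test_that("extractors are location-equivariant where required", {
  set.seed(14)
  x <- 140 + cumsum(rnorm(600, 0, 0.3))
  xc <- x + 25
  expect_equal(approximate_entropy(xc, r_frac = 0.2),
               approximate_entropy(x, r_frac = 0.2), tolerance = 1e-10)
  bp <- band_powers(x); bpc <- band_powers(xc)
  expect_equal(bpc$lf, bp$lf, tolerance = 1e-8)
  expect_equal(mean(xc) - mean(x), 25)
  hv <- hrv_classical(x); hvc <- hrv_classical(xc)
  expect_equal(hvc$stv, hv$stv, tolerance = 1e-10)
  expect_equal(hvc$lti, hv$lti, tolerance = 1e-10)
})

test_that("ground-truth and detected events give concordant features", {
  # gap process off: events hidden inside long gaps are invisible to any
  # detector, which would confound the adequacy question being asked here;
  # drift makes the level genuinely vary between epochs
  spec <- cohort_spec(
    n_healthy = 2, n_acidosis = 1, n_hie = 1,
    labor_length = labor_length_spec(
      median_h = c(healthy = 3, acidosis = 3, hie = 3),
      iqr_h = c(healthy = 0, acidosis = 0, hie = 0)),
    archetypes = default_archetypes(1), seed = 19)
  co <- generate_signal_cohort(spec, trace_spec(gap_rate_per_h = 0,
                                                drift_amp = 6,
                                                drift_period_s = 2400))
  det <- extract_cohort_features(co, use_annotations = FALSE)
  tru <- extract_cohort_features(co, use_annotations = TRUE)
  key <- c("infant_id", "ttd_epoch")
  merged <- dplyr::inner_join(det, tru, by = key, suffix = c("_d", "_t"))
  concord <- function(f) {
    suppressWarnings(cor(merged[[paste0(f, "_d")]],
                         merged[[paste0(f, "_t")]], use = "complete.obs"))
  }
  for (f in c("bl_level", "ac_count", "dc_count", "ct_count",
              "ac_dwell_time", "dc_height")) {
    expect_gt(concord(f), 0.9)
  }
  for (f in c("dc_dwell_time", "dc_area")) {
    expect_gt(concord(f), 0.8)
  }
})
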