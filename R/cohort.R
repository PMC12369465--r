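# Synthetic cohort specification: outcome classes, hospitals, labor
# lengths, epoch availability, and feature archetypes.

#' Feature archetype
#'
#' Describes how one synthetic feature column depends on outcome class and
#' time to delivery. Writing `d(t)` for the (availability-centred) time
#' profile and `s(C)` for the mirror direction (+1 healthy, -1
#' pathological), a value is `base_level + shift(C) + s(C) * d(t) + noise`:
#'
#' * `type_I` — constant pathological shift, no time interaction: the
#'   class difference does not depend on TTD.
#' * `type_II` — mirrored trajectories `base +/- d(t)` with equal
#'   variances; the pooled (over-time) class marginals coincide by mirror
#'   symmetry, so only a time-varying analysis sees the class difference.
#' * `type_III` — pathological shift plus mirrored time interaction: both
#'   the pooled and the per-epoch class differences are real.
#' * `null` — a common time trend shared by every class (time varying but
#'   carrying no outcome information).
#' * `inert` — pure noise, no class and no time dependence.
#'
#' @param name Unique feature name.
#' @param kind One of `"type_I"`, `"type_II"`, `"type_III"`, `"null"`,
#'   `"inert"`.
#' @param base_level Mean level `mu0`.
#' @param class_shift Additive shift of the pathological classes (used by
#'   `type_I` and `type_III`).
#' @param time_amp Amplitude of the linear time profile: `d_raw(t)` spans
#'   `[-time_amp, time_amp]` across the epoch grid before centring.
#' @param noise_sd Gaussian noise standard deviation (continuous features).
#' @param discrete If `TRUE` values are Poisson counts with the linear
#'   predictor (floored at 0.05) as rate.
#' @return An object of class `feature_archetype`.
#' @export
archetype <- function(name, kind = c("type_I", "type_II", "type_III",
                                     "null", "inert"),
                      base_level = 0, class_shift = 0.4, time_amp = 0.5,
                      noise_sd = 1, discrete = FALSE) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), nzchar(name), noise_sd >= 0)
  structure(list(name = name, kind = kind, base_level = base_level,
                 class_shift = class_shift, time_amp = time_amp,
                 noise_sd = noise_sd, discrete = discrete),
            class = "feature_archetype")
}

#' Default archetype set
#'
#' `per_kind` replicates of each requested kind, named `<kind>_<i>`, plus
#' (optionally) one discrete Poisson `type_I` count feature mimicking a
#' late-deceleration count.
#'
#' @param per_kind Number of features per kind.
#' @param kinds Kinds to include.
#' @param include_discrete Append the discrete count archetype.
#' @return List of [archetype()] objects.
#' @export
default_archetypes <- function(per_kind = 2L,
                               kinds = c("type_I", "type_II", "type_III",
                                         "null", "inert"),
                               include_discrete = TRUE) {
  arcs <- purrr::flatten(purrr::map(kinds, function(k) {
    purrr::map(seq_len(per_kind), function(i) {
      archetype(sprintf("%s_%02d", k, i), kind = k)
    })
  }))
  if (include_discrete) {
    arcs <- c(arcs, list(archetype("n_late_decels", "type_I",
                                   base_level = 1.2, class_shift = 0.9,
                                   discrete = TRUE)))
  }
  arcs
}

#' Epoch availability model
#'
#' Availability of an epoch at TTD `t` for class `c` is
#' `level[c] * (floor + (1 - floor) * plogis((midpoint - t)/steepness))`,
#' a logistic rise toward delivery, multiplied by a last-hour drop factor
#' for the final three epochs (`t` = 3, 2, 1). `constant` overrides the
#' whole curve with a fixed probability for every class and epoch.
#'
#' @param level Named per-class plateau, HIE highest by default.
#' @param midpoint,steepness Logistic location/scale on the TTD axis.
#' @param floor_frac Fraction of the plateau available at the earliest
#'   epochs.
#' @param last_hour Multipliers for `t` = 3, 2, 1.
#' @param constant Optional fixed availability probability.
#' @return An object of class `availability_spec`.
#' @export
availability_spec <- function(level = c(healthy = 0.72, acidosis = 0.78,
                                        hie = 0.90),
                              midpoint = 18, steepness = 5,
                              floor_frac = 0.30,
                              last_hour = c(0.85, 0.62, 0.38),
                              constant = NULL) {
  stopifnot(length(last_hour) == 3L)
  structure(list(level = level, midpoint = midpoint, steepness = steepness,
                 floor_frac = floor_frac, last_hour = last_hour,
                 constant = constant), class = "availability_spec")
}

avail_prob <- function(av, cls, t) {
  if (!is.null(av$constant)) return(rep(av$constant, length(t)))
  lev <- unname(av$level[cls])
  p <- lev * (av$floor_frac +
                (1 - av$floor_frac) * stats::plogis((av$midpoint - t) / av$steepness))
  drop <- rev(av$last_hour) # index 1 -> t = 1
  idx <- t <= 3
  p[idx] <- p[idx] * drop[t[idx]]
  pmin(p, 1)
}

#' Labor length model
#'
#' Per-class lognormal labor lengths (hours) parameterised by median and
#' interquartile range; the defaults reproduce the strong ordering healthy
#' < acidosis < HIE. An IQR of 0 makes the draw deterministic.
#'
#' @param median_h,iqr_h Named per-class medians and IQRs in hours.
#' @return An object of class `labor_length_spec`.
#' @export
labor_length_spec <- function(median_h = c(healthy = 11.25, acidosis = 13.33,
                                           hie = 19.2),
                              iqr_h = c(healthy = 18.02 - 6.15,
                                        acidosis = 21.0 - 7.87,
                                        hie = 27.52 - 11.0)) {
  structure(list(median_h = median_h, iqr_h = iqr_h),
            class = "labor_length_spec")
}

# lognormal sdlog from a median/IQR pair: quartiles are
# median * exp(+-qnorm(.75) * sdlog), so IQR = 2 * median * sinh(qnorm(.75) * sdlog)
labor_lognorm_params <- function(ll, cls) {
  m <- unname(ll$median_h[cls])
  iqr <- unname(ll$iqr_h[cls])
  if (iqr <= 0) return(list(meanlog = log(m), sdlog = 0))
  sdlog <- asinh(iqr / (2 * m)) / qnorm(0.75)
  list(meanlog = log(m), sdlog = sdlog)
}

#' Synthetic cohort specification
#'
#' Bundles everything the generator needs: class sizes (strongly
#' imbalanced by default), hospitals, the TTD epoch grid, labor-length and
#' availability models, the feature archetypes, and the root seed.
#' Identical specs (including the seed) produce bit-identical cohorts, and
#' per-infant random streams are derived hierarchically so changing one
#' class's size never perturbs another class's draws.
#'
#' @param n_healthy,n_acidosis,n_hie Infants per outcome class.
#' @param n_hospitals Number of hospitals (default 15).
#' @param epoch_grid Ordered TTD indices, strictly decreasing; default
#'   `36:1` (20-min epochs over the last 12 h).
#' @param labor_length A [labor_length_spec()].
#' @param availability An [availability_spec()].
#' @param archetypes List of [archetype()] objects with unique names.
#' @param seed Integer root seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_healthy = 300L, n_acidosis = 100L, n_hie = 50L,
                        n_hospitals = 15L, epoch_grid = 36:1,
                        labor_length = labor_length_spec(),
                        availability = availability_spec(),
                        archetypes = default_archetypes(),
                        seed = 1L) {
  counts <- c(healthy = n_healthy, acidosis = n_acidosis, hie = n_hie)
  if (any(counts < 1L)) abort("Class counts must be >= 1.")
  if (n_hospitals < 1L) abort("`n_hospitals` must be >= 1.")
  if (length(epoch_grid) < 1L || any(diff(epoch_grid) >= 0)) {
    abort("`epoch_grid` must be strictly decreasing TTD indices.")
  }
  nm <- vapply(archetypes, `[[`, character(1), "name")
  if (anyDuplicated(nm)) abort("Archetype names collide.")
  structure(list(counts = counts, n_hospitals = as.integer(n_hospitals),
                 epoch_grid = as.integer(epoch_grid),
                 labor_length = labor_length, availability = availability,
                 archetypes = setNames(archetypes, nm),
                 seed = as.integer(seed)), class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec> ", paste(names(x$counts), x$counts, sep = " = ",
                              collapse = ", "),
      "; ", x$n_hospitals, " hospitals; ", length(x$epoch_grid),
      " epochs; ", length(x$archetypes), " archetypes; seed ", x$seed,
      "\n", sep = "")
  invisible(x)
}

# deterministic sub-seed derivation (stays inside 32-bit range)
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) %% 2147483647 * 48271 + k * 1664525 + 12345) %%
               2147483647)
}

# expected weight of each grid epoch: availability x probability that
# labor reaches that far back, averaged over classes with equal class
# weights — deliberately independent of the class sizes, so that resizing
# one class never changes the centred profiles (and hence the values)
# another class receives
expected_epoch_weights <- function(spec) {
  grid <- spec$epoch_grid
  w <- numeric(length(grid))
  for (cls in names(spec$counts)) {
    lp <- labor_lognorm_params(spec$labor_length, cls)
    surv <- if (lp$sdlog == 0) as.numeric(exp(lp$meanlog) * 3 >= grid)
            else 1 - stats::plnorm(grid / 3, lp$meanlog, lp$sdlog)
    w <- w + avail_prob(spec$availability, cls, grid) * surv
  }
  w / sum(w)
}

#' Centred time profiles of the archetypes
#'
#' The raw linear profile spans `[-time_amp, time_amp]` across the epoch
#' grid and is centred so that its expected availability-weighted mean is
#' zero — this is what makes the mirrored `type_II` construction leave the
#' pooled class marginals aligned.
#'
#' @param spec A [cohort_spec()].
#' @return Tibble with `archetype`, `ttd_epoch`, `delta`.
#' @export
archetype_profiles <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  grid <- spec$epoch_grid
  mid <- mean(range(grid)); half <- diff(range(grid)) / 2
  raw_unit <- if (half > 0) (grid - mid) / half else rep(0, length(grid))
  w <- expected_epoch_weights(spec)
  centred_unit <- raw_unit - sum(w * raw_unit)
  purrr::map_dfr(spec$archetypes, function(a) {
    tibble::tibble(archetype = a$name, ttd_epoch = grid,
                   delta = a$time_amp * centred_unit)
  })
}

#' Theoretical availability curves
#'
#' @param spec A [cohort_spec()].
#' @return Tibble with `class`, `ttd_epoch` and the availability
#'   probability `prob` (before labor-length truncation).
#' @export
cohort_availability <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  purrr::map_dfr(names(spec$counts), function(cls) {
    tibble::tibble(class = cls, ttd_epoch = spec$epoch_grid,
                   prob = avail_prob(spec$availability, cls, spec$epoch_grid))
  })
}
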