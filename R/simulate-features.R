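# Seeded generation of the long-format per-epoch feature table.

#' Generate a synthetic per-epoch feature table
#'
#' Produces one row per available (infant, epoch) pair. Each infant draws
#' a hospital, a labor length (which truncates how far back its epochs can
#' reach, up to the 12-h analysis horizon), and a Bernoulli availability
#' mask over the epoch grid; every archetype then contributes a feature
#' column following its class/time structure (see [archetype()]).
#'
#' Randomness is hierarchical: the root seed spawns one sub-stream per
#' outcome class and one per infant, so identical specs give bit-identical
#' tables and resizing one class never perturbs another class's draws.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with columns `infant_id`, `hospital_id`, `class`,
#'   `ttd_epoch` and one numeric column per archetype, carrying the spec
#'   and the centred time profiles as attributes `cohort_spec` and
#'   `profiles`.
#' @export
#' @examples
#' tbl <- generate_feature_table(cohort_spec(
#'   n_healthy = 20, n_acidosis = 8, n_hie = 4,
#'   archetypes = default_archetypes(1), seed = 7))
#' dplyr::count(tbl, class)
generate_feature_table <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  grid <- spec$epoch_grid
  n_ep <- length(grid)
  arcs <- spec$archetypes
  prof <- archetype_profiles(spec)
  delta <- tidyr::pivot_wider(prof, names_from = "archetype",
                              values_from = "delta")
  delta <- as.matrix(delta[match(grid, delta$ttd_epoch),
                           names(arcs), drop = FALSE]) # n_ep x n_arch

  class_prefix <- c(healthy = "h", acidosis = "a", hie = "e")
  out <- vector("list", length(spec$counts))

  for (k in seq_along(spec$counts)) {
    cls <- names(spec$counts)[k]
    n_c <- spec$counts[[k]]
    lp <- labor_lognorm_params(spec$labor_length, cls)
    a_prob <- avail_prob(spec$availability, cls, grid)
    dir_c <- if (cls == "healthy") 1 else -1
    infant_seeds <- withr::with_seed(
      derive_seed(spec$seed, k),
      sample.int(2147483646L, n_c))
    rows <- vector("list", n_c)
    for (i in seq_len(n_c)) {
      rows[[i]] <- withr::with_seed(infant_seeds[i], {
        hospital <- sample.int(spec$n_hospitals, 1L)
        labor_h <- if (lp$sdlog == 0) exp(lp$meanlog) else
          rlnorm(1L, lp$meanlog, lp$sdlog)
        labor_epochs <- max(1, floor(labor_h * 3))
        u <- runif(n_ep)
        keep <- which(grid <= labor_epochs & u <= a_prob)
        if (!length(keep)) keep <- which(grid == min(grid))[1] # >=1 epoch
        n_av <- length(keep)
        vals <- matrix(NA_real_, n_av, length(arcs))
        for (j in seq_along(arcs)) {
          a <- arcs[[j]]
          shift <- switch(a$kind,
                          type_I = , type_III = if (dir_c < 0) a$class_shift else 0,
                          0)
          dirj <- switch(a$kind,
                         type_II = , type_III = dir_c,
                         null = 1,
                         0)
          mu <- a$base_level + shift + dirj * delta[keep, j]
          vals[, j] <- if (a$discrete) rpois(n_av, pmax(mu, 0.05))
                       else mu + rnorm(n_av, 0, a$noise_sd)
        }
        colnames(vals) <- names(arcs)
        dplyr::bind_cols(
          tibble::tibble(
            infant_id = sprintf("%s%05d", class_prefix[[cls]], i),
            hospital_id = sprintf("hosp%02d", hospital),
            class = cls, ttd_epoch = grid[keep]),
          tibble::as_tibble(vals))
      })
    }
    out[[k]] <- dplyr::bind_rows(rows)
  }
  tbl <- dplyr::bind_rows(out)
  attr(tbl, "cohort_spec") <- spec
  attr(tbl, "profiles") <- prof
  tbl
}

#' Realised epoch availability of a feature table
#'
#' Proportion of infants in each class contributing an epoch at each TTD
#' index (the availability summary used for reporting).
#'
#' @param tbl A feature table.
#' @return Tibble with `class`, `ttd_epoch`, `n`, `prop`.
#' @export
summarize_availability <- function(tbl) {
  validate_feature_table(tbl)
  totals <- dplyr::summarise(
    dplyr::group_by(dplyr::distinct(tbl, .data$infant_id, .data$class),
                    .data$class),
    n_infants = dplyr::n(), .groups = "drop")
  dplyr::mutate(
    dplyr::left_join(
      dplyr::summarise(dplyr::group_by(tbl, .data$class, .data$ttd_epoch),
                       n = dplyr::n(), .groups = "drop"),
      totals, by = "class"),
    prop = .data$n / .data$n_infants)
}

#' Write / read a feature table as CSV
#'
#' The CSV holds the id columns then the feature columns; attributes are
#' not round-tripped.
#'
#' @param tbl A feature table.
#' @param path File path.
#' @return `path` invisibly; `read_feature_table()` returns the tibble.
#' @export
write_feature_table <- function(tbl, path) {
  validate_feature_table(tbl)
  readr::write_csv(tbl, path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_feature_table(tbl)
  tbl
}
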