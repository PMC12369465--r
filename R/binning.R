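#' Rice rule bin count
#'
#' The Rice discretisation rule sets the number of histogram bins from the
#' number of available samples: \eqn{N_{bins} = \lceil 2 N_{samp}^{1/3}
#' \rceil}. The number of samples used package-wide is the epoch count of
#' the smallest outcome group, so that one bin count is shared by every
#' continuous feature.
#'
#' @param n_samp Number of samples (>= 1).
#' @return List with `raw` (the un-rounded value \eqn{2 n^{1/3}}) and
#'   `n_bins` (its ceiling).
#' @export
#' @examples
#' rice_bins(4040)   # raw ~31.85, n_bins 32
#' rice_bins(1000)   # raw 20, n_bins 20
rice_bins <- function(n_samp) {
  if (length(n_samp) != 1L || !is.finite(n_samp) || n_samp < 1) {
    abort("`n_samp` must be a single count >= 1.")
  }
  raw <- 2 * n_samp^(1 / 3)
  list(raw = raw, n_bins = as.integer(ceiling(raw - 1e-9)))
}

#' Fit a quantisation scheme for one feature
#'
#' Continuous features are quantised over the range between their 1st and
#' 99th percentiles with uniform width `w = (P99 - P1) / n_bins`; values
#' outside that range are clipped into the first/last bin rather than
#' discarded. Discrete features keep their native levels untouched.
#'
#' @param values Numeric vector of observed feature values (NAs dropped).
#' @param n_bins Number of bins for continuous features.
#' @param discrete If `TRUE`, the feature bypasses binning and its sorted
#'   unique values become the levels.
#' @param name Optional feature name (used in error messages / JSON).
#' @return An object of class `binning_scheme`.
#' @export
#' @examples
#' fit_binning(c(1, 50, 99), n_bins = 32)   # w = (99 - 1)/32 = 3.0625
fit_binning <- function(values, n_bins = 32L, discrete = FALSE, name = NULL) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) {
    abort(sprintf("Feature %s has fewer than 2 finite values.",
                  name %||% "<unnamed>"),
          class = "ctgtime_degenerate_feature")
  }
  if (discrete) {
    levels <- sort(unique(values))
    if (length(levels) < 2L) {
      abort(sprintf("Feature %s is constant.", name %||% "<unnamed>"),
            class = "ctgtime_degenerate_feature")
    }
    return(structure(list(name = name, discrete = TRUE, levels = levels,
                          n_levels = length(levels)),
                     class = "binning_scheme"))
  }
  qs <- unname(quantile(values, c(0.01, 0.99), names = FALSE))
  p1 <- qs[1]; p99 <- qs[2]
  if (!(p99 > p1)) {
    abort(sprintf("Feature %s is degenerate (P1 == P99).", name %||% "<unnamed>"),
          class = "ctgtime_degenerate_feature")
  }
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) abort("`n_bins` must be at least 2.")
  structure(list(name = name, discrete = FALSE, n_bins = n_bins,
                 lower = p1, upper = p99, width = (p99 - p1) / n_bins),
            class = "binning_scheme")
}

#' @export
print.binning_scheme <- function(x, ...) {
  if (x$discrete) {
    cat("<binning_scheme> discrete,", x$n_levels, "levels\n")
  } else {
    cat(sprintf("<binning_scheme> %d bins on [%.4g, %.4g], w = %.4g\n",
                x$n_bins, x$lower, x$upper, x$width))
  }
  invisible(x)
}

#' Apply a quantisation scheme
#'
#' Maps raw feature values to integer bin codes `1..n_bins` (continuous;
#' values below P1 / above P99 are clipped into the extreme bins) or to
#' level indices (discrete). `NA` stays `NA`.
#'
#' @param scheme A [fit_binning()] result.
#' @param values Numeric vector.
#' @return Integer codes, same length as `values`.
#' @export
bin_values <- function(scheme, values) {
  stopifnot(inherits(scheme, "binning_scheme"))
  if (scheme$discrete) {
    code <- match(values, scheme$levels)
    # unseen discrete values snap to the nearest known level
    out <- which(is.na(code) & !is.na(values))
    if (length(out)) {
      code[out] <- vapply(values[out],
                          function(v) which.min(abs(scheme$levels - v)),
                          integer(1))
    }
    return(code)
  }
  code <- floor((values - scheme$lower) / scheme$width) + 1
  code[code < 1] <- 1L
  code[code > scheme$n_bins] <- scheme$n_bins
  as.integer(code)
}

n_codes <- function(scheme) {
  if (scheme$discrete) scheme$n_levels else scheme$n_bins
}

#' Serialise binning schemes to JSON
#'
#' @param schemes A named list of [fit_binning()] results.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
binning_to_json <- function(schemes, path = NULL) {
  if (inherits(schemes, "binning_scheme")) schemes <- list(schemes)
  payload <- lapply(schemes, function(s) unclass(s))
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}
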