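# broom-style tidiers for fitted result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an association analysis
#'
#' One row per feature and association kind with the statistic, the
#' permutation p-value, the BH q-value and the rejection flag.
#'
#' @param x A [ctg_association()] result.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ctg_assoc <- function(x, ...) {
  dplyr::left_join(x$results,
                   x$types[, c("feature", "label")], by = "feature")
}

#' One-row summary of an association analysis
#'
#' @param x A [ctg_association()] result.
#' @param ... Unused.
#' @return A one-row tibble: feature/test counts, bin count, rejection
#'   counts per kind, and the taxonomy tally.
#' @export
glance.ctg_assoc <- function(x, ...) {
  rej <- function(kind) sum(x$results$reject[x$results$kind == kind])
  tibble::tibble(
    n_features = length(unique(x$results$feature)),
    n_tests = x$n_tests, n_bins = x$n_bins, n_mc = x$n_mc,
    alpha = x$alpha,
    n_time_varying = rej("F_vs_TTD"),
    n_ti_associated = rej("C_vs_F"),
    n_tv_associated = rej("C_vs_F_given_TTD"),
    n_type_I = sum(x$types$label == "type_I"),
    n_type_II = sum(x$types$label == "type_II"),
    n_type_III = sum(x$types$label == "type_III"),
    n_null = sum(x$types$label == "null"))
}

#' Tidy a time-resolved KS result
#'
#' @param x A [time_resolved_ks()] result.
#' @param ... Unused.
#' @return The underlying tibble with the feature name as a column.
#' @export
tidy.ctg_ks <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$feature <- attr(x, "feature")
  dplyr::relocate(out, "feature")
}

#' One-row summary of a time-resolved KS result
#'
#' @param x A [time_resolved_ks()] result.
#' @param ... Unused.
#' @return A one-row tibble comparing the pooled (TI) statistic with the
#'   per-epoch (TV) profile.
#' @export
glance.ctg_ks <- function(x, ...) {
  ti <- x[x$scope == "TI", ]
  tv <- x[x$scope != "TI" & x$available, ]
  tibble::tibble(
    feature = attr(x, "feature"),
    d_ks_ti = ti$d_ks, threshold_ti = ti$threshold,
    d_ks_tv_max = if (nrow(tv)) max(tv$d_ks) else NA_real_,
    d_ks_tv_mean = if (nrow(tv)) mean(tv$d_ks) else NA_real_,
    n_epochs_significant = sum(tv$significant),
    n_epochs_available = nrow(tv))
}
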