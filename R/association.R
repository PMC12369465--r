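# Association analysis: three NMI statistics per feature, stratified
# Monte-Carlo permutation nulls, BH-corrected decisions, feature taxonomy.

ID_COLS <- c("infant_id", "hospital_id", "class", "ttd_epoch")

validate_feature_table <- function(tbl) {
  missing_cols <- setdiff(ID_COLS, names(tbl))
  if (length(missing_cols)) {
    abort(paste0("Feature table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  feats <- setdiff(names(tbl), ID_COLS)
  feats <- feats[vapply(tbl[feats], is.numeric, logical(1))]
  if (!length(feats)) abort("Feature table has no numeric feature columns.")
  cls <- as.character(tbl$class)
  bad <- setdiff(unique(cls), ctg_classes())
  if (length(bad)) {
    abort(paste0("Unknown outcome class(es): ", paste(bad, collapse = ", ")))
  }
  const <- tapply(cls, tbl$infant_id, function(x) length(unique(x)) == 1L)
  if (!all(const)) abort("`class` must be constant within each infant.")
  feats
}

looks_discrete <- function(v) {
  v <- v[is.finite(v)]
  length(v) > 0 && all(abs(v - round(v)) < 1e-8) && length(unique(v)) <= 25
}

# entropy (bits) straight from a count vector
ent_counts <- function(cnt, base = 2) {
  cnt <- cnt[cnt > 0]
  n <- sum(cnt)
  if (n == 0) return(0)
  (log(n) - sum(cnt * log(cnt)) / n) / log(base)
}

#' Permute outcome classes, stratified by hospital
#'
#' Shuffles infant-level outcome labels within each hospital; every epoch of
#' an infant carries its permuted label, so per-hospital class counts are
#' preserved exactly. Hospitals with fewer than two infants are left
#' unchanged. This is the null model for the time-invariant class-feature
#' association.
#'
#' @param tbl A feature table (one row per infant-epoch).
#' @param seed Optional integer seed (uses and restores the global RNG
#'   stream when `NULL`).
#' @return The table with a permuted `class` column.
#' @export
permute_class <- function(tbl, seed = NULL) {
  validate_feature_table(tbl)
  run <- function() {
    inf <- dplyr::distinct(tbl, .data$infant_id, .data$hospital_id, .data$class)
    o <- order(inf$hospital_id)
    inf <- inf[o, ]
    shuffled <- inf$class[order(inf$hospital_id, runif(nrow(inf)))]
    singles <- sum(table(inf$hospital_id) < 2L)
    if (singles > 0) {
      inform(sprintf("%d hospital(s) with a single infant left unchanged.",
                     singles))
    }
    tbl$class <- shuffled[match(tbl$infant_id, inf$infant_id)]
    tbl
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Permute time-to-delivery labels within each infant
#'
#' Shuffles each infant's TTD epoch indices among that infant's available
#' epochs; feature values and outcome class are untouched. This is the null
#' model both for the feature-time association and for the conditional
#' class-feature association given TTD.
#'
#' @inheritParams permute_class
#' @return The table with a permuted `ttd_epoch` column.
#' @export
permute_ttd <- function(tbl, seed = NULL) {
  validate_feature_table(tbl)
  run <- function() {
    o <- order(tbl$infant_id)
    ttd_sorted <- tbl$ttd_epoch[o]
    inf_sorted <- tbl$infant_id[o]
    perm <- ttd_sorted[order(inf_sorted, runif(length(inf_sorted)))]
    tbl$ttd_epoch[o] <- perm
    tbl
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Monte-Carlo permutation p-value
#'
#' The significance level is the proportion of null replicates greater than
#' or equal to the observed statistic, \eqn{p = N_{MC}^{-1} \sum_i
#' [H_0(S)_i \ge S]}. By default no smoothing is applied, so `p` may be
#' exactly 0; `smooth = TRUE` switches to the (+1)/(N+1) variant.
#'
#' @param S Observed statistic.
#' @param null Numeric vector of null replicates.
#' @param smooth Apply add-one smoothing (default `FALSE`).
#' @return The p-value.
#' @export
#' @examples
#' permutation_pvalue(0.35, c(0.1, 0.2, 0.3, 0.4, 0.5))  # 0.4
permutation_pvalue <- function(S, null, smooth = FALSE) {
  if (!length(null)) abort("Empty null distribution.")
  if (smooth) (1 + sum(null >= S)) / (1 + length(null)) else mean(null >= S)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted q-values controlling the false discovery rate, applied
#' as one family over all tests (three per feature).
#'
#' @param p Vector of raw p-values in `[0, 1]`.
#' @return Adjusted q-values (monotone, `q >= p`).
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(p, method = "BH")
}

#' Feature taxonomy from the two class-association tests
#'
#' Combines the time-invariant (TI, class vs feature) and time-varying (TV,
#' class vs feature given TTD) rejections: TI only = `type_I`, TV only =
#' `type_II`, both = `type_III`, neither = `null`.
#'
#' @param reject_ti,reject_tv Logical vectors of equal length.
#' @return Character vector of labels.
#' @export
classify_feature_types <- function(reject_ti, reject_tv) {
  if (length(reject_ti) != length(reject_tv)) {
    abort("`reject_ti` and `reject_tv` must have equal length.")
  }
  if (anyNA(reject_ti) || anyNA(reject_tv)) {
    abort("Missing test results; run both tests before classifying.")
  }
  dplyr::case_when(
    reject_ti & !reject_tv ~ "type_I",
    !reject_ti & reject_tv ~ "type_II",
    reject_ti & reject_tv ~ "type_III",
    .default = "null"
  )
}

# --- single-feature statistics (pmf route) ---------------------------------

prep_codes <- function(tbl, feature, binning = NULL, n_bins = 32L,
                       discrete = NULL) {
  v <- tbl[[feature]]
  if (is.null(discrete)) discrete <- looks_discrete(v)
  if (is.null(binning)) {
    binning <- fit_binning(v, n_bins = n_bins, discrete = discrete,
                           name = feature)
  }
  f <- bin_values(binning, v)
  cls <- factor(as.character(tbl$class),
                levels = intersect(ctg_classes(), unique(as.character(tbl$class))))
  ttd <- sort(unique(tbl$ttd_epoch), decreasing = TRUE)
  list(f = f, c = as.integer(cls), t = match(tbl$ttd_epoch, ttd),
       binning = binning, n_class = nlevels(cls), n_ttd = length(ttd))
}

assoc_row <- function(feature, kind, value, n) {
  tibble::tibble(feature = feature, kind = kind, statistic = value,
                 n_epochs = n)
}

#' Feature-time association statistic
#'
#' \eqn{NMI_F(F;TTD) = I(F;TTD)/H(F)} computed from the empirical joint pmf
#' of the quantised feature and the TTD epoch index; tests whether a
#' feature is time varying.
#'
#' @param tbl Feature table.
#' @param feature Feature column name.
#' @param binning Optional pre-fitted [fit_binning()] scheme.
#' @param n_bins Bin count used when `binning` is `NULL`.
#' @param discrete Optional override of the discrete-feature flag.
#' @return One-row tibble: feature, kind, statistic, n_epochs.
#' @export
stat_f_ttd <- function(tbl, feature, binning = NULL, n_bins = 32L,
                       discrete = NULL) {
  z <- prep_codes(tbl, feature, binning, n_bins, discrete)
  ok <- !is.na(z$f)
  pmf <- joint_pmf_from_codes(z$f[ok], z$t[ok], roles = c("feature", "ttd"))
  assoc_row(feature, "F_vs_TTD", normalized_mi(pmf, "feature"), sum(ok))
}

#' Time-invariant class-feature association statistic
#'
#' \eqn{NMI_C(C;F) = I(C;F)/H(C)}: the static association between a feature
#' and the outcome class, ignoring time to delivery.
#'
#' @inheritParams stat_f_ttd
#' @return One-row tibble: feature, kind, statistic, n_epochs.
#' @export
stat_c_f <- function(tbl, feature, binning = NULL, n_bins = 32L,
                     discrete = NULL) {
  z <- prep_codes(tbl, feature, binning, n_bins, discrete)
  ok <- !is.na(z$f)
  pmf <- joint_pmf_from_codes(z$c[ok], z$f[ok], roles = c("class", "feature"))
  assoc_row(feature, "C_vs_F", normalized_mi(pmf, "class"), sum(ok))
}

#' Conditional class-feature association given time to delivery
#'
#' \eqn{NMI_C(C;F\mid TTD) = I(C;F\mid TTD)/H(C)}: the class-feature
#' association when accounting for the time to delivery.
#'
#' @inheritParams stat_f_ttd
#' @return One-row tibble: feature, kind, statistic, n_epochs.
#' @export
stat_c_f_given_ttd <- function(tbl, feature, binning = NULL, n_bins = 32L,
                               discrete = NULL) {
  z <- prep_codes(tbl, feature, binning, n_bins, discrete)
  ok <- !is.na(z$f)
  pmf <- joint_pmf_from_codes(z$c[ok], z$f[ok], z$t[ok],
                              roles = c("class", "feature", "ttd"))
  assoc_row(feature, "C_vs_F_given_TTD", conditional_nmi(pmf, "class"), sum(ok))
}

# --- full analysis ---------------------------------------------------------

#' Time-varying association analysis of a feature table
#'
#' For every feature column this computes the three association statistics
#' (feature vs TTD; class vs feature; class vs feature given TTD), builds
#' their stratified Monte-Carlo permutation nulls (classes permuted at the
#' infant level within hospitals; TTD permuted within infants — the TTD
#' permutation serves both the time test and the conditional test), turns
#' them into permutation p-values, applies one Benjamini-Hochberg family
#' over all `3 * n_features` tests, and labels each feature `type_I`,
#' `type_II`, `type_III` or `null` from the two class-test rejections.
#'
#' Permutation streams are shared across features: replicate `i` applies
#' the same permuted labels to every feature, which removes spurious
#' cross-feature variance from the null ensemble.
#'
#' @param tbl Feature table: `infant_id`, `hospital_id`, `class`,
#'   `ttd_epoch` plus numeric feature columns.
#' @param n_mc Number of Monte-Carlo permutations (default 5000).
#' @param alpha FDR level for rejections (default 0.05).
#' @param n_bins Bin count for continuous features; when `NULL` it is set
#'   by the Rice rule on the epoch count of the smallest outcome group.
#' @param discrete Optional character vector naming discrete features;
#'   `NULL` auto-detects integer-valued columns.
#' @param seed Optional integer seed for the permutation streams.
#' @param smooth Use add-one smoothed permutation p-values (default
#'   `FALSE`).
#' @param keep_nulls Retain the null replicate matrices in the result.
#' @return A `ctg_assoc` object: `results` (feature x kind statistics with
#'   p, q and reject flags), `types` (per-feature taxonomy), `n_bins`,
#'   `schemes`, and the call parameters. Degenerate (constant) features are
#'   excluded and listed in `$dropped`.
#' @export
ctg_association <- function(tbl, n_mc = 5000L, alpha = 0.05, n_bins = NULL,
                            discrete = NULL, seed = NULL, smooth = FALSE,
                            keep_nulls = FALSE) {
  feats <- validate_feature_table(tbl)
  if (n_mc < 1L) abort("`n_mc` must be a positive number of permutations.")
  tbl <- dplyr::arrange(tbl, .data$infant_id, dplyr::desc(.data$ttd_epoch))

  cls <- factor(as.character(tbl$class),
                levels = intersect(ctg_classes(), unique(as.character(tbl$class))))
  ccode <- as.integer(cls)
  K <- nlevels(cls)
  ttd_levels <- sort(unique(tbl$ttd_epoch), decreasing = TRUE)
  tcode <- match(tbl$ttd_epoch, ttd_levels)
  TT <- length(ttd_levels)
  n_rows <- nrow(tbl)

  if (is.null(n_bins)) {
    n_min <- min(table(cls))
    rb <- rice_bins(n_min)
    n_bins <- rb$n_bins
  } else {
    rb <- list(raw = NA_real_, n_bins = as.integer(n_bins))
  }

  # per-feature quantisation (degenerate features dropped, logged)
  schemes <- list(); fcodes <- list(); dropped <- character()
  for (f in feats) {
    disc <- if (is.null(discrete)) looks_discrete(tbl[[f]]) else f %in% discrete
    sch <- tryCatch(
      fit_binning(tbl[[f]], n_bins = n_bins, discrete = disc, name = f),
      ctgtime_degenerate_feature = function(e) NULL)
    if (is.null(sch)) { dropped <- c(dropped, f); next }
    schemes[[f]] <- sch
    fcodes[[f]] <- bin_values(sch, tbl[[f]])
  }
  if (length(dropped)) {
    inform(paste0("Dropped degenerate feature(s): ",
                  paste(dropped, collapse = ", ")))
  }
  feats <- names(schemes)
  nf_tot <- length(feats)
  if (!nf_tot) abort("All features are degenerate.")

  # observed statistics through the pmf route
  obs <- purrr::map_dfr(feats, function(f) {
    dplyr::bind_rows(
      stat_f_ttd(tbl, f, binning = schemes[[f]]),
      stat_c_f(tbl, f, binning = schemes[[f]]),
      stat_c_f_given_ttd(tbl, f, binning = schemes[[f]]))
  })

  # infant-level structures for the permutation schemes
  inf <- dplyr::distinct(tbl, .data$infant_id, .data$hospital_id)
  inf <- inf[order(inf$hospital_id, inf$infant_id), ]
  inf_cls <- ccode[match(inf$infant_id, tbl$infant_id)]
  hosp <- as.integer(factor(inf$hospital_id))
  row_inf <- match(tbl$infant_id, inf$infant_id)
  inf_sorted_rows <- as.integer(factor(tbl$infant_id)) # rows sorted by infant

  nf_codes <- vapply(schemes, n_codes, integer(1))
  oks <- lapply(fcodes, function(f) !is.na(f))
  all_ok <- vapply(oks, all, logical(1))

  null_ti <- matrix(NA_real_, n_mc, nf_tot, dimnames = list(NULL, feats))
  null_ttd <- matrix(NA_real_, n_mc, nf_tot, dimnames = list(NULL, feats))
  null_tv <- matrix(NA_real_, n_mc, nf_tot, dimnames = list(NULL, feats))

  run_nulls <- function() {
    for (i in seq_len(n_mc)) {
      # scheme 1: infant-level class shuffle within hospital
      perm_cls_inf <- inf_cls[order(hosp, runif(length(hosp)))]
      ccode_perm <- perm_cls_inf[row_inf]
      # scheme 2: TTD shuffle within infant (rows sorted by infant)
      tcode_perm <- tcode[order(inf_sorted_rows, runif(n_rows))]
      for (j in seq_len(nf_tot)) {
        nfj <- nf_codes[j]
        fj <- fcodes[[j]]; okj <- oks[[j]]
        if (all_ok[j]) { fj_ok <- fj; c1 <- ccode_perm; c2 <- ccode; t2 <- tcode_perm }
        else { fj_ok <- fj[okj]; c1 <- ccode_perm[okj]; c2 <- ccode[okj]; t2 <- tcode_perm[okj] }
        # TI null: I(C;F) with permuted classes
        cnt <- tabulate(c1 + K * (fj_ok - 1L), K * nfj)
        m <- matrix(cnt, K, nfj)
        h_c <- ent_counts(rowSums(m)); h_f <- ent_counts(colSums(m))
        null_ti[i, j] <<- (h_c + h_f - ent_counts(cnt)) / h_c
        # TTD + conditional nulls from one 3-way tabulation (permuted TTD)
        cnt3 <- tabulate(c2 + K * (fj_ok - 1L) + K * nfj * (t2 - 1L),
                         K * nfj * TT)
        a <- array(cnt3, c(K, nfj, TT))
        m_ft <- colSums(a)                       # nfj x TT
        m_ct <- apply(a, c(1, 3), sum)           # K x TT
        h_t <- ent_counts(colSums(m_ft))
        h_ft <- ent_counts(m_ft)
        h_f2 <- ent_counts(rowSums(m_ft))
        h_c2 <- ent_counts(rowSums(m_ct))
        null_ttd[i, j] <<- (h_f2 + h_t - h_ft) / h_f2
        null_tv[i, j] <<- (ent_counts(m_ct) + h_ft - h_t - ent_counts(cnt3)) / h_c2
      }
    }
  }
  if (is.null(seed)) run_nulls() else withr::with_seed(seed, run_nulls())

  obs_wide <- tidyr::pivot_wider(obs, id_cols = "feature",
                                 names_from = "kind",
                                 values_from = "statistic")
  p_ttd <- vapply(seq_len(nf_tot), function(j)
    permutation_pvalue(obs_wide$F_vs_TTD[j], null_ttd[, j], smooth), numeric(1))
  p_ti <- vapply(seq_len(nf_tot), function(j)
    permutation_pvalue(obs_wide$C_vs_F[j], null_ti[, j], smooth), numeric(1))
  p_tv <- vapply(seq_len(nf_tot), function(j)
    permutation_pvalue(obs_wide$C_vs_F_given_TTD[j], null_tv[, j], smooth),
    numeric(1))

  res <- obs
  res$p <- dplyr::case_match(res$kind,
    "F_vs_TTD" ~ p_ttd[match(res$feature, obs_wide$feature)],
    "C_vs_F" ~ p_ti[match(res$feature, obs_wide$feature)],
    "C_vs_F_given_TTD" ~ p_tv[match(res$feature, obs_wide$feature)])
  res$q <- bh_adjust(res$p)
  res$reject <- res$q < alpha

  get_flag <- function(kind) {
    r <- res[res$kind == kind, ]
    r$reject[match(obs_wide$feature, r$feature)]
  }
  types <- tibble::tibble(
    feature = obs_wide$feature,
    reject_ttd = get_flag("F_vs_TTD"),
    reject_ti = get_flag("C_vs_F"),
    reject_tv = get_flag("C_vs_F_given_TTD"))
  types$label <- classify_feature_types(types$reject_ti, types$reject_tv)

  structure(list(
    results = res, types = types, dropped = dropped,
    n_bins = n_bins, rice_raw = rb$raw, schemes = schemes,
    n_mc = as.integer(n_mc), alpha = alpha, smooth = smooth,
    n_tests = 3L * nf_tot,
    nulls = if (keep_nulls) list(ti = null_ti, ttd = null_ttd, tv = null_tv),
    class_counts = table(cls)), class = "ctg_assoc")
}

#' @export
print.ctg_assoc <- function(x, ...) {
  cat("<ctg_assoc> ", length(unique(x$results$feature)), " features, ",
      x$n_tests, " tests (N_MC = ", x$n_mc, ", alpha = ", x$alpha,
      ", n_bins = ", x$n_bins, ")\n", sep = "")
  print(table(x$types$label))
  invisible(x)
}
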