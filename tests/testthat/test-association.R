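test_that("class permutation preserves per-hospital class counts", {
  tbl <- toy_table()
  perm <- suppressMessages(permute_class(tbl, seed = 4))
  # class is still constant within infant
  expect_true(all(tapply(perm$class, perm$infant_id,
                         function(x) length(unique(x)) == 1)))
  # per-hospital class histogram unchanged
  before <- table(tbl$hospital_id, tbl$class)
  after <- table(perm$hospital_id, perm$class)
  expect_equal(unclass(after), unclass(before))
  # single hospital, two infants: labels kept or swapped
  two <- dplyr::filter(tbl, infant_id %in% c("i01", "i03"))
  p2 <- suppressMessages(permute_class(two, seed = 1))
  lab <- function(d) unname(tapply(as.character(d$class), d$infant_id,
                                   unique))
  expect_true(identical(lab(p2), lab(two)) ||
                identical(lab(p2), rev(lab(two))))
})

test_that("within-hospital arrangements are uniformly distributed", {
  tbl <- toy_table()
  # hospitals have 4 infants each with classes (h, h, a, e): 12
  # distinguishable arrangements per hospital
  arr <- replicate(1000, {
    p <- suppressMessages(permute_class(tbl))
    paste(tapply(as.character(p$class), p$infant_id, unique)[
      sprintf("i%02d", 1:4)], collapse = "")
  })
  tab <- table(arr)
  expect_identical(length(tab), 12L)
  expect_gt(suppressWarnings(chisq.test(tab)$p.value), 0.001)
})

test_that("TTD permutation shuffles time only, within each infant", {
  tbl <- toy_table()
  perm <- permute_ttd(tbl, seed = 6)
  expect_identical(perm$f_trend, tbl$f_trend) # values untouched
  expect_identical(perm$class, tbl$class)
  for (id in unique(tbl$infant_id)) {
    expect_setequal(perm$ttd_epoch[perm$infant_id == id],
                    tbl$ttd_epoch[tbl$infant_id == id])
  }
  # a strong time trend collapses to the independence level under the null
  s_obs <- stat_f_ttd(tbl, "f_trend", n_bins = 6)$statistic
  s_null <- vapply(1:30, function(i) {
    stat_f_ttd(permute_ttd(tbl, seed = i), "f_trend", n_bins = 6)$statistic
  }, numeric(1))
  expect_gt(s_obs, max(s_null))
})

test_that("permutation p-values follow the literal counting rule", {
  null <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  expect_equal(permutation_pvalue(0.35, null), 0.4)
  expect_equal(permutation_pvalue(0.9, null), 0)   # above all replicates
  expect_equal(permutation_pvalue(0.05, null), 1)  # below all replicates
  expect_equal(permutation_pvalue(0.3, null), 0.6) # ties count as >=
  expect_equal(permutation_pvalue(0.9, null, smooth = TRUE), 1 / 6)
  expect_error(permutation_pvalue(0.5, numeric(0)))
})

test_that("BH adjustment is the textbook step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("the feature taxonomy follows the two rejection flags", {
  expect_identical(
    classify_feature_types(c(TRUE, FALSE, TRUE, FALSE),
                           c(FALSE, TRUE, TRUE, FALSE)),
    c("type_I", "type_II", "type_III", "null"))
  expect_error(classify_feature_types(TRUE, NA), "Missing")
  expect_error(classify_feature_types(c(TRUE, FALSE), TRUE), "length")
})

test_that("association statistics match a direct contingency-table oracle", {
  tbl <- toy_table()
  sch <- fit_binning(tbl$f_trend, n_bins = 6, name = "f_trend")
  f <- bin_values(sch, tbl$f_trend)
  # independent oracle: explicit empirical pmf + plug-in formulas
  p_ft <- unclass(table(f, tbl$ttd_epoch)) / nrow(tbl)
  hf <- brute_entropy(rowSums(p_ft))
  expect_equal(stat_f_ttd(tbl, "f_trend", binning = sch)$statistic,
               brute_mi(p_ft) / hf, tolerance = 1e-12)
  p_cf <- unclass(table(tbl$class, f)) / nrow(tbl)
  hc <- brute_entropy(rowSums(p_cf))
  expect_equal(stat_c_f(tbl, "f_trend", binning = sch)$statistic,
               brute_mi(p_cf) / hc, tolerance = 1e-12)
  p3 <- unclass(table(tbl$class, f, tbl$ttd_epoch)) / nrow(tbl)
  expect_equal(stat_c_f_given_ttd(tbl, "f_trend", binning = sch)$statistic,
               brute_cmi(p3) / hc, tolerance = 1e-12)
})

test_that("deterministic relations give statistic 1, independence near 0", {
  tbl <- toy_table()
  tbl$f_time <- as.numeric(tbl$ttd_epoch) # deterministic in TTD
  expect_equal(stat_f_ttd(tbl, "f_time", discrete = TRUE)$statistic, 1)
  # class duplicated as a feature in a balanced design: statistic 1 for
  # the class tests at every conditioning level
  tbl$f_class <- match(tbl$class, ctg_classes())
  expect_equal(stat_c_f(tbl, "f_class", discrete = TRUE)$statistic, 1)
  expect_equal(stat_c_f_given_ttd(tbl, "f_class",
                                  discrete = TRUE)$statistic, 1)
})

test_that("the full analysis is deterministic and coherent", {
  spec <- cohort_spec(n_healthy = 40, n_acidosis = 15, n_hie = 8,
                      archetypes = default_archetypes(1), seed = 3)
  tbl <- generate_feature_table(spec)
  a1 <- ctg_association(tbl, n_mc = 60, seed = 10, keep_nulls = TRUE)
  a2 <- ctg_association(tbl, n_mc = 60, seed = 10)
  expect_equal(a1$results, a2$results)
  expect_true(all(a1$results$q >= a1$results$p))
  expect_true(all(a1$results$reject == (a1$results$q < 0.05)))
  expect_identical(a1$n_tests, 3L * length(unique(a1$results$feature)))
  expect_identical(sort(unique(a1$results$kind)),
                   sort(c("F_vs_TTD", "C_vs_F", "C_vs_F_given_TTD")))
  # every null matrix has n_mc rows per feature
  expect_identical(dim(a1$nulls$ti), c(60L, 6L))
  # refusal on n_mc = 0
  expect_error(ctg_association(tbl, n_mc = 0), "positive")
})

test_that("scheme-2 nulls sit at the independence bias, below a real trend", {
  spec <- cohort_spec(n_healthy = 150, n_acidosis = 50, n_hie = 25,
                      archetypes = list(archetype("trend", "null",
                                                  time_amp = 1)),
                      seed = 17)
  tbl <- generate_feature_table(spec)
  a <- ctg_association(tbl, n_mc = 100, seed = 5, keep_nulls = TRUE)
  s_obs <- a$results$statistic[a$results$kind == "F_vs_TTD"]
  expect_gt(s_obs, max(a$nulls$ttd[, "trend"]))
  # null mean is positive (plug-in bias) but well below the observed value
  expect_gt(mean(a$nulls$ttd[, "trend"]), 0)
  expect_lt(mean(a$nulls$ttd[, "trend"]), s_obs / 2)
})

test_that("conditioning on time raises the class association of a mirrored feature", {
  spec <- cohort_spec(n_healthy = 150, n_acidosis = 60, n_hie = 30,
                      archetypes = list(archetype("t2", "type_II")),
                      seed = 23)
  tbl <- generate_feature_table(spec)
  s_ti <- stat_c_f(tbl, "t2", n_bins = 16)$statistic
  s_tv <- stat_c_f_given_ttd(tbl, "t2", n_bins = 16)$statistic
  expect_gt(s_tv, s_ti)
})

test_that("degenerate features are dropped with a message", {
  tbl <- toy_table()
  tbl$flat <- 1
  expect_message(a <- ctg_association(tbl, n_mc = 10, seed = 1),
                 "degenerate")
  expect_identical(a$dropped, "flat")
  expect_false("flat" %in% a$results$feature)
})
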