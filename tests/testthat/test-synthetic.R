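strip_attrs <- function(d) {
  attr(d, "cohort_spec") <- NULL
  attr(d, "profiles") <- NULL
  as.data.frame(d)
}

flat_labor <- function(h = 20) {
  labor_length_spec(median_h = c(healthy = h, acidosis = h, hie = h),
                    iqr_h = c(healthy = 0, acidosis = 0, hie = 0))
}

test_that("full availability yields one row per infant-epoch", {
  spec <- cohort_spec(n_healthy = 8, n_acidosis = 1, n_hie = 1,
                      availability = availability_spec(constant = 1),
                      labor_length = flat_labor(),
                      archetypes = default_archetypes(1), seed = 5)
  tbl <- generate_feature_table(spec)
  expect_identical(nrow(tbl), 360L) # 10 infants x 36 epochs
  expect_setequal(unique(tbl$ttd_epoch), 1:36)
})

test_that("identical spec and seed reproduce the cohort bit for bit", {
  spec <- cohort_spec(n_healthy = 15, n_acidosis = 6, n_hie = 4,
                      archetypes = default_archetypes(1), seed = 21)
  t1 <- generate_feature_table(spec)
  t2 <- generate_feature_table(spec)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
})

test_that("resizing one class leaves another class's draws untouched", {
  base <- cohort_spec(n_healthy = 20, n_acidosis = 6, n_hie = 5,
                      archetypes = default_archetypes(1), seed = 13)
  bigger <- cohort_spec(n_healthy = 35, n_acidosis = 6, n_hie = 5,
                        archetypes = default_archetypes(1), seed = 13)
  hie1 <- dplyr::filter(generate_feature_table(base), class == "hie")
  hie2 <- dplyr::filter(generate_feature_table(bigger), class == "hie")
  expect_identical(strip_attrs(hie1), strip_attrs(hie2))
})

test_that("class sizes in the table equal the spec counts", {
  spec <- cohort_spec(n_healthy = 12, n_acidosis = 7, n_hie = 3,
                      archetypes = default_archetypes(1), seed = 2)
  tbl <- generate_feature_table(spec)
  counts <- dplyr::count(dplyr::distinct(tbl, infant_id, class), class)
  expect_identical(counts$n[counts$class == "healthy"], 12L)
  expect_identical(counts$n[counts$class == "acidosis"], 7L)
  expect_identical(counts$n[counts$class == "hie"], 3L)
})

test_that("spec validation catches bad inputs", {
  expect_error(cohort_spec(n_healthy = 0), ">= 1")
  expect_error(cohort_spec(epoch_grid = c(1, 2, 3)), "decreasing")
  expect_error(cohort_spec(archetypes = list(archetype("a", "null"),
                                             archetype("a", "inert"))),
               "collide")
})

test_that("an inert archetype is pure noise around its base level", {
  spec <- cohort_spec(n_healthy = 60, n_acidosis = 20, n_hie = 10,
                      archetypes = list(archetype("inrt", "inert",
                                                  base_level = 3,
                                                  noise_sd = 1)),
                      seed = 31)
  tbl <- generate_feature_table(spec)
  n <- nrow(tbl)
  expect_lt(abs(mean(tbl$inrt) - 3), 4 / sqrt(n))
})

test_that("mirrored type_II construction hides the class difference from a pooled view", {
  # equal availability and labor across classes: the regime in which the
  # mirror symmetry of the construction is exact
  spec <- cohort_spec(n_healthy = 250, n_acidosis = 150, n_hie = 100,
                      availability = availability_spec(constant = 0.8),
                      labor_length = flat_labor(),
                      archetypes = list(archetype("t2", "type_II")),
                      seed = 77)
  tbl <- generate_feature_table(spec)
  healthy <- tbl$t2[tbl$class == "healthy"]
  patho <- tbl$t2[tbl$class != "healthy"]
  d <- ks_statistic(healthy, patho)$d_ks
  crit <- 1.358 * sqrt((length(healthy) + length(patho)) /
                         (length(healthy) * length(patho)))
  expect_lt(d, crit)
  # while at the earliest epoch the class gap is 2 * delta(36)
  prof <- attr(tbl, "profiles")
  d36 <- prof$delta[prof$ttd_epoch == 36]
  h36 <- tbl$t2[tbl$class == "healthy" & tbl$ttd_epoch == 36]
  p36 <- tbl$t2[tbl$class != "healthy" & tbl$ttd_epoch == 36]
  se <- sqrt(var(h36) / length(h36) + var(p36) / length(p36))
  expect_lt(abs((mean(h36) - mean(p36)) - 2 * d36), 3 * se)
})

test_that("archetype kinds produce their designed mean structure", {
  spec <- cohort_spec(n_healthy = 250, n_acidosis = 150, n_hie = 100,
                      availability = availability_spec(constant = 0.9),
                      labor_length = flat_labor(),
                      archetypes = list(archetype("t1", "type_I"),
                                        archetype("t3", "type_III"),
                                        archetype("nul", "null")),
                      seed = 55)
  tbl <- generate_feature_table(spec)
  gap <- function(f, t) {
    h <- tbl[[f]][tbl$class == "healthy" & tbl$ttd_epoch == t]
    p <- tbl[[f]][tbl$class != "healthy" & tbl$ttd_epoch == t]
    c(diff = mean(h) - mean(p),
      se = sqrt(var(h) / length(h) + var(p) / length(p)))
  }
  # type_I: the class gap does not move with time
  g1a <- gap("t1", 30); g1b <- gap("t1", 6)
  expect_lt(abs(g1a["diff"] - g1b["diff"]),
            3 * sqrt(g1a["se"]^2 + g1b["se"]^2))
  # type_III: the gap changes with time AND the pooled marginals differ
  g3a <- gap("t3", 33); g3b <- gap("t3", 4)
  expect_gt(abs(g3a["diff"] - g3b["diff"]),
            3 * sqrt(g3a["se"]^2 + g3b["se"]^2))
  expect_lt(suppressWarnings(
    ks.test(tbl$t3[tbl$class == "healthy"],
            tbl$t3[tbl$class != "healthy"])$p.value), 0.05)
  # null: class means equal per epoch while the column mean moves with time
  gn <- gap("nul", 18)
  expect_lt(abs(gn["diff"]), 4 * gn["se"])
  m36 <- mean(tbl$nul[tbl$ttd_epoch == 36])
  m1 <- mean(tbl$nul[tbl$ttd_epoch == 1])
  expect_gt(abs(m36 - m1), 0.5) # the trend spans ~2 * time_amp
})

test_that("availability curves rise toward delivery and drop in the last hour", {
  spec <- cohort_spec()
  av <- cohort_availability(spec)
  hie <- av[av$class == "hie", ]
  mid <- hie$prob[hie$ttd_epoch == 10]
  early <- hie$prob[hie$ttd_epoch == 36]
  last <- hie$prob[hie$ttd_epoch == 1]
  expect_gt(mid, early)
  expect_gt(mid, last)
  # HIE availability dominates the other classes everywhere
  wide <- tidyr::pivot_wider(av, names_from = "class", values_from = "prob")
  expect_true(all(wide$hie >= wide$healthy))
  expect_true(all(wide$hie >= wide$acidosis))
})

test_that("feature tables round-trip through CSV", {
  spec <- cohort_spec(n_healthy = 5, n_acidosis = 2, n_hie = 1,
                      archetypes = default_archetypes(1), seed = 9)
  tbl <- generate_feature_table(spec)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tbl, path)
  back <- read_feature_table(path)
  expect_equal(as.data.frame(back), strip_attrs(tbl), tolerance = 1e-12)
})
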