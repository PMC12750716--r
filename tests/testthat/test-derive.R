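test_that("exposure binarization keeps only 'always' as exposed", {
  expect_identical(binarize_exposure("always"), 1L)
  expect_identical(binarize_exposure("sometimes"), 0L)
  expect_identical(binarize_exposure("seldom"), 0L)
  expect_identical(binarize_exposure("never"), 0L)
  expect_identical(binarize_exposure(c("Always", " never ")), c(1L, 0L))
  expect_error(binarize_exposure("often"), "often",
               class = "gcompmed_validation_error")
})

test_that("BSES-SF scoring sums 14 items and respects the 14-70 range", {
  expect_identical(score_bses(rep(5L, 14L)), 70L)
  expect_identical(score_bses(rep(1L, 14L)), 14L)
  expect_identical(score_bses(c(rep(5L, 13L), 1L)), 66L)
  # permutation invariance
  set.seed(11)
  for (i in 1:20) {
    items <- sample(1:5, 14L, replace = TRUE)
    expect_identical(score_bses(items), score_bses(sample(items)))
  }
  expect_error(score_bses(rep(3L, 13L)), "14 items")
  expect_error(score_bses(c(rep(3L, 13L), 6L)), "\\[1, 5\\]")
  # matrix form
  m <- rbind(rep(5L, 14L), rep(1L, 14L))
  expect_identical(score_bses(m), c(70L, 14L))
})

test_that("BSES split is inclusive at the threshold and monotone", {
  expect_identical(binarize_bses(70L), 1L)
  expect_identical(binarize_bses(56L), 1L)
  expect_identical(binarize_bses(55L), 0L)
  totals <- 14:70
  flags <- binarize_bses(totals)
  expect_true(all(diff(flags) >= 0L)) # monotone non-decreasing
  expect_identical(binarize_bses(60L, threshold = 65L), 0L)
  expect_error(binarize_bses(71L), "\\[14, 70\\]")
})

test_that("exclusivity requires current breastfeeding and nothing else ever", {
  expect_identical(derive_exclusivity(TRUE, FALSE), 1L)
  expect_identical(derive_exclusivity(TRUE, TRUE), 0L)
  expect_identical(derive_exclusivity(FALSE, FALSE), 0L)
  expect_identical(derive_exclusivity(FALSE, TRUE), 0L)
  # exclusive subset of currently breastfeeding, pointwise
  cb <- c(TRUE, TRUE, FALSE, FALSE)
  ev <- c(FALSE, TRUE, FALSE, TRUE)
  expect_true(all(derive_exclusivity(cb, ev) <= as.integer(cb)))
  # tolerant boolean parsing
  expect_identical(derive_exclusivity("yes", "no"), 1L)
  expect_identical(derive_exclusivity("1", "0"), 1L)
  expect_identical(derive_exclusivity("TRUE", "False"), 1L)
  expect_error(derive_exclusivity("maybe", "no"), "maybe")
  expect_identical(derive_exclusivity(NA, FALSE), NA_integer_)
})

test_that("HLQ scale scoring means 4 items and cuts at 2.5 inclusively", {
  expect_equal(score_hlq_scale(c(4L, 4L, 4L, 4L)), list(mean = 4, high = 1L))
  expect_equal(score_hlq_scale(c(2L, 2L, 3L, 3L)), list(mean = 2.5, high = 1L))
  expect_equal(score_hlq_scale(c(1L, 2L, 2L, 3L)), list(mean = 2, high = 0L))
  expect_error(score_hlq_scale(c(1L, 2L, 3L)), "4 items")
  expect_error(score_hlq_scale(c(1L, 2L, 3L, 5L)), "\\[1, 4\\]")
})

test_that("asset counting totals 13 boolean items", {
  expect_identical(count_assets(rep(TRUE, 13L)), 13L)
  expect_identical(count_assets(rep(FALSE, 13L)), 0L)
  expect_identical(count_assets(c(rep(1, 8L), rep(0, 5L))), 8L)
  expect_error(count_assets(rep(TRUE, 12L)), "13 items")
})

test_that("derive_variables derives from raw columns and logs exclusions", {
  raw <- dgp_generate(dgp_config(n = 60, rng_seed = 5), raw = TRUE)
  # drop the derived columns to force derivation from raw
  derived_cols <- c("x_helpful", "bses_total", "m_bses_high", "y_exclusive",
                    "hps_high", "hsi_high", "assets")
  stripped <- raw[, setdiff(names(raw), derived_cols)]
  out <- derive_variables(stripped)
  expect_identical(out$x_helpful, raw$x_helpful)
  expect_identical(out$bses_total, raw$bses_total)
  expect_identical(out$m_bses_high, raw$m_bses_high)
  expect_identical(out$y_exclusive, raw$y_exclusive)
  expect_identical(out$hps_high, raw$hps_high)
  expect_identical(out$assets, raw$assets)
  prov <- attr(out, "derived_from")
  expect_identical(prov$x_helpful, "raw")
  log <- attr(out, "exclusion_log")
  expect_identical(log$n_input, 60L)
  expect_identical(log$n_retained, 60L)
})

test_that("pre-derived columns pass through untouched", {
  d <- dgp_generate(dgp_config(n = 30, rng_seed = 6))
  out <- derive_variables(d)
  expect_identical(out$bses_total, d$bses_total)
  expect_identical(attr(out, "derived_from")$bses_total, "passthrough")
})

test_that("records with missing analysis cells are excluded listwise", {
  d <- dgp_generate(dgp_config(n = 120, rng_seed = 9))
  dm <- missingness_inject(d, rate = 0.2, rng_seed = 3)
  n_hit <- attr(dm, "n_affected")
  expect_gt(n_hit, 0L)
  out <- derive_variables(dm)
  log <- attr(out, "exclusion_log")
  expect_identical(log$n_retained, nrow(out))
  expect_identical(log$n_input - log$n_excluded, log$n_retained)
  expect_identical(log$n_excluded, n_hit)
  expect_false(anyNA(out[analysis_cols_for_test(out)]))
})

test_that("missingness injection matches the consort-diagram regime", {
  # a 201-record cohort at 16% per-record missingness loses ~32 records
  d <- dgp_generate(dgp_config(n = 201, rng_seed = 77))
  excluded <- vapply(1:40, function(i) {
    dm <- missingness_inject(d, rate = 0.16, rng_seed = i)
    attr(dm, "n_affected")
  }, integer(1L))
  expect_gt(mean(excluded), 32.2 - 3 * sd(excluded) / sqrt(40))
  expect_lt(mean(excluded), 32.2 + 3 * sd(excluded) / sqrt(40))
  # rate 0 leaves the table unchanged; fixed seed gives a fixed mask
  expect_identical(attr(missingness_inject(d, 0), "n_affected"), 0L)
  m1 <- missingness_inject(d, 0.3, rng_seed = 4)
  m2 <- missingness_inject(d, 0.3, rng_seed = 4)
  expect_identical(m1, m2)
})

test_that("repeat-visit selection keeps only distinct later visits", {
  d <- dgp_generate(dgp_config(n = 150, rng_seed = 12, repeat_visit = TRUE))
  sub <- select_repeat_visit(d)
  expect_true(all(sub$visit2_days_after > 0))
  expect_identical(sub$y_exclusive, sub$y_exclusive_v2)
  expect_identical(sub$bses_total, sub$bses_total_v2)
  expect_true(all(sub$infant_age == sub$infant_age_v2))
  log <- attr(sub, "exclusion_log")
  expect_identical(log$n_input - log$no_distinct_repeat_visit,
                   log$n_retained)
})
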