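series_of <- function(months, volumes, rano = NULL) {
  d <- volumes^(1 / 3)
  tibble::tibble(months = months, d_pa_mm = d, d_ml_mm = d, d_si_mm = d,
                 rano_mm = rano %||% d, measurable = 1L)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("volume estimation is the plain diameter product", {
  expect_equal(estimate_volume(10, 10, 10), 1000)
  expect_equal(estimate_volume(1, 1, 1), 1)
  expect_equal(estimate_volume(10, 12, 8), 960)
  expect_error(estimate_volume(0, 1, 1))
})

test_that("the follow-up window bound is strict", {
  s <- series_of(c(3, 6, 9, 12), rep(1000, 4))
  expect_equal(within_window(s, 9)$months, c(3, 6))
  expect_equal(within_window(s, 24)$months, c(3, 6, 9, 12))
  expect_equal(nrow(within_window(s[0, ], 9)), 0)
})

test_that("volume progression honours both the percent and 27 mm3 rules", {
  b100 <- rep(100^(1 / 3), 3)
  # 26% relative increase but only 26 mm3 absolute: blocked by the floor
  expect_false(volume_progression(b100, series_of(3, 126), 25))
  # exactly 25% with a large absolute change: inclusive threshold fires
  # (diameters chosen so the product is exact in floating point)
  b1000 <- rep(10, 3)
  s1250 <- tibble::tibble(months = 3, d_pa_mm = 12.5, d_ml_mm = 10,
                          d_si_mm = 10, rano_mm = 12.5, measurable = 1L)
  expect_true(volume_progression(b1000, s1250, 25))
  # any-timepoint rule: a later measurement can trigger on its own
  s2 <- tibble::tibble(months = c(3, 6), d_pa_mm = c(9, 11),
                       d_ml_mm = 10, d_si_mm = 10, rano_mm = c(10, 11),
                       measurable = 1L)
  expect_true(volume_progression(b1000, s2, 10))
  expect_false(volume_progression(b1000, s <- series_of(numeric(0),
                                                        numeric(0)), 10))
})

test_that("RANO progression applies the 3 mm small-lesion rule", {
  expect_false(rano_progression(8, series_of(3, 1000, rano = 9.8)))
  expect_true(rano_progression(12, series_of(3, 1000, rano = 14.4)))
  expect_true(rano_progression(8, series_of(3, 1000, rano = 11.2)))
  # unmeasurable timepoints are skipped
  s <- series_of(c(3, 6), c(1000, 1000), rano = c(NA, 20))
  expect_true(rano_progression(10, s))
  expect_error(rano_progression(NA_real_, s))
})

test_that("non-progressors split into stable vs regressing on the last scan", {
  b1000 <- rep(10, 3)
  expect_equal(classify_non_progressors(b1000, 10, series_of(3, 700),
                                        "VOL_25"), "regressing")
  expect_equal(classify_non_progressors(b1000, 10, series_of(3, 990),
                                        "VOL_25"), "stable")
  expect_equal(classify_non_progressors(b1000, 10,
                                        series_of(numeric(0), numeric(0)),
                                        "VOL_25"), "stable")
  # only the LAST in-window point matters
  expect_equal(classify_non_progressors(b1000, 10,
                                        series_of(c(3, 6), c(700, 980)),
                                        "VOL_25"), "stable")
  expect_equal(classify_non_progressors(b1000, 10,
                                        series_of(3, 1000, rano = 6.9),
                                        "RANO_20"), "regressing")
})

test_that("TRSC schemes adjudicate size-based progression correctly", {
  expect_false(apply_trsc_scheme(TRUE, "PP", "TRUE_ONLY"))
  expect_true(apply_trsc_scheme(TRUE, "RN", "TRUE_PLUS_RN"))
  expect_false(apply_trsc_scheme(FALSE, "RN", "TRUE_PLUS_RN_PP"))
  expect_true(apply_trsc_scheme(TRUE, "none", "TRUE_ONLY"))
  expect_false(apply_trsc_scheme(TRUE, "RN", "TRUE_PLUS_PP"))
  expect_error(apply_trsc_scheme(TRUE, "XX", "TRUE_ONLY"))
})

test_that("label_lesion composes the full pipeline", {
  def <- progression_definition(24, "VOL_25", "TRUE_ONLY")
  doubling <- series_of(6, 200)
  b <- rep(100^(1 / 3), 3)
  lab <- label_lesion(b, 8, doubling, "none", def)
  expect_equal(lab$three_way, "progressing")
  # same size change annotated PP under TRUE_ONLY: not progression
  lab_pp <- label_lesion(b, 8, doubling, "PP", def)
  expect_false(lab_pp$adjudicated_progression)
  expect_true(lab_pp$size_based_progression)
  expect_true(lab_pp$three_way != "progressing")
  # no in-window follow-up defaults to stable, or NA when excluded
  empty <- series_of(numeric(0), numeric(0))
  expect_equal(label_lesion(b, 8, empty, "none", def)$three_way, "stable")
  expect_true(is.na(label_lesion(b, 8, empty, "none", def,
                                 empty_followup = "exclude")$three_way))
})

test_that("an all-stable noise-free cohort is labelled all-stable", {
  stable_probs <- c(true_progressor = 0, late_progressor = 0, stable = 1,
                    regressor = 0, pseudo_progression = 0,
                    radiation_necrosis = 0)
  co <- generate_cohort(cohort_config(n_patients = 12, diameter_noise_cv = 0,
                                      class_probs = stable_probs, seed = 9))
  for (def in list(progression_definition(9, "VOL_10", "TRUE_ONLY"),
                   progression_definition(24, "VOL_25", "TRUE_PLUS_RN_PP"),
                   progression_definition(24, "RANO_20", "TRUE_ONLY"))) {
    counts <- label_counts(co, def)
    expect_equal(counts$n_stable, nrow(co$lesions))
    expect_equal(counts$n_progressing + counts$n_regressing, 0)
  }
})

test_that("labelling agrees with the brute-force oracle on random series", {
  for (i in 1:200) {
    fx <- random_series(1000 + i)
    def <- random_definition(2000 + i)
    mine <- label_lesion(fx$baseline, fx$baseline_rano, fx$series,
                         fx$annotation, def)
    oracle <- oracle_label(fx$baseline, fx$baseline_rano, fx$series,
                           fx$annotation, def$window_months, def$metric,
                           def$trsc_scheme)
    expect_identical(mine$three_way, oracle)
  }
})

test_that("label counts conserve and nest across thresholds and schemes", {
  co <- small_cohort(17, n_patients = 25)
  n <- nrow(co$lesions)
  defs <- function(metric, scheme = "TRUE_ONLY", w = 24) {
    progression_definition(w, metric, scheme)
  }
  l10 <- label_lesions(co, defs("VOL_10"))
  l25 <- label_lesions(co, defs("VOL_25"))
  expect_true(all(l25$lesion_id[l25$three_way == "progressing"] %in%
                    l10$lesion_id[l10$three_way == "progressing"]))
  for (lab in list(l10, l25)) {
    expect_equal(sum(table(lab$three_way)), n)
  }
  # scheme nesting
  s_true <- label_lesions(co, defs("VOL_25", "TRUE_ONLY"))
  s_rn <- label_lesions(co, defs("VOL_25", "TRUE_PLUS_RN"))
  s_all <- label_lesions(co, defs("VOL_25", "TRUE_PLUS_RN_PP"))
  p <- function(l) l$lesion_id[l$three_way == "progressing"]
  expect_true(all(p(s_true) %in% p(s_rn)))
  expect_true(all(p(s_rn) %in% p(s_all)))
})

test_that("binary outcomes follow the task mode", {
  expect_false(binary_outcome("stable", "PROG_VS_REST"))
  expect_true(binary_outcome("stable", "PROG_AND_STABLE_VS_REGRESS"))
  expect_false(binary_outcome("regressing", "PROG_VS_REST"))
  expect_false(binary_outcome("regressing", "PROG_AND_STABLE_VS_REGRESS"))
  expect_true(binary_outcome("progressing", "PROG_VS_REST"))
  expect_true(is.na(binary_outcome(NA_character_, "PROG_VS_REST")))
})
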