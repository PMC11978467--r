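test_that("the growth kernel reproduces its closed-form special cases", {
  # stable: flat at any time
  expect_equal(expected_volume("stable", t = c(0, 5, 24), v0 = 120),
               rep(120, 3))
  # exponential doubling at the doubling time
  expect_equal(expected_volume("true_progressor", t = 6, v0 = 100,
                               g = log(2) / 6), 200)
  # pseudo-progression pulse fully resolved by onset + duration
  expect_equal(expected_volume("pseudo_progression", t = 24, v0 = 80,
                               bump_amplitude = 0.6, onset = 4,
                               pp_duration = 6), 80)
  # ... but raised in between
  expect_gt(expected_volume("pseudo_progression", t = 7, v0 = 80,
                            bump_amplitude = 0.6, onset = 4,
                            pp_duration = 6), 80)
  # late progressor flat before onset, growing after
  expect_equal(expected_volume("late_progressor", t = 12, v0 = 50,
                               g = 0.2, late_onset = 12), 50)
  expect_gt(expected_volume("late_progressor", t = 18, v0 = 50,
                            g = 0.2, late_onset = 12), 50)
  expect_error(expected_volume("unknown_class", t = 1, v0 = 10))
})

test_that("class-conditional kernel monotonicity holds (noise-free)", {
  t <- seq(0, 24, by = 1.5)
  reg <- expected_volume("regressor", t, v0 = 500, g = -0.1)
  expect_true(all(diff(reg) < 0))
  pro <- expected_volume("true_progressor", t, v0 = 500, g = 0.1)
  expect_true(all(diff(pro) > 0))
  rn <- expected_volume("radiation_necrosis", t, v0 = 500,
                        bump_amplitude = 0.8, onset = 8)
  expect_true(all(diff(rn) >= 0))  # non-resolving bump
  expect_equal(rn[t <= 8], rep(500, sum(t <= 8)))
})

test_that("cohort generation is reproducible and honours the lesion budget", {
  cfg <- cohort_config(n_patients = 62, n_lesions = 115, seed = 11)
  co1 <- generate_cohort(cfg)
  co2 <- generate_cohort(cfg)
  expect_equal(nrow(co1$lesions), 115)
  expect_equal(dplyr::n_distinct(co1$lesions$patient_id), 62)
  expect_identical(co1$lesions, co2$lesions)
  expect_identical(co1$measurements, co2$measurements)
  co3 <- generate_cohort(cohort_config(n_patients = 62, n_lesions = 115,
                                       seed = 12))
  expect_false(identical(co1$measurements$d_pa_mm,
                         co3$measurements$d_pa_mm))
})

test_that("TRSC annotations mirror the true class and baselines are positive", {
  co <- small_cohort(5, n_patients = 40)
  les <- co$lesions
  expect_identical(les$trsc_annotation == "PP",
                   les$true_class == "pseudo_progression")
  expect_identical(les$trsc_annotation == "RN",
                   les$true_class == "radiation_necrosis")
  expect_true(all(les$baseline_dpa_mm > 0 & les$baseline_dml_mm > 0 &
                    les$baseline_dsi_mm > 0 & les$baseline_rano_mm > 0))
  # months strictly increasing within each lesion
  ok <- co$measurements |>
    dplyr::group_by(lesion_id) |>
    dplyr::summarise(ok = all(diff(months) > 0)) |>
    dplyr::pull(ok)
  expect_true(all(ok))
})

test_that("noise-free diameter products reproduce the kernel volume exactly", {
  cfg <- cohort_config(n_patients = 20, diameter_noise_cv = 0, seed = 7)
  co <- generate_cohort(cfg)
  joined <- co$measurements |>
    dplyr::left_join(co$lesions, by = "lesion_id")
  v_meas <- joined$d_pa_mm * joined$d_ml_mm * joined$d_si_mm
  v_kernel <- purrr::pmap_dbl(
    list(joined$true_class, joined$months, joined$v0_mm3, joined$growth_rate,
         joined$bump_amplitude, joined$bump_onset_months),
    function(cl, t, v0, g, amp, onset) {
      expected_volume(cl, t, v0, g, amp, onset,
                      cfg$pp_duration_months, cfg$rn_rise_tau_months,
                      cfg$late_onset_months)
    })
  expect_equal(v_meas, v_kernel, tolerance = 1e-10)
  # all-stable cohort: constant trajectories
  stable_probs <- c(true_progressor = 0, late_progressor = 0, stable = 1,
                    regressor = 0, pseudo_progression = 0,
                    radiation_necrosis = 0)
  co_st <- generate_cohort(cohort_config(n_patients = 10,
                                         diameter_noise_cv = 0,
                                         class_probs = stable_probs,
                                         seed = 3))
  spread <- co_st$measurements |>
    dplyr::group_by(lesion_id) |>
    dplyr::summarise(s = diff(range(d_pa_mm * d_ml_mm * d_si_mm))) |>
    dplyr::pull(s)
  expect_equal(spread, rep(0, length(spread)), tolerance = 1e-12)
})

test_that("feature table has the promised class-conditional structure", {
  cfg <- feature_table_config(n_features = 107, n_informative = 2,
                              effect_size_d = 1, seed = 21)
  y <- rep(c(TRUE, FALSE), 50)
  f1 <- simulate_features(y, cfg)
  f2 <- simulate_features(y, cfg)
  expect_identical(f1, f2)
  expect_equal(ncol(f1), 108)  # lesion_id + 107
  expect_identical(names(f1)[-1], radiomic_feature_names())
  expect_error(simulate_features(y, feature_table_config(n_features = 5,
                                                         n_informative = 6)))
})

test_that("single-feature AUC converges to the Gaussian closed form", {
  # two unit-variance Gaussians separated by d have AUC = pnorm(d / sqrt(2));
  # check the empirical rank AUC at large n within 3 Monte-Carlo SEs
  n <- 1e5
  y <- rep(c(TRUE, FALSE), n / 2)
  for (d in c(0, 1)) {
    f <- simulate_features(y, feature_table_config(
      n_features = 1, n_informative = 1, effect_size_d = d, seed = 31 + d))
    a <- roc_auc(f[[2]], y)
    target <- pnorm(d / sqrt(2))
    q1 <- target / (2 - target)
    q2 <- 2 * target^2 / (1 + target)
    se <- sqrt((target * (1 - target) + (n / 2 - 1) * (q1 - target^2) +
                  (n / 2 - 1) * (q2 - target^2)) / (n / 2)^2)
    expect_lt(abs(a - target), 3 * max(se, 1e-3))
  }
})

test_that("block correlation is induced at the configured strength", {
  y <- rep(c(TRUE, FALSE), 1000)
  f <- simulate_features(y, feature_table_config(
    n_features = 6, n_informative = 0, block_size = 2,
    within_block_rho = 0.9, seed = 41))
  x <- as.matrix(f[, -1])
  within <- c(cor(x[, 1], x[, 2]), cor(x[, 3], x[, 4]), cor(x[, 5], x[, 6]))
  across <- c(cor(x[, 1], x[, 3]), cor(x[, 2], x[, 5]))
  expect_true(all(abs(within - 0.9) < 0.05))
  expect_true(all(abs(across) < 0.1))
})
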