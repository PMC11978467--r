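# Random measurement series / definitions used by the property tests.
random_series <- function(seed) {
  withr::with_seed(seed, {
    months <- sort(sample(c(3, 6, 9, 12, 15, 18, 21, 24),
                          sample(0:8, 1)))
    n <- length(months)
    d <- matrix(rlnorm(3 * n, log(8), 0.5), ncol = 3)
    rano <- apply(d, 1, max) * rlnorm(n, 0, 0.05)
    if (n > 0) rano[runif(n) < 0.15] <- NA
    list(
      baseline = rlnorm(3, log(8), 0.5),
      baseline_rano = rlnorm(1, log(9), 0.4),
      annotation = sample(c("none", "PP", "RN"), 1),
      series = tibble::tibble(
        months = months,
        d_pa_mm = d[, 1], d_ml_mm = d[, 2], d_si_mm = d[, 3],
        rano_mm = rano,
        measurable = as.integer(!is.na(rano)))
    )
  })
}

random_definition <- function(seed) {
  withr::with_seed(seed, {
    progression_definition(
      sample(c(9, 12, 15, 18, 24), 1),
      sample(c("VOL_10", "VOL_15", "VOL_20", "VOL_25", "RANO_20"), 1),
      sample(c("TRUE_ONLY", "TRUE_PLUS_RN", "TRUE_PLUS_PP",
               "TRUE_PLUS_RN_PP"), 1))
  })
}

small_cohort <- function(seed, n_patients = 15, noise = 0.05,
                         class_probs = NULL) {
  cfg <- if (is.null(class_probs)) {
    cohort_config(n_patients = n_patients, diameter_noise_cv = noise,
                  seed = seed)
  } else {
    cohort_config(n_patients = n_patients, diameter_noise_cv = noise,
                  class_probs = class_probs, seed = seed)
  }
  generate_cohort(cfg)
}
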