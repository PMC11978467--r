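#' Configuration for a synthetic brain-metastasis cohort
#'
#' Bundles every knob of the longitudinal lesion simulator: cohort size,
#' outcome-class mix, growth kinetics, treatment-related size-change (TRSC)
#' phenomena and measurement noise. Defaults describe a single-centre SRS
#' cohort followed every 3 months for up to 2 years: lesion baseline sizes are
#' log-normal with median 6.2 mm (equivalent, under the product-of-diameters
#' volume proxy, to a median volume of ~240 mm^3), pseudo-progression onsets
#' fall in the 3--6 month window and resolve within 6 months, and
#' radiation-necrosis bumps start at 6 months or later and persist.
#'
#' @param n_patients Number of patients.
#' @param n_lesions Optional total lesion count. When supplied, per-patient
#'   counts drawn from `lesions_per_patient` are nudged (random patients gain
#'   or lose a lesion, never below 1) until the total matches exactly.
#' @param lesions_per_patient Named probability vector over lesion counts
#'   1..k per patient.
#' @param class_probs Named probabilities over the six trajectory classes
#'   `true_progressor`, `late_progressor`, `stable`, `regressor`,
#'   `pseudo_progression`, `radiation_necrosis`; must sum to 1.
#' @param baseline_diameter_mm `c(median, sdlog)` of the log-normal baseline
#'   geometric-mean diameter (mm).
#' @param growth_rate_per_month Named per-class exponential volume growth
#'   rates g (fraction/month); positive for progressors, negative for
#'   regressors, zero for stable and TRSC classes.
#' @param late_onset_months Month at which `late_progressor` lesions start
#'   growing (flat before).
#' @param bump_amplitude Named relative peak volume excess for the
#'   `pseudo_progression` and `radiation_necrosis` classes.
#' @param pp_onset_window_months Interval from which pseudo-progression onset
#'   is drawn uniformly.
#' @param pp_duration_months Width of the pseudo-progression pulse; the bump
#'   is exactly 0 again at onset + duration (at most 6 months).
#' @param rn_onset_months_min,rn_onset_months_max Uniform bounds of the
#'   radiation-necrosis onset (min must be >= 6 to match the delayed
#'   presentation of necrosis).
#' @param rn_rise_tau_months Time constant of the saturating necrosis bump.
#' @param followup_schedule_months Strictly increasing imaging schedule, all
#'   values <= 24.
#' @param diameter_noise_cv Coefficient of variation of the multiplicative
#'   log-normal measurement noise applied independently to each diameter at
#'   each timepoint (0 switches noise off).
#' @param axis_ratio_sdlog Spread of the per-lesion fixed axis-ratio draw;
#'   the three orthogonal diameters are `r_i * V(t)^(1/3)` with
#'   `prod(r_i) = 1`, so their product equals the kernel volume exactly in
#'   the noiseless limit.
#' @param prob_unmeasurable Per-timepoint probability that the RANO-BM nodal
#'   diameter is not measurable (cystic appearance); such timepoints carry
#'   `NA` RANO diameter and `measurable = 0`.
#' @param primary_site_probs Named probabilities over `lung` and `other`.
#' @param seed Integer seed; the whole cohort is a pure function of the
#'   config.
#'
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 62L,
                          n_lesions = NULL,
                          lesions_per_patient = c("1" = 0.55, "2" = 0.25, "3" = 0.12,
                                                  "4" = 0.05, "5" = 0.03),
                          class_probs = c(true_progressor = 0.15,
                                          late_progressor = 0.10,
                                          stable = 0.35,
                                          regressor = 0.25,
                                          pseudo_progression = 0.08,
                                          radiation_necrosis = 0.07),
                          baseline_diameter_mm = c(median = 6.2, sdlog = 0.45),
                          growth_rate_per_month = c(true_progressor = log(2) / 6,
                                                    late_progressor = log(2) / 6,
                                                    stable = 0,
                                                    regressor = -log(2) / 6,
                                                    pseudo_progression = 0,
                                                    radiation_necrosis = 0),
                          late_onset_months = 12,
                          bump_amplitude = c(pseudo_progression = 0.6,
                                             radiation_necrosis = 0.8),
                          pp_onset_window_months = c(3, 6),
                          pp_duration_months = 6,
                          rn_onset_months_min = 6,
                          rn_onset_months_max = 12,
                          rn_rise_tau_months = 3,
                          followup_schedule_months = seq(3, 24, by = 3),
                          diameter_noise_cv = 0.05,
                          axis_ratio_sdlog = 0.15,
                          prob_unmeasurable = 0,
                          primary_site_probs = c(lung = 88 / 115, other = 27 / 115),
                          seed = 1L) {
  stopifnot(n_patients >= 1, is.null(n_lesions) || n_lesions >= n_patients)
  if (abs(sum(class_probs) - 1) > 1e-9) {
    stop("`class_probs` must sum to 1", call. = FALSE)
  }
  missing_classes <- setdiff(lesion_classes(), names(class_probs))
  if (length(missing_classes) > 0) {
    stop("`class_probs` is missing classes: ",
         paste(missing_classes, collapse = ", "), call. = FALSE)
  }
  stopifnot(
    all(is.finite(growth_rate_per_month)), all(is.finite(bump_amplitude)),
    all(diff(followup_schedule_months) > 0),
    all(followup_schedule_months > 0), max(followup_schedule_months) <= 24,
    diameter_noise_cv >= 0, pp_duration_months <= 6,
    rn_onset_months_min >= 6, rn_onset_months_max >= rn_onset_months_min,
    prob_unmeasurable >= 0, prob_unmeasurable < 1,
    abs(sum(primary_site_probs) - 1) < 1e-9
  )
  structure(
    list(n_patients = as.integer(n_patients),
         n_lesions = if (!is.null(n_lesions)) as.integer(n_lesions),
         lesions_per_patient = lesions_per_patient / sum(lesions_per_patient),
         class_probs = class_probs,
         baseline_diameter_mm = baseline_diameter_mm,
         growth_rate_per_month = growth_rate_per_month,
         late_onset_months = late_onset_months,
         bump_amplitude = bump_amplitude,
         pp_onset_window_months = pp_onset_window_months,
         pp_duration_months = pp_duration_months,
         rn_onset_months_min = rn_onset_months_min,
         rn_onset_months_max = rn_onset_months_max,
         rn_rise_tau_months = rn_rise_tau_months,
         followup_schedule_months = followup_schedule_months,
         diameter_noise_cv = diameter_noise_cv,
         axis_ratio_sdlog = axis_ratio_sdlog,
         prob_unmeasurable = prob_unmeasurable,
         primary_site_probs = primary_site_probs,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' The six simulated lesion trajectory classes
#' @return Character vector of class names.
#' @export
lesion_classes <- function() {
  c("true_progressor", "late_progressor", "stable", "regressor",
    "pseudo_progression", "radiation_necrosis")
}

#' Noiseless expected lesion volume
#'
#' Deterministic growth kernel `V(t) = V0 * exp(g * t_eff) * (1 + bump(t))`.
#' Stable lesions are flat; regressors shrink exponentially; true progressors
#' grow exponentially from month 0 and late progressors only after
#' `late_onset`. Pseudo-progression carries a raised-cosine pulse starting at
#' `onset` that is exactly 0 again at `onset + pp_duration`;
#' radiation-necrosis carries a saturating, non-resolving bump starting at
#' `onset`.
#'
#' @param lesion_class One of [lesion_classes()].
#' @param t Months post-treatment (vectorised, >= 0).
#' @param v0 Baseline volume (mm^3).
#' @param g Exponential growth rate (fraction/month).
#' @param bump_amplitude Relative peak volume excess (TRSC classes only).
#' @param onset Bump onset month (TRSC classes) .
#' @param pp_duration Pulse width in months for pseudo-progression.
#' @param rn_tau Rise time constant for radiation necrosis.
#' @param late_onset Growth onset month for late progressors.
#'
#' @return Volumes in mm^3, same length as `t`.
#' @examples
#' expected_volume("true_progressor", t = 6, v0 = 100, g = log(2) / 6) # 200
#' @export
expected_volume <- function(lesion_class, t, v0, g = 0, bump_amplitude = 0,
                            onset = NA_real_, pp_duration = 6, rn_tau = 3,
                            late_onset = 12) {
  stopifnot(all(t >= 0), v0 > 0)
  lesion_class <- match.arg(lesion_class, lesion_classes())
  t_eff <- switch(lesion_class,
    true_progressor = t,
    regressor = t,
    late_progressor = pmax(t - late_onset, 0),
    stable = ,
    pseudo_progression = ,
    radiation_necrosis = 0 * t
  )
  bump <- rep(0, length(t))
  if (lesion_class == "pseudo_progression") {
    stopifnot(is.finite(onset))
    inside <- t > onset & t < onset + pp_duration
    bump[inside] <- bump_amplitude *
      sin(pi * (t[inside] - onset) / pp_duration)^2
  } else if (lesion_class == "radiation_necrosis") {
    stopifnot(is.finite(onset))
    after <- t > onset
    bump[after] <- bump_amplitude * (1 - exp(-(t[after] - onset) / rn_tau))
  }
  v0 * exp(g * t_eff) * (1 + bump)
}

# Sample per-patient lesion counts, optionally forced to a fixed total.
sample_lesion_counts <- function(config) {
  sizes <- as.integer(names(config$lesions_per_patient))
  counts <- sample(sizes, config$n_patients, replace = TRUE,
                   prob = config$lesions_per_patient)
  if (!is.null(config$n_lesions)) {
    total <- config$n_lesions
    stopifnot(total >= config$n_patients)
    while (sum(counts) != total) {
      i <- sample.int(config$n_patients, 1)
      if (sum(counts) < total) {
        counts[i] <- counts[i] + 1L
      } else if (counts[i] > 1L) {
        counts[i] <- counts[i] - 1L
      }
    }
  }
  counts
}

#' Generate a synthetic cohort of lesions with longitudinal measurements
#'
#' Draws patients, lesions, trajectory classes and per-lesion kinetic
#' parameters, then evaluates the noiseless kernel [expected_volume()] at the
#' follow-up schedule and converts volumes to three orthogonal diameters via
#' a per-lesion fixed axis-ratio triple (product 1), so the diameter product
#' tracks the kernel volume exactly when noise is off. Each diameter at each
#' timepoint (including baseline) is perturbed by independent multiplicative
#' log-normal noise with the configured CV; the RANO-BM nodal diameter is the
#' largest orthogonal diameter with its own noise draw. The TRSC annotation
#' is `PP`/`RN` exactly for the pseudo-progression / radiation-necrosis
#' classes and `none` otherwise.
#'
#' @param config A [cohort_config()].
#'
#' @return An object of class `bm_cohort`: a list with
#'   * `lesions`: one row per lesion (ids, site, true class, annotation,
#'     baseline diameters and RANO diameter, kernel parameters),
#'   * `measurements`: one row per lesion-timepoint (`lesion_id`, `months`,
#'     `d_pa_mm`, `d_ml_mm`, `d_si_mm`, `rano_mm`, `measurable`),
#'   * `config`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 5, seed = 42))
#' cohort$lesions
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  withr::local_seed(config$seed)

  counts <- sample_lesion_counts(config)
  n_lesion <- sum(counts)
  patient_id <- rep(sprintf("P%03d", seq_len(config$n_patients)), counts)
  lesion_id <- sprintf("L%04d", seq_len(n_lesion))
  true_class <- sample(lesion_classes(), n_lesion, replace = TRUE,
                       prob = config$class_probs[lesion_classes()])
  # primary site is a patient-level attribute shared by all of a patient's BMs
  site_by_patient <- sample(names(config$primary_site_probs),
                            config$n_patients, replace = TRUE,
                            prob = config$primary_site_probs)
  primary_site <- rep(site_by_patient, counts)

  d0 <- rlnorm(n_lesion,
               meanlog = log(config$baseline_diameter_mm[["median"]]),
               sdlog = config$baseline_diameter_mm[["sdlog"]])
  v0 <- d0^3
  g <- unname(config$growth_rate_per_month[true_class])
  amp <- rep(0, n_lesion)
  onset <- rep(NA_real_, n_lesion)
  is_pp <- true_class == "pseudo_progression"
  is_rn <- true_class == "radiation_necrosis"
  amp[is_pp] <- config$bump_amplitude[["pseudo_progression"]]
  amp[is_rn] <- config$bump_amplitude[["radiation_necrosis"]]
  onset[is_pp] <- runif(sum(is_pp), config$pp_onset_window_months[1],
                        config$pp_onset_window_months[2])
  onset[is_rn] <- runif(sum(is_rn), config$rn_onset_months_min,
                        config$rn_onset_months_max)

  # fixed per-lesion axis ratios with product 1
  log_r <- matrix(rnorm(3 * n_lesion, 0, config$axis_ratio_sdlog), ncol = 3)
  log_r <- log_r - rowMeans(log_r)
  axis_ratio <- exp(log_r)

  noise_sdlog <- sqrt(log(1 + config$diameter_noise_cv^2))
  draw_noise <- function(n) {
    if (noise_sdlog == 0) rep(1, n) else rlnorm(n, -noise_sdlog^2 / 2, noise_sdlog)
  }

  times <- config$followup_schedule_months
  rows <- vector("list", n_lesion)
  baseline <- matrix(NA_real_, n_lesion, 4,
                     dimnames = list(NULL, c("d_pa", "d_ml", "d_si", "rano")))
  for (i in seq_len(n_lesion)) {
    v_t <- expected_volume(true_class[i], times, v0[i], g[i], amp[i], onset[i],
                           config$pp_duration_months, config$rn_rise_tau_months,
                           config$late_onset_months)
    d_true <- outer(v_t^(1 / 3), axis_ratio[i, ])           # timepoints x 3
    d_true0 <- d0[i] * axis_ratio[i, ]                       # baseline
    d_meas0 <- d_true0 * draw_noise(3)
    rano0 <- max(d_true0) * draw_noise(1)
    d_meas <- d_true * matrix(draw_noise(3 * length(times)), ncol = 3)
    rano <- apply(d_true, 1, max) * draw_noise(length(times))
    measurable <- runif(length(times)) >= config$prob_unmeasurable
    rano[!measurable] <- NA_real_
    baseline[i, ] <- c(d_meas0, rano0)
    rows[[i]] <- tibble::tibble(
      lesion_id = lesion_id[i],
      months = times,
      d_pa_mm = d_meas[, 1], d_ml_mm = d_meas[, 2], d_si_mm = d_meas[, 3],
      rano_mm = rano,
      measurable = as.integer(measurable)
    )
  }

  lesions <- tibble::tibble(
    lesion_id = lesion_id,
    patient_id = patient_id,
    primary_site = primary_site,
    true_class = true_class,
    trsc_annotation = dplyr::case_when(is_pp ~ "PP", is_rn ~ "RN",
                                       .default = "none"),
    baseline_dpa_mm = baseline[, "d_pa"],
    baseline_dml_mm = baseline[, "d_ml"],
    baseline_dsi_mm = baseline[, "d_si"],
    baseline_rano_mm = baseline[, "rano"],
    v0_mm3 = v0,
    growth_rate = g,
    bump_amplitude = amp,
    bump_onset_months = onset
  )

  structure(list(lesions = lesions,
                 measurements = dplyr::bind_rows(rows),
                 config = config),
            class = "bm_cohort")
}

#' @export
print.bm_cohort <- function(x, ...) {
  cat("<bm_cohort> ", nrow(x$lesions), " lesions / ",
      dplyr::n_distinct(x$lesions$patient_id), " patients, ",
      nrow(x$measurements), " measurements\n", sep = "")
  print(dplyr::count(x$lesions, .data$true_class))
  invisible(x)
}
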