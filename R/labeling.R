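#' A cell of the progression-definition grid
#'
#' A definition of post-SRS progression is a triple: a follow-up window with a
#' strict upper bound (only scans strictly before `window_months` count), a
#' size-change metric (relative volume increase of 10/15/20/25% under the
#' product-of-diameters volume proxy with a 27 mm^3 absolute floor, or a
#' >=20% RANO-BM diameter increase with the 3 mm rule for sub-10 mm
#' baselines), and a treatment-related size-change (TRSC) adjudication scheme
#' saying whether lesions annotated as pseudo-progression (PP) or radiation
#' necrosis (RN) count as progression when they meet the size criterion.
#'
#' @param window_months One of 9, 12, 15, 18, 24 (exclusive upper bound).
#' @param metric One of `"VOL_10"`, `"VOL_15"`, `"VOL_20"`, `"VOL_25"`,
#'   `"RANO_20"`.
#' @param trsc_scheme One of `"TRUE_ONLY"`, `"TRUE_PLUS_RN"`,
#'   `"TRUE_PLUS_PP"`, `"TRUE_PLUS_RN_PP"`.
#'
#' @return A list of class `progression_definition`.
#' @examples
#' progression_definition(24, "VOL_25", "TRUE_ONLY")
#' @export
progression_definition <- function(window_months,
                                   metric = c("VOL_25", "VOL_10", "VOL_15",
                                              "VOL_20", "RANO_20"),
                                   trsc_scheme = c("TRUE_ONLY", "TRUE_PLUS_RN",
                                                   "TRUE_PLUS_PP",
                                                   "TRUE_PLUS_RN_PP")) {
  stopifnot(window_months %in% c(9, 12, 15, 18, 24))
  metric <- match.arg(metric)
  trsc_scheme <- match.arg(trsc_scheme)
  structure(list(window_months = window_months, metric = metric,
                 trsc_scheme = trsc_scheme),
            class = "progression_definition")
}

#' @export
print.progression_definition <- function(x, ...) {
  cat("<progression_definition> window <", x$window_months, " months, ",
      x$metric, ", ", x$trsc_scheme, "\n", sep = "")
  invisible(x)
}

vol_pct <- function(metric) {
  as.numeric(sub("VOL_", "", metric))
}

#' Volume estimate from three orthogonal diameters
#'
#' The product of the posterior-anterior, mediolateral and superior-inferior
#' diameters, the standard proxy when follow-up scans carry diameter
#' measurements but no contours.
#'
#' @param d_pa,d_ml,d_si Diameters in mm (> 0, vectorised).
#' @return Volume estimates in mm^3.
#' @examples
#' estimate_volume(10, 12, 8) # 960
#' @export
estimate_volume <- function(d_pa, d_ml, d_si) {
  if (any(c(d_pa, d_ml, d_si) <= 0, na.rm = TRUE)) {
    stop("diameters must be positive", call. = FALSE)
  }
  d_pa * d_ml * d_si
}

#' Restrict a measurement series to a follow-up window
#'
#' Keeps exactly the timepoints with `months < window_months` (the window
#' bound is strict), preserving order.
#'
#' @param series Data frame with at least a `months` column.
#' @param window_months Window length in months.
#' @return The filtered data frame.
#' @export
within_window <- function(series, window_months) {
  series[series$months < window_months, , drop = FALSE]
}

#' Volume-metric progression test
#'
#' TRUE iff any in-window timepoint's estimated volume `V` satisfies both
#' `V >= V0 * (1 + pct/100)` (inclusive threshold) and `V - V0 >= 27` mm^3
#' (the 3 mm-cubed floor guarding against small-measurement uncertainty),
#' compared always against the pre-treatment baseline.
#'
#' @param baseline Numeric length-3 vector `c(d_pa, d_ml, d_si)` in mm.
#' @param series Window-filtered measurement data frame with `d_pa_mm`,
#'   `d_ml_mm`, `d_si_mm`.
#' @param pct_threshold One of 10, 15, 20, 25.
#' @return Logical flag.
#' @export
volume_progression <- function(baseline, series, pct_threshold) {
  stopifnot(pct_threshold %in% c(10, 15, 20, 25))
  v0 <- estimate_volume(baseline[1], baseline[2], baseline[3])
  if (nrow(series) == 0) return(FALSE)
  v <- estimate_volume(series$d_pa_mm, series$d_ml_mm, series$d_si_mm)
  any(v >= v0 * (1 + pct_threshold / 100) & v - v0 >= 27)
}

#' RANO-BM diameter progression test
#'
#' TRUE iff any in-window timepoint with a measurable nodal diameter shows a
#' >=20% increase over the baseline RANO-BM diameter, additionally requiring
#' an absolute increase of >= 3 mm when the baseline is below 10 mm.
#' Timepoints whose nodal diameter could not be measured (`NA`) are skipped.
#'
#' @param baseline_rano Baseline nodal diameter in mm; an error if missing,
#'   mirroring the exclusion of lesions without a measurable baseline.
#' @param series Window-filtered measurement data frame with `rano_mm`.
#' @return Logical flag.
#' @export
rano_progression <- function(baseline_rano, series) {
  if (is.na(baseline_rano)) {
    stop("baseline RANO-BM diameter is not measurable", call. = FALSE)
  }
  r <- series$rano_mm[!is.na(series$rano_mm)]
  if (length(r) == 0) return(FALSE)
  any(r >= 1.2 * baseline_rano &
        (baseline_rano >= 10 | r - baseline_rano >= 3))
}

#' Classify a non-progressing lesion as stable or regressing
#'
#' Applied after progression adjudication. The last in-window measurement
#' decides: under a volume metric the lesion is regressing iff
#' `V <= V0 * (1 - pct/100)` with `V0 - V >= 27` mm^3 (the progression rule
#' mirrored); under the RANO metric iff the nodal diameter fell to
#' `<= 0.7 * baseline` (the 30% partial-response convention). Everything else
#' -- including a lesion with no in-window follow-up -- is stable.
#'
#' @param baseline Length-3 diameter vector (volume metrics) .
#' @param baseline_rano Baseline nodal diameter (RANO metric).
#' @param series Window-filtered measurement data frame.
#' @param metric Metric string as in [progression_definition()].
#' @return `"stable"` or `"regressing"`.
#' @export
classify_non_progressors <- function(baseline, baseline_rano, series, metric) {
  if (nrow(series) == 0) return("stable")
  if (metric == "RANO_20") {
    r <- series$rano_mm[!is.na(series$rano_mm)]
    if (length(r) == 0) return("stable")
    last <- r[length(r)]
    if (last <= 0.7 * baseline_rano) "regressing" else "stable"
  } else {
    pct <- vol_pct(metric)
    v0 <- estimate_volume(baseline[1], baseline[2], baseline[3])
    n <- nrow(series)
    v <- estimate_volume(series$d_pa_mm[n], series$d_ml_mm[n], series$d_si_mm[n])
    if (v <= v0 * (1 - pct / 100) && v0 - v >= 27) "regressing" else "stable"
  }
}

#' Adjudicate size-based progression under a TRSC scheme
#'
#' A lesion that never met the size criterion is never progression. A lesion
#' that did is true progression if unannotated; if annotated PP or RN it
#' counts as progression only under schemes that include that annotation.
#'
#' @param size_based_progression Logical flag from the size-change metric.
#' @param annotation `"none"`, `"PP"` or `"RN"` (clinician-supplied input).
#' @param scheme TRSC scheme string as in [progression_definition()].
#' @return Logical adjudicated progression flag.
#' @export
apply_trsc_scheme <- function(size_based_progression, annotation, scheme) {
  annotation <- match.arg(annotation, c("none", "PP", "RN"))
  scheme <- match.arg(scheme, c("TRUE_ONLY", "TRUE_PLUS_RN", "TRUE_PLUS_PP",
                                "TRUE_PLUS_RN_PP"))
  if (!size_based_progression) return(FALSE)
  switch(annotation,
         none = TRUE,
         PP = scheme %in% c("TRUE_PLUS_PP", "TRUE_PLUS_RN_PP"),
         RN = scheme %in% c("TRUE_PLUS_RN", "TRUE_PLUS_RN_PP"))
}

#' Label one lesion under a progression definition
#'
#' Composes the pipeline: window filter, size-change metric, TRSC
#' adjudication, and stable/regressing classification for non-progressors.
#'
#' @param baseline Length-3 diameter vector `c(d_pa, d_ml, d_si)` in mm.
#' @param baseline_rano Baseline RANO-BM nodal diameter in mm (may be `NA`
#'   only under volume metrics).
#' @param series Measurement data frame for this lesion (any window).
#' @param annotation TRSC annotation `"none"`, `"PP"` or `"RN"`.
#' @param definition A [progression_definition()].
#' @param empty_followup What a lesion with no in-window follow-up becomes:
#'   `"stable"` (default, conservative) or `"exclude"` (returns `NA` labels).
#'
#' @return A one-row tibble with `three_way`, `size_based_progression`,
#'   `adjudicated_progression`.
#' @export
label_lesion <- function(baseline, baseline_rano, series, annotation,
                         definition, empty_followup = c("stable", "exclude")) {
  stopifnot(inherits(definition, "progression_definition"))
  empty_followup <- match.arg(empty_followup)
  win <- within_window(series, definition$window_months)
  if (nrow(win) == 0 && empty_followup == "exclude") {
    return(tibble::tibble(three_way = NA_character_,
                          size_based_progression = NA,
                          adjudicated_progression = NA))
  }
  size_prog <- if (definition$metric == "RANO_20") {
    rano_progression(baseline_rano, win)
  } else {
    volume_progression(baseline, win, vol_pct(definition$metric))
  }
  adjudicated <- apply_trsc_scheme(size_prog, annotation,
                                   definition$trsc_scheme)
  three_way <- if (adjudicated) {
    "progressing"
  } else {
    classify_non_progressors(baseline, baseline_rano, win, definition$metric)
  }
  tibble::tibble(three_way = three_way,
                 size_based_progression = size_prog,
                 adjudicated_progression = adjudicated)
}

#' Label every lesion of a cohort under a progression definition
#'
#' @param cohort A `bm_cohort` from [generate_cohort()], or a list with
#'   `lesions` and `measurements` tibbles using the same columns.
#' @param definition A [progression_definition()].
#' @param empty_followup See [label_lesion()].
#'
#' @return A tibble with one row per lesion: `lesion_id`, `three_way`,
#'   `size_based_progression`, `adjudicated_progression`.
#' @export
label_lesions <- function(cohort, definition,
                          empty_followup = c("stable", "exclude")) {
  empty_followup <- match.arg(empty_followup)
  les <- cohort$lesions
  meas_by_lesion <- split(cohort$measurements,
                          factor(cohort$measurements$lesion_id,
                                 levels = les$lesion_id))
  labs <- purrr::pmap(
    list(les$lesion_id, les$baseline_dpa_mm, les$baseline_dml_mm,
         les$baseline_dsi_mm, les$baseline_rano_mm, les$trsc_annotation),
    function(id, dpa, dml, dsi, rano, ann) {
      label_lesion(c(dpa, dml, dsi), rano, meas_by_lesion[[id]], ann,
                   definition, empty_followup)
    }
  )
  dplyr::bind_cols(tibble::tibble(lesion_id = les$lesion_id),
                   dplyr::bind_rows(labs))
}

#' Count three-way labels under a definition
#'
#' @inheritParams label_lesions
#' @return A one-row tibble with `n_progressing`, `n_stable`, `n_regressing`.
#' @export
label_counts <- function(cohort, definition) {
  labs <- label_lesions(cohort, definition)
  tibble::tibble(
    n_progressing = sum(labs$three_way == "progressing", na.rm = TRUE),
    n_stable = sum(labs$three_way == "stable", na.rm = TRUE),
    n_regressing = sum(labs$three_way == "regressing", na.rm = TRUE)
  )
}

#' Binary treatment failure outcome under a task mode
#'
#' `PROG_VS_REST` (the main task): failure iff progressing.
#' `PROG_AND_STABLE_VS_REGRESS` (the alternate task): failure iff progressing
#' or stable, success only for regressing lesions.
#'
#' @param three_way Character vector of three-way labels.
#' @param task `"PROG_VS_REST"` or `"PROG_AND_STABLE_VS_REGRESS"`.
#' @return Logical vector, `TRUE` = treatment failure.
#' @export
binary_outcome <- function(three_way,
                           task = c("PROG_VS_REST",
                                    "PROG_AND_STABLE_VS_REGRESS")) {
  task <- match.arg(task)
  stopifnot(all(three_way %in% c("progressing", "stable", "regressing", NA)))
  out <- if (task == "PROG_VS_REST") {
    three_way == "progressing"
  } else {
    three_way %in% c("progressing", "stable")
  }
  out[is.na(three_way)] <- NA
  out
}
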