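# CSV / NIfTI / YAML / JSON interfaces.

#' Write a cohort to CSV files
#'
#' Emits `lesions.csv` (one row per lesion) and `measurements.csv` (one row
#' per lesion-timepoint) into a directory.
#'
#' @param cohort A `bm_cohort`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(cohort$lesions, file.path(dir, "lesions.csv"))
  readr::write_csv(cohort$measurements, file.path(dir, "measurements.csv"))
  invisible(dir)
}

#' Read a cohort from CSV files
#'
#' Counterpart of [write_cohort_csv()]; also accepts externally prepared
#' tables with the same columns (`lesion_id`, `patient_id`, baseline
#' diameters and annotation in `lesions.csv`; `lesion_id`, `months`,
#' `d_pa_mm`, `d_ml_mm`, `d_si_mm`, `rano_mm`, `measurable` in
#' `measurements.csv`).
#'
#' @param dir Directory holding `lesions.csv` and `measurements.csv`.
#' @return A list of class `bm_cohort` (without a config).
#' @export
read_cohort_csv <- function(dir) {
  lesions <- readr::read_csv(file.path(dir, "lesions.csv"),
                             show_col_types = FALSE)
  measurements <- readr::read_csv(file.path(dir, "measurements.csv"),
                                  show_col_types = FALSE)
  need <- c("lesion_id", "months", "d_pa_mm", "d_ml_mm", "d_si_mm",
            "rano_mm", "measurable")
  missing <- setdiff(need, names(measurements))
  if (length(missing) > 0) {
    stop("measurements.csv is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(list(lesions = lesions, measurements = measurements,
                 config = NULL), class = "bm_cohort")
}

#' Write a feature table to CSV
#' @param features Tibble with `lesion_id` plus feature columns.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features, path) {
  readr::write_csv(features, path)
  invisible(path)
}

#' Read a feature table from CSV
#' @param path `features.csv` with a `lesion_id` column.
#' @return A tibble.
#' @export
read_features_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  if (!"lesion_id" %in% names(x)) {
    stop("features.csv must contain a lesion_id column", call. = FALSE)
  }
  x
}

#' Write per-lesion labels to CSV
#' @param labels Labels tibble (e.g. from [label_lesions()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_labels_csv <- function(labels, path) {
  readr::write_csv(labels, path)
  invisible(path)
}

#' Serialise extractor settings to YAML
#' @param settings A [radiomics_settings()] list (or the `settings`
#'   attribute of an [extract_features()] result).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_radiomics_settings <- function(settings, path) {
  yaml::write_yaml(settings, path)
  invisible(path)
}

#' Write grid results to JSON
#'
#' Per-definition metric means/CIs, label counts, category ranges and the
#' mean test fraction, in one machine-readable summary.
#'
#' @param grid_result A `bm_grid_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_results_json <- function(grid_result, path) {
  out <- list(task_mode = grid_result$task_mode,
              seed = grid_result$seed,
              results = grid_result$results,
              ranges = grid_result$ranges)
  jsonlite::write_json(out, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a NIfTI volume as array + spacing
#' @param path `.nii` or `.nii.gz` file.
#' @return List with `image` (3D array) and `spacing` (mm).
#' @export
read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  list(image = as.array(img), spacing = RNifti::pixdim(img)[1:3])
}

#' Write an array as a NIfTI volume
#' @param image 3D array.
#' @param spacing Voxel spacing in mm.
#' @param path Output `.nii`/`.nii.gz` file.
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(image, spacing, path) {
  img <- RNifti::asNifti(image)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}
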