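#' The default 14-cell progression-definition grid
#'
#' Three categories varying one element each while holding the other two at
#' the anchor (window < 24 months, >=25% volume, true progression only):
#' `F` varies the follow-up window over 9/12/15/18/24 months, `S` varies the
#' size-change metric over RANO-BM >=20% and volume >=10/15/20/25%, and `T`
#' varies the TRSC adjudication over the four schemes. The anchor cell
#' appears once per category (14 rows, 12 unique cells, shared `cell_id`).
#'
#' @return A tibble with columns `experiment`, `category`, `window_months`,
#'   `metric`, `trsc_scheme`, `cell_id`.
#' @export
build_default_grid <- function() {
  g <- tibble::tribble(
    ~experiment, ~category, ~window_months, ~metric, ~trsc_scheme,
    "F_lt9_months", "F", 9, "VOL_25", "TRUE_ONLY",
    "F_lt12_months", "F", 12, "VOL_25", "TRUE_ONLY",
    "F_lt15_months", "F", 15, "VOL_25", "TRUE_ONLY",
    "F_lt18_months", "F", 18, "VOL_25", "TRUE_ONLY",
    "F_lt24_months", "F", 24, "VOL_25", "TRUE_ONLY",
    "S_rano_20pct", "S", 24, "RANO_20", "TRUE_ONLY",
    "S_vol_10pct", "S", 24, "VOL_10", "TRUE_ONLY",
    "S_vol_15pct", "S", 24, "VOL_15", "TRUE_ONLY",
    "S_vol_20pct", "S", 24, "VOL_20", "TRUE_ONLY",
    "S_vol_25pct", "S", 24, "VOL_25", "TRUE_ONLY",
    "T_true_only", "T", 24, "VOL_25", "TRUE_ONLY",
    "T_true_plus_rn", "T", 24, "VOL_25", "TRUE_PLUS_RN",
    "T_true_plus_pp", "T", 24, "VOL_25", "TRUE_PLUS_PP",
    "T_true_plus_rn_pp", "T", 24, "VOL_25", "TRUE_PLUS_RN_PP"
  )
  dplyr::mutate(g, cell_id = paste(.data$window_months, .data$metric,
                                   .data$trsc_scheme, sep = "|"))
}

#' Run the full definition-sensitivity analysis
#'
#' For every grid cell: labels the cohort under that definition, derives the
#' binary outcome for the task mode, and runs a bootstrap experiment on the
#' feature table. Duplicate cells (the anchor appears in all three
#' categories) are computed once and reported wherever they occur, under the
#' same derived seed, so a shared cell's rows are identical. A cell whose
#' labels collapse to a single class is reported as degenerate (`NA`
#' metrics) without affecting the others.
#'
#' @param cohort A `bm_cohort` (or compatible list; see [label_lesions()]).
#' @param features Feature tibble with a `lesion_id` column aligned with the
#'   cohort's lesions (e.g. from [simulate_features()] or
#'   [extract_features()]).
#' @param grid Definition grid tibble (default [build_default_grid()]).
#' @param task_mode `"PROG_VS_REST"` or `"PROG_AND_STABLE_VS_REGRESS"`.
#' @param seed Master seed.
#' @param ... Passed to [run_experiment()] (`n_iterations`, `tune_budget`,
#'   ...).
#'
#' @return An object of class `bm_grid_result`: list with `results` (one row
#'   per grid row: definition, label counts, metric means and CIs, test
#'   fraction), `ranges` (per category: max - min of each metric mean),
#'   `importance` (grid rows x features tibble of aggregated importances),
#'   `experiments` (named list of `bm_experiment` per unique cell),
#'   `label_counts`, `grid`, `task_mode`, `seed`.
#' @export
run_grid <- function(cohort, features, grid = build_default_grid(),
                     task_mode = c("PROG_VS_REST",
                                   "PROG_AND_STABLE_VS_REGRESS"),
                     seed = 1L, ...) {
  task_mode <- match.arg(task_mode)
  stopifnot(identical(features$lesion_id, cohort$lesions$lesion_id))
  x <- dplyr::select(features, -"lesion_id")
  patients <- cohort$lesions$patient_id

  cells <- unique(grid$cell_id)
  experiments <- list()
  cell_labels <- list()
  for (ci in seq_along(cells)) {
    cell <- cells[ci]
    row <- grid[grid$cell_id == cell, ][1, ]
    def <- progression_definition(row$window_months, row$metric,
                                  row$trsc_scheme)
    labs <- label_lesions(cohort, def)
    y <- binary_outcome(labs$three_way, task_mode)
    cell_labels[[cell]] <- labs
    experiments[[cell]] <- if (length(unique(y[!is.na(y)])) < 2) {
      NULL  # degenerate definition
    } else {
      run_experiment(x, y, patients, seed = derive_seed(seed, ci), ...)
    }
  }

  results <- purrr::pmap_dfr(grid, function(experiment, category,
                                            window_months, metric,
                                            trsc_scheme, cell_id) {
    labs <- cell_labels[[cell_id]]
    counts <- table(factor(labs$three_way,
                           levels = c("progressing", "stable", "regressing")))
    ex <- experiments[[cell_id]]
    base <- tibble::tibble(
      experiment = experiment, category = category,
      window_months = window_months, metric = metric,
      trsc_scheme = trsc_scheme, cell_id = cell_id,
      n_progressing = as.integer(counts[["progressing"]]),
      n_stable = as.integer(counts[["stable"]]),
      n_regressing = as.integer(counts[["regressing"]]),
      degenerate = is.null(ex))
    if (is.null(ex)) {
      return(dplyr::mutate(base, auc = NA_real_, auc_lo = NA_real_,
                           auc_hi = NA_real_, auprc = NA_real_,
                           auprc_lo = NA_real_, auprc_hi = NA_real_,
                           sensitivity = NA_real_, sens_lo = NA_real_,
                           sens_hi = NA_real_, specificity = NA_real_,
                           spec_lo = NA_real_, spec_hi = NA_real_,
                           baseline_auprc = NA_real_,
                           mean_test_fraction = NA_real_))
    }
    s <- ex$summary
    stat_of <- function(mc, col) s[[col]][s$metric == mc]
    y <- binary_outcome(labs$three_way, task_mode)
    dplyr::mutate(base,
      auc = stat_of("auc", "mean"), auc_lo = stat_of("auc", "ci_low"),
      auc_hi = stat_of("auc", "ci_high"),
      auprc = stat_of("auprc", "mean"),
      auprc_lo = stat_of("auprc", "ci_low"),
      auprc_hi = stat_of("auprc", "ci_high"),
      sensitivity = stat_of("sensitivity", "mean"),
      sens_lo = stat_of("sensitivity", "ci_low"),
      sens_hi = stat_of("sensitivity", "ci_high"),
      specificity = stat_of("specificity", "mean"),
      spec_lo = stat_of("specificity", "ci_low"),
      spec_hi = stat_of("specificity", "ci_high"),
      baseline_auprc = baseline_auprc(y[!is.na(y)]),
      mean_test_fraction = ex$mean_test_fraction)
  })

  ok <- dplyr::filter(results, !.data$degenerate)
  ranges <- if (nrow(ok) == 0) {
    tibble::tibble(category = character(0), auc_range = numeric(0),
                   auprc_range = numeric(0), sensitivity_range = numeric(0),
                   specificity_range = numeric(0))
  } else {
    ok |>
      dplyr::group_by(.data$category) |>
      dplyr::summarise(dplyr::across(c("auc", "auprc", "sensitivity",
                                       "specificity"),
                                     ~ max(.x) - min(.x),
                                     .names = "{.col}_range"),
                       .groups = "drop")
  }

  feature_names <- colnames(x)
  importance <- purrr::map_dfr(seq_len(nrow(grid)), function(r) {
    ex <- experiments[[grid$cell_id[r]]]
    imp <- if (is.null(ex)) rep(NA_real_, length(feature_names)) else
      ex$aggregated_importance
    dplyr::bind_cols(tibble::tibble(experiment = grid$experiment[r]),
                     tibble::as_tibble(as.list(setNames(imp, feature_names))))
  })

  label_counts <- dplyr::select(results, "experiment", "n_progressing",
                                "n_stable", "n_regressing")

  structure(list(results = results, ranges = ranges, importance = importance,
                 experiments = experiments, label_counts = label_counts,
                 grid = grid, task_mode = task_mode, seed = seed),
            class = "bm_grid_result")
}

#' @export
print.bm_grid_result <- function(x, ...) {
  cat("<bm_grid_result> ", nrow(x$grid), " definitions (",
      length(unique(x$grid$cell_id)), " unique cells), task ", x$task_mode,
      "\n", sep = "")
  print(dplyr::select(x$results, "experiment", "n_progressing", "auc",
                      "auc_lo", "auc_hi"))
  cat("\nAUC range per category:\n")
  print(x$ranges)
  invisible(x)
}
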