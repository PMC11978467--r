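test_that("the default grid matches the 14-cell design", {
  g <- build_default_grid()
  expect_equal(nrow(g), 14)
  expect_equal(length(unique(g$cell_id)), 12)
  expect_true(all(g$window_months %in% c(9, 12, 15, 18, 24)))
  # the anchor cell appears once in each category
  anchor <- g$cell_id[g$experiment == "F_lt24_months"]
  expect_equal(sort(g$category[g$cell_id == anchor]), c("F", "S", "T"))
  expect_equal(dplyr::count(g, category)$n, c(5, 5, 4))
  expect_false(any(duplicated(g$experiment)))
})

grid_fixture <- local({
  co <- generate_cohort(cohort_config(n_patients = 30, seed = 61))
  def <- progression_definition(24, "VOL_25", "TRUE_ONLY")
  labs <- label_lesions(co, def)
  y <- binary_outcome(labs$three_way, "PROG_VS_REST")
  feats <- simulate_features(y, feature_table_config(
    n_features = 12, n_informative = 3, effect_size_d = 1.5, seed = 62),
    lesion_id = co$lesions$lesion_id)
  list(cohort = co, features = feats)
})

test_that("a grid run is deterministic with coherent duplicate cells", {
  res <- run_grid(grid_fixture$cohort, grid_fixture$features, seed = 71,
                  n_iterations = 5, tune_budget = 0, n_trees = 50)
  res2 <- run_grid(grid_fixture$cohort, grid_fixture$features, seed = 71,
                   n_iterations = 5, tune_budget = 0, n_trees = 50)
  expect_identical(res$results, res2$results)
  # duplicate-cell coherence: the anchor rows agree in every numeric column
  anchor_rows <- res$results[res$results$cell_id ==
                               "24|VOL_25|TRUE_ONLY", ]
  expect_equal(nrow(anchor_rows), 3)
  num_cols <- setdiff(names(anchor_rows),
                      c("experiment", "category", "cell_id"))
  for (col in num_cols) {
    expect_length(unique(anchor_rows[[col]]), 1)
  }
  # conservation: label counts sum to the cohort size in every definition
  sums <- res$label_counts$n_progressing + res$label_counts$n_stable +
    res$label_counts$n_regressing
  expect_true(all(sums == nrow(grid_fixture$cohort$lesions)))
  # ranges are max - min of the category means
  f_rows <- res$results[res$results$category == "F" & !res$results$degenerate, ]
  expect_equal(res$ranges$auc_range[res$ranges$category == "F"],
               max(f_rows$auc) - min(f_rows$auc))
  # importance matrix has one row per definition, values in [0, 1]
  expect_equal(nrow(res$importance), 14)
  imp_vals <- unlist(res$importance[, -1])
  expect_true(all(is.na(imp_vals) | (imp_vals >= 0 & imp_vals <= 1)))
  # tidy/glance interfaces
  td <- tidy(res)
  expect_equal(nrow(td), 14 * 4)
  gl <- glance(res)
  expect_equal(gl$n_definitions, 14)
  expect_equal(gl$auc_range_followup,
               res$ranges$auc_range[res$ranges$category == "F"])
})

test_that("degenerate definitions are reported without failing the grid", {
  stable_probs <- c(true_progressor = 0, late_progressor = 0, stable = 1,
                    regressor = 0, pseudo_progression = 0,
                    radiation_necrosis = 0)
  co <- generate_cohort(cohort_config(n_patients = 10, diameter_noise_cv = 0,
                                      class_probs = stable_probs, seed = 81))
  y_any <- rep(c(TRUE, FALSE), length.out = nrow(co$lesions))
  feats <- simulate_features(y_any, feature_table_config(n_features = 6,
                                                         seed = 82,
                                                         n_informative = 0),
                             lesion_id = co$lesions$lesion_id)
  res <- run_grid(co, feats, seed = 83, n_iterations = 3, tune_budget = 0,
                  n_trees = 30)
  expect_true(all(res$results$degenerate))
  expect_true(all(is.na(res$results$auc)))
  expect_true(all(res$results$n_stable == nrow(co$lesions)))
})

test_that("results round-trip through the CSV/JSON/YAML interfaces", {
  dir <- withr::local_tempdir()
  co <- grid_fixture$cohort
  write_cohort_csv(co, file.path(dir, "cohort"))
  back <- read_cohort_csv(file.path(dir, "cohort"))
  expect_equal(nrow(back$lesions), nrow(co$lesions))
  expect_equal(back$measurements$d_pa_mm, co$measurements$d_pa_mm)
  # labelling the re-read cohort gives identical labels
  def <- progression_definition(24, "VOL_25", "TRUE_ONLY")
  expect_identical(label_lesions(back, def), label_lesions(co, def))

  write_features_csv(grid_fixture$features, file.path(dir, "features.csv"))
  f_back <- read_features_csv(file.path(dir, "features.csv"))
  expect_equal(as.data.frame(f_back), as.data.frame(grid_fixture$features))

  labs <- label_lesions(co, def)
  write_labels_csv(labs, file.path(dir, "labels.csv"))
  expect_true(file.exists(file.path(dir, "labels.csv")))

  res <- run_grid(co, grid_fixture$features, seed = 91, n_iterations = 3,
                  tune_budget = 0, n_trees = 30)
  write_results_json(res, file.path(dir, "results.json"))
  parsed <- jsonlite::read_json(file.path(dir, "results.json"))
  expect_equal(length(parsed$results), 14)
  write_radiomics_settings(radiomics_settings(), file.path(dir, "set.yaml"))
  expect_equal(yaml::read_yaml(file.path(dir, "set.yaml"))$bin_count, 64)
})

test_that("NIfTI volumes round-trip with spacing intact", {
  dir <- withr::local_tempdir()
  ph <- simulate_lesion_image(dim_vox = c(12, 12, 12), spacing = c(1, 1, 2),
                              seed = 5)
  path <- file.path(dir, "img.nii.gz")
  write_nifti_volume(ph$image, ph$spacing, path)
  back <- read_nifti_volume(path)
  expect_equal(back$spacing, c(1, 1, 2))
  expect_equal(back$image, ph$image, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("grid plots build without error", {
  res <- run_grid(grid_fixture$cohort, grid_fixture$features, seed = 95,
                  n_iterations = 3, tune_budget = 0, n_trees = 30)
  expect_s3_class(autoplot(res), "ggplot")
  expect_s3_class(plot_importance_heatmap(res, top_n = 5), "ggplot")
  expect_s3_class(autoplot(grid_fixture$cohort), "ggplot")
})
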