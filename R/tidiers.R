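#' Tidy a bootstrap experiment
#'
#' @param x A `bm_experiment`.
#' @param ... Unused.
#' @return Tibble with one row per metric: `metric`, `mean`, `ci_low`,
#'   `ci_high`.
#' @export
tidy.bm_experiment <- function(x, ...) {
  x$summary
}

#' One-row summary of a bootstrap experiment
#'
#' @param x A `bm_experiment`.
#' @param ... Unused.
#' @return One-row tibble: mean AUC/AU-PRC/sensitivity/specificity, mean
#'   test fraction, iteration and redraw counts.
#' @export
glance.bm_experiment <- function(x, ...) {
  wide <- setNames(x$summary$mean, x$summary$metric)
  tibble::tibble(auc = wide[["auc"]], auprc = wide[["auprc"]],
                 sensitivity = wide[["sensitivity"]],
                 specificity = wide[["specificity"]],
                 mean_test_fraction = x$mean_test_fraction,
                 n_iterations = x$n_iterations,
                 n_redrawn = x$n_redrawn)
}

#' Tidy a grid run
#'
#' @param x A `bm_grid_result`.
#' @param ... Unused.
#' @return Long tibble: one row per definition x metric with mean and CI.
#' @export
tidy.bm_grid_result <- function(x, ...) {
  res <- x$results
  purrr::map_dfr(
    list(c("auc", "auc_lo", "auc_hi"),
         c("auprc", "auprc_lo", "auprc_hi"),
         c("sensitivity", "sens_lo", "sens_hi"),
         c("specificity", "spec_lo", "spec_hi")),
    function(cols) {
      tibble::tibble(experiment = res$experiment, category = res$category,
                     metric = cols[1], mean = res[[cols[1]]],
                     ci_low = res[[cols[2]]], ci_high = res[[cols[3]]])
    })
}

#' One-row summary of a grid run
#'
#' @param x A `bm_grid_result`.
#' @param ... Unused.
#' @return One-row tibble with the cross-definition AUC range (overall and
#'   per category), definition counts and task mode.
#' @export
glance.bm_grid_result <- function(x, ...) {
  ok <- !x$results$degenerate
  rng <- function(cat) {
    r <- x$ranges$auc_range[x$ranges$category == cat]
    if (length(r) == 0) NA_real_ else r
  }
  tibble::tibble(
    n_definitions = nrow(x$results),
    n_degenerate = sum(!ok),
    auc_range_overall = if (any(ok)) max(x$results$auc[ok]) -
      min(x$results$auc[ok]) else NA_real_,
    auc_range_followup = rng("F"),
    auc_range_size_metric = rng("S"),
    auc_range_trsc = rng("T"),
    task_mode = x$task_mode)
}
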