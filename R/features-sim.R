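#' Configuration for a synthetic radiomic feature table
#'
#' Describes a feature matrix with known statistical structure: a controlled
#' number of outcome-informative columns (class-conditional unit-variance
#' Gaussians whose means differ by `effect_size_d`), the rest standard
#' Gaussian noise, with optional block correlation induced by a shared
#' within-block factor.
#'
#' @param n_features Number of feature columns (default 107; when 107, the
#'   columns carry the standard radiomic feature names).
#' @param n_informative Number of informative columns (the first
#'   `n_informative`); must not exceed `n_features`.
#' @param effect_size_d Standardised mean difference (Cohen's d) between the
#'   failure and success classes on informative columns. The best achievable
#'   single-feature AUC is `pnorm(d / sqrt(2))`.
#' @param block_size Features per correlated block (1 = independent).
#' @param within_block_rho Pairwise correlation within a block, |rho| < 1.
#' @param seed Integer seed.
#'
#' @return A list of class `feature_table_config`.
#' @export
feature_table_config <- function(n_features = 107L, n_informative = 10L,
                                 effect_size_d = 1, block_size = 1L,
                                 within_block_rho = 0, seed = 1L) {
  stopifnot(n_features >= 1, n_informative >= 0,
            abs(within_block_rho) < 1, effect_size_d >= 0, block_size >= 1)
  if (n_informative > n_features) {
    stop("`n_informative` must not exceed `n_features`", call. = FALSE)
  }
  structure(list(n_features = as.integer(n_features),
                 n_informative = as.integer(n_informative),
                 effect_size_d = effect_size_d,
                 block_size = as.integer(block_size),
                 within_block_rho = within_block_rho,
                 seed = as.integer(seed)),
            class = "feature_table_config")
}

#' Simulate a per-lesion radiomic feature table
#'
#' Rows follow the lesion order of `labels`. Informative columns have
#' class-conditional Gaussian distributions with unit variance and mean
#' separation `effect_size_d` (failure class shifted upwards); the remaining
#' columns are standard Gaussian. Consecutive groups of `block_size` columns
#' share a latent factor so that the within-block correlation equals
#' `within_block_rho` in expectation.
#'
#' @param labels Logical (or 0/1) vector, `TRUE` = treatment failure, one per
#'   lesion.
#' @param config A [feature_table_config()].
#' @param lesion_id Optional lesion identifiers for the `lesion_id` column.
#'
#' @return A tibble with `lesion_id` and `n_features` numeric columns.
#' @examples
#' y <- rep(c(TRUE, FALSE), 10)
#' simulate_features(y, feature_table_config(n_features = 5, n_informative = 1))
#' @export
simulate_features <- function(labels, config = feature_table_config(),
                              lesion_id = NULL) {
  stopifnot(inherits(config, "feature_table_config"))
  y <- as.logical(labels)
  stopifnot(!anyNA(y))
  n <- length(y)
  withr::local_seed(config$seed)

  p <- config$n_features
  rho <- config$within_block_rho
  block <- rep(seq_len(ceiling(p / config$block_size)),
               each = config$block_size)[seq_len(p)]
  z_block <- matrix(rnorm(n * max(block)), n, max(block))
  eps <- matrix(rnorm(n * p), n, p)
  x <- sqrt(abs(rho)) * z_block[, block, drop = FALSE] * sign(rho)^0 +
    sqrt(1 - abs(rho)) * eps
  if (rho < 0) {
    # alternate factor sign within each block to induce negative pairing
    flip <- stats::ave(seq_len(p), block, FUN = seq_along) %% 2 == 0
    x[, flip] <- -sqrt(abs(rho)) * z_block[, block[flip], drop = FALSE] +
      sqrt(1 - abs(rho)) * eps[, flip, drop = FALSE]
  }
  if (config$n_informative > 0) {
    idx <- seq_len(config$n_informative)
    x[, idx] <- x[, idx] + config$effect_size_d * y
  }

  nm <- if (p == 107) radiomic_feature_names() else sprintf("f%03d", seq_len(p))
  colnames(x) <- nm
  if (is.null(lesion_id)) lesion_id <- sprintf("L%04d", seq_len(n))
  dplyr::bind_cols(tibble::tibble(lesion_id = lesion_id),
                   tibble::as_tibble(x))
}
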