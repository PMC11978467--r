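firstorder_features <- function(x, voxel_volume, n_bins) {
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  p <- tabulate(discretize_fixed_count(x, n_bins), nbins = n_bins) / n
  q10 <- unname(quantile(x, 0.10, type = 7))
  q90 <- unname(quantile(x, 0.90, type = 7))
  mid <- x[x >= q10 & x <= q90]
  c(Energy = sum(x^2),
    TotalEnergy = sum(x^2) * voxel_volume,
    Entropy = entropy2(p),
    Minimum = min(x),
    Percentile10 = q10,
    Percentile90 = q90,
    Maximum = max(x),
    Mean = mu,
    Median = unname(stats::median(x)),
    InterquartileRange = unname(quantile(x, 0.75) - quantile(x, 0.25)),
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation = mean(abs(mid - mean(mid))),
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(p^2))
}

#' Extract the 107-feature radiomic vector from a lesion
#'
#' Computes 14 shape, 18 first-order, 24 GLCM, 16 GLRLM, 16 GLSZM, 14 GLDM
#' and 5 NGTDM features from the lesion region of a (normalised) image.
#' Gray-level discretisation uses a fixed bin count over the lesion's
#' intensity range; texture matrices are computed in 3D over the 13 unique
#' directions / 26-connected neighbourhoods. The result is deterministic for
#' a fixed input.
#'
#' @param image 3D numeric array (typically the output of
#'   [normalize_zscore()]).
#' @param lesion_mask Logical 3D array on the same grid, non-empty.
#' @param spacing Voxel spacing in mm (length 3).
#' @param bin_count Number of gray-level bins (default 64).
#'
#' @return A one-row tibble with the 107 columns of
#'   [radiomic_feature_names()], with the extractor settings attached as the
#'   `settings` attribute.
#' @examples
#' phantom <- simulate_lesion_image(dim_vox = c(24, 24, 24), seed = 7)
#' feats <- extract_features(phantom$image, phantom$lesion_mask,
#'                           phantom$spacing)
#' ncol(feats) # 107
#' @export
extract_features <- function(image, lesion_mask, spacing = c(0.5, 0.5, 0.5),
                             bin_count = 64) {
  if (!identical(dim(image), dim(lesion_mask))) {
    stop("image and mask grids differ", call. = FALSE)
  }
  stopifnot(length(spacing) == 3, all(spacing > 0), bin_count >= 2)
  if (!any(lesion_mask)) stop("lesion mask is empty", call. = FALSE)
  if (any(!is.finite(image[lesion_mask]))) {
    stop("non-finite intensities inside the lesion mask", call. = FALSE)
  }

  # crop to the mask bounding box (1 voxel pad) to keep matrices small
  idx <- which(lesion_mask, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - 1L, 1L)
  hi <- pmin(apply(idx, 2, max) + 1L, dim(image))
  img <- image[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  msk <- lesion_mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]

  x <- img[msk]
  q <- array(NA_integer_, dim(img))
  q[msk] <- discretize_fixed_count(x, bin_count)

  shp <- shape_features(msk, spacing)
  fo <- firstorder_features(x, prod(spacing), bin_count)
  glcm <- glcm_features(q, bin_count)
  glrlm <- glrlm_features(q, bin_count)
  glszm <- glszm_features(q, bin_count)
  gldm <- gldm_features(q, bin_count)
  ngtdm <- ngtdm_features(q, bin_count)
  v <- c(setNames(shp, paste0("shape_", names(shp))),
         setNames(fo, paste0("firstorder_", names(fo))),
         setNames(glcm, paste0("glcm_", names(glcm))),
         setNames(glrlm, paste0("glrlm_", names(glrlm))),
         setNames(glszm, paste0("glszm_", names(glszm))),
         setNames(gldm, paste0("gldm_", names(gldm))),
         setNames(ngtdm, paste0("ngtdm_", names(ngtdm))))
  stopifnot(identical(names(v), radiomic_feature_names()))
  res <- tibble::as_tibble(as.list(v))
  attr(res, "settings") <- radiomics_settings(bin_count = bin_count,
                                              spacing = spacing)
  res
}

#' Extractor settings used for provenance
#'
#' @param bin_count Gray-level bin count.
#' @param spacing Voxel spacing the features were computed at.
#' @return A named list, serialisable with [write_radiomics_settings()].
#' @export
radiomics_settings <- function(bin_count = 64, spacing = c(0.5, 0.5, 0.5)) {
  list(feature_count = 107L,
       bin_count = as.integer(bin_count),
       bin_mode = "fixed_bin_count",
       spacing_mm = as.numeric(spacing),
       image_interpolation = "trilinear",
       mask_interpolation = "nearest",
       normalization = "zscore_brain_minus_lesion_clip3sd",
       directions = "13_unique_3d_merged",
       connectivity = "26")
}

#' Run the full image pipeline for one lesion
#'
#' Resamples to isotropic spacing, z-score normalises against the brain
#' (lesion excluded) and extracts the 107 features.
#'
#' @inheritParams resample_isotropic
#' @param brain_mask,lesion_mask Logical arrays on the input grid.
#' @param bin_count Gray-level bin count (default 64).
#' @param clip_sd Normalisation clip bound.
#' @return A one-row tibble of 107 features.
#' @export
features_from_image <- function(image, spacing, brain_mask, lesion_mask,
                                target_mm = 0.5, bin_count = 64, clip_sd = 3) {
  rs <- resample_isotropic(image, spacing,
                           masks = list(brain = brain_mask,
                                        lesion = lesion_mask),
                           target_mm = target_mm)
  norm <- normalize_zscore(rs$image, rs$masks$brain, rs$masks$lesion,
                           clip_sd = clip_sd)
  extract_features(norm, rs$masks$lesion, rs$spacing, bin_count = bin_count)
}
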