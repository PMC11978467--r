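#' Simulate a small T1w-CE-like volume with one lesion
#'
#' A deliberately simple phantom to exercise the preprocessing and feature
#' extraction stages: a spherical "brain" of baseline intensity with Gaussian
#' noise, containing one brighter ellipsoidal lesion whose interior carries
#' extra texture (noise plus a low-frequency modulation). Realistic MRI
#' appearance is a non-goal.
#'
#' @param dim_vox Integer length-3 array dimension.
#' @param spacing Voxel spacing in mm (length 3).
#' @param lesion_radii_mm Ellipsoid semi-axes in mm.
#' @param lesion_center_vox Centre in voxel coordinates (defaults to the
#'   array centre).
#' @param brain_intensity,lesion_intensity Mean intensities.
#' @param noise_sd Background Gaussian noise SD.
#' @param texture_sd Extra intra-lesion noise SD (0 gives a near-constant
#'   lesion).
#' @param seed Integer seed.
#'
#' @return A list with `image` (3D array), `spacing`, `lesion_mask` and
#'   `brain_mask` (logical 3D arrays; the brain mask includes the lesion).
#' @export
simulate_lesion_image <- function(dim_vox = c(40L, 40L, 40L),
                                  spacing = c(1, 1, 1),
                                  lesion_radii_mm = c(6, 5, 4),
                                  lesion_center_vox = (dim_vox + 1) / 2,
                                  brain_intensity = 100,
                                  lesion_intensity = 150,
                                  noise_sd = 5,
                                  texture_sd = 15,
                                  seed = 1L) {
  stopifnot(length(dim_vox) == 3, all(spacing > 0))
  withr::local_seed(seed)
  ix <- seq_len(dim_vox[1]); iy <- seq_len(dim_vox[2]); iz <- seq_len(dim_vox[3])
  cx <- (dim_vox + 1) / 2
  # physical offsets from the array centre / lesion centre
  gx <- array(rep((ix - cx[1]) * spacing[1], times = dim_vox[2] * dim_vox[3]), dim_vox)
  gy <- array(rep(rep((iy - cx[2]) * spacing[2], each = dim_vox[1]),
                  times = dim_vox[3]), dim_vox)
  gz <- array(rep((iz - cx[3]) * spacing[3], each = dim_vox[1] * dim_vox[2]), dim_vox)
  brain_radius <- 0.45 * min(dim_vox * spacing)
  brain_mask <- gx^2 + gy^2 + gz^2 <= brain_radius^2

  lx <- gx - (lesion_center_vox[1] - cx[1]) * spacing[1]
  ly <- gy - (lesion_center_vox[2] - cx[2]) * spacing[2]
  lz <- gz - (lesion_center_vox[3] - cx[3]) * spacing[3]
  lesion_mask <- (lx / lesion_radii_mm[1])^2 + (ly / lesion_radii_mm[2])^2 +
    (lz / lesion_radii_mm[3])^2 <= 1
  lesion_mask <- lesion_mask & brain_mask
  if (!any(lesion_mask)) stop("lesion mask is empty", call. = FALSE)

  img <- array(0, dim_vox)
  img[brain_mask] <- brain_intensity + rnorm(sum(brain_mask), 0, noise_sd)
  texture <- texture_sd * (0.7 * rnorm(sum(lesion_mask)) +
                             0.5 * sin(lx[lesion_mask] / 1.5) *
                             cos(ly[lesion_mask] / 2))
  img[lesion_mask] <- lesion_intensity + texture
  list(image = img, spacing = spacing,
       lesion_mask = lesion_mask, brain_mask = brain_mask)
}
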