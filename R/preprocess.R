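#' Resample an image (and masks) to an isotropic grid
#'
#' Trilinear interpolation for the intensity image, nearest-neighbour for the
#' label masks. The output grid shares the first voxel centre with the input
#' and spans the same physical extent at `target_mm` spacing. Input already
#' at the target spacing passes through untouched.
#'
#' @param image 3D numeric array.
#' @param spacing Input voxel spacing in mm (length 3, > 0).
#' @param masks Optional named list of logical/0-1 arrays on the same grid.
#' @param target_mm Target isotropic spacing (default 0.5 mm).
#'
#' @return A list with `image`, `spacing` (the target) and `masks`.
#' @export
resample_isotropic <- function(image, spacing, masks = list(),
                               target_mm = 0.5) {
  stopifnot(length(dim(image)) == 3, all(spacing > 0), target_mm > 0)
  if (length(image) == 0) stop("empty image", call. = FALSE)
  for (m in masks) stopifnot(identical(dim(m), dim(image)))
  if (all(abs(spacing - target_mm) < 1e-12)) {
    return(list(image = image, spacing = rep(target_mm, 3), masks = masks))
  }
  d_in <- dim(image)
  n_out <- pmax(1L, as.integer(floor((d_in - 1) * spacing / target_mm + 1e-9)) + 1L)
  # continuous input index of each output voxel centre, per axis
  pos <- purrr::map2(n_out, seq_len(3),
                     ~ (seq_len(.x) - 1) * target_mm / spacing[.y] + 1)
  lo <- purrr::map2(pos, d_in, ~ pmin(pmax(floor(.x), 1), .y))
  hi <- purrr::map2(lo, d_in, ~ pmin(.x + 1, .y))
  fr <- purrr::map2(pos, lo, ~ .x - .y)

  # expand per-axis pieces to the full output grid
  rep_axis <- function(v, axis) {
    switch(axis,
           rep(v, times = n_out[2] * n_out[3]),
           rep(rep(v, each = n_out[1]), times = n_out[3]),
           rep(v, each = n_out[1] * n_out[2]))
  }
  L <- purrr::imap(lo, rep_axis)
  H <- purrr::imap(hi, rep_axis)
  W <- purrr::imap(fr, rep_axis)
  at <- function(a, i, j, k) a[cbind(i, j, k)]
  out <-
    at(image, L[[1]], L[[2]], L[[3]]) * (1 - W[[1]]) * (1 - W[[2]]) * (1 - W[[3]]) +
    at(image, H[[1]], L[[2]], L[[3]]) * W[[1]] * (1 - W[[2]]) * (1 - W[[3]]) +
    at(image, L[[1]], H[[2]], L[[3]]) * (1 - W[[1]]) * W[[2]] * (1 - W[[3]]) +
    at(image, L[[1]], L[[2]], H[[3]]) * (1 - W[[1]]) * (1 - W[[2]]) * W[[3]] +
    at(image, H[[1]], H[[2]], L[[3]]) * W[[1]] * W[[2]] * (1 - W[[3]]) +
    at(image, H[[1]], L[[2]], H[[3]]) * W[[1]] * (1 - W[[2]]) * W[[3]] +
    at(image, L[[1]], H[[2]], H[[3]]) * (1 - W[[1]]) * W[[2]] * W[[3]] +
    at(image, H[[1]], H[[2]], H[[3]]) * W[[1]] * W[[2]] * W[[3]]
  out <- array(out, n_out)

  NN <- purrr::map(seq_len(3), function(ax) {
    rep_axis(pmin(pmax(round(pos[[ax]]), 1), d_in[ax]), ax)
  })
  masks_out <- purrr::map(masks, function(m) {
    array(at(m, NN[[1]], NN[[2]], NN[[3]]) > 0, n_out)
  })
  list(image = out, spacing = rep(target_mm, 3), masks = masks_out)
}

#' Brain-masked z-score intensity normalisation
#'
#' Standardises an image using the mean and standard deviation of the brain's
#' intensities excluding the lesion voxels, then clips the normalised values
#' to `[-clip_sd, +clip_sd]`. Keeping the lesion out of the statistics stops
#' large bright lesions from shifting their own normalisation.
#'
#' @param image 3D numeric array.
#' @param brain_mask Logical array (brain, including the lesion).
#' @param lesion_mask Logical array (lesion voxels to exclude from the
#'   statistics).
#' @param clip_sd Clip bound in standard deviations (default 3).
#'
#' @return Normalised 3D array.
#' @export
normalize_zscore <- function(image, brain_mask, lesion_mask,
                             clip_sd = 3) {
  stopifnot(identical(dim(image), dim(brain_mask)),
            identical(dim(image), dim(lesion_mask)))
  ref <- image[brain_mask & !lesion_mask]
  if (length(ref) < 2) stop("brain mask minus lesion is empty", call. = FALSE)
  mu <- mean(ref)
  sigma <- sd(ref)
  if (!is.finite(sigma) || sigma == 0) {
    stop("zero variance in reference region", call. = FALSE)
  }
  z <- (image - mu) / sigma
  pmin(pmax(z, -clip_sd), clip_sd)
}
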