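# Mesh-based shape descriptors. The lesion surface is triangulated by
# marching tetrahedra on the binary mask (iso-level 0.5, edge midpoints,
# 6-tetrahedra cube decomposition around the main diagonal); surface area and
# enclosed volume follow from the oriented triangle soup. Axis lengths come
# from the principal components of the voxel-centre point cloud.

# corner offsets of the unit cube, indexed 0..7
cube_corners <- matrix(c(0, 0, 0,  1, 0, 0,  1, 1, 0,  0, 1, 0,
                         0, 0, 1,  1, 0, 1,  1, 1, 1,  0, 1, 1),
                       ncol = 3, byrow = TRUE)

# six tetrahedra sharing the 0-6 diagonal; rows are corner ids
cube_tets <- matrix(c(0, 1, 2, 6,  0, 2, 3, 6,  0, 3, 7, 6,
                      0, 7, 4, 6,  0, 4, 5, 6,  0, 5, 1, 6) + 1,
                    ncol = 4, byrow = TRUE)

# area and signed-volume contribution of triangles (m1, m2, m3) oriented away
# from the inside reference points `ref`; all arguments are n x 3 matrices
tri_patch <- function(m1, m2, m3, ref) {
  e1 <- m2 - m1
  e2 <- m3 - m1
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area <- 0.5 * sqrt(rowSums(nrm^2))
  centroid <- (m1 + m2 + m3) / 3
  outward <- sign(rowSums(nrm * (centroid - ref)))
  outward[outward == 0] <- 1
  svol <- rowSums(m1 * cbind(m2[, 2] * m3[, 3] - m2[, 3] * m3[, 2],
                             m2[, 3] * m3[, 1] - m2[, 1] * m3[, 3],
                             m2[, 1] * m3[, 2] - m2[, 2] * m3[, 1])) / 6
  list(area = sum(area), volume = sum(outward * svol))
}

# Surface area and mesh volume of a binary mask via marching tetrahedra at
# iso-level 0.5. The binary indicator is blended with a [1,2,1]/4-smoothed
# copy before meshing: flat boundaries still cross exactly midway between
# voxel centres, while oblique surfaces lose the staircase facets that
# would otherwise inflate the area estimate.
smooth_121 <- function(a) {
  dm <- dim(a)
  for (ax in 1:3) {
    lo <- a; hi <- a
    n <- dm[ax]
    idx_lo <- c(1, seq_len(n - 1))
    idx_hi <- c(seq(2, n), n)
    if (ax == 1) { lo <- a[idx_lo, , , drop = FALSE]; lo[1, , ] <- 0
                   hi <- a[idx_hi, , , drop = FALSE]; hi[n, , ] <- 0 }
    if (ax == 2) { lo <- a[, idx_lo, , drop = FALSE]; lo[, 1, ] <- 0
                   hi <- a[, idx_hi, , drop = FALSE]; hi[, n, ] <- 0 }
    if (ax == 3) { lo <- a[, , idx_lo, drop = FALSE]; lo[, , 1] <- 0
                   hi <- a[, , idx_hi, drop = FALSE]; hi[, , n] <- 0 }
    a <- (lo + 2 * a + hi) / 4
  }
  a
}

# linear interpolation of the iso-0.5 crossing on an edge (matrix rows)
iso_point <- function(pa, va, pb, vb) {
  t <- (0.5 - va) / (vb - va)
  pa + t * (pb - pa)
}

mesh_area_volume <- function(mask, spacing, smooth_passes = 1) {
  dm <- dim(mask)
  pad <- array(0, dm + 2L)
  pad[2:(dm[1] + 1), 2:(dm[2] + 1), 2:(dm[3] + 1)] <- mask * 1
  field <- pad
  for (i in seq_len(smooth_passes)) field <- smooth_121(field)
  if (!any(field > 0.5)) field <- (pad + smooth_121(pad)) / 2
  if (!any(field > 0.5)) field <- pad
  mesh_from_field(field, spacing)
}

mesh_from_field <- function(pad, spacing) {
  pd <- dim(pad)
  nx <- pd[1] - 1L; ny <- pd[2] - 1L; nz <- pd[3] - 1L
  base <- expand.grid(x = seq_len(nx), y = seq_len(ny), z = seq_len(nz))
  # restrict to cubes touching the surface (mixed corner values)
  corner_lin <- function(cx, cy, cz) {
    (base$z + cz - 1) * pd[1] * pd[2] + (base$y + cy - 1) * pd[1] +
      (base$x + cx)
  }
  vals <- sapply(seq_len(8), function(k) {
    pad[corner_lin(cube_corners[k, 1], cube_corners[k, 2], cube_corners[k, 3])]
  })
  inside <- vals > 0.5
  mixed <- rowSums(inside) > 0 & rowSums(inside) < 8
  if (!any(mixed)) return(list(area = 0, volume = 0))
  base <- base[mixed, , drop = FALSE]
  vals <- vals[mixed, , drop = FALSE]
  inside <- inside[mixed, , drop = FALSE]

  # physical coords of the 8 corners (voxel centres of the padded grid)
  corner_xyz <- function(k) {
    cbind((base$x - 1 + cube_corners[k, 1] - 1) * spacing[1],
          (base$y - 1 + cube_corners[k, 2] - 1) * spacing[2],
          (base$z - 1 + cube_corners[k, 3] - 1) * spacing[3])
  }
  xyz <- lapply(seq_len(8), corner_xyz)

  area <- 0
  volume <- 0
  corner_at <- function(id, rows) xyz[[id]][rows, , drop = FALSE]
  for (t in seq_len(6)) {
    ids <- cube_tets[t, ]
    b <- inside[, ids, drop = FALSE]
    v <- vals[, ids, drop = FALSE]
    code <- b[, 1] + 2L * b[, 2] + 4L * b[, 3] + 8L * b[, 4]
    # single lone corner (inside or outside): one triangle
    lone_codes <- list(c(1L, 14L, 1L), c(2L, 13L, 2L), c(4L, 11L, 3L),
                       c(8L, 7L, 4L))
    for (lc in lone_codes) {
      pos <- lc[3]
      others <- setdiff(1:4, pos)
      for (inside_one in c(TRUE, FALSE)) {
        sel <- which(code == if (inside_one) lc[1] else lc[2])
        if (length(sel) == 0) next
        p <- corner_at(ids[pos], sel)
        vp <- v[sel, pos]
        m <- lapply(others, function(oo) {
          iso_point(p, vp, corner_at(ids[oo], sel), v[sel, oo])
        })
        ref <- if (inside_one) p else
          (corner_at(ids[others[1]], sel) + corner_at(ids[others[2]], sel) +
             corner_at(ids[others[3]], sel)) / 3
        patch <- tri_patch(m[[1]], m[[2]], m[[3]], ref)
        area <- area + patch$area
        volume <- volume + patch$volume
      }
    }
    # two-two split: quad as two triangles
    pair_codes <- list(c(3L, 1L, 2L), c(5L, 1L, 3L), c(9L, 1L, 4L),
                       c(6L, 2L, 3L), c(10L, 2L, 4L), c(12L, 3L, 4L))
    for (pc in pair_codes) {
      sel <- which(code == pc[1])
      if (length(sel) == 0) next
      ins <- c(pc[2], pc[3])
      outs <- setdiff(1:4, ins)
      p1 <- corner_at(ids[ins[1]], sel); p2 <- corner_at(ids[ins[2]], sel)
      q1 <- corner_at(ids[outs[1]], sel); q2 <- corner_at(ids[outs[2]], sel)
      vp1 <- v[sel, ins[1]]; vp2 <- v[sel, ins[2]]
      vq1 <- v[sel, outs[1]]; vq2 <- v[sel, outs[2]]
      m11 <- iso_point(p1, vp1, q1, vq1); m12 <- iso_point(p1, vp1, q2, vq2)
      m21 <- iso_point(p2, vp2, q1, vq1); m22 <- iso_point(p2, vp2, q2, vq2)
      patch1 <- tri_patch(m11, m12, m22, p1)
      patch2 <- tri_patch(m11, m22, m21, p1)
      area <- area + patch1$area + patch2$area
      volume <- volume + patch1$volume + patch2$volume
    }
  }
  list(area = area, volume = abs(volume))
}

max_pairwise_distance <- function(coords) {
  n <- nrow(coords)
  if (n < 2) return(0)
  best <- 0
  chunk <- 512L
  for (i0 in seq(1, n, by = chunk)) {
    i1 <- min(i0 + chunk - 1, n)
    block <- coords[i0:i1, , drop = FALSE]
    d2 <- outer(rowSums(block^2), rowSums(coords^2), "+") -
      2 * block %*% t(coords)
    best <- max(best, max(d2))
  }
  sqrt(max(best, 0))
}

boundary_voxels <- function(mask) {
  dm <- dim(mask)
  core <- mask
  shift_and <- function(m, d) {
    out <- array(FALSE, dm)
    src <- purrr::map2(dm, d, function(n, dd) {
      if (dd >= 0) seq_len(n - dd) else seq(1 - dd, n)
    })
    dst <- purrr::map2(src, d, ~ .x + .y)
    out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    out
  }
  interior <- mask
  for (d in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))) {
    interior <- interior & shift_and(mask, d)
  }
  mask & !interior
}

shape_features <- function(mask, spacing) {
  n <- sum(mask)
  stopifnot(n > 0)
  mesh <- mesh_area_volume(mask, spacing)
  vox_volume <- n * prod(spacing)
  coords <- arrayInd(which(mask), dim(mask))
  phys <- sweep(coords - 1, 2, spacing, "*")
  ctr <- colMeans(phys)
  cc <- sweep(phys, 2, ctr)
  lambda <- sort(eigen(crossprod(cc) / n, symmetric = TRUE,
                       only.values = TRUE)$values, decreasing = TRUE)
  lambda <- pmax(lambda, 0)

  bnd <- boundary_voxels(mask)
  bcoords <- arrayInd(which(bnd), dim(mask))
  bphys <- sweep(bcoords - 1, 2, spacing, "*")
  max3d <- max_pairwise_distance(bphys)
  plane_diameter <- function(fixed_axis) {
    keep_axes <- setdiff(1:3, fixed_axis)
    slices <- split.data.frame(bphys[, keep_axes, drop = FALSE],
                               bcoords[, fixed_axis])
    max(vapply(slices, max_pairwise_distance, numeric(1)))
  }

  sa <- mesh$area
  mv <- max(mesh$volume, .Machine$double.eps)
  c(MeshVolume = mesh$volume,
    VoxelVolume = vox_volume,
    SurfaceArea = sa,
    SurfaceVolumeRatio = sa / mv,
    Sphericity = (36 * pi * mv^2)^(1 / 3) / max(sa, .Machine$double.eps),
    Maximum3DDiameter = max3d,
    Maximum2DDiameterSlice = plane_diameter(3),
    Maximum2DDiameterColumn = plane_diameter(2),
    Maximum2DDiameterRow = plane_diameter(1),
    MajorAxisLength = 4 * sqrt(lambda[1]),
    MinorAxisLength = 4 * sqrt(lambda[2]),
    LeastAxisLength = 4 * sqrt(lambda[3]),
    Elongation = sqrt(lambda[2] / max(lambda[1], .Machine$double.eps)),
    Flatness = sqrt(lambda[3] / max(lambda[1], .Machine$double.eps)))
}
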