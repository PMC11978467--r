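# 107-feature radiomic extractor: first-order statistics, five gray-level
# texture-matrix families on a fixed-bin-count discretisation, and mesh-based
# shape descriptors. Gray levels are bin indices 1..n_bins; texture matrices
# use the 13 unique 3D directions (GLCM/GLRLM counts merged over directions
# before normalisation) and 26-connectivity where a neighbourhood is needed.

# the 13 unique direction vectors of the 26-neighbourhood (no antiparallels)
unique_directions <- function() {
  d <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  d <- d[!(d[, 1] == 0 & d[, 2] == 0 & d[, 3] == 0), ]
  keep <- d[, 3] > 0 | (d[, 3] == 0 & d[, 2] > 0) |
    (d[, 3] == 0 & d[, 2] == 0 & d[, 1] > 0)
  d[keep, , drop = FALSE]
}

all_neighbor_offsets <- function() {
  d <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  d[!(d[, 1] == 0 & d[, 2] == 0 & d[, 3] == 0), , drop = FALSE]
}

# fixed-bin-count discretisation over the masked intensity range
discretize_fixed_count <- function(x, n_bins) {
  rng <- range(x)
  if (rng[2] <= rng[1]) return(rep(1L, length(x)))
  b <- floor((x - rng[1]) / (rng[2] - rng[1]) * n_bins) + 1L
  pmin(b, n_bins)
}

# overlapping subarray pair for an offset; returns two vectors of gray levels
shifted_pairs <- function(q, d) {
  dm <- dim(q)
  rng <- purrr::map2(dm, d, function(n, dd) {
    if (dd >= 0) seq_len(n - dd) else seq(1 - dd, n)
  })
  a <- q[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
  b <- q[rng[[1]] + d[1], rng[[2]] + d[2], rng[[3]] + d[3], drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  list(a = a[ok], b = b[ok])
}

entropy2 <- function(p) {
  p <- p[p > 0]
  if (length(p) == 0) return(0)
  -sum(p * log2(p))
}

# ---- GLCM -------------------------------------------------------------------

glcm_matrix <- function(q, n_bins) {
  dirs <- unique_directions()
  counts <- matrix(0, n_bins, n_bins)
  for (k in seq_len(nrow(dirs))) {
    pr <- shifted_pairs(q, dirs[k, ])
    if (length(pr$a) == 0) next
    tab <- tabulate((pr$a - 1L) * n_bins + pr$b, nbins = n_bins * n_bins)
    counts <- counts + matrix(tab, n_bins, n_bins, byrow = TRUE)
  }
  counts <- counts + t(counts)  # symmetric
  if (sum(counts) == 0) counts[1, 1] <- 1
  counts / sum(counts)
}

glcm_features <- function(q, n_bins) {
  P <- glcm_matrix(q, n_bins)
  used <- which(rowSums(P) + colSums(P) > 0)
  P <- P[used, used, drop = FALSE]
  ng <- length(used)
  lv <- as.numeric(used)
  i <- matrix(lv, ng, ng)
  j <- t(i)
  px <- rowSums(P)
  py <- colSums(P)
  mu_x <- sum(lv * px)
  mu_y <- sum(lv * py)
  sd_x <- sqrt(sum((lv - mu_x)^2 * px))
  sd_y <- sqrt(sum((lv - mu_y)^2 * py))

  k_sum <- 2:(2 * max(lv))
  p_sum <- vapply(k_sum, function(k) sum(P[i + j == k]), numeric(1))
  k_diff <- 0:(max(lv) - 1)
  p_diff <- vapply(k_diff, function(k) sum(P[abs(i - j) == k]), numeric(1))

  autoc <- sum(i * j * P)
  contrast <- sum((i - j)^2 * P)
  corr <- if (sd_x * sd_y > 0) (autoc - mu_x * mu_y) / (sd_x * sd_y) else 1
  da <- sum(k_diff * p_diff)
  joint_ent <- entropy2(P)
  hx <- entropy2(px)
  pxpy <- outer(px, py)
  nz <- P > 0 & pxpy > 0
  hxy1 <- -sum(P[nz] * log2(pxpy[nz]))
  hxy2 <- entropy2(pxpy)
  imc1 <- if (hx > 0) (joint_ent - hxy1) / hx else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * (hxy2 - joint_ent)), 0))

  mcc <- {
    if (ng < 2) {
      1
    } else {
      R1 <- P / px
      C2 <- sweep(P, 2, py, "/")
      Q <- R1 %*% t(C2)
      ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
      sqrt(pmax(ev[2], 0))
    }
  }

  c(Autocorrelation = autoc,
    JointAverage = mu_x,
    ClusterProminence = sum((i + j - mu_x - mu_y)^4 * P),
    ClusterShade = sum((i + j - mu_x - mu_y)^3 * P),
    ClusterTendency = sum((i + j - mu_x - mu_y)^2 * P),
    Contrast = contrast,
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = entropy2(p_diff),
    DifferenceVariance = sum((k_diff - da)^2 * p_diff),
    JointEnergy = sum(P^2),
    JointEntropy = joint_ent,
    Imc1 = imc1,
    Imc2 = imc2,
    Idm = sum(P / (1 + (i - j)^2)),
    Idmn = sum(P / (1 + ((i - j) / n_bins)^2)),
    Id = sum(P / (1 + abs(i - j))),
    Idn = sum(P / (1 + abs(i - j) / n_bins)),
    InverseVariance = sum(P[i != j] / (i[i != j] - j[i != j])^2),
    MaximumProbability = max(P),
    SumAverage = sum(k_sum * p_sum),
    SumEntropy = entropy2(p_sum),
    SumSquares = sum((i - mu_x)^2 * P),
    Mcc = mcc)
}

# ---- GLRLM ------------------------------------------------------------------

glrlm_matrix <- function(q, n_bins) {
  dm <- dim(q)
  idx <- which(!is.na(q))
  vox <- arrayInd(idx, dm)
  g <- q[idx]
  dirs <- unique_directions()
  runs_level <- integer(0)
  runs_len <- integer(0)
  for (k in seq_len(nrow(dirs))) {
    d <- dirs[k, ]
    ax <- which(d != 0)[1]
    s <- vox[, ax] * d[ax]
    lid <- cbind(vox[, 1] - s * d[1], vox[, 2] - s * d[2], vox[, 3] - s * d[3])
    key <- (lid[, 1] + dm[1]) + (lid[, 2] + dm[2]) * (3 * dm[1]) +
      (lid[, 3] + dm[3]) * (9 * dm[1] * dm[2])
    o <- order(key, s)
    ks <- key[o]; ss <- s[o]; gs <- g[o]
    brk <- c(TRUE, ks[-1] != ks[-length(ks)] |
               ss[-1] != ss[-length(ss)] + 1 |
               gs[-1] != gs[-length(gs)])
    starts <- which(brk)
    lens <- diff(c(starts, length(ks) + 1))
    runs_level <- c(runs_level, gs[starts])
    runs_len <- c(runs_len, lens)
  }
  max_len <- max(runs_len)
  m <- matrix(0, n_bins, max_len)
  tab <- table(factor(runs_level, levels = seq_len(n_bins)),
               factor(runs_len, levels = seq_len(max_len)))
  m + unclass(tab)
}

size_weighted_features <- function(counts) {
  # shared machinery for GLRLM / GLSZM style level x size matrices
  n_bins <- nrow(counts)
  sizes <- seq_len(ncol(counts))
  levels <- seq_len(n_bins)
  ns <- sum(counts)
  p <- counts / ns
  pg <- rowSums(counts)   # per gray level
  psz <- colSums(counts)  # per size
  i2 <- levels^2
  j2 <- sizes^2
  mu_g <- sum(levels * rowSums(p))
  mu_s <- sum(sizes * colSums(p))
  list(
    small = sum(sweep(counts, 2, j2, "/")) / ns,
    large = sum(sweep(counts, 2, j2, "*")) / ns,
    gln = sum(pg^2) / ns,
    glnn = sum(pg^2) / ns^2,
    szn = sum(psz^2) / ns,
    sznn = sum(psz^2) / ns^2,
    glv = sum(sweep(p, 1, (levels - mu_g)^2, "*")),
    szv = sum(sweep(p, 2, (sizes - mu_s)^2, "*")),
    ent = entropy2(as.vector(p)),
    lgl = sum(sweep(counts, 1, i2, "/")) / ns,
    hgl = sum(sweep(counts, 1, i2, "*")) / ns,
    slgl = sum(sweep(sweep(counts, 1, i2, "/"), 2, j2, "/")) / ns,
    shgl = sum(sweep(sweep(counts, 1, i2, "*"), 2, j2, "/")) / ns,
    llgl = sum(sweep(sweep(counts, 1, i2, "/"), 2, j2, "*")) / ns,
    lhgl = sum(sweep(sweep(counts, 1, i2, "*"), 2, j2, "*")) / ns,
    n_runs = ns
  )
}

glrlm_features <- function(q, n_bins) {
  counts <- glrlm_matrix(q, n_bins)
  s <- size_weighted_features(counts)
  n_vox <- sum(!is.na(q))
  n_dirs <- nrow(unique_directions())
  c(ShortRunEmphasis = s$small,
    LongRunEmphasis = s$large,
    GrayLevelNonUniformity = s$gln,
    GrayLevelNonUniformityNormalized = s$glnn,
    RunLengthNonUniformity = s$szn,
    RunLengthNonUniformityNormalized = s$sznn,
    RunPercentage = s$n_runs / (n_vox * n_dirs),
    GrayLevelVariance = s$glv,
    RunVariance = s$szv,
    RunEntropy = s$ent,
    LowGrayLevelRunEmphasis = s$lgl,
    HighGrayLevelRunEmphasis = s$hgl,
    ShortRunLowGrayLevelEmphasis = s$slgl,
    ShortRunHighGrayLevelEmphasis = s$shgl,
    LongRunLowGrayLevelEmphasis = s$llgl,
    LongRunHighGrayLevelEmphasis = s$lhgl)
}

# ---- GLSZM ------------------------------------------------------------------

glszm_matrix <- function(q, n_bins) {
  dm <- dim(q)
  idx <- which(!is.na(q))
  offs <- all_neighbor_offsets()
  vox <- arrayInd(idx, dm)
  lin_of <- function(v) (v[, 3] - 1) * dm[1] * dm[2] + (v[, 2] - 1) * dm[1] + v[, 1]
  in_mask <- array(FALSE, dm)
  in_mask[idx] <- TRUE
  visited <- array(FALSE, dm)
  zones_level <- integer(0)
  zones_size <- integer(0)
  for (v in idx) {
    if (visited[v]) next
    level <- q[v]
    visited[v] <- TRUE
    queue <- v
    size <- 0L
    while (length(queue) > 0) {
      cur <- queue[[length(queue)]]
      queue <- queue[-length(queue)]
      size <- size + 1L
      cv <- arrayInd(cur, dm)
      nb <- sweep(offs, 2, as.integer(cv), "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] & nb[, 2] >= 1 & nb[, 2] <= dm[2] &
        nb[, 3] >= 1 & nb[, 3] <= dm[3]
      nb <- nb[ok, , drop = FALSE]
      ln <- lin_of(nb)
      ln <- ln[in_mask[ln] & !visited[ln] & q[ln] == level]
      if (length(ln) > 0) {
        visited[ln] <- TRUE
        queue <- c(queue, ln)
      }
    }
    zones_level <- c(zones_level, level)
    zones_size <- c(zones_size, size)
  }
  m <- table(factor(zones_level, levels = seq_len(n_bins)),
             factor(zones_size, levels = seq_len(max(zones_size))))
  matrix(unclass(m), nrow = n_bins)
}

glszm_features <- function(q, n_bins) {
  counts <- glszm_matrix(q, n_bins)
  s <- size_weighted_features(counts)
  n_vox <- sum(!is.na(q))
  c(SmallAreaEmphasis = s$small,
    LargeAreaEmphasis = s$large,
    GrayLevelNonUniformity = s$gln,
    GrayLevelNonUniformityNormalized = s$glnn,
    SizeZoneNonUniformity = s$szn,
    SizeZoneNonUniformityNormalized = s$sznn,
    ZonePercentage = s$n_runs / n_vox,
    GrayLevelVariance = s$glv,
    ZoneVariance = s$szv,
    ZoneEntropy = s$ent,
    LowGrayLevelZoneEmphasis = s$lgl,
    HighGrayLevelZoneEmphasis = s$hgl,
    SmallAreaLowGrayLevelEmphasis = s$slgl,
    SmallAreaHighGrayLevelEmphasis = s$shgl,
    LargeAreaLowGrayLevelEmphasis = s$llgl,
    LargeAreaHighGrayLevelEmphasis = s$lhgl)
}

# ---- GLDM -------------------------------------------------------------------

gldm_features <- function(q, n_bins, alpha = 0) {
  offs <- all_neighbor_offsets()
  dep <- array(0L, dim(q))
  for (k in seq_len(nrow(offs))) {
    pr_dims <- dim(q)
    d <- offs[k, ]
    rng <- purrr::map2(pr_dims, d, function(n, dd) {
      if (dd >= 0) seq_len(n - dd) else seq(1 - dd, n)
    })
    a <- q[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
    b <- q[rng[[1]] + d[1], rng[[2]] + d[2], rng[[3]] + d[3], drop = FALSE]
    hit <- !is.na(a) & !is.na(b) & abs(a - b) <= alpha
    inc <- array(0L, dim(a))
    inc[hit] <- 1L
    dep[rng[[1]], rng[[2]], rng[[3]]] <- dep[rng[[1]], rng[[2]], rng[[3]]] + inc
  }
  ok <- !is.na(q)
  level <- q[ok]
  k_dep <- dep[ok] + 1L  # centre voxel counts as dependent
  counts <- matrix(unclass(table(factor(level, levels = seq_len(n_bins)),
                                 factor(k_dep, levels = seq_len(max(k_dep))))),
                   nrow = n_bins)
  s <- size_weighted_features(counts)
  c(SmallDependenceEmphasis = s$small,
    LargeDependenceEmphasis = s$large,
    GrayLevelNonUniformity = s$gln,
    DependenceNonUniformity = s$szn,
    DependenceNonUniformityNormalized = s$sznn,
    GrayLevelVariance = s$glv,
    DependenceVariance = s$szv,
    DependenceEntropy = s$ent,
    LowGrayLevelEmphasis = s$lgl,
    HighGrayLevelEmphasis = s$hgl,
    SmallDependenceLowGrayLevelEmphasis = s$slgl,
    SmallDependenceHighGrayLevelEmphasis = s$shgl,
    LargeDependenceLowGrayLevelEmphasis = s$llgl,
    LargeDependenceHighGrayLevelEmphasis = s$lhgl)
}

# ---- NGTDM ------------------------------------------------------------------

ngtdm_features <- function(q, n_bins) {
  offs <- all_neighbor_offsets()
  nb_sum <- array(0, dim(q))
  nb_cnt <- array(0L, dim(q))
  qz <- q
  qz[is.na(q)] <- 0
  inm <- !is.na(q)
  for (k in seq_len(nrow(offs))) {
    d <- offs[k, ]
    rng <- purrr::map2(dim(q), d, function(n, dd) {
      if (dd >= 0) seq_len(n - dd) else seq(1 - dd, n)
    })
    b_val <- qz[rng[[1]] + d[1], rng[[2]] + d[2], rng[[3]] + d[3], drop = FALSE]
    b_in <- inm[rng[[1]] + d[1], rng[[2]] + d[2], rng[[3]] + d[3], drop = FALSE]
    nb_sum[rng[[1]], rng[[2]], rng[[3]]] <-
      nb_sum[rng[[1]], rng[[2]], rng[[3]]] + b_val * b_in
    nb_cnt[rng[[1]], rng[[2]], rng[[3]]] <-
      nb_cnt[rng[[1]], rng[[2]], rng[[3]]] + b_in
  }
  ok <- inm & nb_cnt > 0
  g <- q[ok]
  a_bar <- nb_sum[ok] / nb_cnt[ok]
  n_tot <- length(g)
  lev <- seq_len(n_bins)
  n_i <- vapply(lev, function(l) sum(g == l), numeric(1))
  s_i <- vapply(lev, function(l) sum(abs(g[g == l] - a_bar[g == l])), numeric(1))
  p_i <- n_i / n_tot
  act <- p_i > 0
  ngp <- sum(act)
  iv <- lev[act]; pv <- p_i[act]; sv <- s_i[act]

  coars_den <- sum(pv * sv)
  coarseness <- if (coars_den > 0) 1 / coars_den else 1e6
  contrast <- if (ngp > 1) {
    sum(outer(pv, pv) * outer(iv, iv, "-")^2) / (ngp * (ngp - 1)) *
      sum(sv) / n_tot
  } else 0
  busy_den <- sum(abs(outer(iv * pv, iv * pv, "-")))
  busyness <- if (busy_den > 0) sum(pv * sv) / busy_den else 0
  complexity <- if (n_tot > 0 && ngp > 1) {
    pi_m <- outer(pv, pv, "+")
    num <- abs(outer(iv, iv, "-")) * outer(pv * sv, pv * sv, "+") / pi_m
    sum(num) / n_tot
  } else 0
  strength <- if (sum(sv) > 0) {
    sum(outer(pv, pv, "+") * outer(iv, iv, "-")^2) / sum(sv)
  } else 0
  c(Coarseness = coarseness, Contrast = contrast, Busyness = busyness,
    Complexity = complexity, Strength = strength)
}
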