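#' Discretize in-mask intensities into gray levels
#'
#' Equal-width bins between the in-mask minimum and maximum; the maximum
#' value is assigned to the top bin. Invariant under positive affine
#' transforms of the intensities.
#'
#' @param volume 3D numeric array.
#' @param mask 3D binary array or [lesion_mask()].
#' @param n_bins Number of gray levels (default 32).
#' @return A `discretized_image`: `levels` (3D integer array, 0 outside the
#'   mask, 1..n_bins inside), `n_levels`, `bin_edges`.
#' @export
discretize <- function(volume, mask, n_bins = 32L) {
  if (inherits(mask, "lesion_mask")) mask <- mask$mask
  stopifnot(identical(dim(volume), dim(mask)), n_bins >= 2)
  idx <- which(mask != 0)
  if (length(idx) == 0) stop("mask is empty")
  v <- volume[idx]
  rng <- range(v)
  if (rng[1] == rng[2]) {
    stop("constant region: texture families are undefined, skip them")
  }
  width <- diff(rng) / n_bins
  lev <- pmin(as.integer(floor((v - rng[1]) / width)) + 1L, as.integer(n_bins))
  levels <- array(0L, dim(volume))
  levels[idx] <- lev
  structure(
    list(levels = levels, n_levels = as.integer(n_bins),
         bin_edges = seq(rng[1], rng[2], length.out = n_bins + 1)),
    class = "discretized_image"
  )
}

#' First-order intensity statistics (18 features)
#'
#' IBSI-consistent first-order set computed from the raw in-mask
#' intensities; Entropy and Uniformity use the discretized histogram.
#' Percentiles use linear interpolation (quantile type 7). Variance,
#' skewness and kurtosis are population moments; kurtosis is not
#' excess-corrected. Constant regions get skewness/kurtosis 0.
#'
#' @param volume 3D numeric array.
#' @param mask 3D binary array or [lesion_mask()].
#' @param discretized Optional [discretize()] result (reused if supplied).
#' @param spacing_mm Voxel spacing, for TotalEnergy.
#' @param n_bins Bins for the entropy histogram when `discretized` is NULL.
#' @return Named numeric vector of 18 features.
#' @export
first_order_features <- function(volume, mask, discretized = NULL,
                                 spacing_mm = c(1, 1, 1), n_bins = 32L) {
  if (inherits(mask, "lesion_mask")) mask <- mask$mask
  idx <- which(mask != 0)
  if (length(idx) == 0) stop("mask is empty")
  v <- volume[idx]
  n <- length(v)
  mu <- mean(v)
  m2 <- mean((v - mu)^2)
  p <- if (!is.null(discretized)) {
    tabulate(discretized$levels[idx], discretized$n_levels) / n
  } else if (diff(range(v)) == 0) {
    1
  } else {
    tabulate(discretize(volume, mask, n_bins)$levels[idx], n_bins) / n
  }
  p <- p[p > 0]
  q <- quantile(v, c(0.1, 0.25, 0.75, 0.9), names = FALSE)
  inner <- v[v >= q[1] & v <= q[4]]
  voxvol <- prod(spacing_mm)
  c(
    Energy = sum(v^2),
    TotalEnergy = voxvol * sum(v^2),
    Entropy = -sum(p * log2(p)),
    Minimum = min(v),
    `10Percentile` = q[1],
    `90Percentile` = q[4],
    Maximum = max(v),
    Mean = mu,
    Median = median(v),
    InterquartileRange = q[3] - q[2],
    Range = max(v) - min(v),
    MeanAbsoluteDeviation = mean(abs(v - mu)),
    RobustMeanAbsoluteDeviation = mean(abs(inner - mean(inner))),
    RootMeanSquared = sqrt(mean(v^2)),
    Skewness = if (m2 == 0) 0 else mean((v - mu)^3) / m2^1.5,
    Kurtosis = if (m2 == 0) 0 else mean((v - mu)^4) / m2^2,
    Variance = m2,
    Uniformity = sum(p^2)
  )
}

# Surface voxels: in-mask voxels with at least one out-of-mask 6-neighbour
# (grid borders count as outside).
surface_voxels <- function(mask) {
  d <- dim(mask)
  padded <- array(0L, d + 2)
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- (mask != 0) * 1L
  sub <- function(i, j, k) padded[i, j, k, drop = FALSE]
  core <- sub(2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1))
  nb6 <- sub(1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)) +
    sub(3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)) +
    sub(2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)) +
    sub(2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)) +
    sub(2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]) +
    sub(2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2))
  list(surface = core == 1L & nb6 < 6L, exposed_faces = core * (6L - nb6))
}

max_pairwise_dist <- function(pts) {
  if (nrow(pts) < 2) return(0)
  max(stats::dist(pts))
}

#' Shape features (14 features)
#'
#' Voxel-based conventions throughout: volume is voxel count times voxel
#' volume (the "mesh" volume coincides with it under these conventions);
#' surface area counts exposed voxel faces; diameters are maximal pairwise
#' distances between surface-voxel centres (per plane for the 2D
#' diameters); axis lengths derive from the eigenvalues of the physical
#' voxel-coordinate covariance (4*sqrt(lambda)). Values depend only on the
#' mask, never on intensities. Expect voxel-based surface/diameter values
#' to sit slightly above mesh-based tools' output.
#'
#' @param mask 3D binary array or [lesion_mask()].
#' @param spacing_mm Voxel spacing in mm.
#' @return Named numeric vector of 14 features.
#' @export
shape_features <- function(mask, spacing_mm = c(1, 1, 1)) {
  if (inherits(mask, "lesion_mask")) mask <- mask$mask
  n <- sum(mask != 0)
  if (n == 0) stop("mask is empty")
  sp <- as.numeric(spacing_mm)
  voxvol <- prod(sp)
  volume <- n * voxvol
  sv <- surface_voxels(mask)
  face_area <- c(sp[2] * sp[3], sp[1] * sp[3], sp[1] * sp[2])
  # exposed faces per axis pair: recount by direction for correct areas
  d <- dim(mask)
  m <- (mask != 0) * 1L
  pad <- function(shift_axis, dir) {
    idx <- lapply(1:3, function(a) seq_len(d[a]))
    idx[[shift_axis]] <- idx[[shift_axis]] + dir
    valid <- idx[[shift_axis]] >= 1 & idx[[shift_axis]] <= d[shift_axis]
    out <- array(0L, d)
    src <- lapply(1:3, function(a) if (a == shift_axis) idx[[a]][valid] else idx[[a]])
    dst <- lapply(1:3, function(a) if (a == shift_axis) which(valid) else idx[[a]])
    out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    out
  }
  area <- 0
  for (ax in 1:3) {
    for (dir in c(-1L, 1L)) {
      exposed <- m == 1L & pad(ax, dir) == 0L
      area <- area + sum(exposed) * face_area[ax]
    }
  }
  coords <- sweep(mask_coords(m), 2, sp, `*`) # physical mm coordinates
  surf_pts <- sweep(mask_coords(sv$surface * 1L), 2, sp, `*`)
  if (nrow(surf_pts) == 0) surf_pts <- coords
  max3d <- max_pairwise_dist(surf_pts)
  max2d <- function(drop_axis) {
    keep <- setdiff(1:3, drop_axis)
    planes <- split.data.frame(surf_pts[, keep, drop = FALSE], surf_pts[, drop_axis])
    max(vapply(planes, function(p) max_pairwise_dist(as.matrix(p)), numeric(1)))
  }
  if (n >= 2) {
    ev <- sort(eigen(stats::cov(coords) * (n - 1) / n, symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    ev <- pmax(ev, 0)
  } else {
    ev <- c(0, 0, 0)
  }
  axes <- 4 * sqrt(ev)
  c(
    MeshVolume = volume,
    VoxelVolume = volume,
    SurfaceArea = area,
    SurfaceVolumeRatio = area / volume,
    Sphericity = (pi^(1 / 3)) * (6 * volume)^(2 / 3) / area,
    Maximum3DDiameter = max3d,
    Maximum2DDiameterSlice = max2d(3),
    Maximum2DDiameterColumn = max2d(1),
    Maximum2DDiameterRow = max2d(2),
    MajorAxisLength = axes[1],
    MinorAxisLength = axes[2],
    LeastAxisLength = axes[3],
    Elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0,
    Flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0
  )
}
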