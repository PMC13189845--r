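#' Specification of a single lesion phantom
#'
#' Describes one synthetic lesion: an ellipsoidal lesion on a regular voxel
#' grid, partitioned into contiguous angular sectors, one per tissue
#' signature, with sector voxel counts proportional to `volume_fractions`.
#' Voxel values are the signature mean plus a per-site additive shift,
#' multiplied by a smooth low-frequency bias field, plus Gaussian noise.
#'
#' @param grid_shape Integer vector of 3 positive grid dimensions (voxels).
#' @param spacing_mm Numeric vector of 3 positive voxel spacings in mm.
#' @param lesion_radius_mm Lesion radius in mm; a single value gives a
#'   sphere, a length-3 vector an axis-aligned ellipsoid.
#' @param signatures List of [habitat_signature()] objects.
#' @param volume_fractions Simplex weights over signatures (sum to 1).
#' @param class_label `"positive"` (malignant) or `"negative"` (benign).
#' @param site_id Site/scanner label.
#' @param site_shift Additive per-channel offset `c(t1, t2, adc)` applied
#'   before the bias field, modelling a scanner/site effect.
#' @param bias_amplitude Magnitude of the multiplicative low-frequency bias
#'   field (>= 0); 0 disables it.
#' @param background Per-channel mean `c(t1, t2, adc)` of the surrounding
#'   body tissue (also modulated by the bias field), so bias estimation has
#'   anatomy outside the lesion to work with; `NULL` leaves the background
#'   at zero.
#' @param min_subregion_voxels Minimum planted subregion size; specs whose
#'   sectors fall below this are rejected.
#' @param seed Integer seed; generation is a pure function of the spec.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(grid_shape = c(40L, 40L, 40L),
                         spacing_mm = c(1, 1, 1),
                         lesion_radius_mm = 10,
                         signatures = default_signatures(),
                         volume_fractions = c(0.4, 0.35, 0.25),
                         class_label = c("negative", "positive"),
                         site_id = "site_A",
                         site_shift = c(0, 0, 0),
                         bias_amplitude = 0,
                         background = c(1.0, 1.0, 1.2),
                         min_subregion_voxels = 64L,
                         seed = 1L) {
  class_label <- match.arg(class_label)
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 1))
  if (length(spacing_mm) != 3 || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0)) {
    stop("spacing_mm must be 3 positive numbers")
  }
  if (length(lesion_radius_mm) == 1) lesion_radius_mm <- rep(lesion_radius_mm, 3)
  stopifnot(length(lesion_radius_mm) == 3, all(lesion_radius_mm > 0))
  if (!is.list(signatures) || length(signatures) < 1) stop("need at least one signature")
  if (inherits(signatures, "habitat_signature")) signatures <- list(signatures)
  if (length(volume_fractions) != length(signatures)) {
    stop("volume_fractions must match the number of signatures")
  }
  if (abs(sum(volume_fractions) - 1) > 1e-9) stop("volume_fractions must sum to 1")
  if (any(volume_fractions <= 0)) stop("volume_fractions must be positive")
  if (bias_amplitude < 0) stop("bias_amplitude must be >= 0")
  # lesion must fit: centre at the grid midpoint, radius within half-extents
  centre <- (grid_shape - 1) / 2 * spacing_mm
  half_extent <- (grid_shape - 1) / 2 * spacing_mm
  if (any(lesion_radius_mm > half_extent)) {
    stop("lesion does not fit inside the grid")
  }
  structure(
    list(grid_shape = grid_shape, spacing_mm = as.numeric(spacing_mm),
         lesion_radius_mm = as.numeric(lesion_radius_mm),
         signatures = signatures, volume_fractions = as.numeric(volume_fractions),
         class_label = class_label, site_id = site_id,
         site_shift = as.numeric(site_shift), bias_amplitude = bias_amplitude,
         background = if (is.null(background)) NULL else as.numeric(background),
         min_subregion_voxels = as.integer(min_subregion_voxels),
         seed = as.integer(seed), centre_mm = centre),
    class = "phantom_spec"
  )
}

#' Multiparametric volume container
#'
#' @param t1,t2,adc 3D numeric arrays on a common grid.
#' @param spacing_mm Voxel spacing (3 positive reals, mm).
#' @param orientation Axis-order code (default `"RAS"`).
#' @return An `mp_volume` object.
#' @export
mp_volume <- function(t1, t2, adc, spacing_mm = c(1, 1, 1), orientation = "RAS") {
  dims <- dim(t1)
  if (!identical(dims, dim(t2)) || !identical(dims, dim(adc))) {
    stop("channel arrays must share one grid")
  }
  if (any(!is.finite(t1)) || any(!is.finite(t2)) || any(!is.finite(adc))) {
    stop("channels must be finite")
  }
  structure(list(t1 = t1, t2 = t2, adc = adc,
                 spacing_mm = as.numeric(spacing_mm), orientation = orientation),
            class = "mp_volume")
}

#' Lesion mask container
#'
#' @param mask 3D binary array (1 inside the lesion).
#' @param truth_labels Optional 3D integer array of planted subregion ids
#'   (0 outside the mask).
#' @return A `lesion_mask` object.
#' @export
lesion_mask <- function(mask, truth_labels = NULL) {
  if (sum(mask != 0) == 0) stop("mask is empty")
  if (!is.null(truth_labels)) {
    if (!identical(dim(mask), dim(truth_labels))) stop("truth_labels grid mismatch")
    if (!all((truth_labels != 0) == (mask != 0))) {
      stop("truth_labels must be nonzero exactly on the mask support")
    }
  }
  structure(list(mask = (mask != 0) * 1L, truth_labels = truth_labels),
            class = "lesion_mask")
}

# Smooth low-frequency multiplicative field on normalized [-1,1]^3
# coordinates: a random linear gradient plus a mild quadratic cross-term,
# scaled so |field| <= amplitude.
bias_field <- function(grid_shape, amplitude) {
  if (amplitude == 0) return(array(0, grid_shape))
  dir <- rnorm(3)
  dir <- dir / sqrt(sum(dir^2))
  u <- lapply(grid_shape, function(n) {
    if (n == 1) 0 else seq(-1, 1, length.out = n)
  })
  f <- outer(outer(u[[1]] * dir[1], u[[2]] * dir[2], `+`), u[[3]] * dir[3], `+`)
  q <- outer(outer(u[[1]], u[[2]]), rep(1, grid_shape[3])) # x*y cross term
  raw <- f / sqrt(3) + 0.3 * q
  amplitude * raw / max(abs(raw))
}

#' Generate a multiparametric lesion phantom
#'
#' Builds the ellipsoidal lesion described by a [phantom_spec()]: lesion
#' voxels are partitioned into contiguous azimuthal sectors with voxel
#' counts proportional to the volume fractions (largest-remainder rounding,
#' exact to the voxel), and each channel value is drawn as
#' `(signature mean + site_shift) * (1 + bias) + N(0, sd)`.
#'
#' @param spec A [phantom_spec()].
#' @return List with elements `volume` ([mp_volume()]) and `mask`
#'   ([lesion_mask()] carrying the planted `truth_labels`).
#' @examples
#' ph <- make_phantom(phantom_spec(seed = 7))
#' table(ph$mask$truth_labels[ph$mask$mask == 1])
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  gs <- spec$grid_shape
  sp <- spec$spacing_mm
  centre <- spec$centre_mm
  ax <- lapply(1:3, function(a) ((seq_len(gs[a]) - 1) * sp[a] - centre[a]) / spec$lesion_radius_mm[a])
  d2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  inside <- d2 <= 1
  n_vox <- sum(inside)
  if (n_vox == 0) stop("lesion mask is empty")

  idx <- which(inside)
  coord <- arrayInd(idx, gs)
  dx <- (coord[, 1] - 1) * sp[1] - centre[1]
  dy <- (coord[, 2] - 1) * sp[2] - centre[2]
  theta <- atan2(dy, dx)

  n_sig <- length(spec$signatures)
  counts <- floor(spec$volume_fractions * n_vox)
  rem <- spec$volume_fractions * n_vox - counts
  short <- n_vox - sum(counts)
  if (short > 0) {
    add <- order(rem, decreasing = TRUE)[seq_len(short)]
    counts[add] <- counts[add] + 1L
  }
  if (any(counts < spec$min_subregion_voxels)) {
    stop(sprintf(
      "planted subregion of %d voxels is below the %d-voxel minimum",
      min(counts), spec$min_subregion_voxels
    ))
  }
  ord <- order(theta)
  labels_vec <- integer(n_vox)
  labels_vec[ord] <- rep.int(seq_len(n_sig), counts)

  truth <- array(0L, gs)
  truth[idx] <- labels_vec
  mask_arr <- array(0L, gs)
  mask_arr[idx] <- 1L

  with_seed(spec$seed, {
    bias <- bias_field(gs, spec$bias_amplitude)
    chans <- list(t1 = 1L, t2 = 2L, adc = 3L)
    vols <- lapply(names(chans), function(ch) {
      mu <- vapply(spec$signatures, function(s) s[[paste0("mean_", ch)]], numeric(1))
      sds <- vapply(spec$signatures, function(s) s$sd, numeric(1))
      shift <- spec$site_shift[chans[[ch]]]
      if (is.null(spec$background)) {
        v <- array(0, gs)
      } else {
        bg <- spec$background[chans[[ch]]]
        v <- (bg + shift) * (1 + bias) + array(rnorm(length(bias), 0, 0.1), gs)
      }
      v[idx] <- (mu[labels_vec] + shift) * (1 + bias[idx]) +
        rnorm(n_vox, 0, sds[labels_vec])
      v
    })
    names(vols) <- names(chans)
    list(
      volume = mp_volume(vols$t1, vols$t2, vols$adc, spacing_mm = sp),
      mask = lesion_mask(mask_arr, truth)
    )
  })
}
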