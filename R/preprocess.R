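#' Preprocessing configuration
#'
#' @param target_spacing_mm Isotropic target spacing (default 1 mm).
#' @param interpolation_order Spline order for image resampling: 0
#'   (nearest), 1 (trilinear) or 3 (cubic). Masks always use order 0.
#' @param bias_poly_degree Polynomial degree of the log-domain bias
#'   estimator (>= 0).
#' @param standardize_per_patient Z-score in-mask intensities per channel
#'   and patient before clustering.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(target_spacing_mm = c(1, 1, 1),
                              interpolation_order = 3L,
                              bias_poly_degree = 2L,
                              standardize_per_patient = TRUE) {
  if (any(target_spacing_mm <= 0)) stop("target spacing must be positive")
  if (!interpolation_order %in% c(0L, 1L, 3L)) {
    stop("interpolation_order must be 0, 1 or 3")
  }
  structure(list(target_spacing_mm = as.numeric(target_spacing_mm),
                 interpolation_order = as.integer(interpolation_order),
                 bias_poly_degree = as.integer(bias_poly_degree),
                 standardize_per_patient = isTRUE(standardize_per_patient)),
            class = "preprocess_config")
}

# Monomial design matrix of total degree <= d over normalized coordinates.
poly_design <- function(coords, degree) {
  terms <- list()
  for (a in 0:degree) for (b in 0:(degree - a)) for (cc in 0:(degree - a - b)) {
    terms[[length(terms) + 1]] <- coords[, 1]^a * coords[, 2]^b * coords[, 3]^cc
  }
  do.call(cbind, terms)
}

#' Low-frequency bias-field correction
#'
#' Estimates a smooth multiplicative intensity non-uniformity by fitting a
#' polynomial of total degree `degree` in normalized voxel coordinates to
#' the log-intensities inside the mask (ordinary least squares), divides the
#' whole volume by the exponentiated fitted field, and rescales so the
#' in-mask median is unchanged. This is a deliberately simple log-domain
#' polynomial estimator standing in the usual place of N4 in the pipeline;
#' the interface allows a full N4 implementation to be swapped in.
#'
#' @param volume 3D numeric array.
#' @param mask 3D binary array or [lesion_mask()]; the field is fitted to
#'   voxels where the mask is 1.
#' @param degree Polynomial total degree (>= 0).
#' @return Corrected 3D array, with attributes `shift` (additive offset
#'   applied to make in-mask intensities positive, 0 if none was needed)
#'   and `field_coef` (fitted coefficients).
#' @export
correct_bias <- function(volume, mask, degree = 2L) {
  if (inherits(mask, "lesion_mask")) mask <- mask$mask
  stopifnot(identical(dim(volume), dim(mask)))
  degree <- as.integer(degree)
  if (degree < 0) stop("degree must be >= 0")
  idx <- which(mask != 0)
  if (length(idx) == 0) stop("mask is empty")
  v <- volume
  mn <- min(v[idx])
  shift <- 0
  if (mn <= 0) {
    shift <- -mn + 1e-6 * max(abs(v[idx]), 1)
    v <- v + shift
  }
  gs <- dim(v)
  n_terms <- choose(degree + 3, 3)
  if (length(idx) < n_terms) {
    stop("degenerate fit: fewer in-mask voxels than polynomial terms")
  }
  coord <- arrayInd(idx, gs)
  norm_coord <- sweep(sweep(coord - 1, 2, pmax(gs - 1, 1) / 2, `/`), 2, 1, `-`)
  X <- poly_design(norm_coord, degree)
  fit <- lm.fit(X, log(v[idx]))
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  all_coord <- arrayInd(seq_along(v), gs)
  all_norm <- sweep(sweep(all_coord - 1, 2, pmax(gs - 1, 1) / 2, `/`), 2, 1, `-`)
  field <- exp(poly_design(all_norm, degree) %*% beta)
  corrected <- array(as.vector(v) / as.vector(field), gs)
  scale <- median(v[idx]) / median(corrected[idx])
  out <- corrected * scale
  attr(out, "shift") <- shift
  attr(out, "field_coef") <- beta
  out
}

# Interpolation weights of one axis: rows = output samples, cols = input.
# Catmull-Rom cubic (order 3), linear (order 1) or nearest (order 0), with
# clamped borders. Positions are voxel centres at index * spacing.
axis_weights <- function(n_in, spacing_in, n_out, spacing_out, order) {
  W <- matrix(0, n_out, n_in)
  pos <- (seq_len(n_out) - 1) * spacing_out / spacing_in # in input index units
  clampi <- function(i) pmin(pmax(i, 0L), n_in - 1L)
  for (r in seq_len(n_out)) {
    t <- pos[r]
    if (order == 0L) {
      W[r, clampi(as.integer(floor(t + 0.5))) + 1] <- 1
    } else if (order == 1L) {
      i0 <- floor(t); f <- t - i0
      ii <- clampi(as.integer(c(i0, i0 + 1))) + 1
      W[r, ii[1]] <- W[r, ii[1]] + (1 - f)
      W[r, ii[2]] <- W[r, ii[2]] + f
    } else {
      i0 <- floor(t); f <- t - i0
      # Catmull-Rom kernel over the 4 nearest samples
      w <- c(
        -0.5 * f^3 + f^2 - 0.5 * f,
        1.5 * f^3 - 2.5 * f^2 + 1,
        -1.5 * f^3 + 2 * f^2 + 0.5 * f,
        0.5 * f^3 - 0.5 * f^2
      )
      ii <- clampi(as.integer(i0 + (-1:2))) + 1
      for (q in 1:4) W[r, ii[q]] <- W[r, ii[q]] + w[q]
    }
  }
  W
}

apply_axis <- function(arr, W, axis) {
  d <- dim(arr)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  a <- aperm(arr, perm)
  da <- dim(a)
  m <- W %*% matrix(a, nrow = da[1])
  out <- array(m, c(nrow(W), da[2], da[3]))
  aperm(out, order(perm))
}

#' Resample a volume to a target (isotropic) spacing
#'
#' Separable interpolation onto a grid covering the same physical extent;
#' voxel centres sit at `index * spacing` (0-based indices). Images use the
#' configured spline order (cubic by default), masks nearest-neighbour.
#'
#' @param volume 3D numeric array.
#' @param spacing_in Input voxel spacing (3 positive reals, mm).
#' @param config A [preprocess_config()], or a target spacing vector.
#' @param is_mask Resample as a label image (order 0, integer output).
#' @return Resampled array with attribute `spacing_mm`.
#' @export
resample_isotropic <- function(volume, spacing_in, config = preprocess_config(),
                               is_mask = FALSE) {
  if (is.numeric(config)) config <- preprocess_config(target_spacing_mm = config)
  if (any(spacing_in <= 0)) stop("input spacing must be positive")
  if (any(!is.finite(volume))) stop("volume contains non-finite values")
  sp_out <- config$target_spacing_mm
  order <- if (is_mask) 0L else config$interpolation_order
  d_in <- dim(volume)
  d_out <- pmax(1L, as.integer(round(d_in * spacing_in / sp_out)))
  out <- volume
  for (ax in 1:3) {
    if (d_out[ax] == d_in[ax] && spacing_in[ax] == sp_out[ax]) next
    W <- axis_weights(d_in[ax], spacing_in[ax], d_out[ax], sp_out[ax], order)
    out <- apply_axis(out, W, ax)
    d_in[ax] <- d_out[ax] # dims updated as axes are processed
  }
  if (is_mask) {
    out <- array(as.integer(round(out)), dim(out))
  }
  attr(out, "spacing_mm") <- sp_out
  out
}

#' Z-score in-mask intensities
#'
#' Standardizes the voxel intensities inside the mask to mean 0 and unit
#' population SD (per channel, per patient); voxels outside the mask are
#' untouched.
#' Used to put the three channels on a common scale before voxel
#' clustering, so the ADC channel's numeric scale cannot dominate the
#' k-means metric.
#'
#' @param volume 3D numeric array.
#' @param mask 3D binary array or [lesion_mask()].
#' @return Array with standardized in-mask values.
#' @export
standardize_roi_intensities <- function(volume, mask) {
  if (inherits(mask, "lesion_mask")) mask <- mask$mask
  stopifnot(identical(dim(volume), dim(mask)))
  idx <- which(mask != 0)
  if (length(idx) == 0) stop("mask is empty")
  v <- volume[idx]
  s <- sqrt(mean((v - mean(v))^2)) # population SD
  if (!is.finite(s) || s == 0) {
    stop("constant in-mask channel: exclude this channel rather than standardizing")
  }
  out <- volume
  out[idx] <- (v - mean(v)) / s
  out
}

# Full per-patient preprocessing: bias correction, resampling to the target
# grid (mask nearest-neighbour, truth labels carried along), and optional
# z-scored copies for clustering.
preprocess_patient <- function(phantom, config = preprocess_config()) {
  vol <- phantom$volume; msk <- phantom$mask
  sp_in <- vol$spacing_mm
  chans <- list()
  for (ch in c("t1", "t2", "adc")) {
    # the bias field is estimated over the whole body region, not the
    # lesion: fitting inside the ROI would absorb genuine tissue contrast
    body <- array(1L, dim(vol[[ch]]))
    body[vol[[ch]] <= 0] <- 0L
    corrected <- correct_bias(vol[[ch]], body, degree = config$bias_poly_degree)
    chans[[ch]] <- resample_isotropic(corrected, sp_in, config)
  }
  mask_rs <- resample_isotropic(msk$mask, sp_in, config, is_mask = TRUE)
  truth_rs <- NULL
  if (!is.null(msk$truth_labels)) {
    truth_rs <- resample_isotropic(msk$truth_labels, sp_in, config, is_mask = TRUE)
    truth_rs[mask_rs == 0] <- 0L
    # NN resampling can strand mask voxels with no label; fill from mask
    if (any(truth_rs[mask_rs != 0] == 0)) truth_rs[mask_rs != 0 & truth_rs == 0] <- 1L
  }
  volume <- mp_volume(chans$t1, chans$t2, chans$adc,
                      spacing_mm = config$target_spacing_mm)
  standardized <- NULL
  if (config$standardize_per_patient) {
    standardized <- mp_volume(
      standardize_roi_intensities(chans$t1, mask_rs),
      standardize_roi_intensities(chans$t2, mask_rs),
      standardize_roi_intensities(chans$adc, mask_rs),
      spacing_mm = config$target_spacing_mm
    )
  }
  list(volume = volume, mask = lesion_mask(mask_rs, truth_rs),
       standardized = standardized)
}
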