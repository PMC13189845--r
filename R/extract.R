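#' Feature extraction configuration
#'
#' @param n_bins Gray levels for discretization (default 32; with per-region
#'   equal-width binning a fixed bin count is the natural choice because
#'   channel scales are arbitrary).
#' @param families Feature families to compute.
#' @param gldm_alpha Gray-level tolerance for the dependence matrix.
#' @return A `feature_config` list.
#' @export
feature_config <- function(n_bins = 32L,
                           families = c("firstorder", "shape", "glcm", "glrlm",
                                        "glszm", "gldm", "ngtdm"),
                           gldm_alpha = 0L) {
  structure(list(n_bins = as.integer(n_bins), families = families,
                 gldm_alpha = as.integer(gldm_alpha)),
            class = "feature_config")
}

sequence_names <- c(t1 = "T1WI", t2 = "T2WI", adc = "ADC")

family_feature_names <- function() {
  list(
    firstorder = c("Energy", "TotalEnergy", "Entropy", "Minimum", "10Percentile",
                   "90Percentile", "Maximum", "Mean", "Median",
                   "InterquartileRange", "Range", "MeanAbsoluteDeviation",
                   "RobustMeanAbsoluteDeviation", "RootMeanSquared", "Skewness",
                   "Kurtosis", "Variance", "Uniformity"),
    shape = c("MeshVolume", "VoxelVolume", "SurfaceArea", "SurfaceVolumeRatio",
              "Sphericity", "Maximum3DDiameter", "Maximum2DDiameterSlice",
              "Maximum2DDiameterColumn", "Maximum2DDiameterRow",
              "MajorAxisLength", "MinorAxisLength", "LeastAxisLength",
              "Elongation", "Flatness"),
    glcm = c("Autocorrelation", "JointAverage", "ClusterProminence",
             "ClusterShade", "ClusterTendency", "Contrast", "Correlation",
             "DifferenceAverage", "DifferenceEntropy", "DifferenceVariance",
             "Id", "Idm", "Idmn", "Idn", "Imc1", "Imc2", "InverseVariance",
             "JointEnergy", "JointEntropy", "MaximumProbability", "MCC",
             "SumAverage", "SumEntropy", "SumSquares"),
    glrlm = c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
              "GrayLevelVariance", "HighGrayLevelRunEmphasis",
              "LongRunEmphasis", "LongRunHighGrayLevelEmphasis",
              "LongRunLowGrayLevelEmphasis", "LowGrayLevelRunEmphasis",
              "RunEntropy", "RunLengthNonUniformity",
              "RunLengthNonUniformityNormalized", "RunPercentage",
              "RunVariance", "ShortRunEmphasis", "ShortRunHighGrayLevelEmphasis",
              "ShortRunLowGrayLevelEmphasis"),
    glszm = c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
              "GrayLevelVariance", "HighGrayLevelZoneEmphasis",
              "LargeAreaEmphasis", "LargeAreaHighGrayLevelEmphasis",
              "LargeAreaLowGrayLevelEmphasis", "LowGrayLevelZoneEmphasis",
              "SizeZoneNonUniformity", "SizeZoneNonUniformityNormalized",
              "SmallAreaEmphasis", "SmallAreaHighGrayLevelEmphasis",
              "SmallAreaLowGrayLevelEmphasis", "ZoneEntropy", "ZonePercentage",
              "ZoneVariance"),
    gldm = c("DependenceEntropy", "DependenceNonUniformity",
             "DependenceNonUniformityNormalized", "DependenceVariance",
             "GrayLevelNonUniformity", "GrayLevelVariance",
             "HighGrayLevelEmphasis", "LargeDependenceEmphasis",
             "LargeDependenceHighGrayLevelEmphasis",
             "LargeDependenceLowGrayLevelEmphasis", "LowGrayLevelEmphasis",
             "SmallDependenceEmphasis", "SmallDependenceHighGrayLevelEmphasis",
             "SmallDependenceLowGrayLevelEmphasis"),
    ngtdm = c("Coarseness", "Contrast", "Busyness", "Complexity", "Strength")
  )
}

#' Canonical feature-name schema
#'
#' Stable `{sequence}_{family}_{feature}` identifiers: 107 per sequence
#' (18 first-order, 14 shape, 24 GLCM, 16 GLRLM, 16 GLSZM, 14 GLDM,
#' 5 NGTDM), 321 across the three sequences.
#'
#' @param config A [feature_config()].
#' @return Character vector of feature names.
#' @export
feature_names <- function(config = feature_config()) {
  fam <- family_feature_names()[config$families]
  unlist(lapply(sequence_names, function(sq) {
    unlist(lapply(names(fam), function(f) paste(sq, f, fam[[f]], sep = "_")))
  }), use.names = FALSE)
}

# 107 features for one sequence volume restricted to one region mask.
# Shape depends only on the mask, so callers may pass a precomputed value
# shared across sequences.
extract_sequence <- function(volume, region_mask, spacing_mm, config,
                             shape_vals = NULL) {
  fam <- family_feature_names()
  n_vox <- sum(region_mask != 0)
  out <- list()
  disc <- NULL
  texture_ok <- n_vox >= 2 && diff(range(volume[region_mask != 0])) > 0
  if (texture_ok) disc <- discretize(volume, region_mask, config$n_bins)
  for (f in config$families) {
    vals <- switch(f,
      firstorder = first_order_features(volume, region_mask, disc, spacing_mm,
                                        config$n_bins),
      shape = shape_vals %||% shape_features(region_mask, spacing_mm),
      glcm = if (texture_ok) glcm_features(disc) else NULL,
      glrlm = if (texture_ok) glrlm_features(disc) else NULL,
      glszm = if (texture_ok) glszm_features(disc) else NULL,
      gldm = if (texture_ok) gldm_features(disc, alpha = config$gldm_alpha) else NULL,
      ngtdm = if (texture_ok) ngtdm_features(disc) else NULL
    )
    if (is.null(vals)) vals <- setNames(rep(NA_real_, length(fam[[f]])), fam[[f]])
    names(vals) <- paste(f, names(vals), sep = "_")
    out[[f]] <- vals
  }
  unlist(out, use.names = FALSE) |>
    setNames(unlist(lapply(config$families,
                           function(f) paste(f, fam[[f]], sep = "_"))))
}

#' Extract the full radiomic feature set for one patient
#'
#' Computes 107 features per sequence (T1WI, T2WI, ADC) for the whole
#' lesion and, when a habitat labelling is supplied, for each habitat —
#' 321 named values per region. Excluded (undersized) habitats yield
#' missing values; regions of fewer than 2 voxels or with constant
#' intensities get missing texture features while first-order and shape
#' are still computed.
#'
#' @param mpvolume An [mp_volume()] (preprocessed, unstandardized units).
#' @param mask_or_habitat A [lesion_mask()] / binary array (whole lesion
#'   only) or a `habitat_labeling` from [assign_habitats()].
#' @param config A [feature_config()].
#' @param patient_id Identifier recorded in the output.
#' @return Tibble, one row per region (`whole`, `habitat_1`, ...), with
#'   `patient_id`, `region` and one column per feature name.
#' @examples
#' ph <- make_phantom(phantom_spec(grid_shape = c(16, 16, 16),
#'                                 lesion_radius_mm = 5, seed = 2))
#' fx <- extract_all(ph$volume, ph$mask)
#' ncol(fx) - 2 # 321 feature columns
#' @export
extract_all <- function(mpvolume, mask_or_habitat, config = feature_config(),
                        patient_id = NA_character_) {
  regions <- list()
  if (inherits(mask_or_habitat, "habitat_labeling")) {
    hl <- mask_or_habitat
    regions$whole <- (hl$labels > 0) * 1L
    for (h in seq_len(hl$k)) {
      nm <- paste0("habitat_", h)
      if (h %in% hl$excluded_habitats) {
        regions[[nm]] <- NULL
        regions[nm] <- list(NULL) # excluded: row of missing values
      } else {
        regions[[nm]] <- (hl$labels == h) * 1L
      }
    }
  } else {
    m <- if (inherits(mask_or_habitat, "lesion_mask")) mask_or_habitat$mask else mask_or_habitat
    regions$whole <- (m != 0) * 1L
  }
  nms <- feature_names(config)
  sp <- mpvolume$spacing_mm
  rows <- purrr::imap(regions, function(region, region_name) {
    if (is.null(region)) {
      vals <- setNames(rep(NA_real_, length(nms)), nms)
    } else {
      shape_vals <- if ("shape" %in% config$families) {
        shape_features(region, sp)
      } else NULL
      vals <- unlist(lapply(c("t1", "t2", "adc"), function(ch) {
        v <- extract_sequence(mpvolume[[ch]], region, sp, config, shape_vals)
        setNames(v, paste(sequence_names[[ch]], names(v), sep = "_"))
      }))
      vals <- vals[nms]
    }
    dplyr::bind_cols(
      tibble::tibble(patient_id = patient_id, region = region_name),
      tibble::as_tibble(as.list(vals))
    )
  })
  dplyr::bind_rows(rows)
}

#' Extract features for a whole cohort
#'
#' @param phantoms Named list of `list(volume, mask)` patients (already
#'   preprocessed).
#' @param habitats Optional named list of `habitat_labeling` objects.
#' @param manifest Tibble with `patient_id`, `site`, `label` merged into
#'   the result.
#' @param config A [feature_config()].
#' @return Feature table tibble: one row per patient x region.
#' @export
extract_cohort_features <- function(phantoms, habitats = NULL, manifest = NULL,
                                    config = feature_config()) {
  tab <- dplyr::bind_rows(purrr::imap(phantoms, function(ph, id) {
    target <- if (!is.null(habitats)) habitats[[id]] else ph$mask
    extract_all(ph$volume, target, config, patient_id = id)
  }))
  if (!is.null(manifest)) {
    tab <- dplyr::left_join(tab,
                            dplyr::select(manifest, dplyr::all_of(c("patient_id", "site", "label"))),
                            by = "patient_id")
    tab <- dplyr::relocate(tab, dplyr::all_of(c("patient_id", "site", "label", "region")))
  }
  tab
}
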