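#' Write a cohort to NIfTI files plus a CSV manifest
#'
#' One `.nii.gz` file per channel and per mask, with voxel spacing encoded
#' in the header; masks are written as integers. The manifest lists
#' `patient_id, site, label, t1_path, t2_path, adc_path, mask_path` and is
#' also written to `manifest.csv` in `directory`.
#'
#' @param cohort Output of [make_cohort()] (elements `manifest`, `phantoms`).
#' @param directory Output directory (created if needed).
#' @return The manifest tibble with file-path columns, invisibly written to
#'   `manifest.csv`.
#' @export
write_nifti_dataset <- function(cohort, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  man <- cohort$manifest
  paths <- purrr::map(man$patient_id, function(id) {
    ph <- cohort$phantoms[[id]]
    if (!identical(dim(ph$volume$t1), dim(ph$mask$mask))) {
      stop("grid mismatch between volume and mask for ", id)
    }
    out <- list()
    for (ch in c("t1", "t2", "adc")) {
      f <- file.path(directory, sprintf("%s_%s.nii.gz", id, ch))
      write_nifti_volume(ph$volume[[ch]], ph$volume$spacing_mm, f)
      out[[paste0(ch, "_path")]] <- f
    }
    fm <- file.path(directory, sprintf("%s_mask.nii.gz", id))
    write_nifti_volume(ph$mask$mask, ph$volume$spacing_mm, fm, integer = TRUE)
    out$mask_path <- fm
    if (!is.null(ph$mask$truth_labels)) {
      ft <- file.path(directory, sprintf("%s_truth.nii.gz", id))
      write_nifti_volume(ph$mask$truth_labels, ph$volume$spacing_mm, ft, integer = TRUE)
      out$truth_path <- ft
    }
    tibble::as_tibble(out)
  })
  man <- dplyr::bind_cols(man, dplyr::bind_rows(paths))
  readr::write_csv(man, file.path(directory, "manifest.csv"))
  man
}

write_nifti_volume <- function(arr, spacing_mm, path, integer = FALSE) {
  img <- RNifti::asNifti(unclass(arr))
  RNifti::pixdim(img) <- spacing_mm
  ok <- try(RNifti::writeNifti(img, path,
                               datatype = if (integer) "int16" else "double"),
            silent = TRUE)
  if (inherits(ok, "try-error")) stop("failed to write NIfTI file: ", path)
  invisible(path)
}

read_nifti_volume <- function(path) {
  if (!file.exists(path)) stop("missing NIfTI file: ", path)
  img <- try(suppressWarnings(RNifti::readNifti(path)), silent = TRUE)
  if (inherits(img, "try-error")) stop("failed to read NIfTI file: ", path)
  a <- as.array(img)
  spacing <- as.numeric(RNifti::pixdim(img))
  attributes(a) <- list(dim = dim(a))
  list(data = a, spacing_mm = spacing)
}

#' Read a cohort back from a manifest
#'
#' Validates per-patient grid agreement across channels and mask, reports
#' voxel counts, and excludes patients whose mask is empty (the synthetic
#' analogue of a minimum-lesion-size exclusion criterion).
#'
#' @param manifest Path to a `manifest.csv` written by
#'   [write_nifti_dataset()], or the manifest tibble itself.
#' @return List with `manifest` (tibble incl. `n_voxels`), `phantoms`
#'   (named list of `volume` + `mask`) and `excluded` (tibble of skipped
#'   patients with reasons).
#' @export
read_cohort <- function(manifest) {
  if (is.character(manifest)) {
    manifest <- readr::read_csv(manifest, show_col_types = FALSE)
  }
  need <- c("patient_id", "site", "label", "t1_path", "t2_path", "adc_path", "mask_path")
  missing_cols <- setdiff(need, names(manifest))
  if (length(missing_cols)) {
    stop("manifest missing columns: ", paste(missing_cols, collapse = ", "))
  }
  phantoms <- list(); excluded <- list(); n_vox <- integer(nrow(manifest))
  for (r in seq_len(nrow(manifest))) {
    id <- manifest$patient_id[r]
    chans <- lapply(manifest[r, c("t1_path", "t2_path", "adc_path")], read_nifti_volume)
    msk <- read_nifti_volume(manifest$mask_path[[r]])
    dims <- lapply(c(chans, list(msk)), function(x) dim(x$data))
    if (length(unique(lapply(dims, as.integer))) != 1) {
      stop("grid mismatch across files for patient ", id)
    }
    truth <- NULL
    if ("truth_path" %in% names(manifest) && !is.na(manifest$truth_path[[r]])) {
      truth <- read_nifti_volume(manifest$truth_path[[r]])$data
      storage.mode(truth) <- "integer"
    }
    n_vox[r] <- sum(msk$data != 0)
    if (n_vox[r] == 0) {
      excluded[[id]] <- tibble::tibble(patient_id = id, reason = "empty lesion mask")
      next
    }
    phantoms[[id]] <- list(
      volume = mp_volume(chans[[1]]$data, chans[[2]]$data, chans[[3]]$data,
                         spacing_mm = chans[[1]]$spacing_mm),
      mask = lesion_mask(msk$data, truth)
    )
  }
  manifest$n_voxels <- n_vox
  list(
    manifest = manifest[manifest$n_voxels > 0, , drop = FALSE],
    phantoms = phantoms,
    excluded = dplyr::bind_rows(excluded)
  )
}
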