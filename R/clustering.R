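#' Build the voxel x modality matrix of a lesion
#'
#' One row per in-mask voxel in lexicographic (column-major) voxel-index
#' order, with fixed column order T1, T2, ADC. Channels are expected to be
#' standardized when the matrix is destined for clustering.
#'
#' @param mpvolume An [mp_volume()].
#' @param mask A [lesion_mask()] or 3D binary array.
#' @param patient_id Optional identifier carried along.
#' @return A `voxel_matrix` object: list with `values` (n x 3 matrix),
#'   `coords` (n x 3 0-based voxel indices) and `patient_id`.
#' @export
build_voxel_matrix <- function(mpvolume, mask, patient_id = NA_character_) {
  if (inherits(mask, "lesion_mask")) mask <- mask$mask
  stopifnot(identical(dim(mpvolume$t1), dim(mask)))
  idx <- which(mask != 0)
  if (length(idx) == 0) stop("mask is empty")
  values <- cbind(t1 = mpvolume$t1[idx], t2 = mpvolume$t2[idx],
                  adc = mpvolume$adc[idx])
  if (any(!is.finite(values))) stop("non-finite voxel values")
  structure(list(values = values, coords = mask_coords(mask),
                 index = idx, patient_id = patient_id),
            class = "voxel_matrix")
}

kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (j in seq_len(k - 1)) {
    p <- d2 / sum(d2)
    if (!all(is.finite(p)) || sum(d2) == 0) {
      pick <- sample.int(n, 1)
    } else {
      pick <- sample.int(n, 1, prob = p)
    }
    centers[j + 1, ] <- x[pick, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j + 1, ])^2))
  }
  centers
}

lloyd_once <- function(x, centers, max_iter, tol) {
  fit <- .lloyd(x, centers, as.integer(max_iter), tol)
  list(centers = fit$centers, labels = fit$labels, inertia = fit$inertia,
       n_iter = fit$n_iter)
}

#' K-means clustering of a voxel matrix
#'
#' Lloyd iterations from k-means++ initialization, best of `n_init`
#' restarts by within-cluster sum of squares; empty clusters are repaired
#' by reseeding at the farthest point. Deterministic for a fixed seed.
#'
#' @param matrix A `voxel_matrix` (from [build_voxel_matrix()]) or a plain
#'   numeric matrix.
#' @param k Number of clusters (>= 2, <= number of rows).
#' @param seed Integer seed.
#' @param n_init Number of restarts.
#' @param max_iter Maximum Lloyd iterations per restart.
#' @param tol Relative tolerance on the inertia decrease.
#' @return A `kmeans_result`: `k`, `centroids`, `labels` (1..k), `inertia`,
#'   `n_iter`, `seed`, plus the voxel `coords` when available.
#' @export
kmeans_fit <- function(matrix, k, seed = 1L, n_init = 10L, max_iter = 300L,
                       tol = 1e-4) {
  coords <- NULL; index <- NULL
  if (inherits(matrix, "voxel_matrix")) {
    coords <- matrix$coords; index <- matrix$index
    x <- matrix$values
  } else {
    x <- as.matrix(matrix)
  }
  n <- nrow(x)
  if (k < 1) stop("k must be >= 1")
  if (k > n) stop("k exceeds the number of voxels")
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_init)) {
      init <- kmeanspp_init(x, k)
      fit <- lloyd_once(x, init, max_iter, tol)
      if (is.null(best) || fit$inertia < best$inertia) best <- fit
    }
  })
  structure(
    list(k = as.integer(k), centroids = best$centers, labels = best$labels,
         inertia = best$inertia, n_iter = best$n_iter, seed = as.integer(seed),
         coords = coords, index = index),
    class = "kmeans_result"
  )
}

#' Calinski-Harabasz index
#'
#' Ratio of between-cluster to within-cluster dispersion normalized by
#' degrees of freedom: `[B/(k-1)] / [W/(n-k)]`, where
#' `B = sum_i n_i * ||c_i - c||^2` and `W` is the pooled within-cluster sum
#' of squares. `W = 0` returns `Inf`.
#'
#' @param matrix A `voxel_matrix` or numeric matrix.
#' @param labels Integer cluster labels (>= 2 distinct values).
#' @return The index value.
#' @export
calinski_harabasz <- function(matrix, labels) {
  x <- if (inherits(matrix, "voxel_matrix")) matrix$values else as.matrix(matrix)
  labels <- as.integer(factor(labels))
  k <- max(labels)
  n <- nrow(x)
  if (k < 2) stop("need at least 2 nonempty clusters")
  if (n <= k) stop("need n > k")
  sizes <- tabulate(labels, k)
  centers <- rowsum(x, labels) / sizes
  grand <- colMeans(x)
  B <- sum(sizes * rowSums(sweep(centers, 2, grand)^2))
  W <- sum((x - centers[labels, , drop = FALSE])^2)
  if (W == 0) return(Inf)
  (B / (k - 1)) / (W / (n - k))
}

# Argmax with ties broken toward the smaller k.
pick_k <- function(scores, ks) {
  ks[which.max(scores)]
}

#' Select the number of clusters by the Calinski-Harabasz index
#'
#' Fits k-means for each k in `k_range`, scores each labelling with
#' [calinski_harabasz()], and returns the argmax (ties toward smaller k)
#' together with the full score curve.
#'
#' @param matrix A `voxel_matrix` or numeric matrix.
#' @param k_range Candidate cluster numbers (default 2:10).
#' @param seed Integer seed (one k-means seed per k, derived).
#' @param ... Passed to [kmeans_fit()].
#' @return List with `k_best`, `scores` (tibble k, score) and `fits`.
#' @export
select_k <- function(matrix, k_range = 2:10, seed = 1L, ...) {
  n <- if (inherits(matrix, "voxel_matrix")) nrow(matrix$values) else nrow(matrix)
  if (n <= max(k_range)) stop("need more voxels than max(k_range)")
  fits <- lapply(k_range, function(k) {
    kmeans_fit(matrix, k, seed = derive_seed(seed, paste0("k", k)), ...)
  })
  scores <- vapply(fits, function(f) calinski_harabasz(matrix, f$labels), numeric(1))
  list(
    k_best = pick_k(scores, k_range),
    scores = tibble::tibble(k = as.integer(k_range), score = scores),
    fits = setNames(fits, paste0("k", k_range))
  )
}

#' Canonical habitat assignment
#'
#' Orders the clusters of a k-means labelling by DESCENDING mean raw ADC,
#' so the highest habitat index is the lowest-ADC (most cellular) habitat —
#' the "malignant triad" slot. Habitats smaller than `min_size` voxels are
#' flagged as excluded (their features are later set missing). The centroid
#' table is reported in raw (unstandardized) channel units.
#'
#' @param result A `kmeans_result` fitted on a voxel matrix with coords.
#' @param mask A [lesion_mask()] or 3D binary array.
#' @param raw_mpvolume The unstandardized [mp_volume()].
#' @param min_size Minimum habitat size in voxels (default 64).
#' @return A `habitat_labeling`: `labels` (3D integer array, 0 outside),
#'   `k`, `centroid_table` (tibble habitat, n_voxels, t1, t2, adc,
#'   excluded) and `excluded_habitats`.
#' @export
assign_habitats <- function(result, mask, raw_mpvolume, min_size = 64L) {
  if (inherits(mask, "lesion_mask")) mask <- mask$mask
  if (is.null(result$index)) stop("kmeans result lacks voxel coordinates")
  idx <- result$index
  if (length(idx) != sum(mask != 0)) stop("labels do not cover the mask")
  raw <- cbind(t1 = raw_mpvolume$t1[idx], t2 = raw_mpvolume$t2[idx],
               adc = raw_mpvolume$adc[idx])
  k <- result$k
  sizes <- tabulate(result$labels, k)
  cent_raw <- rowsum(raw, result$labels) / sizes
  ord <- order(cent_raw[, "adc"], decreasing = TRUE)
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  new_labels <- relabel[result$labels]
  labels3d <- array(0L, dim(mask))
  labels3d[idx] <- new_labels
  sizes_new <- sizes[ord]
  centroid_table <- tibble::tibble(
    habitat = seq_len(k),
    n_voxels = as.integer(sizes_new),
    t1 = cent_raw[ord, "t1"], t2 = cent_raw[ord, "t2"], adc = cent_raw[ord, "adc"],
    excluded = sizes_new < min_size
  )
  structure(
    list(labels = labels3d, k = as.integer(k), centroid_table = centroid_table,
         excluded_habitats = centroid_table$habitat[centroid_table$excluded]),
    class = "habitat_labeling"
  )
}

#' @export
tidy.habitat_labeling <- function(x, ...) x$centroid_table

#' Cohort-level cluster-number selection
#'
#' Runs [select_k()] per training patient and returns the modal optimum
#' across patients (ties toward the smaller k). All patients are then
#' expected to be re-clustered at this global k, which is what makes
#' habitat indices comparable across the cohort.
#'
#' @param matrices Named list of `voxel_matrix` objects (training patients).
#' @param k_range Candidate cluster numbers.
#' @param seed Integer seed.
#' @param ... Passed to [select_k()].
#' @return List with `k_global`, `per_patient` (tibble patient, k_best) and
#'   `curves` (tibble patient, k, score).
#' @export
cohort_k_selection <- function(matrices, k_range = 2:10, seed = 1L, ...) {
  if (length(matrices) == 0) stop("empty cohort")
  ids <- names(matrices) %||% as.character(seq_along(matrices))
  per <- purrr::imap(matrices, function(m, id) {
    sel <- select_k(m, k_range, seed = derive_seed(seed, id), ...)
    list(k_best = sel$k_best, scores = dplyr::mutate(sel$scores, patient_id = id))
  })
  k_best <- vapply(per, `[[`, integer(1), "k_best")
  tab <- table(k_best)
  modal <- min(as.integer(names(tab)[tab == max(tab)]))
  list(
    k_global = modal,
    per_patient = tibble::tibble(patient_id = ids, k_best = unname(k_best)),
    curves = dplyr::bind_rows(purrr::map(per, "scores"))
  )
}
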