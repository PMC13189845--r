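test_that("voxel matrix has one row per in-mask voxel in index order", {
  t1 <- array(seq_len(8), c(2, 2, 2))
  t2 <- t1 * 10; adc <- t1 / 10
  m <- array(0L, c(2, 2, 2)); m[1, 1, 1] <- 1L; m[2, 2, 2] <- 1L
  vm <- build_voxel_matrix(mp_volume(t1, t2, adc), m)
  expect_equal(dim(vm$values), c(2L, 3L))
  expect_equal(vm$values[, "t1"], c(1, 8))
  expect_equal(vm$values[, "adc"], c(0.1, 0.8))
  expect_equal(vm$coords[1, ], c(i = 0L, j = 0L, k = 0L))
  # round trip: entries equal channel values at coords
  for (r in 1:2) {
    co <- vm$coords[r, ] + 1
    expect_equal(vm$values[r, "t2"], t2[co[1], co[2], co[3]], ignore_attr = TRUE)
  }
  ph <- test_phantom(seed = 1, radius = 5, grid = 20)
  vm2 <- build_voxel_matrix(ph$volume, ph$mask)
  expect_equal(nrow(vm2$values), sum(ph$mask$mask))
  expect_error(build_voxel_matrix(ph$volume, array(0L, c(20, 20, 20))), "empty")
})

test_that("k-means solves the separated 1-D instance exactly", {
  x <- cbind(c(0, 1, 10, 11), 0, 0)
  fit <- kmeans_fit(x, 2, seed = 1)
  expect_equal(fit$inertia, 1.0)
  expect_equal(sort(fit$centroids[, 1]), c(0.5, 10.5))
  expect_equal(fit$labels[1], fit$labels[2])
  expect_equal(fit$labels[3], fit$labels[4])
  expect_false(fit$labels[1] == fit$labels[3])
})

test_that("k-means attains the exhaustive-partition optimum on tiny instances", {
  withr::local_seed(7)
  for (rep in 1:8) {
    n <- sample(5:8, 1); k <- sample(2:3, 1)
    x <- matrix(rnorm(n * 2), n, 2)
    fit <- kmeans_fit(cbind(x, 0), k, seed = rep, n_init = 20)
    best <- oracle_kmeans_best(x, k)
    expect_equal(fit$inertia, best, tolerance = 1e-9)
  }
})

test_that("degenerate k equals n gives zero inertia and seeds reproduce fits", {
  x <- cbind(rnorm(6), rnorm(6), rnorm(6))
  fit <- kmeans_fit(x, 6, seed = 2)
  expect_equal(fit$inertia, 0)
  expect_error(kmeans_fit(x, 7, seed = 1), "exceeds")
  a <- kmeans_fit(x, 3, seed = 5); b <- kmeans_fit(x, 3, seed = 5)
  expect_identical(a$labels, b$labels)
  expect_identical(a$centroids, b$centroids)
})

test_that("Calinski-Harabasz matches hand and brute-force evaluations", {
  x <- cbind(c(0, 1, 10, 11), 0, 0)
  expect_equal(calinski_harabasz(x, c(1, 1, 2, 2)), 200)
  # duplicated dataset: only n changes; assert against the oracle
  x2 <- rbind(x, x)
  expect_equal(calinski_harabasz(x2, rep(c(1, 1, 2, 2), 2)),
               oracle_ch(x2, rep(c(1, 1, 2, 2), 2)))
  expect_identical(calinski_harabasz(cbind(c(0, 0, 10, 10), 0, 0), c(1, 1, 2, 2)),
                   Inf)
  expect_error(calinski_harabasz(x, rep(1, 4)), "2 nonempty")

  withr::local_seed(8)
  for (rep in 1:25) {
    n <- sample(10:50, 1); k <- sample(2:4, 1)
    x <- matrix(rnorm(n * 3), n, 3)
    labels <- sample.int(k, n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    expect_equal(calinski_harabasz(x, labels), oracle_ch(x, labels),
                 tolerance = 1e-9)
  }
})

test_that("CH-based selection recovers the planted cluster number", {
  ph <- test_phantom(seed = 13, radius = 8)
  sel <- select_k(standardized_voxels(ph), 2:10, seed = 1)
  expect_equal(sel$k_best, 3L)
  expect_equal(nrow(sel$scores), 9L)
  # a single Gaussian blob still returns an argmax and the full curve
  withr::local_seed(4)
  blob <- matrix(rnorm(600), 200, 3)
  sel2 <- select_k(blob, 2:6, seed = 2)
  expect_true(sel2$k_best %in% 2:6)
  expect_equal(nrow(sel2$scores), 5L)
})

test_that("ties in the CH curve break toward smaller k", {
  expect_equal(habitatomics:::pick_k(c(5, 5, 4), 2:4), 2L)
  expect_equal(habitatomics:::pick_k(c(3, 7, 7), 2:4), 3L)
})

test_that("habitats are ordered by descending ADC and sized correctly", {
  ph <- test_phantom(seed = 17, radius = 8)
  vm <- standardized_voxels(ph)
  km <- kmeans_fit(vm, 3, seed = 3)
  hab <- assign_habitats(km, ph$mask, ph$volume)
  ct <- hab$centroid_table
  expect_equal(order(ct$adc, decreasing = TRUE), seq_len(3))
  expect_equal(sum(ct$n_voxels), sum(ph$mask$mask))
  # last habitat is the low-ADC triad slot
  expect_lt(ct$adc[3], 1.0)
  expect_equal(tidy(hab), ct)

  # permutation invariance of the canonical labelling
  km2 <- km
  perm <- c(3L, 1L, 2L)
  km2$labels <- perm[km$labels]
  km2$centroids <- km$centroids[order(perm), ]
  hab2 <- assign_habitats(km2, ph$mask, ph$volume)
  expect_identical(hab$labels, hab2$labels)
})

test_that("habitats under the 64-voxel floor are flagged excluded", {
  withr::local_seed(9)
  # 100 voxels in two obvious groups of 63 and 37? use 63 vs 200 split
  x <- rbind(matrix(rnorm(63 * 3, 0, 0.1), 63, 3),
             matrix(rnorm(200 * 3, 5, 0.1), 200, 3))
  m <- array(0L, c(15, 15, 2)); m[seq_len(263)] <- 1L
  vm <- list(values = x, coords = habitatomics:::mask_coords(m),
             index = which(m == 1), patient_id = "x")
  class(vm) <- "voxel_matrix"
  km <- kmeans_fit(vm, 2, seed = 1)
  raw <- mp_volume(m * 1.0, m * 1.0,
                   array(rep(c(1.4, 0.8), c(63, 450 - 63)), c(15, 15, 2)))
  hab <- assign_habitats(km, m, raw, min_size = 64)
  expect_equal(length(hab$excluded_habitats), 1L)
  expect_equal(hab$centroid_table$n_voxels[hab$centroid_table$excluded], 63L)
})

test_that("cohort-level k is the modal per-patient optimum with ties downward", {
  phs <- lapply(c(23, 29, 31), function(s) test_phantom(seed = s, radius = 7))
  mats <- lapply(phs, standardized_voxels)
  names(mats) <- paste0("P", seq_along(mats))
  sel <- cohort_k_selection(mats, 2:6, seed = 1)
  expect_equal(sel$k_global, 3L)
  expect_equal(nrow(sel$per_patient), 3L)
  expect_equal(nrow(sel$curves), 3L * 5L)
  expect_error(cohort_k_selection(list()), "empty")
  # single patient: that patient's optimum
  one <- cohort_k_selection(mats[1], 2:6, seed = 1)
  expect_equal(one$k_global, sel$per_patient$k_best[1])
})

test_that("modal-k tie-break uses the smaller k", {
  # exercise the tie rule through the same tabulation the function uses
  k_best <- c(3L, 3L, 4L, 4L)
  tab <- table(k_best)
  expect_equal(min(as.integer(names(tab)[tab == max(tab)])), 3L)
})

test_that("habitat recovery against planted truth is near-perfect at default noise", {
  aris <- vapply(c(41, 43, 47), function(s) {
    ph <- test_phantom(seed = s, radius = 8)
    vm <- standardized_voxels(ph)
    sel <- select_k(vm, 2:6, seed = s)
    hab <- assign_habitats(sel$fits[[paste0("k", sel$k_best)]], ph$mask, ph$volume)
    habitatomics:::adjusted_rand_index(
      hab$labels[ph$mask$mask == 1],
      ph$mask$truth_labels[ph$mask$mask == 1]
    )
  }, numeric(1))
  expect_true(all(aris >= 0.9))
})

test_that("internal ARI agrees with mclust", {
  skip_if_not_installed("mclust")
  withr::local_seed(10)
  for (i in 1:5) {
    a <- sample.int(3, 40, replace = TRUE)
    b <- sample.int(4, 40, replace = TRUE)
    expect_equal(habitatomics:::adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
})

test_that("Lloyd iterations match stats::kmeans from shared starts", {
  withr::local_seed(11)
  x <- matrix(rnorm(300), 100, 3)
  centers <- x[1:3, ]
  ours <- habitatomics:::lloyd_once(x, centers, 100, 0)
  ref <- suppressWarnings(stats::kmeans(x, centers, iter.max = 100,
                                        algorithm = "Lloyd"))
  expect_equal(ours$inertia, ref$tot.withinss, tolerance = 1e-8)
})
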