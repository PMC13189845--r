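line_image <- function(levels_vec) {
  lv <- array(0L, c(1, 1, length(levels_vec)))
  lv[1, 1, ] <- as.integer(levels_vec)
  lv
}

test_that("discretization uses equal-width bins with the max in the top bin", {
  v <- array(0, c(5, 1, 1)); v[] <- c(0, 0.25, 0.5, 0.75, 1)
  m <- array(1L, c(5, 1, 1))
  d <- discretize(v, m, 4)
  expect_equal(as.vector(d$levels), c(1L, 2L, 3L, 4L, 4L))
  expect_equal(d$bin_edges, seq(0, 1, by = 0.25))
  # histogram of levels covers the mask
  ph <- test_phantom(seed = 3, radius = 5, grid = 20)
  dd <- discretize(ph$volume$t1, ph$mask, 16)
  expect_equal(sum(tabulate(dd$levels[ph$mask$mask == 1], 16)),
               sum(ph$mask$mask))
  # affine invariance
  d2 <- discretize(5 * ph$volume$t1 + 3, ph$mask, 16)
  expect_identical(dd$levels, d2$levels)
  expect_error(discretize(array(1, c(3, 3, 3)), array(1L, c(3, 3, 3)), 4),
               "constant")
})

test_that("first-order features match closed forms and a direct recompute", {
  v <- array(0, c(3, 1, 1)); v[] <- c(1, 2, 3)
  m <- array(1L, c(3, 1, 1))
  fo <- first_order_features(v, m, n_bins = 3)
  expect_equal(fo[["Mean"]], 2)
  expect_equal(fo[["Range"]], 2)
  expect_equal(fo[["Variance"]], 2 / 3)
  expect_equal(fo[["Energy"]], 14)
  expect_equal(fo[["RootMeanSquared"]], sqrt(14 / 3))

  cv <- array(5, c(2, 2, 2)); cm <- array(1L, c(2, 2, 2))
  foc <- first_order_features(cv, cm)
  expect_equal(foc[["Entropy"]], 0)
  expect_equal(foc[["Uniformity"]], 1)
  expect_equal(foc[["Skewness"]], 0)

  withr::local_seed(12)
  rv <- array(rnorm(125), c(5, 5, 5)); rm_ <- array(1L, c(5, 5, 5))
  d <- discretize(rv, rm_, 8)
  fo2 <- first_order_features(rv, rm_, d)
  x <- as.vector(rv); n <- length(x)
  p <- tabulate(d$levels, 8) / n
  mu <- mean(x); m2 <- mean((x - mu)^2)
  inner <- x[x >= quantile(x, 0.1) & x <= quantile(x, 0.9)]
  expected <- c(
    Energy = sum(x^2), TotalEnergy = sum(x^2), Entropy = -sum(p * log2(p)),
    Minimum = min(x), `10Percentile` = quantile(x, 0.1, names = FALSE),
    `90Percentile` = quantile(x, 0.9, names = FALSE), Maximum = max(x),
    Mean = mu, Median = median(x),
    InterquartileRange = diff(quantile(x, c(0.25, 0.75), names = FALSE)),
    Range = diff(range(x)), MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation = mean(abs(inner - mean(inner))),
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = mean((x - mu)^3) / m2^1.5, Kurtosis = mean((x - mu)^4) / m2^2,
    Variance = m2, Uniformity = sum(p^2)
  )
  expect_equal(fo2, expected, tolerance = 1e-12)
  # voxel-order invariance
  perm <- array(0, c(5, 5, 5)); perm[] <- sample(as.vector(rv))
  expect_equal(first_order_features(perm, rm_, n_bins = 8)[["Variance"]],
               fo2[["Variance"]], tolerance = 1e-12)
})

test_that("shape features follow the stated voxel conventions", {
  m1 <- array(0L, c(3, 3, 3)); m1[2, 2, 2] <- 1L
  sf <- shape_features(m1, c(1, 1, 1))
  expect_equal(sf[["VoxelVolume"]], 1)
  expect_equal(sf[["SurfaceArea"]], 6)
  expect_equal(sf[["SurfaceVolumeRatio"]], 6)
  expect_equal(sf[["Maximum3DDiameter"]], 0)

  m2 <- array(0L, c(5, 1, 1)); m2[c(1, 4), 1, 1] <- 1L
  expect_equal(shape_features(m2, c(1, 1, 1))[["Maximum3DDiameter"]], 3)

  cube <- array(0L, c(24, 24, 24)); cube[1:10, 1:10, 1:10] <- 1L
  box <- array(0L, c(24, 24, 24)); box[1:20, 1:5, 1:10] <- 1L
  s_cube <- shape_features(cube, c(1, 1, 1))
  s_box <- shape_features(box, c(1, 1, 1))
  expect_equal(s_cube[["VoxelVolume"]], s_box[["VoxelVolume"]])
  expect_gt(s_cube[["Sphericity"]], s_box[["Sphericity"]])
  # intensity invariance is structural: shape reads only the mask
  expect_equal(length(s_cube), 14L)
})

test_that("GLCM counts and features agree with hand and brute-force oracles", {
  lv <- line_image(c(1, 1, 2, 2))
  counts <- glcm_matrices(as_discretized(lv, 2))
  zdir <- counts[, , 3] # direction (0,0,1)
  expect_equal(zdir, matrix(c(2, 1, 1, 2), 2, 2))

  const <- as_discretized(array(1L, c(3, 3, 1)), 2)
  fc <- glcm_features(const)
  expect_equal(fc[["MaximumProbability"]], 1)
  expect_equal(fc[["JointEntropy"]], 0)
  expect_equal(fc[["Correlation"]], 1)
  expect_equal(fc[["Imc1"]], 0)

  withr::local_seed(13)
  for (rep in 1:10) {
    lv <- random_level_image(c(4, 4, 4), 4)
    if (sum(lv > 0) < 3) next
    expect_identical(glcm_matrices(as_discretized(lv, 4)), oracle_glcm(lv, 4))
  }
})

test_that("GLRLM runs match enumeration", {
  single <- array(0L, c(3, 3, 3)); single[2, 2, 2] <- 1L
  f1 <- glrlm_features(as_discretized(single, 2))
  expect_equal(f1[["ShortRunEmphasis"]], 1)
  expect_equal(f1[["RunPercentage"]], 1)

  lv <- line_image(c(3, 3, 3, 3))
  counts <- glrlm_matrices(as_discretized(lv, 3))
  expect_equal(counts[3, 4, 3], 1L) # one run of length 4 along (0,0,1)
  expect_equal(sum(counts[, , 3]), 1L)

  withr::local_seed(14)
  for (rep in 1:10) {
    lv <- random_level_image(c(5, 4, 3), 3)
    if (sum(lv > 0) < 3) next
    got <- glrlm_matrices(as_discretized(lv, 3))
    want <- oracle_glrlm(lv, 3, dim(got)[2])
    expect_identical(got, want)
  }
})

test_that("GLSZM zones match flood-fill enumeration", {
  uni <- array(0L, c(2, 2, 4)); uni[, , 1] <- 1L
  d <- as_discretized(uni, 2)
  f <- glszm_features(d)
  expect_equal(f[["SizeZoneNonUniformity"]], 1)
  expect_equal(f[["ZonePercentage"]], 0.25)

  checker <- array(0L, c(2, 2, 1))
  checker[1, 1, 1] <- 1L; checker[2, 2, 1] <- 1L
  checker[1, 2, 1] <- 2L; checker[2, 1, 1] <- 2L
  # 26-connectivity joins the two like-level diagonals: two zones of size 2
  zt <- glszm_zone_table(as_discretized(checker, 2))
  expect_equal(nrow(zt), 2L)
  expect_equal(sort(zt[, 2]), c(2L, 2L))

  withr::local_seed(15)
  for (rep in 1:10) {
    lv <- random_level_image(c(4, 4, 4), 4)
    if (sum(lv > 0) < 2) next
    got <- glszm_zone_table(as_discretized(lv, 4))
    want <- oracle_glszm(lv)
    key <- function(m) sort(paste(m[, 1], m[, 2]))
    expect_identical(key(got), key(want))
  }
})

test_that("GLDM dependence counts match a neighbour-scan oracle", {
  single <- array(0L, c(3, 3, 3)); single[2, 2, 2] <- 1L
  tab <- gldm_dependence_table(as_discretized(single, 2))
  expect_equal(tab[1, 2], 0L) # no dependent neighbours; stored at size d+1
  f <- gldm_features(as_discretized(single, 2))
  expect_equal(f[["SmallDependenceEmphasis"]], 1) # single voxel at j = 1

  flat <- array(0L, c(3, 3, 1)); flat[, , 1] <- 1L
  tab2 <- gldm_dependence_table(as_discretized(flat, 2))
  centre <- tab2[tab2[, 2] == max(tab2[, 2]), , drop = FALSE]
  expect_equal(centre[1, 2], 8L)

  withr::local_seed(16)
  for (rep in 1:10) {
    lv <- random_level_image(c(4, 4, 4), 4)
    if (sum(lv > 0) < 2) next
    got <- gldm_dependence_table(as_discretized(lv, 4))
    want <- oracle_gldm(lv)
    key <- function(m) sort(paste(m[, 1], m[, 2]))
    expect_identical(key(got), key(unname(want)))
  }
})

test_that("NGTDM statistics match the direct formula oracle", {
  const <- as_discretized(array(1L, c(3, 3, 1)), 2)
  expect_equal(ngtdm_features(const)[["Contrast"]], 0)

  two <- as_discretized(line_image(c(1, 2)), 2)
  f <- ngtdm_features(two)
  # s_1 = |1 - 2| = 1, s_2 = |2 - 1| = 1, p_i = 0.5 each
  # Coarseness = 1 / (0.5*1 + 0.5*1) = 1
  expect_equal(f[["Coarseness"]], 1)

  withr::local_seed(17)
  for (rep in 1:10) {
    lv <- random_level_image(c(4, 4, 4), 4)
    if (sum(lv > 0) < 3) next
    vox <- habitatomics:::.ngtdm_voxels(as.vector(lv), dim(lv))
    want <- oracle_ngtdm(lv, 4)
    ni <- tabulate(vox[vox[, 2] > 0, 1], 4)
    si <- numeric(4)
    agg <- rowsum(vox[vox[, 2] > 0, 3], vox[vox[, 2] > 0, 1])
    si[as.integer(rownames(agg))] <- agg[, 1]
    expect_equal(ni, want$n, tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(si, want$s, tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("normalized texture matrices sum to one", {
  withr::local_seed(18)
  lv <- random_level_image(c(5, 5, 5), 4)
  d <- as_discretized(lv, 4)
  counts <- glcm_matrices(d)
  for (k in seq_len(13)) {
    s <- sum(counts[, , k])
    if (s > 0) expect_equal(sum(counts[, , k] / s), 1, tolerance = 1e-12)
  }
  zt <- glszm_zone_table(d)
  expect_equal(sum(zt[, 2]), sum(lv > 0)) # zones partition the region
})

test_that("extraction yields 107 features per sequence and 321 per region", {
  ph <- test_phantom(seed = 19, radius = 5, grid = 20)
  nms <- feature_names()
  expect_equal(length(nms), 321L)
  expect_equal(sum(startsWith(nms, "T1WI_")), 107L)
  expect_equal(sum(startsWith(nms, "T2WI_")), 107L)
  expect_equal(sum(startsWith(nms, "ADC_")), 107L)
  expect_false(any(duplicated(nms)))
  expect_true(all(c("T2WI_glszm_SizeZoneNonUniformity",
                    "T2WI_shape_Maximum3DDiameter",
                    "T1WI_shape_SurfaceVolumeRatio",
                    "ADC_glcm_Imc1",
                    "ADC_glrlm_ShortRunEmphasis",
                    "ADC_glszm_ZonePercentage",
                    "ADC_glszm_GrayLevelNonUniformity",
                    "T1WI_glszm_LowGrayLevelZoneEmphasis",
                    "ADC_gldm_SmallDependenceLowGrayLevelEmphasis") %in% nms))

  fx <- extract_all(ph$volume, ph$mask, patient_id = "P1")
  expect_equal(nrow(fx), 1L)
  expect_equal(setdiff(names(fx), c("patient_id", "region")), nms)
  expect_false(anyNA(fx))

  # identical channels produce identical per-sequence values
  same <- mp_volume(ph$volume$t1, ph$volume$t1, ph$volume$t1)
  fs <- extract_all(same, ph$mask)
  t1_vals <- unlist(fs[paste0("T1WI_", substring(nms[1:107], 6))])
  adc_vals <- unlist(fs[paste0("ADC_", substring(nms[1:107], 6))])
  expect_equal(unname(t1_vals), unname(adc_vals), tolerance = 1e-12)
})

test_that("excluded habitats and degenerate regions yield missing textures", {
  ph <- test_phantom(seed = 23, radius = 6, grid = 24)
  vm <- standardized_voxels(ph)
  km <- kmeans_fit(vm, 3, seed = 1)
  hab <- assign_habitats(km, ph$mask, ph$volume, min_size = 64)
  hab$excluded_habitats <- 2L # force one excluded habitat
  fx <- extract_all(ph$volume, hab)
  expect_equal(nrow(fx), 4L)
  h2 <- fx[fx$region == "habitat_2", setdiff(names(fx), c("patient_id", "region"))]
  expect_true(all(is.na(h2)))
  h3 <- fx[fx$region == "habitat_3", setdiff(names(fx), c("patient_id", "region"))]
  expect_false(anyNA(h3))

  # 1-voxel region: first-order and shape defined, textures missing
  m <- array(0L, c(5, 5, 5)); m[3, 3, 3] <- 1L
  v <- array(rnorm(125), c(5, 5, 5))
  fx1 <- extract_all(mp_volume(v, v, v), m)
  expect_equal(fx1[["T1WI_firstorder_Mean"]], v[3, 3, 3])
  expect_equal(fx1[["T1WI_shape_VoxelVolume"]], 1)
  expect_true(is.na(fx1[["T1WI_glcm_Contrast"]]))
})
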