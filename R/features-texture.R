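# Texture feature families computed from the C++ counting kernels.
# Conventions for degenerate inputs (single gray level, single voxel) are
# fixed here and exercised in the unit tests: GLCM Correlation -> 1 and
# IMC1/IMC2/MCC -> 0/0/1 when only one level is present; direction-averaged
# families skip directions with no voxel pairs.

entropy2 <- function(p) {
  p <- p[p > 0]
  if (!length(p)) return(0)
  -sum(p * log2(p))
}

glcm_features_one <- function(P) {
  ng <- nrow(P)
  s <- sum(P)
  if (s == 0) return(NULL)
  P <- P / s
  i <- row(P); j <- col(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(i * P); muy <- sum(j * P)
  sigx <- sqrt(sum((i - mux)^2 * P)); sigy <- sqrt(sum((j - muy)^2 * P))
  # diagonal (difference) and cross-diagonal (sum) distributions
  pdiff <- vapply(0:(ng - 1), function(k) sum(P[abs(i - j) == k]), numeric(1))
  psum <- vapply(2:(2 * ng), function(k) sum(P[(i + j) == k]), numeric(1))
  kd <- 0:(ng - 1); ks <- 2:(2 * ng)
  HX <- entropy2(px); HY <- entropy2(py)
  HXY <- entropy2(as.vector(P))
  pq <- outer(px, py)
  pos <- P > 0 & pq > 0
  HXY1 <- -sum(P[pos] * log2(pq[pos]))
  posq <- pq > 0
  HXY2 <- -sum(pq[posq] * log2(pq[posq]))
  da <- sum(kd * pdiff)
  correlation <- if (sigx * sigy == 0) 1 else (sum(i * j * P) - mux * muy) / (sigx * sigy)
  imc1 <- if (max(HX, HY) == 0) 0 else (HXY - HXY1) / max(HX, HY)
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (HXY2 - HXY))))
  # MCC: sqrt of second-largest eigenvalue of Q
  mcc <- if (ng == 1 || sum(px > 0) < 2) 1 else {
    Q <- matrix(0, ng, ng)
    nz <- which(px > 0)
    for (a in nz) {
      Q[a, ] <- colSums(P[a, ] * t(P) / pmax(py, .Machine$double.xmin)) / px[a]
    }
    lam <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(pmax(0, lam[2]))
  }
  offdiag <- abs(i - j) > 0
  c(
    Autocorrelation = sum(i * j * P),
    JointAverage = mux,
    ClusterProminence = sum((i + j - mux - muy)^4 * P),
    ClusterShade = sum((i + j - mux - muy)^3 * P),
    ClusterTendency = sum((i + j - mux - muy)^2 * P),
    Contrast = sum((i - j)^2 * P),
    Correlation = correlation,
    DifferenceAverage = da,
    DifferenceEntropy = entropy2(pdiff),
    DifferenceVariance = sum((kd - da)^2 * pdiff),
    Id = sum(P / (1 + abs(i - j))),
    Idm = sum(P / (1 + (i - j)^2)),
    Idmn = sum(P / (1 + ((i - j) / ng)^2)),
    Idn = sum(P / (1 + abs(i - j) / ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = sum(P[offdiag] / (i[offdiag] - j[offdiag])^2),
    JointEnergy = sum(P^2),
    JointEntropy = HXY,
    MaximumProbability = max(P),
    MCC = mcc,
    SumAverage = sum(ks * psum),
    SumEntropy = entropy2(psum),
    SumSquares = sum((i - mux)^2 * P)
  )
}

#' Gray-level co-occurrence matrix features (24)
#'
#' Symmetric co-occurrence at distance 1 over the 13 unique 3D directions;
#' features are computed per direction and averaged over directions that
#' contain at least one voxel pair.
#'
#' @param discretized A [discretize()] result.
#' @param mask Unused (levels already carry the mask); kept for a uniform
#'   signature.
#' @param spacing_mm Unused; kept for a uniform signature.
#' @return Named numeric vector of 24 features.
#' @export
glcm_features <- function(discretized, mask = NULL, spacing_mm = NULL) {
  ng <- discretized$n_levels
  counts <- glcm_matrices(discretized)
  nd_all <- dim(counts)[3]
  E <- matrix(as.numeric(counts), ng * ng, nd_all)
  tot <- colSums(E)
  valid <- tot > 0 # directions with at least one voxel pair
  nm <- names(glcm_features_one(matrix(1, 1, 1)))
  if (!any(valid)) return(setNames(rep(NA_real_, length(nm)), nm))
  P <- sweep(E[, valid, drop = FALSE], 2, tot[valid], `/`)
  iv <- rep(seq_len(ng), times = ng)
  jv <- rep(seq_len(ng), each = ng)
  wsum <- function(w) colSums(P * w)
  cent <- function(M) { # per-column entropy in bits
    L <- ifelse(M > 0, log2(M), 0)
    -colSums(M * L)
  }
  px <- rowsum(P, iv); py <- rowsum(P, jv)
  mux <- wsum(iv); muy <- wsum(jv)
  sigx2 <- wsum(iv^2) - mux^2; sigy2 <- wsum(jv^2) - muy^2
  s1 <- wsum(iv + jv); s2 <- wsum((iv + jv)^2)
  s3 <- wsum((iv + jv)^3); s4 <- wsum((iv + jv)^4)
  m <- mux + muy
  pdiff <- rowsum(P, abs(iv - jv)) # rows ordered by diff 0..ng-1
  kd <- sort(unique(abs(iv - jv)))
  psum <- rowsum(P, iv + jv)
  ks <- sort(unique(iv + jv))
  da <- colSums(pdiff * kd)
  HX <- cent(px); HY <- cent(py)
  HXY <- cent(P)
  PQ <- px[iv, , drop = FALSE] * py[jv, , drop = FALSE]
  L1 <- ifelse(P > 0 & PQ > 0, log2(pmax(PQ, .Machine$double.xmin)), 0)
  HXY1 <- -colSums(P * L1)
  HXY2 <- cent(PQ)
  corr <- ifelse(sigx2 * sigy2 <= 0, 1,
                 (wsum(iv * jv) - mux * muy) / sqrt(pmax(sigx2 * sigy2, 0)))
  imc1 <- ifelse(pmax(HX, HY) == 0, 0, (HXY - HXY1) / pmax(HX, HY))
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (HXY2 - HXY))))
  mcc <- vapply(seq_len(ncol(P)), function(d) {
    Pd <- matrix(P[, d], ng, ng)
    pxd <- rowSums(Pd); pyd <- colSums(Pd)
    nz <- which(pxd > 0)
    if (length(nz) < 2) return(1)
    Q <- matrix(0, ng, ng)
    for (a in nz) {
      Q[a, ] <- colSums(Pd[a, ] * t(Pd) / pmax(pyd, .Machine$double.xmin)) / pxd[a]
    }
    lam <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(pmax(0, lam[2]))
  }, numeric(1))
  w_id <- 1 / (1 + abs(iv - jv))
  w_idm <- 1 / (1 + (iv - jv)^2)
  w_idmn <- 1 / (1 + ((iv - jv) / ng)^2)
  w_idn <- 1 / (1 + abs(iv - jv) / ng)
  w_invvar <- ifelse(iv == jv, 0, 1 / (iv - jv)^2)
  feats <- rbind(
    Autocorrelation = wsum(iv * jv),
    JointAverage = mux,
    ClusterProminence = s4 - 4 * m * s3 + 6 * m^2 * s2 - 4 * m^3 * s1 + m^4,
    ClusterShade = s3 - 3 * m * s2 + 3 * m^2 * s1 - m^3,
    ClusterTendency = s2 - 2 * m * s1 + m^2,
    Contrast = wsum((iv - jv)^2),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = cent(pdiff),
    DifferenceVariance = colSums(pdiff * kd^2) - da^2,
    Id = wsum(w_id),
    Idm = wsum(w_idm),
    Idmn = wsum(w_idmn),
    Idn = wsum(w_idn),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = wsum(w_invvar),
    JointEnergy = colSums(P^2),
    JointEntropy = HXY,
    MaximumProbability = apply(P, 2, max),
    MCC = mcc,
    SumAverage = colSums(psum * ks),
    SumEntropy = cent(psum),
    SumSquares = sigx2
  )
  rowMeans(feats)[nm]
}

#' Raw symmetric GLCM count matrices (one per direction)
#' @param discretized A [discretize()] result.
#' @return ng x ng x 13 integer array of symmetric pair counts.
#' @export
glcm_matrices <- function(discretized) {
  .glcm_counts(as.vector(discretized$levels), dim(discretized$levels),
               discretized$n_levels)
}

rlm_features_one <- function(C, n_voxels) {
  nr <- sum(C)
  if (nr == 0) return(NULL)
  p <- C / nr
  g <- row(C); l <- col(C)
  pg <- rowSums(p); pl <- colSums(p)
  mug <- sum(g * p); mul <- sum(l * p)
  c(
    GrayLevelNonUniformity = sum(rowSums(C)^2) / nr,
    GrayLevelNonUniformityNormalized = sum(pg^2),
    GrayLevelVariance = sum((g - mug)^2 * p),
    HighGrayLevelRunEmphasis = sum(g^2 * p),
    LongRunEmphasis = sum(l^2 * p),
    LongRunHighGrayLevelEmphasis = sum(g^2 * l^2 * p),
    LongRunLowGrayLevelEmphasis = sum(l^2 * p / g^2),
    LowGrayLevelRunEmphasis = sum(p / g^2),
    RunEntropy = entropy2(as.vector(p)),
    RunLengthNonUniformity = sum(colSums(C)^2) / nr,
    RunLengthNonUniformityNormalized = sum(pl^2),
    RunPercentage = nr / n_voxels,
    RunVariance = sum((l - mul)^2 * p),
    ShortRunEmphasis = sum(p / l^2),
    ShortRunHighGrayLevelEmphasis = sum(g^2 * p / l^2),
    ShortRunLowGrayLevelEmphasis = sum(p / (g^2 * l^2))
  )
}

#' Gray-level run-length matrix features (16)
#'
#' Run-length matrices over the 13 unique 3D directions, features averaged
#' across directions.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 16 features.
#' @export
glrlm_features <- function(discretized, mask = NULL) {
  counts <- glrlm_matrices(discretized)
  ng <- dim(counts)[1]; nl <- dim(counts)[2]
  n_vox <- sum(discretized$levels > 0)
  C <- matrix(as.numeric(counts), ng * nl, dim(counts)[3])
  nr <- colSums(C)
  C <- C[, nr > 0, drop = FALSE]; nr <- nr[nr > 0]
  P <- sweep(C, 2, nr, `/`)
  g <- rep(seq_len(ng), times = nl)
  l <- rep(seq_len(nl), each = ng)
  wsum <- function(w) colSums(P * w)
  cent <- function(M) { L <- ifelse(M > 0, log2(M), 0); -colSums(M * L) }
  pg <- rowsum(P, g); pl <- rowsum(P, l)
  Cg <- rowsum(C, g); Cl <- rowsum(C, l)
  mug <- wsum(g); mul <- wsum(l)
  feats <- rbind(
    GrayLevelNonUniformity = colSums(Cg^2) / nr,
    GrayLevelNonUniformityNormalized = colSums(pg^2),
    GrayLevelVariance = wsum(g^2) - mug^2,
    HighGrayLevelRunEmphasis = wsum(g^2),
    LongRunEmphasis = wsum(l^2),
    LongRunHighGrayLevelEmphasis = wsum(g^2 * l^2),
    LongRunLowGrayLevelEmphasis = wsum(l^2 / g^2),
    LowGrayLevelRunEmphasis = wsum(1 / g^2),
    RunEntropy = cent(P),
    RunLengthNonUniformity = colSums(Cl^2) / nr,
    RunLengthNonUniformityNormalized = colSums(pl^2),
    RunPercentage = nr / n_vox,
    RunVariance = wsum(l^2) - mul^2,
    ShortRunEmphasis = wsum(1 / l^2),
    ShortRunHighGrayLevelEmphasis = wsum(g^2 / l^2),
    ShortRunLowGrayLevelEmphasis = wsum(1 / (g^2 * l^2))
  )
  rowMeans(feats)
}

#' Raw GLRLM count matrices (one per direction), trimmed to the longest run
#' @param discretized A [discretize()] result.
#' @return ng x max_run x 13 integer array of run counts.
#' @export
glrlm_matrices <- function(discretized) {
  counts <- .glrlm_counts(as.vector(discretized$levels), dim(discretized$levels),
                          discretized$n_levels)
  maxlen <- max(1L, max(which(apply(counts, 2, sum) > 0), 0L))
  counts[, seq_len(maxlen), , drop = FALSE]
}

#' Gray-level size-zone matrix features (16)
#'
#' Zones are 26-connected components of equal gray level across the whole
#' region (no directionality).
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 16 features.
#' @export
glszm_features <- function(discretized, mask = NULL) {
  zones <- glszm_zone_table(discretized)
  n_vox <- sum(discretized$levels > 0)
  nz <- nrow(zones)
  C <- matrix(0, discretized$n_levels, max(zones[, 2]))
  for (r in seq_len(nz)) {
    C[zones[r, 1], zones[r, 2]] <- C[zones[r, 1], zones[r, 2]] + 1
  }
  p <- C / nz
  g <- row(C); s <- col(C)
  pg <- rowSums(p); ps <- colSums(p)
  mug <- sum(g * p); mus <- sum(s * p)
  c(
    GrayLevelNonUniformity = sum(rowSums(C)^2) / nz,
    GrayLevelNonUniformityNormalized = sum(pg^2),
    GrayLevelVariance = sum((g - mug)^2 * p),
    HighGrayLevelZoneEmphasis = sum(g^2 * p),
    LargeAreaEmphasis = sum(s^2 * p),
    LargeAreaHighGrayLevelEmphasis = sum(g^2 * s^2 * p),
    LargeAreaLowGrayLevelEmphasis = sum(s^2 * p / g^2),
    LowGrayLevelZoneEmphasis = sum(p / g^2),
    SizeZoneNonUniformity = sum(colSums(C)^2) / nz,
    SizeZoneNonUniformityNormalized = sum(ps^2),
    SmallAreaEmphasis = sum(p / s^2),
    SmallAreaHighGrayLevelEmphasis = sum(g^2 * p / s^2),
    SmallAreaLowGrayLevelEmphasis = sum(p / (g^2 * s^2)),
    ZoneEntropy = entropy2(as.vector(p)),
    ZonePercentage = nz / n_vox,
    ZoneVariance = sum((s - mus)^2 * p)
  )
}

#' Zone table (level, size) of the 26-connected equal-level decomposition
#' @param discretized A [discretize()] result.
#' @return Integer matrix with one row per zone: level, size.
#' @export
glszm_zone_table <- function(discretized) {
  .glszm_zones(as.vector(discretized$levels), dim(discretized$levels))
}

#' Gray-level dependence matrix features (14)
#'
#' The dependence of a voxel is the number of 26-neighbours (inside the
#' region) whose gray level differs by at most `alpha`; the matrix column
#' index is the dependence size `d + 1` (the voxel itself counts), so a
#' single isolated voxel contributes at size 1.
#'
#' @inheritParams glcm_features
#' @param alpha Gray-level difference tolerance (default 0).
#' @return Named numeric vector of 14 features.
#' @export
gldm_features <- function(discretized, mask = NULL, alpha = 0L) {
  vox <- gldm_dependence_table(discretized, alpha)
  ng <- discretized$n_levels
  nd <- max(vox[, 2]) + 1L
  C <- matrix(0, ng, nd)
  for (r in seq_len(nrow(vox))) {
    jj <- vox[r, 2] + 1L
    C[vox[r, 1], jj] <- C[vox[r, 1], jj] + 1
  }
  nz <- sum(C)
  p <- C / nz
  g <- row(C); j <- col(C)
  pg <- rowSums(p); pj <- colSums(p)
  mug <- sum(g * p); muj <- sum(j * p)
  c(
    DependenceEntropy = entropy2(as.vector(p)),
    DependenceNonUniformity = sum(colSums(C)^2) / nz,
    DependenceNonUniformityNormalized = sum(pj^2),
    DependenceVariance = sum((j - muj)^2 * p),
    GrayLevelNonUniformity = sum(rowSums(C)^2) / nz,
    GrayLevelVariance = sum((g - mug)^2 * p),
    HighGrayLevelEmphasis = sum(g^2 * p),
    LargeDependenceEmphasis = sum(j^2 * p),
    LargeDependenceHighGrayLevelEmphasis = sum(g^2 * j^2 * p),
    LargeDependenceLowGrayLevelEmphasis = sum(j^2 * p / g^2),
    LowGrayLevelEmphasis = sum(p / g^2),
    SmallDependenceEmphasis = sum(p / j^2),
    SmallDependenceHighGrayLevelEmphasis = sum(g^2 * p / j^2),
    SmallDependenceLowGrayLevelEmphasis = sum(p / (g^2 * j^2))
  )
}

#' Per-voxel dependence counts (level, dependent-neighbour count)
#' @param discretized A [discretize()] result.
#' @param alpha Gray-level difference tolerance.
#' @return Integer matrix, one row per in-region voxel.
#' @export
gldm_dependence_table <- function(discretized, alpha = 0L) {
  .gldm_voxels(as.vector(discretized$levels), dim(discretized$levels),
               as.integer(alpha))
}

#' Neighbourhood gray-tone difference features (5)
#'
#' Coarseness, Contrast, Busyness, Complexity and Strength from 26-
#' neighbourhood mean gray-tone differences. Voxels without any in-region
#' neighbour are excluded from the tally. A zero Coarseness denominator
#' returns the 1e6 sentinel.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 5 features.
#' @export
ngtdm_features <- function(discretized, mask = NULL) {
  vox <- .ngtdm_voxels(as.vector(discretized$levels), dim(discretized$levels))
  valid <- vox[, 2] > 0
  vox <- vox[valid, , drop = FALSE]
  ng <- discretized$n_levels
  n <- nrow(vox)
  ni <- tabulate(vox[, 1], ng)
  si <- numeric(ng)
  if (n > 0) {
    agg <- rowsum(vox[, 3], vox[, 1])
    si[as.integer(rownames(agg))] <- agg[, 1]
  }
  pi_ <- ni / n
  act <- which(ni > 0)
  ngp <- length(act)
  gi <- seq_len(ng)
  coarse_den <- sum(pi_ * si)
  coarseness <- if (coarse_den == 0) 1e6 else 1 / coarse_den
  contrast <- if (ngp <= 1) 0 else {
    (sum(outer(pi_[act], pi_[act]) * outer(gi[act], gi[act], `-`)^2) /
       (ngp * (ngp - 1))) * (sum(si) / n)
  }
  busy_den <- sum(abs(outer(gi[act] * pi_[act], gi[act] * pi_[act], `-`)))
  busyness <- if (busy_den == 0) 0 else sum(pi_ * si) / busy_den
  complexity <- if (n == 0) 0 else {
    tot <- 0
    for (a in act) for (b in act) {
      if (a == b) next
      tot <- tot + abs(a - b) * (pi_[a] * si[a] + pi_[b] * si[b]) / (pi_[a] + pi_[b])
    }
    tot / n
  }
  strength_den <- sum(si)
  strength <- if (strength_den == 0) 0 else {
    sum(outer(pi_[act], pi_[act], `+`) * outer(gi[act], gi[act], `-`)^2) /
      strength_den
  }
  c(Coarseness = coarseness, Contrast = contrast, Busyness = busyness,
    Complexity = complexity, Strength = strength)
}
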