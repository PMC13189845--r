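# Independent brute-force oracles used to validate the fast implementations.
# These are deliberately written as plain loops over voxels/pairs and share
# no code with the package internals.

oracle_offsets13 <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
  c(0, 1, 1), c(0, 1, -1),
  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1)
)

oracle_offsets26 <- {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

in_grid <- function(p, d) all(p >= 1) && all(p <= d)

# Symmetric GLCM counts, one ng x ng matrix per direction.
oracle_glcm <- function(levels, ng) {
  d <- dim(levels)
  out <- array(0L, c(ng, ng, 13))
  vox <- which(levels > 0, arr.ind = TRUE)
  for (k in seq_len(13)) {
    off <- oracle_offsets13[k, ]
    for (r in seq_len(nrow(vox))) {
      p <- vox[r, ]; q <- p + off
      if (!in_grid(q, d)) next
      b <- levels[q[1], q[2], q[3]]
      if (b <= 0) next
      a <- levels[p[1], p[2], p[3]]
      out[a, b, k] <- out[a, b, k] + 1L
      out[b, a, k] <- out[b, a, k] + 1L
    }
  }
  out
}

# Run-length counts per direction by explicit line walking.
oracle_glrlm <- function(levels, ng, max_len) {
  d <- dim(levels)
  out <- array(0L, c(ng, max_len, 13))
  all_idx <- as.matrix(expand.grid(seq_len(d[1]), seq_len(d[2]), seq_len(d[3])))
  for (k in seq_len(13)) {
    off <- oracle_offsets13[k, ]
    for (r in seq_len(nrow(all_idx))) {
      p <- all_idx[r, ]
      if (in_grid(p - off, d)) next # not a line start
      cur <- 0L; len <- 0L
      q <- p
      while (in_grid(q, d)) {
        v <- levels[q[1], q[2], q[3]]
        if (v > 0 && v == cur) {
          len <- len + 1L
        } else {
          if (cur > 0L) out[cur, len, k] <- out[cur, len, k] + 1L
          cur <- v; len <- if (v > 0) 1L else 0L
        }
        q <- q + off
      }
      if (cur > 0L) out[cur, len, k] <- out[cur, len, k] + 1L
    }
  }
  out
}

# 26-connected equal-level zones by repeated flood fill.
oracle_glszm <- function(levels) {
  d <- dim(levels)
  seen <- array(FALSE, d)
  zones <- list()
  vox <- which(levels > 0)
  for (s in vox) {
    if (seen[s]) next
    lvl <- levels[s]
    frontier <- s
    seen[s] <- TRUE
    members <- s
    while (length(frontier)) {
      nxt <- integer()
      for (f in frontier) {
        p <- arrayInd(f, d)[1, ]
        for (r in seq_len(nrow(oracle_offsets26))) {
          q <- p + oracle_offsets26[r, ]
          if (!in_grid(q, d)) next
          qi <- q[1] + d[1] * (q[2] - 1) + d[1] * d[2] * (q[3] - 1)
          if (!seen[qi] && levels[qi] == lvl) {
            seen[qi] <- TRUE
            nxt <- c(nxt, qi)
          }
        }
      }
      members <- c(members, nxt)
      frontier <- nxt
    }
    zones[[length(zones) + 1]] <- c(lvl, length(members))
  }
  do.call(rbind, zones)
}

# Per-voxel dependence counts by neighbour scan.
oracle_gldm <- function(levels, alpha = 0L) {
  d <- dim(levels)
  vox <- which(levels > 0, arr.ind = TRUE)
  t(apply(vox, 1, function(p) {
    a <- levels[p[1], p[2], p[3]]
    dep <- 0L
    for (r in seq_len(nrow(oracle_offsets26))) {
      q <- p + oracle_offsets26[r, ]
      if (!in_grid(q, d)) next
      b <- levels[q[1], q[2], q[3]]
      if (b > 0 && abs(b - a) <= alpha) dep <- dep + 1L
    }
    c(a, dep)
  }))
}

# NGTDM per-level counts n_i and sums s_i by neighbour scan.
oracle_ngtdm <- function(levels, ng) {
  d <- dim(levels)
  vox <- which(levels > 0, arr.ind = TRUE)
  ni <- numeric(ng); si <- numeric(ng)
  for (r in seq_len(nrow(vox))) {
    p <- vox[r, ]
    a <- levels[p[1], p[2], p[3]]
    nb <- c()
    for (k in seq_len(nrow(oracle_offsets26))) {
      q <- p + oracle_offsets26[k, ]
      if (!in_grid(q, d)) next
      b <- levels[q[1], q[2], q[3]]
      if (b > 0) nb <- c(nb, b)
    }
    if (length(nb)) {
      ni[a] <- ni[a] + 1
      si[a] <- si[a] + abs(a - mean(nb))
    }
  }
  list(n = ni, s = si)
}

# Calinski-Harabasz by direct evaluation of the defining sums.
oracle_ch <- function(x, labels) {
  x <- as.matrix(x)
  labs <- unique(labels)
  k <- length(labs); n <- nrow(x)
  grand <- colMeans(x)
  B <- 0; W <- 0
  for (l in labs) {
    xi <- x[labels == l, , drop = FALSE]
    ci <- colMeans(xi)
    B <- B + nrow(xi) * sum((ci - grand)^2)
    W <- W + sum(sweep(xi, 2, ci)^2)
  }
  if (W == 0) return(Inf)
  (B / (k - 1)) / (W / (n - k))
}

# Trapezoidal area under the empirical ROC curve.
oracle_auc_trapezoid <- function(scores, labels) {
  y <- as.integer(labels != 0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[y == 1] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[y == 0] >= t), numeric(1))
  tpr <- c(tpr, 1); fpr <- c(fpr, 1)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# Exhaustive k-means optimum over all label assignments (tiny n only).
oracle_kmeans_best <- function(x, k) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(k^n <= 4e5)
  best <- Inf
  assign <- rep(1L, n)
  for (code in 0:(k^n - 1)) {
    c0 <- code
    for (i in seq_len(n)) {
      assign[i] <- c0 %% k + 1L
      c0 <- c0 %/% k
    }
    if (length(unique(assign)) < k) next
    ss <- 0
    for (l in seq_len(k)) {
      xi <- x[assign == l, , drop = FALSE]
      ss <- ss + sum(sweep(xi, 2, colMeans(xi))^2)
    }
    best <- min(best, ss)
  }
  best
}

# Random discretized test image: 0 outside a random mask, 1..ng inside.
random_level_image <- function(dims, ng, mask_prob = 0.8) {
  lv <- array(0L, dims)
  inside <- array(runif(prod(dims)) < mask_prob, dims)
  lv[inside] <- sample.int(ng, sum(inside), replace = TRUE)
  lv
}

# Wrap a level array as the package's discretized_image container.
as_discretized <- function(levels, ng) {
  structure(list(levels = levels, n_levels = as.integer(ng),
                 bin_edges = seq(0, 1, length.out = ng + 1)),
            class = "discretized_image")
}

# Small standard phantom used across tests.
test_phantom <- function(seed = 1, radius = 8, grid = 32, ...) {
  make_phantom(phantom_spec(grid_shape = rep(grid, 3),
                            lesion_radius_mm = radius, seed = seed, ...))
}

standardized_voxels <- function(ph) {
  sv <- mp_volume(
    standardize_roi_intensities(ph$volume$t1, ph$mask),
    standardize_roi_intensities(ph$volume$t2, ph$mask),
    standardize_roi_intensities(ph$volume$adc, ph$mask),
    spacing_mm = ph$volume$spacing_mm
  )
  build_voxel_matrix(sv, ph$mask)
}
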