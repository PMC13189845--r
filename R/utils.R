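# Shared internal helpers: seeded RNG scopes, grid/coordinate utilities,
# neighbour offsets and small statistics used across modules.

# Run `code` under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Deterministically derive a sub-seed from a global seed; keeps results
# reproducible per stage while staying inside the 32-bit integer range.
derive_seed <- function(seed, stage) {
  offs <- sum(utf8ToInt(as.character(stage))) %% 1000L
  as.integer((as.double(seed) * 1009 + offs * 7919 + 17) %% 2147483647)
}

# 13 unique 3D direction offsets (half of the 26-neighbourhood).
offsets13 <- function() {
  m <- rbind(
    c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
    c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
    c(0, 1, 1), c(0, 1, -1),
    c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1)
  )
  storage.mode(m) <- "integer"
  m
}

# Full 26-neighbourhood offsets.
offsets26 <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  storage.mode(g) <- "integer"
  g
}

# Voxel-index coordinates (0-based) of TRUE entries of a 3D logical array,
# in lexicographic (column-major) order.
mask_coords <- function(mask) {
  stopifnot(length(dim(mask)) == 3)
  idx <- which(mask != 0)
  arr <- arrayInd(idx, dim(mask))
  storage.mode(arr) <- "integer"
  colnames(arr) <- c("i", "j", "k")
  arr - 1L
}

# Wilson score interval for a binomial proportion.
wilson_ci <- function(x, n, level = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- qnorm(1 - (1 - level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, centre - half), min(1, centre + half))
}

# Adjusted Rand index between two integer label vectors.
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# Binary labels coerced to 0/1 integer; accepts factor, character
# ("positive"/"negative"), logical or numeric.
as_binary_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    lv <- sort(unique(labels))
    if (all(lv %in% c("negative", "positive"))) {
      return(as.integer(labels == "positive"))
    }
    if (length(lv) > 2) stop("labels must be binary")
    return(as.integer(labels == lv[length(lv)]))
  }
  out <- as.integer(as.logical(labels != 0))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
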