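#' Selection configuration
#'
#' @param icc_threshold Features with ICC below this are dropped (0.75).
#' @param pearson_threshold Absolute-correlation redundancy cutoff (0.90).
#' @param mrmr_keep Number of features kept by the mRMR ranking.
#' @param lasso_folds Cross-validation folds for the LASSO (10).
#' @param lambda_rule `"min"` or `"1se"`.
#' @param seed Seed for CV fold assignment.
#' @return A `selection_config` list.
#' @export
selection_config <- function(icc_threshold = 0.75, pearson_threshold = 0.90,
                             mrmr_keep = 30L, lasso_folds = 10L,
                             lambda_rule = c("min", "1se"), seed = 1L) {
  lambda_rule <- match.arg(lambda_rule)
  stopifnot(icc_threshold > 0, icc_threshold <= 1,
            pearson_threshold > 0, pearson_threshold <= 1, lasso_folds >= 2)
  structure(list(icc_threshold = icc_threshold,
                 pearson_threshold = pearson_threshold,
                 mrmr_keep = as.integer(mrmr_keep),
                 lasso_folds = as.integer(lasso_folds),
                 lambda_rule = lambda_rule, seed = as.integer(seed)),
            class = "selection_config")
}

#' Intraclass correlation coefficient, ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single rater, from the
#' standard mean-square decomposition:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#'
#' @param ratings Numeric matrix, subjects x raters (at least 3 subjects
#'   and 2 raters).
#' @return The ICC value, or `NA` when the total variance is zero.
#' @examples
#' m <- cbind(c(9, 6, 8, 7, 10, 6), c(2, 1, 4, 1, 5, 2))
#' compute_icc(m)
#' @export
compute_icc <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 3 || k < 2) stop("need >= 3 subjects and >= 2 raters")
  grand <- mean(ratings)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  SSR <- k * sum((row_m - grand)^2)
  SSC <- n * sum((col_m - grand)^2)
  SST <- sum((ratings - grand)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  if (SST == 0) return(NA_real_)
  (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
}

#' Reproducibility screen across repeat delineations
#'
#' Computes ICC(2,1) per feature from two feature tables extracted from
#' repeat delineations of the same subjects, and drops features below the
#' threshold (or with undefined ICC).
#'
#' @param table1,table2 Numeric data frames with the same feature columns
#'   and subjects in the same row order.
#' @param threshold ICC cutoff (default 0.75).
#' @return List with `icc` (tibble feature, icc) and `survivors`.
#' @export
icc_filter <- function(table1, table2, threshold = 0.75) {
  feats <- intersect(names(table1), names(table2))
  icc <- vapply(feats, function(f) {
    ok <- stats::complete.cases(table1[[f]], table2[[f]])
    if (sum(ok) < 3) return(NA_real_)
    compute_icc(cbind(table1[[f]][ok], table2[[f]][ok]))
  }, numeric(1))
  undefined <- is.na(icc)
  if (any(undefined)) {
    warning("ICC undefined (zero variance) for ",
            sum(undefined), " feature(s); dropped")
  }
  list(icc = tibble::tibble(feature = feats, icc = unname(icc)),
       survivors = feats[!undefined & icc >= threshold])
}

#' Univariate Welch t-test per feature
#'
#' Two-sided Welch t-test of each feature between classes; the resulting
#' p-values order features by relevance downstream. Zero variance in both
#' groups yields p = 1.
#'
#' @param table Numeric data frame of features.
#' @param labels Binary class labels.
#' @return Tibble with `feature`, `statistic`, `p_value`.
#' @export
univariate_test <- function(table, labels) {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2) stop("both classes must be nonempty")
  if (min(table(y)) < 2) stop("need at least 2 samples per class")
  res <- purrr::map(names(table), function(f) {
    x <- table[[f]]
    if (sd(x[y == 0]) == 0 && sd(x[y == 1]) == 0) {
      return(tibble::tibble(feature = f, statistic = 0, p_value = 1))
    }
    tt <- tryCatch(t.test(x[y == 1], x[y == 0]),
                   error = function(e) NULL)
    if (is.null(tt)) {
      return(tibble::tibble(feature = f, statistic = 0, p_value = 1))
    }
    tibble::tibble(feature = f, statistic = unname(tt$statistic),
                   p_value = tt$p.value)
  })
  dplyr::bind_rows(res)
}

#' Pearson redundancy filter
#'
#' For every feature pair with `|r| > threshold`, the member with the
#' weaker univariate relevance is marked for removal (ties by lexicographic
#' name, the later name dropped). The drop set is computed from the full
#' correlation matrix at once, so the result does not depend on column
#' order. Constant features are dropped first.
#'
#' @param table Numeric data frame of features.
#' @param threshold Absolute correlation cutoff.
#' @param relevance_scores Named numeric vector; larger = more relevant
#'   (e.g. `-log10` p-values). Missing names get relevance `-Inf`.
#' @return List with `survivors`, `dropped` (tibble feature, partner, r).
#' @export
pearson_filter <- function(table, threshold = 0.90, relevance_scores = NULL) {
  feats <- names(table)
  const <- vapply(table, function(x) sd(x) == 0 || !is.finite(sd(x)), logical(1))
  if (any(const)) {
    warning("dropping constant feature(s): ", paste(feats[const], collapse = ", "))
  }
  keep <- feats[!const]
  if (length(keep) < 2) {
    return(list(survivors = keep, dropped = tibble::tibble(
      feature = character(), partner = character(), r = numeric())))
  }
  rel <- setNames(rep(-Inf, length(keep)), keep)
  if (!is.null(relevance_scores)) {
    common <- intersect(names(relevance_scores), keep)
    rel[common] <- relevance_scores[common]
  }
  cm <- cor(as.matrix(table[keep]))
  drop <- character(); dropped_rows <- list()
  pairs <- which(abs(cm) > threshold & upper.tri(cm), arr.ind = TRUE)
  for (r in seq_len(nrow(pairs))) {
    a <- keep[pairs[r, 1]]; b <- keep[pairs[r, 2]]
    loser <- if (rel[a] < rel[b]) a
    else if (rel[b] < rel[a]) b
    else max(a, b) # tie: lexicographically later name is dropped
    dropped_rows[[length(dropped_rows) + 1]] <- tibble::tibble(
      feature = loser, partner = setdiff(c(a, b), loser), r = cm[a, b])
    drop <- c(drop, loser)
  }
  list(survivors = setdiff(keep, unique(drop)),
       dropped = dplyr::bind_rows(dropped_rows))
}

# Mutual information between two integer-coded discrete vectors.
discrete_mi <- function(a, b) {
  tab <- table(a, b)
  p <- tab / sum(tab)
  pa <- rowSums(p); pb <- colSums(p)
  ex <- outer(pa, pb)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / ex[nz]))
}

quantile_bin <- function(x, bins = 4L) {
  br <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1)))
  if (length(br) < 2) return(rep(1L, length(x)))
  as.integer(cut(x, br, include.lowest = TRUE))
}

#' Minimum-redundancy maximum-relevance feature ranking
#'
#' Greedy mRMR with the MID criterion (relevance minus mean redundancy),
#' mutual information computed on 4-bin quantile-discretized features.
#' Deterministic: ties break toward the lexicographically earlier name.
#'
#' @param table Numeric data frame of features.
#' @param labels Binary class labels.
#' @param keep Number of features to rank (clamped to the feature count).
#' @param bins Quantile bins for the MI estimate.
#' @return Character vector of ranked feature names (best first).
#' @export
mrmr_rank <- function(table, labels, keep = 30L, bins = 4L) {
  y <- as_binary_labels(labels)
  feats <- names(table)
  if (length(feats) < 1) stop("need at least one feature")
  keep <- min(as.integer(keep), length(feats))
  disc <- lapply(table, quantile_bin, bins = bins)
  relevance <- vapply(feats, function(f) discrete_mi(disc[[f]], y), numeric(1))
  ord <- order(-relevance, feats) # ties -> lexicographic
  selected <- feats[ord[1]]
  remaining <- setdiff(feats, selected)
  red_cache <- matrix(NA_real_, length(feats), length(feats),
                      dimnames = list(feats, feats))
  while (length(selected) < keep && length(remaining) > 0) {
    score <- vapply(remaining, function(f) {
      reds <- vapply(selected, function(s) {
        if (is.na(red_cache[f, s])) {
          red_cache[f, s] <<- discrete_mi(disc[[f]], disc[[s]])
        }
        red_cache[f, s]
      }, numeric(1))
      relevance[f] - mean(reds)
    }, numeric(1))
    pick <- remaining[order(-score, remaining)[1]]
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
  }
  selected
}

#' LASSO feature selection with cross-validation
#'
#' L1-penalized logistic regression over a log-spaced lambda grid with
#' stratified k-fold cross-validated deviance; features with nonzero
#' coefficients at the chosen lambda survive.
#'
#' @param table Numeric data frame of (standardized) features.
#' @param labels Binary class labels.
#' @param config A [selection_config()].
#' @return List with `survivors`, `coefficients` (tibble feature, coef),
#'   `lambda`, `lambda_grid`, `cv_deviance` and the `glmnet` fit.
#' @export
lasso_cv_select <- function(table, labels, config = selection_config()) {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2) stop("labels are all one class")
  x <- as.matrix(table)
  n <- nrow(x)
  if (n < config$lasso_folds) stop("need n >= number of folds")
  foldid <- stratified_folds(y, config$lasso_folds, config$seed)
  cvfit <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1,
                             foldid = foldid, type.measure = "deviance",
                             standardize = FALSE)
  lam <- if (config$lambda_rule == "min") cvfit$lambda.min else cvfit$lambda.1se
  co <- as.matrix(coef(cvfit, s = lam))
  nz <- rownames(co)[co[, 1] != 0 & rownames(co) != "(Intercept)"]
  list(
    survivors = nz,
    coefficients = tibble::tibble(feature = rownames(co)[-1],
                                  coef = unname(co[-1, 1])),
    lambda = lam, lambda_grid = cvfit$lambda,
    cv_deviance = cvfit$cvm, fit = cvfit
  )
}

stratified_folds <- function(y, k, seed) {
  foldid <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      foldid[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  foldid
}

#' Staged feature selection pipeline
#'
#' ICC reproducibility screen (when repeat-delineation ratings are
#' available), univariate Welch t relevance, Pearson redundancy filter,
#' mRMR ranking, then cross-validated LASSO. Each stage's survivors are a
#' subset of the previous stage's (recorded for audit).
#'
#' @param table Numeric data frame of features (rows = patients).
#' @param labels Binary class labels.
#' @param config A [selection_config()].
#' @param icc_tables Optional list of two feature tables from repeat
#'   delineations (subjects x features) for the ICC stage.
#' @return A `selection_result` with per-stage survivors and diagnostics.
#' @export
select_features <- function(table, labels, config = selection_config(),
                            icc_tables = NULL) {
  stopifnot(is.data.frame(table))
  table <- table[vapply(table, is.numeric, logical(1))]
  stages <- list(input = names(table))

  icc <- NULL
  current <- names(table)
  if (!is.null(icc_tables)) {
    ic <- icc_filter(icc_tables[[1]], icc_tables[[2]], config$icc_threshold)
    icc <- ic$icc
    current <- intersect(current, ic$survivors)
    stages$icc <- current
  }

  # z-score features across patients (feature-level normalization)
  ztab <- standardize_feature_table(table[current])
  current <- names(ztab)

  uni <- univariate_test(ztab, labels)
  relevance <- setNames(-log10(pmax(uni$p_value, 1e-300)), uni$feature)
  stages$univariate <- current

  pf <- pearson_filter(ztab[current], config$pearson_threshold, relevance)
  current <- intersect(current, pf$survivors)
  stages$pearson <- current

  ranked <- mrmr_rank(ztab[current], labels, keep = config$mrmr_keep)
  current <- ranked
  stages$mrmr <- current

  if (nrow(ztab) < config$lasso_folds) {
    warning("fewer samples than LASSO folds; reducing to leave-one-out")
    config$lasso_folds <- nrow(ztab)
  }
  las <- lasso_cv_select(ztab[current], labels, config)
  survivors <- las$survivors
  if (length(survivors) == 0) {
    # fall back to the densest end of the path so a model can still be fit
    co <- as.matrix(coef(las$fit$glmnet.fit,
                         s = min(las$lambda_grid)))
    nz <- rownames(co)[co[, 1] != 0 & rownames(co) != "(Intercept)"]
    survivors <- if (length(nz)) nz else current[1]
    warning("LASSO selected no features at the chosen lambda; ",
            "falling back to the densest path end")
  }
  stages$lasso <- survivors

  structure(
    list(stages = stages, survivors = survivors, icc = icc,
         univariate = uni, pearson_dropped = pf$dropped, mrmr = ranked,
         lasso = las[c("coefficients", "lambda", "lambda_grid", "cv_deviance")],
         scaling = attr(ztab, "scaling"), config = config),
    class = "selection_result"
  )
}

standardize_feature_table <- function(table) {
  mu <- vapply(table, mean, numeric(1))
  sg <- vapply(table, sd, numeric(1))
  keep <- is.finite(sg) & sg > 0
  out <- as.data.frame(mapply(function(x, m, s) (x - m) / s,
                              table[keep], mu[keep], sg[keep],
                              SIMPLIFY = FALSE), check.names = FALSE)
  out <- tibble::as_tibble(out)
  attr(out, "scaling") <- tibble::tibble(feature = names(table)[keep],
                                         mean = mu[keep], sd = sg[keep])
  out
}

#' @export
tidy.selection_result <- function(x, ...) {
  dplyr::left_join(
    tibble::tibble(feature = x$stages$input),
    dplyr::rename(x$lasso$coefficients, lasso_coef = "coef"),
    by = "feature"
  ) |>
    dplyr::mutate(
      selected = .data$feature %in% x$survivors,
      mrmr_rank = match(.data$feature, x$mrmr)
    ) |>
    dplyr::arrange(dplyr::desc(.data$selected), .data$mrmr_rank)
}

#' @export
glance.selection_result <- function(x, ...) {
  tibble::tibble(
    n_input = length(x$stages$input),
    n_after_icc = length(x$stages$icc %||% x$stages$input),
    n_after_pearson = length(x$stages$pearson),
    n_after_mrmr = length(x$stages$mrmr),
    n_selected = length(x$survivors),
    lambda = x$lasso$lambda
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat("Feature selection:",
      paste(vapply(names(x$stages), function(s)
        sprintf("%s=%d", s, length(x$stages[[s]])), character(1)),
        collapse = " -> "), "\n")
  invisible(x)
}
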