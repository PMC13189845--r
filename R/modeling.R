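#' Fit a logistic classifier on selected features
#'
#' Unpenalized maximum-likelihood logistic regression on feature-table
#' columns standardized with training means/SDs (a tiny ridge via `glmnet`
#' is used instead, with a warning, when the MLE does not converge or the
#' classes are separable). Reports a stratified 5-fold cross-validated AUC
#' and sets the decision threshold at the Youden optimum of the training
#' ROC.
#'
#' @param table Data frame of features (training rows).
#' @param labels Binary class labels.
#' @param features Feature names to use (default: all numeric columns).
#' @param cv_folds Stratified CV folds (default 5).
#' @param seed Seed for the fold assignment.
#' @param ridge_lambda Penalty used by the fallback fit.
#' @return A `lesion_lr` model: coefficients, intercept, per-feature
#'   training mean/SD, Youden `threshold`, `cv_auc`.
#' @export
fit_logistic <- function(table, labels, features = NULL, cv_folds = 5L,
                         seed = 1L, ridge_lambda = 1e-3) {
  y <- as_binary_labels(labels)
  if (min(table(y)) < 2) stop("need at least 2 samples per class")
  if (is.null(features)) {
    features <- names(table)[vapply(table, is.numeric, logical(1))]
  }
  x <- as.matrix(table[features])
  mu <- colMeans(x)
  sg <- apply(x, 2, sd)
  if (any(!is.finite(sg)) || any(sg == 0)) stop("constant feature in model matrix")
  xs <- scale(x, mu, sg)

  fit_one <- function(xs, y) {
    fit <- suppressWarnings(glm.fit(cbind(1, xs), y, family = binomial()))
    separated <- !fit$converged || anyNA(fit$coefficients) ||
      any(abs(fit$coefficients[-1]) > 20)
    if (separated) {
      xr <- if (ncol(xs) == 1) cbind(xs, 0) else xs # glmnet needs >= 2 cols
      gf <- glmnet::glmnet(xr, y, family = "binomial", alpha = 0,
                           lambda = ridge_lambda, standardize = FALSE)
      co <- as.matrix(coef(gf))
      list(intercept = co[1, 1], beta = co[1 + seq_len(ncol(xs)), 1],
           ridge = TRUE)
    } else {
      list(intercept = fit$coefficients[1], beta = fit$coefficients[-1],
           ridge = FALSE)
    }
  }
  full <- fit_one(xs, y)
  if (full$ridge) warning("separation or non-convergence: ridge fallback used")

  foldid <- stratified_folds(y, cv_folds, seed)
  cv_scores <- rep(NA_real_, length(y))
  for (f in seq_len(cv_folds)) {
    tr <- foldid != f
    if (length(unique(y[tr])) < 2) next
    m <- fit_one(xs[tr, , drop = FALSE], y[tr])
    eta <- m$intercept + xs[!tr, , drop = FALSE] %*% m$beta
    cv_scores[!tr] <- stats::plogis(eta)
  }
  ok <- !is.na(cv_scores)
  cv_auc <- if (sum(ok) && length(unique(y[ok])) == 2) {
    roc_auc(cv_scores[ok], y[ok])
  } else NA_real_

  train_scores <- as.vector(stats::plogis(full$intercept + xs %*% full$beta))
  thr <- youden_threshold(train_scores, y)
  structure(
    list(feature_names = features,
         coefficients = setNames(as.vector(full$beta), features),
         intercept = unname(full$intercept),
         scaling = tibble::tibble(feature = features, mean = mu, sd = sg),
         threshold = thr, cv_auc = cv_auc, ridge = full$ridge,
         train_scores = train_scores, train_labels = y, seed = seed),
    class = "lesion_lr"
  )
}

#' Predicted malignancy probabilities from a fitted model
#' @param object A `lesion_lr` model.
#' @param newdata Data frame containing the model's feature columns.
#' @param ... Unused.
#' @return Numeric vector of probabilities.
#' @export
predict.lesion_lr <- function(object, newdata, ...) {
  x <- as.matrix(newdata[object$feature_names])
  xs <- scale(x, object$scaling$mean, object$scaling$sd)
  as.vector(stats::plogis(object$intercept + xs %*% object$coefficients))
}

#' @export
tidy.lesion_lr <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", x$feature_names),
                 estimate = c(x$intercept, unname(x$coefficients)))
}

#' @export
glance.lesion_lr <- function(x, ...) {
  tibble::tibble(n_features = length(x$feature_names),
                 cv_auc = x$cv_auc, threshold = x$threshold, ridge = x$ridge)
}

youden_threshold <- function(scores, labels) {
  y <- as_binary_labels(labels)
  cand <- sort(unique(scores))
  best <- cand[1]; best_j <- -Inf
  for (t in cand) {
    sens <- mean(scores[y == 1] >= t)
    spec <- mean(scores[y == 0] < t)
    j <- sens + spec - 1
    if (j > best_j) { best_j <- j; best <- t }
  }
  best
}

#' Area under the ROC curve (Mann-Whitney estimator)
#'
#' Probability that a random positive scores above a random negative, with
#' ties credited 0.5 — identical to the trapezoidal area under the
#' empirical ROC curve.
#'
#' @param scores Numeric risk scores.
#' @param labels Binary class labels.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong structural components: list(auc, v10 (per positive), v01 (per
# negative)). The placement values psi(X_i, Y_j) with 0.5 tie credit.
delong_components <- function(scores, labels) {
  y <- as_binary_labels(labels)
  xs <- scores[y == 1]; ys <- scores[y == 0]
  m <- length(xs); n <- length(ys)
  cmp <- outer(xs, ys, function(a, b) (a > b) + 0.5 * (a == b))
  list(auc = mean(cmp), v10 = rowMeans(cmp), v01 = colMeans(cmp),
       m = m, n = n)
}

#' DeLong confidence interval for one AUC
#'
#' Variance from the DeLong structural components with a normal
#' approximation, clipped to `[0, 1]`. A degenerate zero-variance case
#' (perfect separation without ties) returns the point interval with a
#' warning.
#'
#' @param scores Numeric risk scores.
#' @param labels Binary class labels (>= 2 per class).
#' @param level Confidence level (default 0.95).
#' @return Named vector `c(auc, lo, hi)`.
#' @export
delong_ci <- function(scores, labels, level = 0.95) {
  dc <- delong_components(scores, labels)
  if (dc$m < 2 || dc$n < 2) stop("need at least 2 samples per class")
  v <- var(dc$v10) / dc$m + var(dc$v01) / dc$n
  if (v == 0) {
    warning("zero DeLong variance: degenerate confidence interval")
    return(c(auc = dc$auc, lo = dc$auc, hi = dc$auc))
  }
  z <- qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(v)
  c(auc = dc$auc, lo = max(0, dc$auc - half), hi = min(1, dc$auc + half))
}

#' Paired DeLong test for two correlated AUCs
#'
#' Compares the ROC curves of two score vectors on the same samples:
#' `z = (AUC_A - AUC_B) / SE(diff)` with the covariance of the structural
#' components, two-sided normal p-value. Identical score vectors give
#' z = 0, p = 1.
#'
#' @param scores_a,scores_b Paired risk scores on identical samples.
#' @param labels Binary class labels.
#' @return Named vector `c(auc_a, auc_b, z, p_value)`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  stopifnot(length(scores_a) == length(scores_b))
  da <- delong_components(scores_a, labels)
  db <- delong_components(scores_b, labels)
  s10 <- cov(cbind(da$v10, db$v10))
  s01 <- cov(cbind(da$v01, db$v01))
  S <- s10 / da$m + s01 / da$n
  v <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  d <- da$auc - db$auc
  if (v <= 0) {
    z <- if (d == 0) 0 else sign(d) * Inf
  } else {
    z <- d / sqrt(v)
  }
  p <- if (is.infinite(z)) 0 else 2 * pnorm(-abs(z))
  if (d == 0 && v <= 0) p <- 1
  c(auc_a = da$auc, auc_b = db$auc, z = unname(z), p_value = unname(p))
}

#' Confusion-matrix metrics with Wilson confidence intervals
#'
#' Accuracy, sensitivity, specificity, PPV and NPV of the classifier
#' `score >= threshold`, each with a Wilson score interval. An empty
#' predicted-positive (or -negative) set leaves PPV (NPV) missing.
#'
#' @param scores Numeric risk scores in `[0, 1]`.
#' @param labels Binary class labels.
#' @param threshold Decision threshold in `[0, 1]`.
#' @param level Confidence level.
#' @return Tibble with `metric`, `estimate`, `lo`, `hi`.
#' @export
threshold_metrics <- function(scores, labels, threshold, level = 0.95) {
  stopifnot(threshold >= 0, threshold <= 1)
  y <- as_binary_labels(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  tn <- sum(pred == 0 & y == 0); fn <- sum(pred == 0 & y == 1)
  one <- function(metric, x, n) {
    if (n == 0) {
      return(tibble::tibble(metric = metric, estimate = NA_real_,
                            lo = NA_real_, hi = NA_real_))
    }
    ci <- wilson_ci(x, n, level)
    tibble::tibble(metric = metric, estimate = x / n, lo = ci[1], hi = ci[2])
  }
  dplyr::bind_rows(
    one("accuracy", tp + tn, length(y)),
    one("sensitivity", tp, tp + fn),
    one("specificity", tn, tn + fp),
    one("ppv", tp, tp + fp),
    one("npv", tn, tn + fn)
  )
}

#' Calibration curve and logistic recalibration
#'
#' Equal-width bins of the predicted probabilities (empty bins omitted)
#' with observed event rates, plus the slope/intercept of a logistic
#' recalibration of the outcome on the score logits.
#'
#' @param scores Predicted probabilities in `[0, 1]`.
#' @param labels Binary class labels.
#' @param n_bins Number of equal-width bins (default 10).
#' @return List with `bins` (tibble bin, mean_predicted, observed_rate, n)
#'   and `slope`, `intercept` of the recalibration fit.
#' @export
calibration_curve <- function(scores, labels, n_bins = 10L) {
  stopifnot(all(scores >= 0 & scores <= 1))
  y <- as_binary_labels(labels)
  bin <- pmin(as.integer(floor(scores * n_bins)) + 1L, n_bins)
  bins <- tibble::tibble(bin = bin, score = scores, y = y) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(mean_predicted = mean(.data$score),
                     observed_rate = mean(.data$y), n = dplyr::n(),
                     .groups = "drop")
  eps <- 1e-12
  lg <- stats::qlogis(pmin(pmax(scores, eps), 1 - eps))
  rec <- tryCatch(glm(y ~ lg, family = binomial()), error = function(e) NULL)
  slope <- if (is.null(rec)) NA_real_ else unname(coef(rec)[2])
  intercept <- if (is.null(rec)) NA_real_ else unname(coef(rec)[1])
  list(bins = bins, slope = slope, intercept = intercept)
}

#' Decision-curve analysis
#'
#' Net benefit `NB(pt) = TP/n - (FP/n) * pt/(1-pt)` of the model's
#' threshold rule across a grid of threshold probabilities, alongside the
#' treat-all and treat-none strategies.
#'
#' @param scores Predicted probabilities.
#' @param labels Binary class labels.
#' @param thresholds Grid of threshold probabilities in (0, 1).
#' @return Tibble with `threshold`, `net_benefit_model`,
#'   `net_benefit_all`, `net_benefit_none`.
#' @export
decision_curve <- function(scores, labels,
                           thresholds = seq(0.01, 0.99, by = 0.01)) {
  if (any(thresholds <= 0 | thresholds >= 1)) {
    stop("thresholds must lie strictly inside (0, 1)")
  }
  y <- as_binary_labels(labels)
  n <- length(y)
  prev <- mean(y)
  rows <- purrr::map(thresholds, function(pt) {
    pred <- scores >= pt
    tp <- sum(pred & y == 1); fp <- sum(pred & y == 0)
    w <- pt / (1 - pt)
    tibble::tibble(
      threshold = pt,
      net_benefit_model = tp / n - fp / n * w,
      net_benefit_all = prev - (1 - prev) * w,
      net_benefit_none = 0
    )
  })
  dplyr::bind_rows(rows)
}

#' Exact SHAP attributions for a linear logistic model
#'
#' For a model linear in its inputs the Shapley values have the closed
#' form `phi_j = beta_j * (x_j - mean(x_j))` on the logit scale, and the
#' attributions satisfy `sum(phi) + base = logit(score)` exactly.
#'
#' @param model A `lesion_lr` model.
#' @param samples Data frame containing the model's features.
#' @param background Data frame whose column means define the background
#'   (default: the model's training standardization means).
#' @return List with `attributions` (samples x features tibble), `base`
#'   (expected logit) and `logit` (per-sample total).
#' @export
linear_shap <- function(model, samples, background = NULL) {
  x <- as.matrix(samples[model$feature_names])
  xs <- scale(x, model$scaling$mean, model$scaling$sd)
  bg <- if (is.null(background)) {
    rep(0, length(model$feature_names)) # training means standardize to 0
  } else {
    colMeans(scale(as.matrix(background[model$feature_names]),
                   model$scaling$mean, model$scaling$sd))
  }
  phi <- sweep(xs, 2, bg) * rep(model$coefficients, each = nrow(xs))
  base <- model$intercept + sum(model$coefficients * bg)
  logit <- base + rowSums(phi)
  list(attributions = tibble::as_tibble(as.data.frame(phi)),
       base = base, logit = as.vector(logit))
}

#' Mean-ADC baseline classifier
#'
#' The conventional quantitative baseline: lower mean in-lesion ADC means
#' more malignant. Scores are the negated mean in-mask ADC; the threshold
#' rule classifies positive when mean ADC falls below `threshold`
#' (default 1.29, in 10^-3 mm^2/s units).
#'
#' @param adc_volumes List of 3D ADC arrays (clinical 10^-3 mm^2/s scale).
#' @param masks List of matching masks ([lesion_mask()] or arrays).
#' @param threshold Clinical ADC decision threshold.
#' @return Tibble with `mean_adc`, `score`, `predicted`.
#' @export
mean_adc_baseline <- function(adc_volumes, masks, threshold = 1.29) {
  stopifnot(length(adc_volumes) == length(masks))
  mean_adc <- purrr::map2_dbl(adc_volumes, masks, function(v, m) {
    if (inherits(m, "lesion_mask")) m <- m$mask
    idx <- which(m != 0)
    if (length(idx) == 0) stop("empty mask in ADC baseline")
    mean(v[idx])
  })
  tibble::tibble(mean_adc = mean_adc, score = -mean_adc,
                 predicted = as.integer(mean_adc < threshold))
}

#' Evaluate a fitted model on a cohort
#'
#' @param model A `lesion_lr` model.
#' @param table Feature data frame for the evaluation cohort.
#' @param labels Binary class labels.
#' @param dca_thresholds Grid for the decision curve.
#' @return An `evaluation_report`: AUC with DeLong CI, threshold metrics at
#'   the model's training Youden threshold, calibration, decision curve,
#'   SHAP attributions and the raw scores.
#' @export
evaluate_model <- function(model, table, labels,
                           dca_thresholds = seq(0.05, 0.95, by = 0.05)) {
  y <- as_binary_labels(labels)
  scores <- predict(model, table)
  ci <- delong_ci(scores, y)
  structure(
    list(
      auc = ci[["auc"]], auc_ci = c(ci[["lo"]], ci[["hi"]]),
      metrics = threshold_metrics(scores, y, model$threshold),
      calibration = calibration_curve(scores, y),
      dca = decision_curve(scores, y, dca_thresholds),
      shap = linear_shap(model, table),
      scores = scores, labels = y, threshold = model$threshold
    ),
    class = "evaluation_report"
  )
}

#' @export
glance.evaluation_report <- function(x, ...) {
  wide <- setNames(x$metrics$estimate, x$metrics$metric)
  tibble::tibble(auc = x$auc, auc_lo = x$auc_ci[1], auc_hi = x$auc_ci[2],
                 accuracy = wide[["accuracy"]],
                 sensitivity = wide[["sensitivity"]],
                 specificity = wide[["specificity"]],
                 ppv = wide[["ppv"]], npv = wide[["npv"]])
}

#' @export
tidy.evaluation_report <- function(x, ...) x$metrics

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f), threshold %.3f\n",
              x$auc, x$auc_ci[1], x$auc_ci[2], x$threshold))
  print(x$metrics)
  invisible(x)
}
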