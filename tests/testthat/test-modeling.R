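test_that("AUC estimator matches trivial cases and the trapezoid oracle", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1.0)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")

  withr::local_seed(30)
  for (rep in 1:20) {
    y <- rep(c(0, 1), each = 20)
    s <- rnorm(40) + y
    if (rep %% 2 == 0) s <- round(s, 1) # force ties
    expect_equal(roc_auc(s, y), oracle_auc_trapezoid(s, y), tolerance = 1e-12)
  }
})

test_that("AUC and DeLong agree with pROC", {
  skip_if_not_installed("pROC")
  withr::local_seed(31)
  y <- rep(c(0, 1), each = 30)
  a <- rnorm(60) + y * 1.2
  b <- rnorm(60) + y * 0.7
  r <- pROC::roc(y, a, quiet = TRUE, direction = "<")
  expect_equal(roc_auc(a, y), as.numeric(pROC::auc(r)), tolerance = 1e-12)
  ci <- delong_ci(a, y)
  pci <- as.numeric(pROC::ci.auc(r, method = "delong"))
  expect_equal(unname(ci), c(pci[2], pci[1], pci[3]), tolerance = 1e-9)
  dt <- delong_test(a, b, y)
  rb <- pROC::roc(y, b, quiet = TRUE, direction = "<")
  pt <- pROC::roc.test(r, rb, method = "delong", paired = TRUE)
  expect_equal(dt[["p_value"]], pt$p.value, tolerance = 1e-9)
})

test_that("DeLong CI degenerates gracefully and tracks the bootstrap", {
  expect_warning(ci <- delong_ci(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)),
                 "degenerate")
  expect_equal(unname(ci), c(1, 1, 1))

  withr::local_seed(32)
  y <- rep(c(0, 1), each = 50)
  s <- rnorm(100) + y * 1.1
  dc <- habitatomics:::delong_components(s, y)
  v <- var(dc$v10) / dc$m + var(dc$v01) / dc$n
  boot <- replicate(2000, {
    i <- c(sample(which(y == 0), 50, TRUE), sample(which(y == 1), 50, TRUE))
    roc_auc(s[i], y[i])
  })
  expect_equal(v, var(boot), tolerance = 0.2)
})

test_that("the paired DeLong test is symmetric with sane degenerate limits", {
  withr::local_seed(33)
  y <- rep(c(0, 1), each = 25)
  a <- rnorm(50) + y * 2
  expect_equal(delong_test(a, a, y)[["p_value"]], 1)
  expect_equal(delong_test(a, a, y)[["z"]], 0)

  b <- -a # reversed ranking
  dt <- delong_test(a, b, y)
  expect_lt(dt[["p_value"]], 0.01)
  flipped <- delong_test(b, a, y)
  expect_equal(dt[["z"]], -flipped[["z"]], tolerance = 1e-12)
})

test_that("threshold metrics reproduce hand-computed confusion matrices", {
  scores <- c(rep(0.9, 9), rep(0.1, 1), rep(0.2, 8), rep(0.8, 2))
  labels <- c(rep(1, 10), rep(0, 10))
  tm <- threshold_metrics(scores, labels, threshold = 0.5)
  est <- setNames(tm$estimate, tm$metric)
  expect_equal(est[["sensitivity"]], 0.9)
  expect_equal(est[["specificity"]], 0.8)
  expect_equal(est[["ppv"]], 9 / 11)
  expect_equal(est[["accuracy"]], 17 / 20)
  expect_true(all(tm$lo <= tm$estimate & tm$estimate <= tm$hi))

  perfect <- threshold_metrics(c(1, 1, 0, 0), c(1, 1, 0, 0), 0.5)
  expect_true(all(perfect$estimate == 1))

  forced <- threshold_metrics(rep(1, 10), rep(c(1, 0), 5), 0.5)
  f <- setNames(forced$estimate, forced$metric)
  expect_equal(f[["sensitivity"]], 1)
  expect_equal(f[["specificity"]], 0)
  expect_equal(f[["ppv"]], 0.5) # prevalence
  expect_true(is.na(f[["npv"]])) # empty predicted-negative set
})

test_that("calibration bins and recalibration slope behave as constructed", {
  withr::local_seed(34)
  p <- runif(5000)
  y <- rbinom(5000, 1, p)
  cal <- calibration_curve(p, y)
  expect_equal(cal$slope, 1, tolerance = 0.1)
  expect_true(all(abs(cal$bins$mean_predicted - cal$bins$observed_rate) < 0.1))

  one_bin <- calibration_curve(rep(0.5, 400), rbinom(400, 1, 0.5))
  expect_equal(nrow(one_bin$bins), 1L)
  expect_equal(one_bin$bins$observed_rate, 0.5, tolerance = 0.08)

  over <- calibration_curve(rep(0.9, 500), rbinom(500, 1, 0.5))
  expect_lt(over$bins$observed_rate, 0.75) # overconfident in a known direction
})

test_that("decision curves follow the net-benefit formulas", {
  withr::local_seed(35)
  y <- rep(c(0, 1), times = c(60, 40)) # prevalence 0.4
  dca <- decision_curve(runif(100), y, thresholds = 0.5)
  expect_equal(dca$net_benefit_all, 0.4 - 0.6, tolerance = 1e-12)
  expect_equal(dca$net_benefit_none, 0)

  perfect <- decision_curve(y, y, thresholds = c(0.2, 0.5, 0.8))
  expect_equal(perfect$net_benefit_model, rep(0.4, 3), tolerance = 1e-12)

  allpos <- decision_curve(rep(1, 100), y, thresholds = c(0.3, 0.6))
  expect_equal(allpos$net_benefit_model, allpos$net_benefit_all)

  # NB never exceeds prevalence
  s <- runif(100)
  dd <- decision_curve(s, y)
  expect_true(all(dd$net_benefit_model <= 0.4 + 1e-12))
  expect_error(decision_curve(s, y, thresholds = c(0, 0.5)), "inside")
})

test_that("logistic model fits, predicts, cross-validates and explains", {
  withr::local_seed(36)
  n <- 120
  y <- rep(c(0, 1), each = n / 2)
  tab <- tibble::tibble(sig = y + rnorm(n, 0, 0.6), junk = rnorm(n))
  fit <- fit_logistic(tab, y, cv_folds = 5, seed = 2)
  expect_gt(fit$cv_auc, 0.85)
  expect_equal(tidy(fit)$term, c("(Intercept)", "sig", "junk"))
  expect_equal(glance(fit)$n_features, 2L)

  null_tab <- tibble::tibble(a = rnorm(n), b = rnorm(n))
  null_fit <- fit_logistic(null_tab, y, cv_folds = 5, seed = 3)
  expect_lt(abs(null_fit$cv_auc - 0.5), 0.15)

  refit <- fit_logistic(tab, y, cv_folds = 5, seed = 2)
  expect_identical(fit$coefficients, refit$coefficients)

  sep <- tibble::tibble(x = c(rep(0, 10), rep(1, 10)))
  expect_warning(sfit <- fit_logistic(sep, rep(c(0, 1), each = 10), seed = 1),
                 "ridge")
  expect_true(sfit$ridge)

  # exact linear SHAP
  sh <- linear_shap(fit, tab)
  expect_equal(sh$logit,
               qlogis(predict(fit, tab)), tolerance = 1e-10)
  expect_equal(rowSums(sh$attributions) + sh$base, sh$logit, tolerance = 1e-12)
  at_mean <- tab[1, ]
  at_mean$sig <- fit$scaling$mean[1]; at_mean$junk <- fit$scaling$mean[2]
  expect_equal(unlist(linear_shap(fit, at_mean)$attributions), c(sig = 0, junk = 0),
               tolerance = 1e-12)
  double <- fit; double$coefficients["sig"] <- 2 * fit$coefficients["sig"]
  expect_equal(linear_shap(double, tab)$attributions$sig,
               2 * sh$attributions$sig, tolerance = 1e-12)
})

test_that("evaluation reports assemble the full metric set", {
  withr::local_seed(37)
  n <- 100
  y <- rep(c(0, 1), each = n / 2)
  tab <- tibble::tibble(sig = y + rnorm(n, 0, 0.7))
  fit <- fit_logistic(tab, y, seed = 1)
  ev <- evaluate_model(fit, tab, y)
  expect_true(ev$auc > 0.7)
  expect_true(ev$auc_ci[1] <= ev$auc && ev$auc <= ev$auc_ci[2])
  expect_equal(nrow(ev$metrics), 5L)
  expect_s3_class(autoplot(ev), "ggplot")
  expect_s3_class(plot_calibration(ev), "ggplot")
  expect_s3_class(plot_decision_curve(ev), "ggplot")
  expect_s3_class(plot_shap(ev), "ggplot")
  expect_equal(glance(ev)$auc, ev$auc)
})

test_that("the mean-ADC baseline scores lesions by restricted diffusion", {
  m <- array(1L, c(4, 4, 4))
  lo <- array(1.0, c(4, 4, 4)) # restricted diffusion
  hi <- array(1.5, c(4, 4, 4))
  res <- mean_adc_baseline(list(lo, hi), list(m, m))
  expect_equal(res$predicted, c(1L, 0L))
  expect_gt(res$score[1], res$score[2])

  const <- mean_adc_baseline(rep(list(lo), 4), rep(list(m), 4))
  expect_equal(roc_auc(const$score, c(1, 0, 1, 0)), 0.5)
  expect_error(mean_adc_baseline(list(lo), list(array(0L, c(4, 4, 4)))), "empty")
})
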