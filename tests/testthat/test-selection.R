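test_that("ICC(2,1) handles agreement, disagreement and a worked example", {
  m <- cbind(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_equal(compute_icc(m), 1)

  centred <- c(-2, -1, 0, 1, 2)
  expect_lt(compute_icc(cbind(centred, -centred)), 0)

  # 6-subject two-rater example, checked against an aov-based mean-square
  # decomposition computed independently here
  r <- cbind(c(9, 6, 8, 7, 10, 6), c(2, 1, 4, 1, 5, 2))
  n <- nrow(r); k <- ncol(r)
  df <- data.frame(y = as.vector(r),
                   subject = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  ms <- anova(stats::aov(y ~ subject + rater, data = df))["Mean Sq"]
  msr <- ms["subject", 1]; msc <- ms["rater", 1]; mse <- ms["Residuals", 1]
  expected <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  expect_equal(compute_icc(r), expected, tolerance = 1e-12)

  expect_true(is.na(compute_icc(cbind(rep(1, 4), rep(1, 4)))))
  expect_error(compute_icc(cbind(1:2, 1:2)), "3 subjects")
})

test_that("ICC screen drops irreproducible and undefined features", {
  withr::local_seed(20)
  base <- data.frame(stable = rnorm(10), unstable = rnorm(10), flat = rep(1, 10))
  repeat2 <- data.frame(stable = base$stable + rnorm(10, 0, 0.05),
                        unstable = rnorm(10), flat = rep(1, 10))
  expect_warning(res <- icc_filter(base, repeat2, threshold = 0.75), "undefined")
  expect_true("stable" %in% res$survivors)
  expect_false("unstable" %in% res$survivors)
  expect_false("flat" %in% res$survivors)
  expect_equal(nrow(res$icc), 3L)
})

test_that("the Pearson filter keeps the most relevant of correlated groups", {
  withr::local_seed(21)
  x <- rnorm(40)
  tab <- tibble::tibble(a = x, b = x, c = x + rnorm(40, 0, 0.01),
                        d = rnorm(40))
  rel <- c(a = 1, b = 3, c = 2, d = 0.5)
  res <- pearson_filter(tab, 0.9, rel)
  expect_equal(sort(res$survivors), c("b", "d"))

  # duplicated column with tied relevance: lexicographically earlier kept
  dup <- tibble::tibble(z1 = x, z2 = x)
  res2 <- pearson_filter(dup, 0.9, c(z1 = 1, z2 = 1))
  expect_equal(res2$survivors, "z1")

  # nothing above threshold: identity
  ind <- tibble::tibble(a = rnorm(40), b = rnorm(40))
  expect_equal(sort(pearson_filter(ind, 0.99)$survivors), c("a", "b"))

  expect_warning(pearson_filter(tibble::tibble(a = rep(1, 10), b = rnorm(10)), 0.9),
                 "constant")
})

test_that("univariate Welch test behaves under null and shifted alternatives", {
  withr::local_seed(22)
  y <- rep(c(0, 1), each = 50)
  null_tab <- as.data.frame(matrix(rnorm(100 * 200), 100, 200))
  res <- univariate_test(null_tab, y)
  expect_lt(abs(mean(res$p_value) - 0.5), 0.05)

  shifted <- data.frame(f = c(rnorm(50), rnorm(50, 2)))
  expect_lt(univariate_test(shifted, y)$p_value, 1e-3)

  flat <- data.frame(f = rep(1, 100))
  expect_equal(univariate_test(flat, y)$p_value, 1)

  expect_error(univariate_test(data.frame(f = c(1, 2)), c(0, 1)), "2 samples")
})

test_that("mRMR ranks a label-identical feature first and penalizes redundancy", {
  withr::local_seed(23)
  y <- rep(c(0, 1), each = 30)
  tab <- tibble::tibble(
    signal = y + rnorm(60, 0, 0.01),
    noise1 = rnorm(60), noise2 = rnorm(60)
  )
  expect_equal(mrmr_rank(tab, y, keep = 3)[1], "signal")
  expect_equal(mrmr_rank(tab, y, keep = 1), "signal")

  # duplicate of the informative feature is pushed below an independent
  # moderately informative feature by the redundancy term
  tab2 <- tibble::tibble(
    a_info = y + rnorm(60, 0, 0.01),
    b_copy = NA_real_,
    c_weak = y + rnorm(60, 0, 0.8)
  )
  tab2$b_copy <- tab2$a_info
  ranked <- mrmr_rank(tab2, y, keep = 3)
  expect_equal(ranked[1], "a_info")
  expect_equal(ranked[2], "c_weak")
  # keep > n_features keeps everything
  expect_equal(length(mrmr_rank(tab2, y, keep = 10)), 3L)
})

test_that("LASSO selection honours the penalty limits", {
  withr::local_seed(24)
  n <- 120
  y <- rep(c(0, 1), each = n / 2)
  x <- data.frame(a = y + rnorm(n, 0, 0.8), b = rnorm(n), c = rnorm(n))
  xs <- as.data.frame(scale(x))

  res <- lasso_cv_select(xs, y, selection_config(lasso_folds = 5, seed = 1))
  # strong-penalty end of the path: everything shrunk to zero
  co_max <- as.matrix(coef(res$fit$glmnet.fit, s = max(res$lambda_grid)))
  expect_true(all(co_max[-1, 1] == 0))
  # weak-penalty end approaches the unpenalized MLE
  mle <- glm(y ~ ., data = cbind(xs, y = y), family = binomial())
  co_min <- as.matrix(coef(res$fit$glmnet.fit, s = min(res$lambda_grid)))
  expect_equal(unname(co_min[-1, 1]), unname(coef(mle)[-1]), tolerance = 0.05)
  expect_true("a" %in% res$survivors)

  expect_error(lasso_cv_select(xs, rep(1, n), selection_config()), "one class")
})

test_that("LASSO recovers planted informative features across reruns", {
  hits <- 0L
  for (rep in 1:10) {
    withr::with_seed(100 + rep, {
      n <- 200
      y <- rep(c(0, 1), each = n / 2)
      info <- sapply(1:3, function(i) y + rnorm(n, 0, 1))
      noise <- matrix(rnorm(n * 20), n, 20)
      tab <- as.data.frame(scale(cbind(info, noise)))
      names(tab) <- c(paste0("info", 1:3), paste0("nz", 1:20))
      res <- lasso_cv_select(tab, y, selection_config(seed = rep))
      if (all(paste0("info", 1:3) %in% res$survivors)) hits <- hits + 1L
    })
  }
  expect_gte(hits, 9L)
})

test_that("the staged pipeline is nested, deterministic and tidy-able", {
  withr::local_seed(25)
  n <- 60
  y <- rep(c("negative", "positive"), each = n / 2)
  yb <- as.integer(y == "positive")
  tab <- tibble::tibble(
    good = yb + rnorm(n, 0, 0.5),
    copy = NA_real_,
    weak = yb + rnorm(n, 0, 2),
    n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n)
  )
  tab$copy <- tab$good + rnorm(n, 0, 0.01)
  cfg <- selection_config(lasso_folds = 5, mrmr_keep = 4, seed = 3)
  res <- select_features(tab, y, cfg)
  st <- res$stages
  expect_true(all(st$pearson %in% st$univariate))
  expect_true(all(st$mrmr %in% st$pearson))
  expect_true(all(st$lasso %in% st$mrmr))
  expect_true("good" %in% res$survivors || "copy" %in% res$survivors)
  expect_false(all(c("good", "copy") %in% st$pearson)) # redundancy removed

  res2 <- select_features(tab, y, cfg)
  expect_identical(res$survivors, res2$survivors)

  td <- tidy(res)
  expect_true(all(c("feature", "lasso_coef", "selected") %in% names(td)))
  gl <- glance(res)
  expect_equal(gl$n_selected, length(res$survivors))
})
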