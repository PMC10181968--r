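# IRLS logistic fits, LR machinery, backward selection, QCT integration.

test_that("intercept-only fit recovers the logit of the prevalence", {
  y <- rep(c(1, 0), c(20, 80))
  f <- fit_logistic(matrix(numeric(0), nrow = 100, ncol = 0), y)
  expect_equal(unname(f$coefficients), qlogis(0.2), tolerance = 1e-9)
})

test_that("coefficients match a generic-optimizer oracle to 1e-6", {
  set.seed(81)
  for (i in 1:20) {
    n <- sample(60:120, 1)
    p <- sample(1:3, 1)
    X <- matrix(rnorm(n * p), n)
    beta <- runif(p + 1, -0.8, 0.8)
    y <- rbinom(n, 1, plogis(beta[1] + X %*% beta[-1]))
    if (min(table(y)) < 5) next
    f <- tryCatch(fit_logistic(X, y), error = function(e) NULL)
    if (is.null(f)) next    # rare separation at small n
    want <- oracle_logistic(X, y)
    expect_equal(unname(f$coefficients), want, tolerance = 1e-6)
  }
})

test_that("Wald table exposes odds ratios with ordered CIs", {
  set.seed(82)
  X <- matrix(rnorm(400), 200)
  colnames(X) <- c("a", "b")
  y <- rbinom(200, 1, plogis(0.8 * X[, 1]))
  f <- fit_logistic(X, y)
  expect_equal(f$table$or, exp(f$table$estimate))
  expect_true(all(f$table$or_low < f$table$or))
  expect_true(all(f$table$or > 0))
  expect_lte(f$loglik, 0)
  expect_true(f$converged)
})

test_that("separation and rank deficiency raise explicit errors", {
  x <- rbinom(60, 1, 0.5)
  expect_error(fit_logistic(cbind(x), x), "separation")
  set.seed(83)
  Z <- cbind(a = rnorm(50), b = 1:50, c = 2 * (1:50))
  expect_error(fit_logistic(Z, rbinom(50, 1, 0.5)), "c")
  expect_error(fit_logistic(matrix(rnorm(10), 5), c(1, 0, 2, 0, 1)), "binary")
  expect_error(fit_logistic(matrix(rnorm(12), 2), c(0, 1)), "observations")
})

test_that("LR statistic is invariant to affine covariate rescaling", {
  set.seed(84)
  X <- matrix(rnorm(600), 300, 2)
  y <- rbinom(300, 1, plogis(0.5 * X[, 1] - 0.3 * X[, 2]))
  full <- fit_logistic(X, y)
  red <- fit_logistic(X[, 1, drop = FALSE], y)
  lr1 <- lr_test(full, red)$lr
  Xs <- X
  Xs[, 1] <- 100 * X[, 1] - 7
  Xs[, 2] <- -0.01 * X[, 2] + 3
  lr2 <- lr_test(fit_logistic(Xs, y),
                 fit_logistic(Xs[, 1, drop = FALSE], y))$lr
  expect_equal(lr1, lr2, tolerance = 1e-6)
})

test_that("backward selection honours p_remove extremes and logs its path", {
  set.seed(85)
  n <- 400
  d <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  d$malignant <- rbinom(n, 1, plogis(1.2 * d$a - 1))
  # removal threshold above any attainable p: nothing is dropped
  all_kept <- backward_select_lr(d, c("a", "b", "c"), p_remove = 1.01)
  expect_setequal(all_kept$selected, c("a", "b", "c"))
  expect_equal(nrow(all_kept$path), 0)
  # removal threshold 0: every candidate is dropped, path logs each step
  none <- backward_select_lr(d, c("a", "b", "c"), p_remove = 0)
  expect_equal(none$selected, character(0))
  expect_equal(nrow(none$path), 3)
  expect_null(none$fit)
  # a single strong candidate survives the default threshold untouched
  one <- backward_select_lr(d, "a")
  expect_equal(one$selected, "a")
  expect_equal(nrow(one$path), 0)
  expect_error(backward_select_lr(d, character(0)), "no candidate")
})

test_that("QCT integration is a proper nested comparison with df = 2", {
  set.seed(86)
  n <- 600
  base_lin <- rnorm(n)
  qct <- cbind(mld_hu = rnorm(n, -770, 40), pei_pct = rnorm(n, 42, 10))
  y <- rbinom(n, 1, plogis(-1 + base_lin + 0.02 * (qct[, 2] - 42)))
  p_base <- plogis(-1 + base_lin)
  ex <- extend_with_qct(p_base, qct, y)
  expect_equal(ex$comparison$df, 2)
  expect_gte(ex$comparison$lr, 0)
  expect_s3_class(ex$auc_base, "roc_result")
  # duplicating the base logit as a QCT column is rank-deficient
  expect_error(extend_with_qct(p_base, cbind(dup = qlogis(p_base)), y),
               "collinear|rank")
  expect_error(extend_with_qct(rep(0.5, n), qct, y), "degenerate")
  expect_error(extend_with_qct(c(0, p_base[-1]), qct, y), "strictly")

  # offset mode: base keeps coefficient 1, comparison still df = 2
  ex2 <- extend_with_qct(p_base, qct, y, mode = "offset")
  expect_equal(ex2$comparison$df, 2)
  expect_gte(ex2$comparison$lr, 0)
})
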