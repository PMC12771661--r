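test_that("exact linear truth is recovered with zero residual", {
  set.seed(71)
  cover <- runif(40, 0, 80)
  mgmt <- rep(c("abandoned", "mown"), 20)
  y <- 1 + 0.5 * cover - 2 * (mgmt == "mown")
  # summary.lm warns about the (deliberately) perfect fit
  fit <- suppressWarnings(fit_interaction_model(y, cover, mgmt))
  est <- stats::setNames(fit$coefficients$estimate, fit$coefficients$term)
  expect_equal(est[["(Intercept)"]], 1, tolerance = 1e-10)
  expect_equal(est[["cover"]], 0.5, tolerance = 1e-10)
  expect_equal(est[["managementmown"]], -2, tolerance = 1e-10)
  expect_equal(est[["cover:managementmown"]], 0, tolerance = 1e-10)
  expect_equal(fit$r2_pct, 100, tolerance = 1e-8)
})

test_that("reference level is abandoned and AIC follows the Gaussian convention", {
  set.seed(72)
  cover <- runif(30, 0, 50)
  mgmt <- rep(c("mown", "abandoned"), 15)
  y <- rnorm(30) + 0.02 * cover
  fit <- fit_interaction_model(y, cover, mgmt)
  expect_equal(fit$reference, "abandoned")
  expect_true("managementmown" %in% fit$coefficients$term)
  n <- 30; rss <- sum(stats::residuals(fit$model)^2)
  expect_equal(fit$aic, n * (log(2 * pi) + log(rss / n) + 1) + 2 * 5,
               tolerance = 1e-10)
})

test_that("R-squared is invariant to response standardization, coefficients rescale", {
  set.seed(73)
  cover <- runif(30, 0, 50)
  mgmt <- rep(c("mown", "abandoned"), 15)
  y <- 2 - 0.03 * cover + 0.5 * (mgmt == "mown") + rnorm(30, 0, 0.3)
  f_raw <- fit_interaction_model(y, cover, mgmt)
  f_std <- fit_interaction_model(y, cover, mgmt, standardize = TRUE)
  expect_equal(f_raw$r2_pct, f_std$r2_pct, tolerance = 1e-10)
  expect_equal(f_std$coefficients$estimate[-1] * stats::sd(y),
               f_raw$coefficients$estimate[-1], tolerance = 1e-10)
  # slope terms keep their p-values (the intercept's changes with centering)
  expect_equal(f_raw$coefficients$p_value[-1], f_std$coefficients$p_value[-1],
               tolerance = 1e-10)
})

test_that("degenerate designs are rejected", {
  mgmt <- rep(c("mown", "abandoned"), 10)
  cover <- as.numeric(mgmt == "mown")  # collinear with the factor
  expect_error(fit_interaction_model(rnorm(20), cover, mgmt), "rank")
  expect_error(fit_interaction_model(rnorm(3), 1:3, c("a", "b", "a")), "5 plots")
})

test_that("pure-noise responses give adjusted R2 near zero on average", {
  set.seed(74)
  cover <- runif(60, 0, 80)
  mgmt <- rep(c("mown", "abandoned"), 30)
  adj <- replicate(200, fit_interaction_model(rnorm(60), cover, mgmt)$adj_r2_pct)
  expect_lt(abs(mean(adj)), 2)  # percent scale
})

test_that("hierarchical partitioning: orthogonal and duplicated predictors", {
  # orthogonal predictors: I_k = gof({k}), J_k = 0
  x1 <- rep(c(-1, 1), each = 8)
  x2 <- rep(c(-1, 1), 8)
  set.seed(75)
  y <- 0.8 * x1 + 0.3 * x2 + rnorm(16, 0, 0.4)
  hp <- hierarchical_partition(y, data.frame(x1 = x1, x2 = x2))
  g1 <- 100 * summary(stats::lm(y ~ x1))$r.squared
  g2 <- 100 * summary(stats::lm(y ~ x2))$r.squared
  expect_equal(hp$independent, c(g1, g2), tolerance = 1e-8)
  expect_equal(hp$joint, c(0, 0), tolerance = 1e-8)

  # duplicated predictor: the full-model R2 splits evenly
  hp2 <- hierarchical_partition(y, data.frame(a = x1, b = x1))
  expect_equal(hp2$independent[1], hp2$independent[2], tolerance = 1e-10)
  expect_equal(sum(hp2$independent), attr(hp2, "full_gof_pct"), tolerance = 1e-10)
})

test_that("independent contributions match the all-orderings oracle", {
  set.seed(76)
  for (k in 2:4) {
    n <- 30
    X <- matrix(rnorm(n * k), n, k, dimnames = list(NULL, paste0("x", 1:k)))
    y <- X %*% runif(k, -1, 1) + rnorm(n)
    for (gof in c("R2", "adjR2")) {
      hp <- hierarchical_partition(y, as.data.frame(X), gof = gof)
      expect_equal(hp$independent, 100 * oracle_hierpart(y, X, gof),
                   tolerance = 1e-10)
    }
  }
})

test_that("independent contributions sum to the full-model R2", {
  set.seed(77)
  for (rep in 1:25) {
    k <- sample(2:5, 1)
    n <- sample(20:40, 1)
    X <- matrix(rnorm(n * k), n, k, dimnames = list(NULL, paste0("x", 1:k)))
    y <- X %*% runif(k, -1, 1) + rnorm(n)
    hp <- hierarchical_partition(y, as.data.frame(X))
    expect_equal(sum(hp$independent), attr(hp, "full_gof_pct"), tolerance = 1e-10)
  }
  expect_error(hierarchical_partition(rnorm(20), as.data.frame(matrix(rnorm(260), 20)),
                                      gof = "R2"), "k <= 12")
})

test_that("unpaired t-test: identical samples, zero variance, Welch option", {
  tt <- unpaired_ttest(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(tt$t, 0)
  expect_equal(tt$p_value, 1)
  expect_error(unpaired_ttest(rep(0, 4), rep(1, 4)), "zero variance")
  set.seed(78)
  x1 <- rnorm(20); x2 <- rnorm(20, 1, 3)
  tw <- unpaired_ttest(x1, x2, var_equal = FALSE)
  ref <- stats::t.test(x1, x2)
  expect_equal(tw$p_value, ref$p.value)
})

test_that("aspect folding maps compass degrees to the north-south scale", {
  expect_equal(fold_aspect(c(0, 360, 180, 333, 290, 90, 270)),
               c(0, 0, 180, 27, 70, 90, 90))
  expect_error(fold_aspect(400), "within")
})

test_that("standardization gives mean 0, sd 1, and errors on constants", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  z <- standardize(rnorm(20, 5, 3))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(stats::sd(z), 1, tolerance = 1e-12)
  expect_error(standardize(rep(2, 5)), "constant")
  expect_error(standardize(3), "n >= 2")
})
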