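test_that("weight partition gamma + lambda' + phi is exactly 1", {
  w <- covariance_weights(0.5, 0.5)
  expect_equal(w$lambda_prime, 0.25)
  expect_equal(w$gamma, 0.25)
  w10 <- covariance_weights(1, 0)
  expect_equal(w10$lambda_prime, 1)
  expect_equal(w10$gamma, 0)
  set.seed(2)
  for (i in 1:50) {
    w <- covariance_weights(runif(1), runif(1))
    expect_equal(w$gamma + w$lambda_prime + w$phi, 1, tolerance = 1e-12)
  }
  expect_error(covariance_weights(-0.1, 0), "lambda")
  expect_error(covariance_weights(0, 1.1), "phi")
})

test_that("combined covariance reduces correctly at the corners", {
  sys <- make_system(8)
  S <- sys$S$sigma; W <- sys$W$w
  expect_equal(combine_covariance(covariance_weights(0, 0), S, W), diag(8),
               ignore_attr = TRUE)
  expect_equal(combine_covariance(covariance_weights(1, 0), S, W), S,
               ignore_attr = TRUE, tolerance = 1e-12)
  V <- combine_covariance(covariance_weights(0.5, 0.5), S, W)
  expect_equal(V, 0.25 * diag(8) + 0.25 * S + 0.5 * W,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(unname(diag(V)), rep(1, 8))
})

test_that("PSD repair tolerates numerical noise and rejects indefinite W", {
  # W with a tiny negative eigenvalue: ridge repair
  Q <- qr.Q(qr(matrix(rnorm(16, 0, 1), 4)))
  W_noise <- Q %*% diag(c(2, 1, 0.5, -5e-9)) %*% t(Q)
  W_noise <- (W_noise + t(W_noise)) / 2
  V <- combine_covariance(covariance_weights(0, 1), diag(4), W_noise)
  expect_gt(min(eigen(V, symmetric = TRUE, only.values = TRUE)$values), 0)

  # genuinely indefinite W at full spatial weight: hard error
  W_bad <- Q %*% diag(c(2, 1, 0.5, -0.5)) %*% t(Q)
  W_bad <- (W_bad + t(W_bad)) / 2
  expect_error(combine_covariance(covariance_weights(0, 1), diag(4), W_bad),
               "not positive definite")
})

test_that("GLS with identity covariance reduces to ordinary least squares", {
  set.seed(3)
  for (i in 1:20) {
    n <- sample(10:30, 1)
    X <- cbind(1, matrix(rnorm(n * 2), n))
    y <- rnorm(n)
    fit <- gls_fit(y, X, diag(n))
    ols <- lm(y ~ X - 1)
    expect_equal(unname(fit$beta), unname(coef(ols)), tolerance = 1e-8)
    expect_equal(fit$sigma2, sum(resid(ols)^2) / n, tolerance = 1e-8)
    expect_equal(unname(fit$p_values), unname(summary(ols)$coefficients[, 4]),
                 tolerance = 1e-8)
  }
  expect_equal(gls_fit(c(1, 2, 3), matrix(1, 3, 1), diag(3))$beta[[1]], 2)
})

test_that("profiled log-likelihood equals the dense MVN density oracle", {
  set.seed(4)
  for (i in 1:10) {
    sys <- make_system(8, seed = 100 + i)
    wts <- covariance_weights(runif(1), runif(1, 0, 0.6))
    V <- combine_covariance(wts, sys$S$sigma, sys$W$w)
    X <- cbind(1, rnorm(8))
    y <- drop(t(chol(V)) %*% rnorm(8)) + X %*% c(1, 0.5)
    fit <- gls_fit(y, X, V)
    expect_equal(fit$loglik,
                 oracle_mvn_logdensity(drop(y), drop(X %*% fit$beta),
                                       fit$sigma2 * V),
                 tolerance = 1e-6)
  }
})

test_that("singular covariance and collinear designs are errors", {
  V <- matrix(1, 3, 3)  # zero eigenvalues
  expect_error(gls_fit(c(1, 2, 3), matrix(1, 3, 1), V), "singular")
  X <- cbind(1, c(1, 2, 3, 4), c(2, 4, 6, 8))
  expect_error(gls_fit(rnorm(4), X, diag(4)), "n >= k \\+ 1|collinear")
})

test_that("likelihood-ratio p-values match the chi-square tail", {
  expect_equal(likelihood_ratio_test(-10, -10, 1), 1)
  expect_equal(likelihood_ratio_test(-10 + 3.841 / 2, -10, 1),
               pchisq(3.841, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(likelihood_ratio_test(-10 + 5.991 / 2, -10, 2),
               pchisq(5.991, 2, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(round(likelihood_ratio_test(-10 + 3.841 / 2, -10, 1), 4), 0.05)
  expect_error(likelihood_ratio_test(-11, -10, 1), "not nested")
  # boundary-mixture option halves the tail for positive statistics
  expect_equal(likelihood_ratio_test(-10 + 2, -10, 1, null = "mixture"),
               0.5 * pchisq(4, 1, lower.tail = FALSE))
  expect_equal(likelihood_ratio_test(-10, -10, 1, null = "mixture"), 1)
})

test_that("grid fit covers the full grid and attains the surface maximum", {
  sys <- make_system(10, seed = 21)
  y <- simulate_trait(sys$S, sys$W, covariance_weights(0.6, 0.2), seed = 22)
  gf <- profile_grid_fit(y, NULL, sys$S, sys$W, step = 0.02)
  expect_equal(dim(gf$surface), c(51, 51))
  expect_equal(gf$fit$loglik, max(gf$surface[is.finite(gf$surface)]))
  expect_true(all(gf$surface[is.finite(gf$surface)] <= gf$fit$loglik))

  # coarse grid, lambda-only: 11 points on one axis
  gf2 <- profile_grid_fit(y, NULL, sys$S, sys$W, step = 0.1, mode = "lambda_only")
  expect_equal(dim(gf2$surface), c(11, 1))
  expect_error(profile_grid_fit(y, NULL, sys$S, sys$W, step = 0.03), "divide 1")
})

test_that("nested grid modes have monotone log-likelihoods", {
  sys <- make_system(12, seed = 31)
  y <- simulate_trait(sys$S, sys$W, covariance_weights(0.5, 0.3), seed = 32)
  ll <- sapply(c("both", "lambda_only", "phi_only", "neither"), function(m) {
    profile_grid_fit(y, NULL, sys$S, sys$W, mode = m)$fit$loglik
  })
  expect_gte(ll["both"], max(ll["lambda_only"], ll["phi_only"]) - 1e-8)
  expect_gte(min(ll["lambda_only"], ll["phi_only"]), ll["neither"] - 1e-8)
})

test_that("fit at the grid null equals OLS", {
  sys <- make_system(10, seed = 41)
  y <- rnorm(10)
  gf <- profile_grid_fit(y, NULL, sys$S, sys$W, mode = "neither")
  ols <- lm(y ~ 1)
  expect_equal(gf$weights$lambda, 0)
  expect_equal(gf$weights$phi, 0)
  expect_equal(unname(gf$fit$beta), unname(coef(ols)), tolerance = 1e-8)
})

test_that("ties on the log-likelihood surface resolve toward the null", {
  # with Sigma* = W = I every grid point mixes to exactly V = I (the step-0.25
  # weights are dyadic, so the partition sums to 1 without rounding): all 25
  # log-likelihoods tie exactly and the argmax must be the null corner
  set.seed(51)
  y <- rnorm(8)
  gf <- profile_grid_fit(y, NULL, diag(8), diag(8), step = 0.25)
  expect_true(all(gf$surface == gf$fit$loglik))
  expect_equal(gf$weights$lambda, 0)
  expect_equal(gf$weights$phi, 0)
})

test_that("rows with missing data are dropped consistently", {
  sys <- make_system(12, seed = 61)
  y <- simulate_trait(sys$S, sys$W, covariance_weights(0.5, 0), seed = 62)
  y[c(3, 7)] <- NA
  expect_message(
    gf <- profile_grid_fit(y, NULL, sys$S, sys$W, step = 0.1),
    "dropping 2 rows"
  )
  expect_equal(gf$fit$n, 10)
})

test_that("single-axis lambda estimate agrees with an independent PGLS lambda", {
  # phytools profiles Pagel's lambda continuously; on an ultrametric tree the
  # lambda_only grid mode estimates the same quantity, up to grid resolution
  set.seed(71)
  tree <- simulate_tree(30)
  S <- normalize_covariance(phylo_covariance(tree, tree$tip.label))
  y <- simulate_trait(S, diag(30), covariance_weights(0.7, 0), seed = 72)
  names(y) <- tree$tip.label
  gf <- profile_grid_fit(y, NULL, S, diag(30), mode = "lambda_only")
  ps <- phytools::phylosig(tree, y, method = "lambda")
  expect_lt(abs(gf$weights$lambda - ps$lambda), 0.025)
})
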