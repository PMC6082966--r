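test_that("ridge BLUP matches the generalized-inverse oracle on random systems", {
  set.seed(41)
  for (i in 1:5) {
    Z <- matrix(rnorm(10 * 8), 10, 8)
    X <- cbind(1, rbinom(10, 1, 0.5))
    y <- rnorm(10)
    s2a <- runif(1, 0.1, 2); s2e <- runif(1, 0.1, 2)
    fit <- fit_ridge_blup(Z, y, X, s2a, s2e)
    oracle <- ginv_oracle(Z, y, X, rep(s2e / (s2a / 8), 8))
    expect_equal(fit$predictor_effects, oracle$b, tolerance = 1e-8)
    expect_equal(unname(fit$fixed_effects), oracle$fixed, tolerance = 1e-8)
  }
})

test_that("ridge BLUP reduces to ordinary least squares without shrinkage", {
  set.seed(42)
  Z <- matrix(rnorm(12 * 4), 12, 4)
  X <- matrix(1, 12, 1)
  y <- rnorm(12)
  fit <- fit_ridge_blup(Z, y, X, sigma2_a = 1e12, sigma2_e = 1)
  ols <- stats::lm.fit(cbind(X, Z), y)$coefficients
  expect_equal(unname(c(fit$fixed_effects, fit$predictor_effects)),
               unname(ols), tolerance = 1e-5)
})

test_that("eigenvalue-weighted BLUP shrinks low-eigenvalue coordinates harder", {
  set.seed(43)
  sc <- matrix(rnorm(20 * 2), 20, 2)
  X <- matrix(1, 20, 1)
  y <- sc %*% c(1, 1) + rnorm(20, 0, 0.5)
  lam <- c(0.9, 0.1)
  fit <- fit_pcr_eigen(sc, y, X, sigma2_a = 0.5, lambda = lam, sigma2_e = 1)
  oracle <- ginv_oracle(sc, y, X, 1 / (0.5 * lam))  # lam already sums to 1
  expect_equal(fit$predictor_effects, oracle$b, tolerance = 1e-8)
  # same data, isotropic solver at matched total variance: coordinate 2 is
  # shrunk harder under the eigenvalue prior
  iso <- fit_ridge_blup(sc, y, X, sigma2_a = 0.5, sigma2_e = 1)
  expect_lt(abs(fit$predictor_effects[2] / iso$predictor_effects[2]), 1)
  # all-equal eigenvalues reduce PCR-Eigen to isotropic ridge
  fit_eq <- fit_pcr_eigen(sc, y, X, 0.5, c(1, 1), 1)
  expect_equal(fit_eq$predictor_effects, iso$predictor_effects,
               tolerance = 1e-10)
  expect_error(fit_pcr_eigen(sc, y, X, 0.5, c(1, 0), 1), "eigenvalue")
})

test_that("a confounded fixed-effect design is reduced with a warning", {
  set.seed(44)
  Z <- matrix(rnorm(10 * 3), 10, 3)
  X <- cbind(`(Intercept)` = rep(1, 10), dup = rep(1, 10))  # singular
  expect_warning(fit <- fit_ridge_blup(Z, rnorm(10), X, 1, 1), "singular")
  expect_length(fit$fixed_effects, 1)
})

test_that("fixed-variance Gibbs chains match the conjugate normal closed form", {
  set.seed(45)
  for (i in 1:3) {
    n <- 6
    Z <- matrix(rnorm(n), n, 1)
    X <- matrix(1, n, 1)
    y <- 0.8 * Z[, 1] + rnorm(n)
    s2b <- 0.5; s2e <- 1
    fit <- fit_bayes(Z, y, X, prior = "gaussian", niter = 12000,
                     burnin = 2000, thin = 5,
                     fixed_sigma2_e = s2e, fixed_sigma2_b = s2b,
                     keep_effect_draws = TRUE)
    post <- conjugate_posterior(Z, y, X, s2b, s2e)
    draws <- fit$b_draws[, 1]
    mcse <- mcse_batch(draws)
    expect_lt(abs(mean(draws) - post$mean[2]), 3 * mcse + 1e-8)
    expect_equal(sd(draws), sqrt(post$cov[2, 2]), tolerance = 0.1)
  }
})

test_that("the spike-and-slab sampler with no spike reduces to the scaled-t model", {
  set.seed(46)
  g <- random_genotypes(100, 20)
  b_true <- rnorm(20, 0, 0.3)
  y <- g %*% b_true + rnorm(100)
  X <- matrix(1, 100, 1)
  set.seed(123)
  fit_a <- fit_bayes(g, y, X, prior = "scaled_t", niter = 6000, burnin = 1000)
  set.seed(123)
  fit_b <- fit_bayes(g, y, X, prior = "spike_slab_t", niter = 6000,
                     burnin = 1000, fixed_pi = 0)
  expect_gt(cor(fit_a$predictor_effects, fit_b$predictor_effects), 0.98)
  expect_lt(mean(abs(fit_a$fitted_gebv - fit_b$fitted_gebv)) / sd(y), 0.05)
})

test_that("the Bayesian Lasso recovers strong effects and stays finite", {
  set.seed(47)
  g <- random_genotypes(200, 10)
  b_true <- c(1, -1, 0.5, rep(0, 7))
  y <- g %*% b_true + rnorm(200, 0, 0.5)
  X <- matrix(1, 200, 1)
  fit <- fit_bayes(g, y, X, prior = "double_exponential",
                   niter = 5000, burnin = 1000)
  expect_true(all(is.finite(fit$predictor_effects)))
  expect_gt(cor(fit$predictor_effects, b_true), 0.9)
  expect_gt(fit$gamma2, 0)
})

test_that("BayesB learns a high zero proportion on a sparse trait", {
  set.seed(48)
  g <- random_genotypes(150, 30)
  b_true <- c(rep(1.5, 2), rep(0, 28))
  y <- g %*% b_true + rnorm(150, 0, 0.5)
  X <- matrix(1, 150, 1)
  fit <- fit_bayes(g, y, X, prior = "spike_slab_t", niter = 5000,
                   burnin = 1000)
  expect_gt(fit$pi_zero, 0.5)
  expect_gt(cor(fit$predictor_effects, b_true), 0.9)
})

test_that("identical seeds give identical chains", {
  set.seed(49)
  g <- random_genotypes(40, 8)
  y <- rnorm(40)
  X <- matrix(1, 40, 1)
  f1 <- fit_bayes(g, y, X, prior = "scaled_t", niter = 1000, burnin = 200,
                  seed = 7)
  f2 <- fit_bayes(g, y, X, prior = "scaled_t", niter = 1000, burnin = 200,
                  seed = 7)
  expect_identical(f1$predictor_effects, f2$predictor_effects)
  expect_identical(f1$sigma2_e_chain, f2$sigma2_e_chain)
})

test_that("GEBV prediction is a pure design-times-effects product", {
  set.seed(50)
  g <- random_genotypes(30, 6)
  y <- rnorm(30)
  X <- matrix(1, 30, 1)
  fit <- fit_ridge_blup(g, y, X, 0.25, 0.75)
  expect_equal(predict_gebv(fit, g), fit$fitted_gebv)
  expect_equal(predict_gebv(fit, matrix(0, 1, 6)), 0)
  expect_error(predict_gebv(fit, matrix(0, 1, 5)), "columns")
  # pc-based fit projects marker data through the stored basis
  md <- marker_data(g)
  basis <- fit_pca(md)
  k <- basis$retained_k
  sc <- project(md, basis)
  ms <- model_spec("pcr-normal", niter = 600, burnin = 100)
  fitpc <- fit_model(ms, sc[, 1:k, drop = FALSE], y, X, basis = basis)
  expect_equal(predict_gebv(fitpc, md),
               as.vector(sc[, 1:k, drop = FALSE] %*% fitpc$predictor_effects))
})

test_that("posterior residual variance is recovered at full training scale", {
  fx <- full_replicate()  # n = 1820, true residual variance 0.75
  X <- sex_design(fx$train$sex)
  fit <- fit_bayes(fx$md$genotypes, fx$train$phenotype, X,
                   prior = "gaussian", niter = 3000, burnin = 500, thin = 5)
  expect_gt(fit$sigma2_e, 0.65)
  expect_lt(fit$sigma2_e, 0.85)
})
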