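test_that("bias regression reproduces closed-form cases", {
  set.seed(61)
  tbv <- rnorm(50)
  expect_equal(bias_regression(tbv, tbv),
               c(b0 = 0, b1 = 1, r2 = 1), tolerance = 1e-12)
  halved <- bias_regression(tbv, tbv / 2)
  expect_equal(halved[["b1"]], 2, tolerance = 1e-12)
  # four-point table solved by hand through the normal equations:
  # t = (1, 2, 3, 0), g = (0.5, 1.5, 2.0, 0.2)
  # Sgt = 3.2, Sgg = 2.13  ->  b1 = 3.2/2.13, b0 = 1.5 - b1*1.05,
  # r2 = 3.2^2/(2.13*5)
  br <- bias_regression(c(1, 2, 3, 0), c(0.5, 1.5, 2.0, 0.2))
  expect_equal(br[["b1"]], 3.2 / 2.13, tolerance = 1e-12)
  expect_equal(br[["b0"]], 1.5 - (3.2 / 2.13) * 1.05, tolerance = 1e-12)
  expect_equal(br[["r2"]], 3.2^2 / (2.13 * 5), tolerance = 1e-12)
  expect_error(bias_regression(1:2, 1:2), "at least 3")
  expect_warning(br0 <- bias_regression(rnorm(5), rep(1, 5)), "zero GEBV")
  expect_true(all(is.na(br0)))
})

test_that("accuracy is invariant to scaling and shifting of GEBV", {
  set.seed(62)
  tbv <- rnorm(30)
  gebv <- 0.6 * tbv + rnorm(30, 0, 0.5)
  base <- accuracy(gebv, tbv)
  for (a in c(0.1, 2, 5)) {
    for (cshift in c(-3, 0, 1)) {
      expect_equal(accuracy(a * gebv + cshift, tbv), base, tolerance = 1e-12)
      expect_equal(accuracy(-a * gebv + cshift, tbv), -base, tolerance = 1e-12)
    }
  }
})

test_that("an oracle model scores perfect accuracy and unit slope in CV", {
  set.seed(63)
  n <- 100
  tbv <- rnorm(n)
  design <- matrix(tbv, ncol = 1)  # the single predictor IS the TBV
  X <- matrix(1, n, 1)
  ms <- model_spec("ridge")
  cv <- five_fold_cv(ms, design, tbv, tbv, X, sigma2_a = 1e9, sigma2_e = 1)
  expect_equal(cv$accuracy, rep(1, 5), tolerance = 1e-6)
  expect_equal(cv$b1, rep(1, 5), tolerance = 1e-3)
  s <- attr(cv, "summary")
  expect_equal(s$accuracy_mean, 1, tolerance = 1e-6)
})

test_that("an uninformative model scores near-zero accuracy in CV", {
  set.seed(64)
  n <- 400
  tbv <- rnorm(n)
  design <- matrix(rnorm(n), ncol = 1)  # independent of the trait
  X <- matrix(1, n, 1)
  ms <- model_spec("ridge")
  accs <- unlist(lapply(1:4, function(i)
    five_fold_cv(ms, design, rnorm(n), tbv, X)$accuracy))
  # null accuracy averages to zero within Monte-Carlo error
  expect_lt(abs(mean(accs)), 3 * sd(accs) / sqrt(length(accs)) + 0.05)
})

test_that("cross-validation folds partition the training set", {
  set.seed(65)
  n <- 53
  g <- random_genotypes(n, 10)
  ms <- model_spec("ridge")
  cv <- five_fold_cv(ms, g, rnorm(n), rnorm(n), matrix(1, n, 1))
  folds <- attr(cv, "folds")
  expect_length(folds, n)
  expect_setequal(unique(folds), 1:5)
  expect_equal(sum(cv$n), n)
  expect_equal(as.vector(table(folds)), cv$n)
  # summary SE definition: sd over folds divided by sqrt(#folds)
  s <- attr(cv, "summary")
  expect_equal(s$accuracy_se, sd(cv$accuracy) / sqrt(5), tolerance = 1e-12)
})

test_that("persistency applies one fit across generations", {
  set.seed(66)
  n <- 60
  tbv_list <- lapply(1:3, function(i) rnorm(n))
  designs <- lapply(tbv_list, function(tb) matrix(tb, ncol = 1))
  X <- matrix(1, n, 1)
  fit <- fit_ridge_blup(designs[[1]], tbv_list[[1]], X, 1e9, 1)
  rep <- persistency(fit, designs, tbv_list, generations = 10:12)
  expect_equal(rep$generation, 10:12)
  expect_equal(rep$accuracy, rep(1, 3), tolerance = 1e-6)
  expect_equal(rep$b1, rep(1, 3), tolerance = 1e-3)
})
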