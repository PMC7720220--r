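test_that("naive fit equals the normal-equations oracle and handles nulls", {
  data <- make_predicted_data(6, seed = 9)
  spec <- inference_spec("gaussian_identity", ~ x1)
  naive <- fit_naive(data, spec)
  oracle <- ols_oracle(cbind(1, data$covariates$x1), data$predicted)
  expect_equal(unname(naive$beta_p), unname(oracle$coef), tolerance = 1e-10)
  expect_equal(unname(naive$se_p), unname(oracle$se), tolerance = 1e-10)
  expect_equal(naive$sigma_p, oracle$sigma, tolerance = 1e-10)

  data$predicted <- rep(0, 6)
  null_fit <- fit_naive(data, spec)
  expect_equal(unname(null_fit$beta_p), c(0, 0))
  expect_equal(null_fit$sigma_p, 0)
})

test_that("formula subsetting restricts the design to the named covariate", {
  set.seed(2)
  cov <- as.data.frame(replicate(4, rnorm(30), simplify = FALSE))
  names(cov) <- paste0("x", 1:4)
  data <- labeled_dataset(cov, predicted = rnorm(30))
  naive <- fit_naive(data, inference_spec("gaussian_identity", ~ x2))
  expect_identical(colnames(naive$design), c("(Intercept)", "x2"))
})

test_that("collinear designs raise an error naming the redundant column", {
  set.seed(3)
  x <- rnorm(25)
  data <- labeled_dataset(data.frame(x1 = x, x2 = 2 * x),
                          predicted = rnorm(25))
  expect_error(fit_naive(data, inference_spec("gaussian_identity", ~ x1 + x2)),
               "collinear.*x2")
})

test_that("identity relationship makes the correction a no-op", {
  data <- make_predicted_data(50, seed = 4)
  spec <- inference_spec("gaussian_identity", ~ x1)
  naive <- fit_naive(data, spec)
  rel <- structure(list(gamma0 = 0, gamma1 = 1, sigma_r = 0, n_fit = 50),
                   class = "continuous_relationship")
  corr <- correct_analytical(naive, rel)
  expect_equal(corr$estimate, unname(naive$beta_p), tolerance = 1e-12)
  expect_equal(corr$se, unname(naive$se_p), tolerance = 1e-12)
})

test_that("zero relationship slope zeroes every non-intercept estimate", {
  data <- make_predicted_data(40, seed = 5)
  naive <- fit_naive(data, inference_spec("gaussian_identity", ~ x1))
  rel <- structure(list(gamma0 = 1.3, gamma1 = 0, sigma_r = 0.5, n_fit = 40),
                   class = "continuous_relationship")
  corr <- correct_analytical(naive, rel)
  slope <- corr[corr$coefficient == "x1", ]
  expect_equal(slope$estimate, 0, tolerance = 1e-12)
  expect_equal(slope$statistic, 0, tolerance = 1e-12)
  intercept <- corr[corr$coefficient == "(Intercept)", ]
  expect_equal(intercept$estimate, 1.3, tolerance = 1e-12)
})

test_that("correction matches a literal transcription of the displayed formulas", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 20
    x1 <- rnorm(n); x2 <- rnorm(n)
    data <- labeled_dataset(data.frame(x1 = x1, x2 = x2),
                            predicted = rnorm(n, 1 + x1 - x2))
    spec <- inference_spec("gaussian_identity", ~ x1 + x2)
    naive <- fit_naive(data, spec)
    g0 <- rnorm(1); g1 <- rnorm(1); sr <- abs(rnorm(1))
    rel <- structure(list(gamma0 = g0, gamma1 = g1, sigma_r = sr, n_fit = n),
                     class = "continuous_relationship")
    corr <- correct_analytical(naive, rel)

    # independent evaluation with explicit matrix algebra
    X <- cbind(1, x1, x2)
    o <- ols_oracle(X, data$predicted)
    est_oracle <- drop(o$XtX_inv %*% (t(X) %*% (g0 + g1 * drop(X %*% o$coef))))
    se_oracle <- sqrt(diag(o$XtX_inv) * (sr^2 + g1^2 * o$sigma^2))
    expect_equal(corr$estimate, unname(est_oracle), tolerance = 1e-10)
    expect_equal(corr$se, unname(se_oracle), tolerance = 1e-10)
    expect_equal(corr$statistic, unname(est_oracle / se_oracle),
                 tolerance = 1e-10)
  }
})

test_that("corrected variance decomposes into the two fitted components", {
  data <- make_predicted_data(60, seed = 6)
  spec <- inference_spec("gaussian_identity", ~ x1)
  naive <- fit_naive(data, spec)
  rel <- structure(list(gamma0 = 0.2, gamma1 = 0.8, sigma_r = 0.7, n_fit = 60),
                   class = "continuous_relationship")
  corr <- correct_analytical(naive, rel)
  expect_equal(corr$se^2,
               diag(naive$XtX_inv) * (rel$sigma_r^2 +
                                        rel$gamma1^2 * naive$sigma_p^2),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("identity-predictor stub reduces the pipeline to classical OLS", {
  data <- make_predicted_data(90, seed = 7)
  data$predicted <- NULL
  split <- split_three_way(data, seed = 1)
  fp <- train_predictor(split$train, stub_identity_predictor())
  test <- predict(fp, split$test)
  val <- predict(fp, split$validation)
  rel <- fit_continuous_relationship(test)
  expect_equal(c(rel$gamma0, rel$gamma1, rel$sigma_r), c(0, 1, 0),
               tolerance = 1e-10)
  spec <- inference_spec("gaussian_identity", ~ x1)
  corr <- correct_analytical(fit_naive(val, spec), rel)
  classical <- fit_inference(val, spec, "observed")
  expect_equal(corr$estimate, classical$estimate, tolerance = 1e-10)
  expect_equal(corr$se, classical$se, tolerance = 1e-10)
  expect_equal(corr$statistic, classical$statistic, tolerance = 1e-10)
})

test_that("fully degenerate corrections follow the documented edge contract", {
  set.seed(8)
  X <- cbind("(Intercept)" = 1, x1 = rnorm(30))
  naive <- structure(list(beta_p = c("(Intercept)" = 2, x1 = 3),
                          se_p = c("(Intercept)" = 0, x1 = 0),
                          sigma_p = 0, df = 28, design = X,
                          XtX_inv = solve(crossprod(X))),
                     class = "naive_fit")
  rel0 <- structure(list(gamma0 = 0, gamma1 = 1, sigma_r = 0, n_fit = 30),
                    class = "continuous_relationship")
  corr <- correct_analytical(naive, rel0)
  expect_true(all(is.infinite(corr$statistic)))
  expect_true(all(corr$p_value == 0))

  naive$beta_p <- c("(Intercept)" = 0, x1 = 0)
  rel_zero <- structure(list(gamma0 = 0, gamma1 = 0, sigma_r = 0, n_fit = 30),
                        class = "continuous_relationship")
  expect_error(correct_analytical(naive, rel_zero), "degenerate")
})
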