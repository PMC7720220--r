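test_that("3RS3R leaves constant and monotone series unchanged", {
  expect_equal(tukey_smooth_3rs3r(rep(2.5, 10)), rep(2.5, 10))
  expect_equal(tukey_smooth_3rs3r(1:15), as.numeric(1:15))
  expect_equal(tukey_smooth_3rs3r(c(5, 1)), c(5, 1))
  expect_equal(tukey_smooth_3rs3r(3), 3)
})

test_that("3RS3R removes an interior spike", {
  expect_equal(tukey_smooth_3rs3r(c(1, 1, 9, 1, 1)), rep(1, 5))
})

test_that("3RS3R matches the independent reference on random series", {
  set.seed(12)
  for (r in 1:60) {
    x <- rnorm(25)
    expect_identical(tukey_smooth_3rs3r(x), ref_3rs3r(x))
  }
  for (r in 1:40) {
    n <- sample(5:80, 1)
    x <- rnorm(n)
    expect_identical(tukey_smooth_3rs3r(x), ref_3rs3r(x))
  }
})

test_that("repeated 3RS3R passes reach an invariant fixed point quickly", {
  set.seed(13)
  for (r in 1:200) {
    x <- rnorm(sample(3:60, 1))
    passes <- 0L
    repeat {
      s <- tukey_smooth_3rs3r(x)
      if (identical(s, x)) break
      x <- s
      passes <- passes + 1L
      expect_lte(passes, 10L)
    }
    expect_identical(tukey_smooth_3rs3r(x), x)
  }
})

test_that("continuous generator reproduces the stated design", {
  scen <- simulation_scenario("continuous", seed = 1)
  split <- generate_continuous(scen, beta1 = 2, seed = 1)
  expect_equal(vapply(split[c("train", "test", "validation")], n_obs,
                      integer(1), USE.NAMES = FALSE), c(300L, 300L, 300L))
  expect_identical(names(split$train$covariates), c("x1", "x2", "x3", "x4"))

  again <- generate_continuous(scen, beta1 = 2, seed = 1)
  expect_identical(split$validation$observed, again$validation$observed)

  expect_error(simulation_scenario("continuous", n_total = 901L),
               "divisible by 3")
})

test_that("null model with silenced noise gives identically zero outcomes", {
  scen <- simulation_scenario("continuous",
                              betas = c(beta2 = 0, beta3 = 0, beta4 = 0),
                              seed = 2)
  split <- generate_continuous(scen, beta1 = 0, noise_sd = 0, seed = 2)
  expect_equal(split$train$observed, rep(0, 300))
})

test_that("large-sample regression on the unsmoothed covariate recovers its slope", {
  scen <- simulation_scenario("continuous", n_total = 49998L,
                              betas = c(beta2 = 0, beta3 = 0, beta4 = 0),
                              seed = 3)
  split <- generate_continuous(scen, beta1 = 1, seed = 3)
  y <- unlist(lapply(split[c("train", "test", "validation")],
                     function(d) d$observed), use.names = FALSE)
  x1 <- unlist(lapply(split[c("train", "test", "validation")],
                      function(d) d$covariates$x1), use.names = FALSE)
  slope <- ols_oracle(cbind(1, x1), y)$coef[2]
  expect_equal(unname(slope), 1, tolerance = 0.02)
})

test_that("binary generator reproduces the stated design and inverse-logit law", {
  scen <- simulation_scenario("binary", seed = 4)
  split <- generate_binary(scen, betaC = 1, seed = 4)
  expect_equal(vapply(split[c("train", "test", "validation")], n_obs,
                      integer(1), USE.NAMES = FALSE), c(500L, 500L, 500L))
  expect_true(all(split$train$observed %in% c(0, 1)))
  expect_setequal(unique(split$train$covariates$xc), c("A", "B", "C"))

  # with all effects and noise silenced, Pr(y = 1) = 1/(1 + e^0) = 1/2
  null_scen <- simulation_scenario("binary", n_total = 99999L,
                                   betas = c(beta1 = 0, beta2 = 0, betaB = 0),
                                   seed = 5)
  null_split <- generate_binary(null_scen, betaC = 0, noise_sd = 0, seed = 5)
  y <- unlist(lapply(null_split[c("train", "test", "validation")],
                     function(d) d$observed), use.names = FALSE)
  expect_equal(mean(y), 0.5, tolerance = 0.005)
})

test_that("generated covariates match their stated distributions", {
  scen <- simulation_scenario("continuous", n_total = 99999L, seed = 6)
  split <- generate_continuous(scen, beta1 = 0, seed = 6)
  x <- do.call(rbind, lapply(split[c("train", "test", "validation")],
                             function(d) d$covariates))
  expect_equal(colMeans(x), c(x1 = 1, x2 = 1, x3 = 1, x4 = 2),
               tolerance = 0.02)
  expect_equal(unname(apply(x, 2, sd)), rep(1, 4), tolerance = 0.02)

  scenb <- simulation_scenario("binary", n_total = 99999L, seed = 7)
  splitb <- generate_binary(scenb, betaC = 0, seed = 7)
  xc <- unlist(lapply(splitb[c("train", "test", "validation")],
                      function(d) d$covariates$xc), use.names = FALSE)
  expect_equal(unname(table(xc)) / length(xc), rep(1 / 3, 3),
               tolerance = 0.01, ignore_attr = TRUE)
})

test_that("sparse-replicate flag agrees with a direct tabulation oracle", {
  spec <- inference_spec("binomial_logit", ~ I(xc == "C"))
  scen <- simulation_scenario("binary", n_total = 90L, seed = 8)
  set.seed(8)
  for (r in 1:25) {
    split <- generate_binary(scen, betaC = runif(1, -2, 5))
    flag <- flag_sparse_replicate(split, spec, threshold = 2L)
    val <- split$validation
    tab <- table(factor(val$observed, levels = c(0, 1)),
                 factor(as.numeric(val$covariates$xc == "C"),
                        levels = c(0, 1)))
    expect_identical(flag, any(tab < 2))
  }
})

test_that("explicitly empty cells are flagged at threshold 1", {
  scen <- simulation_scenario("binary", n_total = 90L, seed = 9)
  split <- generate_binary(scen, betaC = 0, seed = 9)
  spec <- inference_spec("binomial_logit", ~ I(xc == "C"))
  # force an empty (y = 1, xc = C) cell in the validation part
  val <- split$validation
  val$observed[val$covariates$xc == "C"] <- 0
  split$validation <- val
  expect_true(flag_sparse_replicate(split, spec, threshold = 1L))

  # perfectly balanced table with all cells at 10 passes a threshold of 5
  balanced <- labeled_dataset(
    data.frame(x1 = rnorm(60), x2 = rnorm(60),
               xc = rep(c("A", "B", "C"), each = 20),
               stringsAsFactors = FALSE),
    observed = rep(c(0, 1), 30), outcome_kind = "binary")
  split$validation <- balanced
  expect_false(flag_sparse_replicate(split, spec, threshold = 5L))
})

test_that("correlation sweep weakens predictions through training label noise", {
  base <- simulation_scenario("correlation_sweep", seed = 10,
                              label_noise_sd = 0)
  noisy <- simulation_scenario("correlation_sweep", seed = 10,
                               label_noise_sd = 8)
  cor_for <- function(scen) {
    split <- generate_continuous(scen, beta1 = 1, seed = 10)
    fp <- train_predictor(split$train, predictor_spec("gam"))
    test <- predict(fp, split$test)
    cor(test$observed, test$predicted)
  }
  expect_gt(cor_for(base), cor_for(noisy))
})
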