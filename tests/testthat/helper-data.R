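# Fixture builders shared across test files.

make_continuous_data <- function(n, seed = 1, p = 2) {
  set.seed(seed)
  cov <- as.data.frame(setNames(replicate(p, rnorm(n), simplify = FALSE),
                                paste0("x", seq_len(p))))
  labeled_dataset(cov, observed = rnorm(n, cov$x1), outcome_kind = "continuous")
}

make_predicted_data <- function(n, seed = 1, gamma0 = 0, gamma1 = 1,
                                sigma = 0.5) {
  set.seed(seed)
  x1 <- rnorm(n)
  yp <- 2 + 1.5 * x1 + rnorm(n, 0, 0.3)
  y <- gamma0 + gamma1 * yp + rnorm(n, 0, sigma)
  labeled_dataset(data.frame(x1 = x1), observed = y, predicted = yp,
                  outcome_kind = "continuous")
}

make_binary_probability_data <- function(n, seed = 1) {
  set.seed(seed)
  x1 <- rnorm(n)
  pr <- plogis(x1)
  y <- rbinom(n, 1, pr)
  probs <- cbind("0" = 1 - pr, "1" = pr)
  labeled_dataset(data.frame(x1 = x1), observed = as.numeric(y),
                  predicted = as.numeric(pr > 0.5), probabilities = probs,
                  outcome_kind = "binary")
}

# predictor stub that "predicts" the observed outcome itself; with it the
# whole pipeline reduces to classical inference on y
stub_identity_predictor <- function() {
  predictor_spec("custom",
                 fit = function(train) NULL,
                 predict = function(state, data) data$observed)
}

small_scenario <- function(generator, n_reps, seed, B = 50L, grid = NULL) {
  simulation_scenario(generator, n_reps = n_reps, seed = seed, B = B,
                      grid = grid)
}
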