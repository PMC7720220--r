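#' Tukey 3RS3R compound running-median smoother
#'
#' Running medians of 3 repeated to convergence, splitting of two-flats, then
#' repeated medians of 3 again, with Tukey's end rule (endpoints copied; the
#' second and penultimate points smoothed by one-sided split rules). This is
#' the classic exploratory-data-analysis compound smoother. Constant and
#' monotone series pass through unchanged and isolated spikes are removed.
#' Because the splitting step runs once, a single pass can occasionally leave
#' a newly formed two-flat behind; repeated application reaches a fixed point
#' within a few passes.
#'
#' @param series numeric vector (length >= 1; lengths 1 and 2 are returned
#'   unchanged).
#' @return The smoothed numeric vector, same length as the input.
#' @export
tukey_smooth_3rs3r <- function(series) {
  series <- as.numeric(series)
  if (length(series) < 3L) return(series)
  as.numeric(smooth(series, kind = "3RS3R"))
}

#' Describe a simulation scenario
#'
#' Bundles a generator with all of its generative and experimental
#' parameters. Defaults are the study conditions of the reference simulation
#' designs: the continuous scenario draws 900 rows split 300/300/300 with
#' fixed slopes (0.5, 3, 4) on the non-focal terms and sweeps the focal slope
#' over -6..6 with a GAM predictor; the binary scenario draws 1,500 rows
#' split 500/500/500 with fixed effects (1, -2, 1), sweeps the focal
#' indicator effect over -2..5 (step 0.5), and predicts with 5-nearest
#' neighbours; both run 300 replicates with B = 100 bootstrap iterations.
#'
#' @param generator `"continuous"`, `"binary"`, or `"correlation_sweep"`
#'   (a continuous variant whose prediction quality is degraded by training
#'   label noise for sensitivity studies).
#' @param n_total total rows per replicate (split equally three ways).
#' @param betas named vector of fixed generative coefficients.
#' @param grid values swept for the coefficient of interest; replicates cycle
#'   through the grid.
#' @param n_reps number of replicates.
#' @param B bootstrap iterations per replicate.
#' @param seed integer seed driving the whole experiment.
#' @param predictor a [predictor_spec()]; defaults to a GAM on all covariates
#'   (continuous) or k-NN with k = 5 (binary).
#' @param sparse_threshold minimum outcome-by-level cell count in the
#'   validation set before a binary replicate is excluded (see
#'   [flag_sparse_replicate()]).
#' @param label_noise_sd extra N(0, sd) noise added to *training* outcomes
#'   (correlation_sweep only) to weaken the predictor.
#' @return A `simulation_scenario` object.
#' @export
simulation_scenario <- function(generator = c("continuous", "binary",
                                              "correlation_sweep"),
                                n_total = NULL, betas = NULL, grid = NULL,
                                n_reps = 300L, B = 100L, seed = 1L,
                                predictor = NULL, sparse_threshold = 2L,
                                label_noise_sd = 0) {
  generator <- match.arg(generator)
  if (generator == "binary") {
    n_total <- n_total %||% 1500L
    betas <- betas %||% c(beta1 = 1, beta2 = -2, betaB = 1)
    grid <- grid %||% seq(-2, 5, by = 0.5)
    predictor <- predictor %||% predictor_spec("knn", hyperparameters = list(k = 5L))
  } else {
    n_total <- n_total %||% 900L
    betas <- betas %||% c(beta2 = 0.5, beta3 = 3, beta4 = 4)
    grid <- grid %||% seq(-6, 6, by = 1)
    predictor <- predictor %||% predictor_spec("gam")
  }
  if (!length(grid))
    stop_predinfer("the coefficient-of-interest grid must be nonempty",
                   "predinfer_config_error")
  if (n_total %% 3L != 0L)
    stop_predinfer("n_total must be divisible by 3 for the equal three-way split",
                   "predinfer_size_error")
  structure(list(generator = generator, n_total = n_total, betas = betas,
                 grid = grid, n_reps = as.integer(n_reps), B = as.integer(B),
                 seed = as.integer(seed), predictor = predictor,
                 sparse_threshold = as.integer(sparse_threshold),
                 label_noise_sd = label_noise_sd),
            class = "simulation_scenario")
}

#' @export
print.simulation_scenario <- function(x, ...) {
  cat(sprintf("<simulation_scenario> %s: n = %d, %d reps over %d grid values, B = %d, seed = %d\n",
              x$generator, x$n_total, x$n_reps, length(x$grid), x$B, x$seed))
  invisible(x)
}

#' Generate one replicate of the continuous simulation scenario
#'
#' Draws `x1, x2, x3 ~ N(1, 1)`, `x4 ~ N(2, 1)`, `eu ~ N(0, 1)` and builds
#' \deqn{y = \beta_1 x_1 + \beta_2 x_2 + \beta_3\,smooth(x_3) +
#'   \beta_4\,smooth(x_4) + e_u,}
#' where `smooth` is [tukey_smooth_3rs3r()] applied to the covariate column
#' in its generated row order. Smoothing the column as generated couples each
#' row to its neighbours in the draw sequence, which makes the smoothed terms
#' only partially recoverable from the covariates — the intended source of
#' irreducible prediction error in this scenario. The rows are then split
#' into three equal train/test/validation parts.
#'
#' @param scenario a continuous [simulation_scenario()].
#' @param beta1 slope of the covariate of interest `x1` for this replicate.
#' @param noise_sd SD of the error term `eu`; the default 1 is the study
#'   condition (0 is a degenerate test hook, not reachable from the CLI).
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @return A `data_split` with observed outcomes in all three parts.
#' @export
generate_continuous <- function(scenario, beta1, noise_sd = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- scenario$n_total
  b <- scenario$betas
  x1 <- rnorm(n, 1, 1); x2 <- rnorm(n, 1, 1); x3 <- rnorm(n, 1, 1)
  x4 <- rnorm(n, 2, 1)
  eu <- if (noise_sd == 0) rep(0, n) else rnorm(n, 0, noise_sd)
  y <- beta1 * x1 + b[["beta2"]] * x2 +
    b[["beta3"]] * tukey_smooth_3rs3r(x3) +
    b[["beta4"]] * tukey_smooth_3rs3r(x4) + eu
  data <- labeled_dataset(data.frame(x1 = x1, x2 = x2, x3 = x3, x4 = x4),
                          observed = y, outcome_kind = "continuous")
  split <- split_three_way(data)
  if (scenario$generator == "correlation_sweep" && scenario$label_noise_sd > 0)
    split$train$observed <- split$train$observed +
      rnorm(n_obs(split$train), 0, scenario$label_noise_sd)
  split
}

#' Generate one replicate of the binary simulation scenario
#'
#' Draws `x1 ~ N(1, 1)`, `x2 ~ N(2, 1)`, a three-level categorical covariate
#' `xc` uniform over {A, B, C} and `eu ~ N(0, 1)`, forms the linear predictor
#' \deqn{z = \beta_B 1(x_c = B) + \beta_C 1(x_c = C) +
#'   \beta_1\,smooth(x_1) + \beta_2\,smooth(x_2) + e_u,}
#' applies the inverse logit and draws `y ~ Bernoulli(1 / (1 + e^{-z}))`.
#' Rows are split into three equal parts.
#'
#' @param scenario a binary [simulation_scenario()].
#' @param betaC effect of the `xc = C` indicator for this replicate.
#' @param noise_sd SD of `eu` (test hook as in [generate_continuous()]).
#' @param seed optional integer seed.
#' @return A `data_split` with binary observed outcomes.
#' @export
generate_binary <- function(scenario, betaC, noise_sd = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- scenario$n_total
  b <- scenario$betas
  x1 <- rnorm(n, 1, 1); x2 <- rnorm(n, 2, 1)
  xc <- sample(c("A", "B", "C"), n, replace = TRUE)
  eu <- if (noise_sd == 0) rep(0, n) else rnorm(n, 0, noise_sd)
  z <- b[["betaB"]] * (xc == "B") + betaC * (xc == "C") +
    b[["beta1"]] * tukey_smooth_3rs3r(x1) +
    b[["beta2"]] * tukey_smooth_3rs3r(x2) + eu
  y <- rbinom(n, 1L, plogis(z))
  data <- labeled_dataset(data.frame(x1 = x1, x2 = x2, xc = xc,
                                     stringsAsFactors = FALSE),
                          observed = as.numeric(y), outcome_kind = "binary")
  split_three_way(data)
}

#' Flag a sparse binary replicate
#'
#' Logistic inference on a dichotomized covariate is unstable when an
#' outcome-by-level cell of the validation set is (near-)empty: SEs explode
#' for every method — for the observed-outcome truth when an observed cell is
#' empty, and for the naive predicted-label fit when a predicted cell is.
#' Such replicates are excluded from rmse aggregation. When the validation
#' part carries predicted labels, both the observed and the predicted
#' outcome-by-level tables are checked.
#'
#' @param split a `data_split` whose validation part has observed binary
#'   outcomes.
#' @param spec the [inference_spec()] naming the (indicator) covariate of
#'   interest.
#' @param threshold minimum count per outcome-by-level cell (default 2).
#' @return `TRUE` when any cell count falls below `threshold`.
#' @export
flag_sparse_replicate <- function(split, spec, threshold = 2L) {
  val <- split$validation
  if (is.null(val$observed))
    stop_predinfer("validation part has no observed outcome", "predinfer_schema_error")
  X <- build_design(spec, val)
  col <- X[, coef_of_interest(spec, X)]
  if (!all(col %in% c(0, 1)))
    stop_predinfer("sparsity check needs a 0/1 covariate of interest",
                   "predinfer_config_error")
  sparse_cells <- function(y) {
    counts <- table(factor(y, levels = c(0, 1)),
                    factor(col, levels = c(0, 1)))
    any(counts < threshold)
  }
  sparse_cells(val$observed) ||
    (!is.null(val$predicted) && sparse_cells(val$predicted))
}
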