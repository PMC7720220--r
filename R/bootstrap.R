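#' Bootstrap draws for post-prediction inference correction
#'
#' The bootstrap correction for any supported inference family. For each of B
#' iterations: (i) resample the validation rows (predictions and matching
#' covariates) with replacement; (ii) draw outcomes from the testing-set
#' relationship model at the resampled predictions, re-injecting the
#' prediction error; (iii) fit the inference model to the drawn outcomes;
#' (iv–v) record the coefficient estimates and their model SEs.
#'
#' One RNG stream is consumed in the fixed order (row resample, outcome draw)
#' per iteration, so a run is fully reproducible from `seed` and `B`.
#' Iterations whose GLM fit does not converge (or is separated) are excluded
#' and counted rather than retried — retrying would bias the draw
#' distribution; more than 20% exclusions is an error.
#'
#' @param validation a [labeled_dataset()] with predicted outcomes (and
#'   predicted probabilities when `rel` is categorical).
#' @param rel a fitted relationship model from the testing set.
#' @param spec an [inference_spec()].
#' @param B number of bootstrap iterations (>= 2); 100 matches the reference
#'   simulation studies.
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @return A `bootstrap_draws` object: matrices `estimates` and `ses`
#'   (valid draws x coefficients), the realised draw count `B`, the requested
#'   `B_requested` and the exclusion count `n_excluded`.
#' @export
bootstrap_draws <- function(validation, rel, spec, B = 100L, seed = NULL) {
  if (B < 2L)
    stop_predinfer("B must be at least 2", "predinfer_config_error")
  continuous_rel <- inherits(rel, "continuous_relationship")
  if (!continuous_rel && !inherits(rel, "categorical_relationship"))
    stop_predinfer("rel must be a fitted relationship model", "predinfer_state_error")
  if (continuous_rel && is.null(validation$predicted))
    stop_predinfer("validation data has no predicted outcome", "predinfer_schema_error")
  if (!continuous_rel && is.null(validation$probabilities))
    stop_predinfer("validation data has no predicted probabilities",
                   "predinfer_schema_error")
  if (!is.null(seed)) set.seed(seed)

  X <- build_design(spec, validation)
  n <- nrow(X)
  pred <- if (continuous_rel) as.numeric(validation$predicted)
          else validation$probabilities
  gaussian <- spec$family == "gaussian_identity"
  if (!gaussian && continuous_rel)
    stop_predinfer("a continuous relationship cannot drive a binomial inference model",
                   "predinfer_config_error")

  est <- matrix(NA_real_, B, ncol(X), dimnames = list(NULL, colnames(X)))
  ses <- est
  ok <- logical(B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    ytil <- if (continuous_rel) sample_from_relationship(rel, pred[idx])
            else sample_from_relationship(rel, pred[idx, , drop = FALSE])
    Xb <- X[idx, , drop = FALSE]
    if (gaussian) {
      if (qr(Xb)$rank < ncol(Xb)) next
      fit <- ols_components(Xb, as.numeric(ytil))
      if (!all(is.finite(fit$coef)) || !all(is.finite(fit$se))) next
      est[b, ] <- fit$coef; ses[b, ] <- fit$se; ok[b] <- TRUE
    } else {
      ynum <- if (is.numeric(ytil)) ytil
              else as.numeric(as.character(ytil) == rel$positive_class)
      fit <- tryCatch(logistic_components(Xb, ynum), error = function(e) NULL)
      if (is.null(fit) || !fit$converged) next
      est[b, ] <- fit$coef; ses[b, ] <- fit$se; ok[b] <- TRUE
    }
  }
  n_excluded <- sum(!ok)
  if (n_excluded > 0.2 * B)
    stop_predinfer(sprintf("%d of %d bootstrap fits failed to converge (over 20%%)",
                           n_excluded, B),
                   "predinfer_convergence_error")
  structure(list(estimates = est[ok, , drop = FALSE],
                 ses = ses[ok, , drop = FALSE],
                 B = sum(ok), B_requested = B, n_excluded = n_excluded,
                 seed = seed),
            class = "bootstrap_draws")
}

#' @export
print.bootstrap_draws <- function(x, ...) {
  cat(sprintf("<bootstrap_draws> B = %d valid draws (%d excluded), %d coefficients\n",
              x$B, x$n_excluded, ncol(x$estimates)))
  invisible(x)
}

check_draws <- function(draws) {
  if (!inherits(draws, "bootstrap_draws"))
    stop_predinfer("draws must come from bootstrap_draws()", "predinfer_state_error")
  if (draws$B < 2L)
    stop_predinfer("need at least 2 valid draws to summarize",
                   "predinfer_size_error")
}

#' Parametric bootstrap summary
#'
#' The corrected estimate is the median of the per-draw coefficient
#' estimates; the corrected SE is the median of the per-draw model SEs (even
#' draw counts use the mean of the two central order statistics). The test
#' statistic is their ratio, with a two-sided standard-normal p-value.
#'
#' @param draws a [bootstrap_draws()] result.
#' @return A `corrected_inference` data frame, `method = "boot_parametric"`.
#' @export
summarize_parametric <- function(draws) {
  check_draws(draws)
  est <- apply(draws$estimates, 2L, median)
  se <- apply(draws$ses, 2L, median)
  inference_rows(est, se, "boot_parametric", reference = "normal")
}

#' Nonparametric bootstrap summary
#'
#' The corrected estimate is the median of the per-draw coefficient
#' estimates; the corrected SE is their sample standard deviation
#' (denominator B - 1), ignoring the per-draw model SEs entirely.
#'
#' @param draws a [bootstrap_draws()] result.
#' @return A `corrected_inference` data frame,
#'   `method = "boot_nonparametric"`.
#' @export
summarize_nonparametric <- function(draws) {
  check_draws(draws)
  est <- apply(draws$estimates, 2L, median)
  se <- apply(draws$estimates, 2L, sd)
  if (any(se == 0))
    stop_predinfer("bootstrap estimates have zero spread; nonparametric SE is degenerate",
                   "predinfer_degenerate_error")
  inference_rows(est, se, "boot_nonparametric", reference = "normal")
}
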