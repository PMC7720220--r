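#' Specify the downstream inference model
#'
#' The inference model is the (generalized) linear regression whose
#' coefficient, SE and test statistic are the scientific targets. Its
#' covariates must be a subset of the columns used by the prediction model.
#'
#' @param family `"gaussian_identity"` (linear model) or `"binomial_logit"`
#'   (logistic regression).
#' @param formula model formula; the left-hand side (if any) is ignored and an
#'   intercept is always included, e.g. `~ x1` or `y ~ I(xc == "C")`.
#' @param coef name of the design-matrix column of interest; defaults to the
#'   first non-intercept column.
#' @return An `inference_spec` object.
#' @export
inference_spec <- function(family = c("gaussian_identity", "binomial_logit"),
                           formula, coef = NULL) {
  family <- match.arg(family)
  formula <- as.formula(formula)
  rhs <- if (length(formula) == 3L) formula[-2L] else formula
  structure(list(family = family, rhs = rhs, coef = coef),
            class = "inference_spec")
}

build_design <- function(spec, data) {
  vars <- all.vars(spec$rhs)
  if (length(bad <- setdiff(vars, names(data$covariates))))
    stop_predinfer(paste("inference covariates not in schema:",
                         paste(bad, collapse = ", ")),
                   "predinfer_schema_error")
  X <- model.matrix(spec$rhs, data$covariates)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dropped <- colnames(X)[qrx$pivot[-seq_len(qrx$rank)]]
    stop_predinfer(paste("design matrix is rank deficient; collinear column(s):",
                         paste(dropped, collapse = ", ")),
                   "predinfer_collinearity_error")
  }
  X
}

coef_of_interest <- function(spec, X) {
  nm <- spec$coef %||% setdiff(colnames(X), "(Intercept)")[1L]
  if (!nm %in% colnames(X))
    stop_predinfer(sprintf("coefficient '%s' not in the design (have: %s)",
                           nm, paste(colnames(X), collapse = ", ")),
                   "predinfer_config_error")
  nm
}

# OLS components via the normal equations (design is pre-checked full rank)
ols_components <- function(X, y) {
  XtX_inv <- chol2inv(chol(crossprod(X)))
  coefs <- drop(XtX_inv %*% crossprod(X, y))
  res <- y - drop(X %*% coefs)
  df <- nrow(X) - ncol(X)
  sigma2 <- if (df > 0) sum(res^2) / df else 0
  list(coef = setNames(coefs, colnames(X)),
       se = setNames(sqrt(diag(XtX_inv) * sigma2), colnames(X)),
       sigma = sqrt(sigma2), df = df, XtX_inv = XtX_inv)
}

# logistic MLE via stats::glm.fit, with Wald SEs from the weighted
# least-squares decomposition (as summary.glm computes them)
logistic_components <- function(X, y) {
  fit <- suppressWarnings(
    glm.fit(X, y, family = binomial(),
            control = glm.control(epsilon = 1e-10, maxit = 100)))
  p <- fit$rank
  covmat <- chol2inv(fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE])
  se <- sqrt(diag(covmat))
  list(coef = setNames(unname(fit$coefficients), colnames(X)),
       se = setNames(se, colnames(X)),
       converged = fit$converged && all(is.finite(fit$coefficients)) &&
         all(abs(fit$coefficients) < 30) && all(is.finite(se)))
}

inference_rows <- function(coefs, ses, method, reference = c("normal", "t"),
                           df = NULL) {
  reference <- match.arg(reference)
  statistic <- coefs / ses
  p <- if (reference == "t") 2 * pt(abs(statistic), df, lower.tail = FALSE)
       else 2 * pnorm(-abs(statistic))
  structure(data.frame(method = method, coefficient = names(coefs),
                       estimate = unname(coefs), se = unname(ses),
                       statistic = unname(statistic), p_value = unname(p),
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("corrected_inference", "data.frame"))
}

#' Fit the inference model directly on observed or predicted outcomes
#'
#' The two uncorrected reference fits: `outcome = "observed"` is the gold
#' standard analysis available only when outcomes were collected;
#' `outcome = "predicted"` is the naive, uncorrected post-prediction fit.
#'
#' @param data a [labeled_dataset()].
#' @param spec an [inference_spec()].
#' @param outcome which outcome vector to regress.
#' @return A `corrected_inference` data frame (one row per coefficient) with
#'   columns `method`, `coefficient`, `estimate`, `se`, `statistic`,
#'   `p_value`. Linear fits use the t reference for p-values, logistic fits
#'   the normal reference.
#' @export
fit_inference <- function(data, spec, outcome = c("observed", "predicted")) {
  outcome <- match.arg(outcome)
  y <- if (outcome == "observed") data$observed else data$predicted
  if (is.null(y))
    stop_predinfer(sprintf("dataset has no %s outcome", outcome),
                   "predinfer_schema_error")
  X <- build_design(spec, data)
  method <- if (outcome == "observed") "observed_outcome" else "no_correction"
  if (spec$family == "gaussian_identity") {
    fit <- ols_components(X, as.numeric(y))
    inference_rows(fit$coef, fit$se, method, reference = "t", df = fit$df)
  } else {
    if (data$outcome_kind == "binary") y <- as.numeric(y)
    else stop_predinfer("binomial_logit inference requires a binary outcome",
                        "predinfer_config_error")
    fit <- logistic_components(X, y)
    if (!fit$converged)
      stop_predinfer("logistic inference model did not converge",
                     "predinfer_convergence_error")
    inference_rows(fit$coef, fit$se, method, reference = "normal")
  }
}

#' Fit the naive predicted-outcome linear model on the validation set
#'
#' OLS of the predicted outcome on the inference design (intercept included).
#' This fit is what uncorrected post-prediction inference reports; its
#' coefficients, residual SD and design matrix are the raw material of the
#' analytical correction.
#'
#' @param validation a [labeled_dataset()] with predicted outcomes.
#' @param spec a gaussian-identity [inference_spec()].
#' @return A `naive_fit` with fields `beta_p`, `se_p`, `sigma_p` (residual
#'   SD, denominator n - rank), `df`, `design`, `XtX_inv`.
#' @export
fit_naive <- function(validation, spec) {
  if (spec$family != "gaussian_identity")
    stop_predinfer("fit_naive applies to linear inference models only",
                   "predinfer_config_error")
  if (is.null(validation$predicted))
    stop_predinfer("validation data has no predicted outcome",
                   "predinfer_schema_error")
  X <- build_design(spec, validation)
  fit <- ols_components(X, as.numeric(validation$predicted))
  structure(list(beta_p = fit$coef, se_p = fit$se, sigma_p = fit$sigma,
                 df = fit$df, design = X, XtX_inv = fit$XtX_inv),
            class = "naive_fit")
}

#' @export
print.naive_fit <- function(x, ...) {
  cat(sprintf("<naive_fit> %d coefficients, n = %d, residual SD %.4g\n",
              length(x$beta_p), nrow(x$design), x$sigma_p))
  invisible(x)
}

#' Analytical post-prediction correction for linear inference models
#'
#' Closed-form correction of the naive predicted-outcome fit. The corrected
#' estimate projects the relationship-adjusted conditional mean back onto the
#' design:
#' \deqn{\hat\beta^\star = (X^T X)^{-1} X^T(\hat\gamma_0 +
#'   \hat\gamma_1 X \hat\beta_p),}
#' which with an intercept column equals \eqn{\hat\gamma_1 \hat\beta_p} for
#' every slope and \eqn{\hat\gamma_0 + \hat\gamma_1 \hat\beta_{p0}} for the
#' intercept. The corrected variance combines the relationship residual
#' variance with the slope-scaled naive residual variance:
#' \deqn{SE_j = \sqrt{[(X^T X)^{-1}]_{jj}\,
#'   (\hat\sigma_r^2 + \hat\gamma_1^2 \hat\sigma_p^2)},}
#' and the test statistic is their ratio, referred to a standard normal
#' (two-sided) — the asymptotic reference, since no finite-sample df mixing
#' the testing- and validation-set sizes is available.
#'
#' @param naive a [fit_naive()] result.
#' @param rel a [fit_continuous_relationship()] result.
#' @return A `corrected_inference` data frame, `method = "analytical"`.
#' @export
correct_analytical <- function(naive, rel) {
  if (!inherits(naive, "naive_fit"))
    stop_predinfer("naive must come from fit_naive()", "predinfer_state_error")
  if (!inherits(rel, "continuous_relationship"))
    stop_predinfer("rel must be a fitted continuous_relationship",
                   "predinfer_state_error")
  X <- naive$design
  ystar <- rel$gamma0 + rel$gamma1 * drop(X %*% naive$beta_p)
  est <- setNames(drop(naive$XtX_inv %*% crossprod(X, ystar)),
                  colnames(X))
  total_var <- rel$sigma_r^2 + rel$gamma1^2 * naive$sigma_p^2
  if (total_var == 0) {
    if (all(est == 0))
      stop_predinfer("degenerate correction: zero variance and zero estimates",
                     "predinfer_degenerate_error")
    se <- setNames(rep(0, length(est)), names(est))
    statistic <- ifelse(est == 0, 0, sign(est) * Inf)
    out <- data.frame(method = "analytical", coefficient = names(est),
                      estimate = unname(est), se = unname(se),
                      statistic = unname(statistic),
                      p_value = as.numeric(est == 0), row.names = NULL,
                      stringsAsFactors = FALSE)
    return(structure(out, class = c("corrected_inference", "data.frame")))
  }
  se <- setNames(sqrt(diag(naive$XtX_inv) * total_var), names(est))
  inference_rows(est, se, "analytical", reference = "normal")
}

#' @export
print.corrected_inference <- function(x, ...) {
  cat(sprintf("<corrected_inference> method: %s\n",
              paste(unique(x$method), collapse = ", ")))
  print.data.frame(x, digits = 4)
  invisible(x)
}
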