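#' Estimate the continuous observed-vs-predicted relationship model
#'
#' On the testing set, regresses the observed outcome on the predicted
#' outcome, `y = gamma0 + gamma1 * yp + e`, `e ~ N(0, sigma_r^2)`. This simple
#' linear model is the object every correction consumes: it captures the bias
#' (intercept/slope) and the lost variability (residual SD) of the prediction,
#' whatever machine-learning model produced it.
#'
#' @param test a [labeled_dataset()] with both observed and predicted
#'   outcomes; at least 3 rows and non-degenerate predictions.
#' @return A `continuous_relationship` with fields `gamma0`, `gamma1`,
#'   `sigma_r` (residual SD, denominator n - 2) and `n_fit`.
#' @export
fit_continuous_relationship <- function(test) {
  if (is.null(test$observed) || is.null(test$predicted))
    stop_predinfer("testing data needs observed and predicted outcomes",
                   "predinfer_schema_error")
  y <- as.numeric(test$observed)
  yp <- as.numeric(test$predicted)
  n <- length(y)
  if (n < 3L)
    stop_predinfer("need at least 3 testing rows to fit the relationship",
                   "predinfer_size_error")
  if (var(yp) == 0)
    stop_predinfer("predicted outcomes are constant; relationship model is degenerate",
                   "predinfer_degenerate_error")
  X <- cbind(1, yp)
  fit <- lm.fit(X, y)
  res <- fit$residuals
  structure(list(gamma0 = unname(fit$coefficients[1L]),
                 gamma1 = unname(fit$coefficients[2L]),
                 sigma_r = sqrt(sum(res^2) / (n - 2)),
                 n_fit = n),
            class = "continuous_relationship")
}

#' @export
print.continuous_relationship <- function(x, ...) {
  cat(sprintf("<continuous_relationship> y = %.4g + %.4g * yp + N(0, %.4g^2), n = %d\n",
              x$gamma0, x$gamma1, x$sigma_r, x$n_fit))
  invisible(x)
}

#' Estimate the categorical observed-vs-predicted relationship model
#'
#' For dichotomous outcomes the hard predicted label carries too little
#' information to model outcome variability, so the relationship is fitted on
#' the predicted class probability instead: a logistic regression
#' `logit Pr(y = 1) = gamma0 + gamma1 * pr` for binary outcomes, or a k-NN
#' map from probability rows to class distributions (`knn_in_probability`,
#' required for 3+ classes).
#'
#' @param test a [labeled_dataset()] with observed outcomes and predicted
#'   class probabilities; at least two classes must be observed.
#' @param model_kind `"logistic_in_probability"` (binary only) or
#'   `"knn_in_probability"`.
#' @param k neighbourhood size for `knn_in_probability`.
#' @return A `categorical_relationship` that can evaluate class distributions
#'   for new probability rows (see [predict_class_distribution()]) and be
#'   sampled from (see [sample_from_relationship()]).
#' @export
fit_categorical_relationship <- function(test,
                                         model_kind = c("logistic_in_probability",
                                                        "knn_in_probability"),
                                         k = 5L) {
  model_kind <- match.arg(model_kind)
  if (is.null(test$observed) || is.null(test$probabilities))
    stop_predinfer("testing data needs observed outcomes and predicted probabilities",
                   "predinfer_schema_error")
  classes <- test$classes
  y_chr <- as.character(test$observed)
  if (length(unique(y_chr)) < 2L)
    stop_predinfer("only one outcome class observed; relationship model is separated",
                   "predinfer_separation_error")

  if (model_kind == "logistic_in_probability") {
    if (length(classes) != 2L)
      stop_predinfer("logistic_in_probability requires a binary outcome; use knn_in_probability",
                     "predinfer_config_error")
    pr <- test$probabilities[, test$positive_class]
    y01 <- as.numeric(y_chr == test$positive_class)
    X <- cbind(`(Intercept)` = 1, pr = pr)
    fit <- suppressWarnings(
      glm.fit(X, y01, family = binomial(),
              control = glm.control(epsilon = 1e-10, maxit = 100)))
    if (!fit$converged)
      stop_predinfer("logistic relationship model did not converge within 100 iterations",
                     "predinfer_convergence_error")
    model <- list(gamma0 = unname(fit$coefficients[1L]),
                  gamma1 = unname(fit$coefficients[2L]))
  } else {
    model <- caret::knn3(test$probabilities,
                         factor(y_chr, levels = classes), k = k)
  }
  structure(list(model_kind = model_kind, model = model, classes = classes,
                 positive_class = test$positive_class,
                 n_fit = length(y_chr)),
            class = "categorical_relationship")
}

#' @export
print.categorical_relationship <- function(x, ...) {
  cat(sprintf("<categorical_relationship> %s over classes {%s}, n = %d\n",
              x$model_kind, paste(x$classes, collapse = ", "), x$n_fit))
  invisible(x)
}

#' Evaluate class distributions under a categorical relationship model
#'
#' @param rel a `categorical_relationship`.
#' @param probabilities numeric matrix of predicted class probabilities
#'   (columns named by class).
#' @return An n x C matrix of proper class distributions.
#' @export
predict_class_distribution <- function(rel, probabilities) {
  if (!inherits(rel, "categorical_relationship"))
    stop_predinfer("rel must be a fitted categorical_relationship",
                   "predinfer_state_error")
  if (rel$model_kind == "logistic_in_probability") {
    pr <- probabilities[, rel$positive_class]
    p1 <- plogis(rel$model$gamma0 + rel$model$gamma1 * pr)
    out <- cbind(1 - p1, p1)
    colnames(out) <- c(setdiff(rel$classes, rel$positive_class),
                       rel$positive_class)
    out[, rel$classes, drop = FALSE]
  } else {
    out <- predict(rel$model, probabilities, type = "prob")
    out <- out[, rel$classes, drop = FALSE]
    rownames(out) <- NULL
    out / rowSums(out)
  }
}

#' Sample outcomes from a fitted relationship model
#'
#' The sampling step of the bootstrap correction: given predictions, draws
#' outcomes carrying the prediction error the relationship model measured.
#' Continuous relationships draw `gamma0 + gamma1 * yp + N(0, sigma_r^2)`;
#' categorical ones evaluate the class distribution per row and draw one
#' label (binomial for two classes, multinomial beyond).
#'
#' @param rel a `continuous_relationship` or `categorical_relationship`.
#' @param predicted for continuous relationships, a numeric vector of
#'   predicted outcomes; for categorical ones, a probability matrix.
#' @param ... unused.
#' @return A sampled outcome vector (numeric; 0/1 for binary outcomes,
#'   character labels for 3+ classes).
#' @export
sample_from_relationship <- function(rel, predicted, ...) {
  UseMethod("sample_from_relationship")
}

#' @export
sample_from_relationship.default <- function(rel, predicted, ...) {
  stop_predinfer("rel must be a fitted relationship model", "predinfer_state_error")
}

#' @export
sample_from_relationship.continuous_relationship <- function(rel, predicted, ...) {
  mu <- rel$gamma0 + rel$gamma1 * as.numeric(predicted)
  rnorm(length(mu), mean = mu, sd = rel$sigma_r)
}

#' @export
sample_from_relationship.categorical_relationship <- function(rel, predicted, ...) {
  dist <- predict_class_distribution(rel, predicted)
  n <- nrow(dist)
  if (length(rel$classes) == 2L) {
    draw <- rbinom(n, 1L, dist[, rel$positive_class])
    lab <- ifelse(draw == 1L, rel$positive_class,
                  setdiff(rel$classes, rel$positive_class))
    if (all(rel$classes %in% c("0", "1"))) as.numeric(lab) else lab
  } else {
    vapply(seq_len(n),
           function(i) sample(rel$classes, 1L, prob = dist[i, ]),
           character(1))
  }
}
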