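#' Specify a prediction model
#'
#' The prediction function is deliberately pluggable: the correction methods
#' never look inside it, they only consume its predictions through the
#' testing-set relationship model. Reference implementations cover the models
#' used by the simulation studies (a GAM for continuous outcomes, k-nearest
#' neighbours for classification) plus random forests; arbitrary models hook
#' in through `kind = "custom"`.
#'
#' @param kind one of `"gam"`, `"knn"`, `"random_forest"`, `"custom"`.
#' @param hyperparameters named list. Recognised entries: `k` (k-NN, default
#'   5, on standardized features), `ntree` (random forest, default 500).
#' @param features covariate columns used as predictors; default all.
#' @param fit,predict for `kind = "custom"`: `fit(train)` returns an opaque
#'   state; `predict(state, data)` returns either a vector of predicted
#'   values/labels or a list with elements `values` or `labels` +
#'   `probabilities`.
#' @return A `predictor_spec` object.
#' @export
predictor_spec <- function(kind = c("gam", "knn", "random_forest", "custom"),
                           hyperparameters = list(), features = NULL,
                           fit = NULL, predict = NULL) {
  kind <- match.arg(kind)
  if (kind == "custom" && (!is.function(fit) || !is.function(predict)))
    stop_predinfer("custom predictors need fit() and predict() functions",
                   "predinfer_config_error")
  structure(list(kind = kind, hyperparameters = hyperparameters,
                 features = features, fit = fit, predict = predict),
            class = "predictor_spec")
}

# feature encoder shared by distance-based models: standardize numeric
# columns by training mean/sd, one-hot encode categorical ones with the
# training level set
make_encoder <- function(covariates, features) {
  cols <- lapply(features, function(nm) {
    col <- covariates[[nm]]
    if (is.numeric(col)) {
      s <- sd(col)
      list(name = nm, type = "numeric", center = mean(col),
           scale = if (is.na(s) || s == 0) 1 else s)
    } else {
      list(name = nm, type = "categorical",
           levels = sort(unique(as.character(col))))
    }
  })
  structure(list(cols = cols), class = "predinfer_encoder")
}

encode_features <- function(encoder, covariates) {
  blocks <- lapply(encoder$cols, function(ci) {
    col <- covariates[[ci$name]]
    if (ci$type == "numeric") {
      m <- matrix((col - ci$center) / ci$scale, ncol = 1)
      colnames(m) <- ci$name
      m
    } else {
      m <- vapply(ci$levels, function(l) as.numeric(as.character(col) == l),
                  numeric(length(col)))
      if (length(col) == 1L) m <- matrix(m, nrow = 1)
      if (length(col) == 0L) m <- matrix(0, 0, length(ci$levels))
      colnames(m) <- paste0(ci$name, ".", ci$levels)
      m
    }
  })
  do.call(cbind, blocks)
}

#' Train a prediction model on the training set
#'
#' @param train a [labeled_dataset()] with an observed outcome.
#' @param spec a [predictor_spec()].
#' @return A `fitted_predictor` whose [predict()] method fills the
#'   `predicted` slot (and `probabilities`, when classifying) of new data.
#' @export
train_predictor <- function(train, spec) {
  if (!inherits(spec, "predictor_spec"))
    stop_predinfer("spec must be a predictor_spec", "predinfer_config_error")
  if (is.null(train$observed))
    stop_predinfer("training data must carry an observed outcome",
                   "predinfer_schema_error")
  features <- spec$features %||% names(train$covariates)
  if (length(bad <- setdiff(features, names(train$covariates))))
    stop_predinfer(paste("features not in schema:", paste(bad, collapse = ", ")),
                   "predinfer_schema_error")

  y <- train$observed
  kind <- spec$kind
  classify <- train$outcome_kind != "continuous"
  output_kind <- if (classify) "class_with_probability" else "value"

  if (!classify && var(y) == 0) {
    warning("training outcome has zero variance; using a constant predictor")
    return(structure(list(spec = spec, features = features, state = NULL,
                          constant = y[1L], output_kind = output_kind,
                          classes = train$classes,
                          positive_class = train$positive_class,
                          outcome_kind = train$outcome_kind),
                     class = "fitted_predictor"))
  }

  encoder <- NULL
  state <- switch(
    kind,
    gam = {
      if (classify)
        stop_predinfer("the GAM reference predictor supports continuous outcomes only",
                       "predinfer_config_error")
      df <- train$covariates[features]
      df$.y <- y
      rhs <- vapply(features, function(nm) {
        # smooth terms need enough unique covariate values; fall back to linear
        if (length(unique(df[[nm]])) >= 10) sprintf("s(%s)", nm) else nm
      }, character(1))
      mgcv::gam(as.formula(paste(".y ~", paste(rhs, collapse = " + "))),
                data = df)
    },
    knn = {
      k <- spec$hyperparameters$k %||% 5L
      encoder <- make_encoder(train$covariates, features)
      X <- encode_features(encoder, train$covariates)
      if (classify)
        caret::knn3(X, factor(as.character(y), levels = train$classes), k = k)
      else caret::knnreg(X, y, k = k)
    },
    random_forest = {
      ntree <- spec$hyperparameters$ntree %||% 500L
      X <- train$covariates[features]
      X[] <- lapply(X, function(col) if (is.character(col)) factor(col) else col)
      resp <- if (classify) factor(as.character(y), levels = train$classes) else y
      randomForest::randomForest(X, resp, ntree = ntree)
    },
    custom = spec$fit(train),
    stop_predinfer(paste("unknown predictor kind:", kind),
                   "predinfer_config_error"))

  structure(list(spec = spec, features = features, state = state,
                 encoder = encoder, constant = NULL, output_kind = output_kind,
                 classes = train$classes, positive_class = train$positive_class,
                 outcome_kind = train$outcome_kind),
            class = "fitted_predictor")
}

#' Predict outcomes for a labeled dataset
#'
#' Fills the `predicted` component (and `probabilities`, for classifiers) of
#' `data`; the observed outcome, if present, is left untouched. The predicted
#' class label is always the argmax of the predicted class probabilities
#' (first class wins ties).
#'
#' @param object a `fitted_predictor` from [train_predictor()].
#' @param data a [labeled_dataset()] whose schema contains the spec features.
#' @param ... unused.
#' @return `data` with predictions filled in.
#' @export
predict.fitted_predictor <- function(object, data, ...) {
  if (length(bad <- setdiff(object$features, names(data$covariates))))
    stop_predinfer(paste("missing feature column(s):", paste(bad, collapse = ", ")),
                   "predinfer_schema_error")
  n <- n_obs(data)
  classify <- object$output_kind == "class_with_probability"

  finish <- function(values, probs = NULL) {
    data$predicted <- values
    if (!is.null(probs)) data$probabilities <- probs
    data$classes <- data$classes %||% object$classes
    data$positive_class <- data$positive_class %||% object$positive_class
    validate_labeled_dataset(data)
    data
  }
  labels_from_probs <- function(probs) {
    lab <- object$classes[max.col(probs, ties.method = "first")]
    if (object$outcome_kind == "binary") as.numeric(lab) else lab
  }
  empty <- function() {
    probs <- if (classify)
      matrix(0, 0, length(object$classes),
             dimnames = list(NULL, object$classes))
    vals <- if (object$outcome_kind == "categorical") character(0) else numeric(0)
    finish(vals, probs)
  }
  if (n == 0L) return(empty())
  if (!is.null(object$constant)) return(finish(rep(object$constant, n)))

  kind <- object$spec$kind
  if (kind == "custom") {
    out <- object$spec$predict(object$state, data)
    if (is.list(out) && !is.null(out$probabilities)) {
      probs <- out$probabilities[, object$classes, drop = FALSE]
      vals <- out$labels %||% labels_from_probs(probs)
      return(finish(vals, probs))
    }
    vals <- if (is.list(out)) out$values else out
    return(finish(as.vector(vals)))
  }

  if (kind == "gam")
    return(finish(as.numeric(predict(object$state,
                                     newdata = data$covariates[object$features]))))

  newX <- if (kind == "knn")
    encode_features(object$encoder, data$covariates)
  else {
    X <- data$covariates[object$features]
    X[] <- lapply(X, function(col) if (is.character(col)) factor(col) else col)
    X
  }
  if (!classify) {
    vals <- if (kind == "knn") predict(object$state, newX)
            else as.numeric(predict(object$state, newX))
    return(finish(as.numeric(vals)))
  }
  probs <- predict(object$state, newX,
                   type = if (kind == "knn") "prob" else "prob")
  probs <- probs[, object$classes, drop = FALSE]
  rownames(probs) <- NULL
  # guard against tiny negative / >1 values from accumulated float error
  probs <- probs / rowSums(probs)
  finish(labels_from_probs(probs), probs)
}
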