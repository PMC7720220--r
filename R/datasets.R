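#' Labeled dataset for post-prediction inference
#'
#' Container for a covariate table together with any of: an observed outcome,
#' a predicted outcome, and predicted class probabilities. The same structure
#' is used for the training role (observed outcome only), the testing role
#' (observed + predicted) and the validation role (predicted only).
#'
#' @param covariates data frame of covariates (numeric columns, plus
#'   character/factor columns for categorical covariates). Column names are
#'   the schema every other component refers to.
#' @param observed optional observed outcome vector: numeric for
#'   `outcome_kind = "continuous"`, numeric 0/1 for `"binary"`, character for
#'   `"categorical"`.
#' @param predicted optional predicted outcome vector, same value domain as
#'   `observed`.
#' @param probabilities optional numeric matrix (n x C) of predicted class
#'   probabilities with one named column per class; rows must lie in \[0, 1\]
#'   and sum to 1 within 1e-8.
#' @param outcome_kind one of `"continuous"`, `"binary"`, `"categorical"`.
#' @param classes ordered class labels for binary/categorical outcomes.
#'   Defaults to `c("0", "1")` for binary. The binary class coded 1 is always
#'   recorded explicitly via `positive_class`, never inferred from sort order.
#' @param positive_class label of the class coded 1 in binary outcomes.
#'
#' @return An object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(covariates, observed = NULL, predicted = NULL,
                            probabilities = NULL,
                            outcome_kind = c("continuous", "binary", "categorical"),
                            classes = NULL, positive_class = NULL) {
  outcome_kind <- match.arg(outcome_kind)
  covariates <- as.data.frame(covariates, stringsAsFactors = FALSE)
  if (is.null(names(covariates)) || any(!nzchar(names(covariates))))
    stop_predinfer("covariate columns must be named", "predinfer_schema_error")
  n <- nrow(covariates)

  if (outcome_kind == "binary") {
    classes <- classes %||% c("0", "1")
    if (length(classes) != 2L)
      stop_predinfer("binary outcomes need exactly two classes", "predinfer_config_error")
    positive_class <- positive_class %||% classes[2L]
    if (!positive_class %in% classes)
      stop_predinfer("positive_class must be one of the classes", "predinfer_config_error")
  }
  if (outcome_kind == "categorical" && is.null(classes))
    classes <- sort(unique(as.character(c(observed, predicted))))

  obj <- structure(
    list(covariates = covariates, observed = observed, predicted = predicted,
         probabilities = probabilities, outcome_kind = outcome_kind,
         classes = classes, positive_class = positive_class),
    class = "labeled_dataset")
  validate_labeled_dataset(obj)
  obj
}

validate_labeled_dataset <- function(x) {
  n <- nrow(x$covariates)
  for (nm in names(x$covariates)) {
    col <- x$covariates[[nm]]
    if (anyNA(col))
      stop_predinfer(sprintf("missing values in covariate '%s' (row %d)",
                             nm, which(is.na(col))[1L]),
                     "predinfer_parse_error")
  }
  check_outcome <- function(v, what) {
    if (length(v) != n)
      stop_predinfer(sprintf("%s has %d rows but covariates have %d",
                             what, length(v), n), "predinfer_schema_error")
    if (anyNA(v))
      stop_predinfer(sprintf("missing values in %s", what), "predinfer_parse_error")
    if (x$outcome_kind %in% c("continuous", "binary") && !is.numeric(v))
      stop_predinfer(sprintf("%s must be numeric for %s outcomes", what, x$outcome_kind),
                     "predinfer_schema_error")
    if (x$outcome_kind == "binary" && !all(v %in% c(0, 1)))
      stop_predinfer(sprintf("binary %s must be coded {0,1}", what),
                     "predinfer_schema_error")
    if (x$outcome_kind == "categorical" && !all(as.character(v) %in% x$classes))
      stop_predinfer(sprintf("%s contains labels outside the class list", what),
                     "predinfer_schema_error")
  }
  if (!is.null(x$observed)) check_outcome(x$observed, "observed outcome")
  if (!is.null(x$predicted)) check_outcome(x$predicted, "predicted outcome")
  if (!is.null(x$probabilities)) {
    p <- x$probabilities
    if (!is.matrix(p) || nrow(p) != n)
      stop_predinfer("probabilities must be an n-row matrix", "predinfer_schema_error")
    if (is.null(colnames(p)))
      stop_predinfer("probability columns must be named by class", "predinfer_schema_error")
    if (anyNA(p) || any(p < -1e-12) || any(p > 1 + 1e-12))
      stop_predinfer("probabilities must lie in [0, 1]", "predinfer_invariant_error")
    if (n > 0 && any(abs(rowSums(p) - 1) > 1e-8))
      stop_predinfer("probability rows must sum to 1 within 1e-8",
                     "predinfer_invariant_error")
  }
  invisible(x)
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d rows, %d covariates (%s outcome)\n",
              nrow(x$covariates), ncol(x$covariates), x$outcome_kind))
  parts <- c(observed = !is.null(x$observed), predicted = !is.null(x$predicted),
             probabilities = !is.null(x$probabilities))
  cat("  components:", paste(names(parts)[parts], collapse = ", "), "\n")
  invisible(x)
}

n_obs <- function(data) nrow(data$covariates)

dataset_subset <- function(data, idx) {
  structure(
    list(covariates = data$covariates[idx, , drop = FALSE],
         observed = if (!is.null(data$observed)) data$observed[idx],
         predicted = if (!is.null(data$predicted)) data$predicted[idx],
         probabilities = if (!is.null(data$probabilities))
           data$probabilities[idx, , drop = FALSE],
         outcome_kind = data$outcome_kind, classes = data$classes,
         positive_class = data$positive_class),
    class = "labeled_dataset")
}

#' Split a dataset into training, testing and validation parts
#'
#' Uniformly random three-way partition of the rows. Part sizes are
#' floor-allocated from the proportions; remainder rows go to the training
#' part first, then the testing part, so the split is fully determined by the
#' permutation (no second random draw).
#'
#' @param data a [labeled_dataset()].
#' @param proportions positive numeric triple summing to 1 (within 1e-9),
#'   giving the train/test/validation fractions.
#' @param seed optional integer seed; when supplied the partition is
#'   reproducible, otherwise the current RNG stream is used.
#' @param stratify_by optional observed-outcome stratification: `TRUE`
#'   partitions within each outcome class separately (categorical/binary
#'   outcomes only). Unstratified splitting is the default.
#'
#' @return A `data_split` list with elements `train`, `test`, `validation`,
#'   each a [labeled_dataset()] sharing the source schema. The row indices of
#'   the three parts are disjoint and exhaust the source.
#' @export
split_three_way <- function(data, proportions = c(1, 1, 1) / 3, seed = NULL,
                            stratify_by = FALSE) {
  if (length(proportions) != 3L || any(proportions <= 0))
    stop_predinfer("proportions must be three positive numbers",
                   "predinfer_config_error")
  if (abs(sum(proportions) - 1) > 1e-9)
    stop_predinfer("proportions must sum to 1 within 1e-9",
                   "predinfer_config_error")
  n <- n_obs(data)
  if (n < 3L)
    stop_predinfer("need at least 3 rows to split", "predinfer_size_error")
  if (!is.null(seed)) set.seed(seed)

  allocate <- function(idx) {
    m <- length(idx)
    sizes <- floor(m * proportions)
    rem <- m - sum(sizes)
    if (rem >= 1L) sizes[1L] <- sizes[1L] + 1L
    if (rem == 2L) sizes[2L] <- sizes[2L] + 1L
    perm <- idx[sample.int(m)]
    list(train = perm[seq_len(sizes[1L])],
         test = perm[seq_len(sizes[2L]) + sizes[1L]],
         validation = perm[seq_len(sizes[3L]) + sizes[1L] + sizes[2L]])
  }

  if (isTRUE(stratify_by) && !is.null(data$observed) &&
      data$outcome_kind != "continuous") {
    by_class <- split(seq_len(n), as.character(data$observed))
    parts <- lapply(by_class, allocate)
    idx <- list(train = sort(unlist(lapply(parts, `[[`, "train"), use.names = FALSE)),
                test = sort(unlist(lapply(parts, `[[`, "test"), use.names = FALSE)),
                validation = sort(unlist(lapply(parts, `[[`, "validation"),
                                         use.names = FALSE)))
  } else {
    idx <- allocate(seq_len(n))
  }
  if (any(lengths(idx) == 0L))
    stop_predinfer("a split part would be empty", "predinfer_size_error")

  structure(list(train = dataset_subset(data, idx$train),
                 test = dataset_subset(data, idx$test),
                 validation = dataset_subset(data, idx$validation),
                 indices = idx),
            class = "data_split")
}

#' @export
print.data_split <- function(x, ...) {
  cat(sprintf("<data_split> train %d / test %d / validation %d rows\n",
              n_obs(x$train), n_obs(x$test), n_obs(x$validation)))
  invisible(x)
}

guess_delim <- function(path) if (grepl("\\.tsv$", path)) "\t" else ","

#' Read a labeled dataset from a delimited text file
#'
#' Reads a CSV (or TSV, by file extension) with a header row and maps columns
#' to roles. Columns not named by any role become covariates.
#'
#' @param path file path.
#' @param outcome name of the observed-outcome column, or `NULL`.
#' @param predicted name of the predicted-outcome column, or `NULL`.
#' @param probability_columns named character vector mapping class labels to
#'   probability column names (e.g. `c("0" = "pr_0", "1" = "pr_1")`), or `NULL`.
#' @param covariate_columns explicit covariate column names; default is every
#'   column not assigned a role.
#' @inheritParams labeled_dataset
#' @return A [labeled_dataset()].
#' @export
read_dataset <- function(path, outcome = NULL, predicted = NULL,
                         probability_columns = NULL, covariate_columns = NULL,
                         outcome_kind = c("continuous", "binary", "categorical"),
                         classes = NULL, positive_class = NULL) {
  outcome_kind <- match.arg(outcome_kind)
  df <- read.csv(path, sep = guess_delim(path), check.names = FALSE,
                 stringsAsFactors = FALSE)
  role_cols <- c(outcome, predicted, unname(probability_columns))
  missing_cols <- setdiff(role_cols, names(df))
  if (length(missing_cols))
    stop_predinfer(paste("missing role column(s):",
                         paste(missing_cols, collapse = ", ")),
                   "predinfer_schema_error")
  covariate_columns <- covariate_columns %||% setdiff(names(df), role_cols)
  if (length(bad <- setdiff(covariate_columns, names(df))))
    stop_predinfer(paste("missing covariate column(s):",
                         paste(bad, collapse = ", ")),
                   "predinfer_schema_error")

  cov <- df[covariate_columns]
  for (nm in names(cov)) {
    if (is.character(cov[[nm]])) {
      num <- suppressWarnings(as.numeric(cov[[nm]]))
      bad_row <- which(is.na(num) & !is.na(cov[[nm]]))
      # fully non-numeric columns are categorical covariates; mixed ones are errors
      if (length(bad_row) && length(bad_row) < sum(!is.na(cov[[nm]])))
        stop_predinfer(sprintf("non-numeric value in covariate '%s' at row %d",
                               nm, bad_row[1L]),
                       "predinfer_parse_error")
      if (!length(bad_row)) cov[[nm]] <- num
    }
  }

  grab_outcome <- function(nm) {
    v <- df[[nm]]
    if (outcome_kind %in% c("continuous", "binary")) {
      num <- suppressWarnings(as.numeric(v))
      bad_row <- which(is.na(num) & !is.na(v))
      if (length(bad_row))
        stop_predinfer(sprintf("non-numeric value in column '%s' at row %d",
                               nm, bad_row[1L]),
                       "predinfer_parse_error")
      num
    } else as.character(v)
  }

  probs <- NULL
  if (!is.null(probability_columns)) {
    probs <- as.matrix(df[unname(probability_columns)])
    colnames(probs) <- names(probability_columns) %||% unname(probability_columns)
    storage.mode(probs) <- "double"
  }
  labeled_dataset(cov,
                  observed = if (!is.null(outcome)) grab_outcome(outcome),
                  predicted = if (!is.null(predicted)) grab_outcome(predicted),
                  probabilities = probs, outcome_kind = outcome_kind,
                  classes = classes, positive_class = positive_class)
}

#' Write a labeled dataset to CSV
#'
#' Writes covariates plus any outcome components. Numeric values are formatted
#' with 17 significant digits so a write/read round trip reproduces every
#' double exactly. Probability columns are written as `pr_<class>`.
#'
#' @param data a [labeled_dataset()].
#' @param path output file path (CSV).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  fmt <- function(v) if (is.double(v)) sprintf("%.17g", v) else v
  out <- as.data.frame(lapply(data$covariates, fmt), check.names = FALSE,
                       stringsAsFactors = FALSE)
  names(out) <- names(data$covariates)
  if (!is.null(data$observed)) out$y <- fmt(data$observed)
  if (!is.null(data$predicted)) out$yp <- fmt(data$predicted)
  if (!is.null(data$probabilities))
    for (cl in colnames(data$probabilities))
      out[[paste0("pr_", cl)]] <- fmt(data$probabilities[, cl])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize corrected inference results as JSON records
#'
#' @param results a data frame of corrected inference rows (as returned by
#'   [correct_analytical()], [summarize_parametric()], [fit_inference()], or
#'   several of them row-bound together).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  results <- as.data.frame(results)
  keep <- intersect(c("method", "coefficient", "estimate", "se",
                      "statistic", "p_value"), names(results))
  jsonlite::write_json(results[keep], path, dataframe = "rows", digits = NA,
                       auto_unbox = FALSE)
  invisible(path)
}
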