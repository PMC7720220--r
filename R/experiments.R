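#' Root mean-square error
#'
#' @param values,reference equal-length finite numeric vectors; `reference`
#'   holds the per-replicate observed-outcome ("truth") values.
#' @return `sqrt(mean((values - reference)^2))`.
#' @export
rmse <- function(values, reference) {
  if (length(values) != length(reference))
    stop_predinfer("rmse inputs must have equal length", "predinfer_size_error")
  if (length(values) < 1L)
    stop_predinfer("rmse needs at least one pair", "predinfer_size_error")
  if (!all(is.finite(values)) || !all(is.finite(reference)))
    stop_predinfer("rmse inputs must be finite", "predinfer_config_error")
  sqrt(mean((values - reference)^2))
}

scenario_inference_spec <- function(scenario) {
  if (scenario$generator == "binary")
    inference_spec("binomial_logit", ~ I(xc == "C"))
  else inference_spec("gaussian_identity", ~ x1)
}

default_methods <- function(scenario) {
  if (scenario$generator == "binary")
    c("no_correction", "boot_parametric", "boot_nonparametric")
  else c("no_correction", "analytical", "boot_parametric", "boot_nonparametric")
}

replicate_rows <- function(rep_id, beta_true, fits, coef_name) {
  rows <- do.call(rbind, lapply(fits, function(f) f[f$coefficient == coef_name, ]))
  data.frame(rep = rep_id, beta_true = beta_true, excluded = FALSE,
             reason = "", method = rows$method, estimate = rows$estimate,
             se = rows$se, statistic = rows$statistic,
             row.names = NULL, stringsAsFactors = FALSE)
}

excluded_row <- function(rep_id, beta_true, reason) {
  data.frame(rep = rep_id, beta_true = beta_true, excluded = TRUE,
             reason = reason, method = NA_character_, estimate = NA_real_,
             se = NA_real_, statistic = NA_real_,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Run a full replicated simulation experiment
#'
#' The replication harness behind the operating-characteristic studies. For
#' each replicate it draws a fresh three-way split (the focal coefficient
#' cycling through the scenario grid), trains the predictor on the training
#' part, predicts on the testing and validation parts, fits the relationship
#' model on the testing part, and computes on the validation part the
#' observed-outcome ("truth") fit plus every requested correction flavor.
#' Binary replicates with sparse validation cells, and replicates whose
#' fits fail, are recorded as excluded rather than silently dropped.
#'
#' All randomness flows from one stream seeded once with `scenario$seed`, so
#' a rerun with the same scenario reproduces the record table exactly.
#'
#' @param scenario a [simulation_scenario()].
#' @param methods correction methods to compute; default all that apply
#'   (the analytical correction only for linear inference).
#' @return A data frame of per-replicate records: `rep`, `beta_true`,
#'   `excluded`, `reason`, `method`, `estimate`, `se`, `statistic`, with an
#'   `observed_outcome` row per included replicate.
#' @export
run_experiment <- function(scenario, methods = NULL) {
  methods <- methods %||% default_methods(scenario)
  spec <- scenario_inference_spec(scenario)
  binary <- scenario$generator == "binary"
  need_boot <- any(c("boot_parametric", "boot_nonparametric") %in% methods)
  set.seed(scenario$seed)

  records <- vector("list", scenario$n_reps)
  for (r in seq_len(scenario$n_reps)) {
    beta <- scenario$grid[(r - 1L) %% length(scenario$grid) + 1L]
    records[[r]] <- tryCatch({
      split <- if (binary) generate_binary(scenario, betaC = beta)
               else generate_continuous(scenario, beta1 = beta)
      fp <- train_predictor(split$train, scenario$predictor)
      test <- predict(fp, split$test)
      val <- predict(fp, split$validation)
      split$validation <- val
      if (binary && flag_sparse_replicate(split, spec, scenario$sparse_threshold)) {
        excluded_row(r, beta, "sparse validation cells")
      } else {
        fits <- list(fit_inference(val, spec, "observed"))
        if ("no_correction" %in% methods)
          fits <- c(fits, list(fit_inference(val, spec, "predicted")))
        if (binary) {
          rel <- fit_categorical_relationship(test, "logistic_in_probability")
        } else {
          rel <- fit_continuous_relationship(test)
          if ("analytical" %in% methods)
            fits <- c(fits, list(correct_analytical(fit_naive(val, spec), rel)))
        }
        if (need_boot) {
          draws <- bootstrap_draws(val, rel, spec, B = scenario$B)
          if ("boot_parametric" %in% methods)
            fits <- c(fits, list(summarize_parametric(draws)))
          if ("boot_nonparametric" %in% methods)
            fits <- c(fits, list(summarize_nonparametric(draws)))
        }
        X <- build_design(spec, val)
        replicate_rows(r, beta, fits, coef_of_interest(spec, X))
      }
    }, predinfer_error = function(e) excluded_row(r, beta, conditionMessage(e)))
  }
  out <- do.call(rbind, records)
  attr(out, "scenario") <- scenario
  out
}

#' Aggregate an experiment into pooled rmse summaries
#'
#' For every correction method and every quantity (estimate, SE, test
#' statistic), computes the rmse of the per-replicate values against the
#' observed-outcome values of the same replicates, pooled over the whole
#' grid x replicate table. Excluded replicates are omitted.
#'
#' @param records the record table from [run_experiment()].
#' @return A data frame with columns `method`, `quantity`, `rmse`,
#'   `n_included`.
#' @export
summarize_experiment <- function(records) {
  inc <- records[!records$excluded, , drop = FALSE]
  if (!nrow(inc))
    stop_predinfer("all replicates were excluded", "predinfer_size_error")
  truth <- inc[inc$method == "observed_outcome", , drop = FALSE]
  methods <- setdiff(unique(inc$method), "observed_outcome")
  out <- list()
  for (m in methods) {
    mm <- inc[inc$method == m, , drop = FALSE]
    common <- intersect(mm$rep, truth$rep)
    mm <- mm[match(common, mm$rep), ]
    tt <- truth[match(common, truth$rep), ]
    for (q in c("estimate", "se", "statistic")) {
      fin <- is.finite(mm[[q]]) & is.finite(tt[[q]])
      out[[length(out) + 1L]] <- data.frame(
        method = m, quantity = q,
        rmse = rmse(mm[[q]][fin], tt[[q]][fin]),
        n_included = sum(fin), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Two-sided rejection rates at a significance level
#'
#' Helper for type-I-error studies: the fraction of included replicates whose
#' two-sided p-value falls below `alpha`, per method. Linear observed/naive
#' fits use their native t reference; corrected methods use the normal
#' reference their summaries are defined with.
#'
#' @param records the record table from [run_experiment()].
#' @param alpha significance level.
#' @param df residual degrees of freedom for the t reference of the
#'   observed-outcome and no-correction linear fits; `NULL` uses the normal
#'   reference for every method.
#' @return A named numeric vector of rejection rates.
#' @export
rejection_rates <- function(records, alpha = 0.05, df = NULL) {
  inc <- records[!records$excluded & is.finite(records$statistic), , drop = FALSE]
  vapply(split(inc, inc$method), function(d) {
    p <- if (!is.null(df) && d$method[1L] %in% c("observed_outcome", "no_correction"))
      2 * pt(abs(d$statistic), df, lower.tail = FALSE)
    else 2 * pnorm(-abs(d$statistic))
    mean(p < alpha)
  }, numeric(1))
}
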