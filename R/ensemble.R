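#' Out-of-fold component probabilities for stacking
#'
#' For each component block model, refits the component's final design on
#' each cross-validation training fold and records the held-out predicted
#' probability, reusing one fold scheme (derived from `spec$seed`) across all
#' components. With repeats > 1 each sample is held out once per repeat and
#' its entry is the mean of those out-of-fold probabilities. This matrix is
#' what the stacking combiner is trained on, so the combiner never sees
#' resubstitution-optimistic probabilities.
#'
#' @param models Named list of `block_model`s.
#' @param tables Named list of strictly positive `abund_tbl`s, one per
#'   abundance component (names matching the models'). Clinical components
#'   use `meta` instead.
#' @param meta A `cohort_meta` tibble (training samples, shared sample order
#'   across blocks).
#' @param spec A [cv_spec()].
#' @return A tibble with `sample_id`, `diagnosis` and one probability column
#'   per component.
#' @export
out_of_fold_probs <- function(models, tables, meta, spec = cv_spec()) {
  ids <- meta$sample_id
  for (nm in names(tables)) {
    if (!identical(tables[[nm]]$sample_id, ids)) {
      abort(sprintf("sample ids of block '%s' do not match the metadata", nm))
    }
  }
  y <- diagnosis_to_binary(meta$diagnosis)
  folds <- make_folds(y, spec)
  oof <- purrr::imap(models, function(model, nm) {
    if (model$representation == "raw_clinical") {
      design <- clinical_design(meta)
    } else {
      if (!nm %in% names(tables)) abort(sprintf("missing table for block '%s'", nm))
      design <- build_design_from_model(model, tables[[nm]])
    }
    acc <- matrix(NA_real_, length(y), ncol(folds))
    for (r in seq_len(ncol(folds))) {
      for (k in seq_len(spec$folds)) {
        test <- folds[, r] == k
        fit <- fit_logistic(design[!test, , drop = FALSE], y[!test],
                            ridge = model$ridge)
        acc[test, r] <- predict_logistic(fit, design[test, , drop = FALSE])
      }
    }
    rowMeans(acc)
  })
  bind_cols(tibble(sample_id = ids, diagnosis = meta$diagnosis),
            as_tibble(oof))
}

# Design matrix for a component's *final* feature set (fixed balance/features).
build_design_from_model <- function(model, x) {
  m <- abund_matrix(x)
  if (model$representation == "balance") {
    matrix(balance_value_matrix(m, model$balance), ncol = 1,
           dimnames = list(NULL, "balance"))
  } else {
    log10(m[, model$features, drop = FALSE])
  }
}

#' Combine block models into an ensemble
#'
#' The default combiner is stacked logistic regression: a logistic model of
#' diagnosis on the components' out-of-fold probabilities. The alternative
#' `mean_probability` simply averages component probabilities and needs no
#' fitting.
#'
#' @param models Named list of `block_model`s (the ensemble components).
#' @param oof Out-of-fold probability tibble from [out_of_fold_probs()]
#'   (required for `stacked_logistic`).
#' @param combiner `"stacked_logistic"` or `"mean_probability"`.
#' @param ridge Ridge penalty for the stacking fit.
#' @return An object of class `ensemble_model`.
#' @export
fit_ensemble <- function(models, oof = NULL,
                         combiner = c("stacked_logistic", "mean_probability"),
                         ridge = 1e-4) {
  combiner <- match.arg(combiner)
  if (!length(models)) abort("need at least one component model")
  if (is.null(names(models))) abort("models must be a named list")
  weights <- NULL
  intercept <- NULL
  if (combiner == "stacked_logistic") {
    if (is.null(oof)) abort("stacked_logistic needs out-of-fold probabilities")
    miss <- setdiff(names(models), names(oof))
    if (length(miss)) abort(paste0("oof columns missing for: ",
                                   paste(miss, collapse = ", ")))
    X <- as.matrix(oof[names(models)])
    y <- diagnosis_to_binary(oof$diagnosis)
    fit <- fit_logistic(X, y, ridge = ridge)
    intercept <- fit$intercept
    weights <- fit$coefficients
  }
  structure(list(components = models, combiner = combiner,
                 intercept = intercept, weights = weights, ridge = ridge),
            class = "ensemble_model")
}

#' Predict case probabilities from an ensemble
#'
#' Each component (refitted on the full training set inside its
#' `block_model`) predicts a probability, and the combiner merges them.
#'
#' @param object An `ensemble_model`.
#' @param tables Named list of strictly positive `abund_tbl`s covering every
#'   abundance component.
#' @param meta A `cohort_meta` tibble for the clinical component (and the
#'   sample order).
#' @param ... Unused.
#' @return A tibble with `sample_id`, one column per component probability,
#'   and `prob` (the ensemble probability of AD).
#' @export
predict.ensemble_model <- function(object, tables, meta, ...) {
  comp <- purrr::imap(object$components, function(model, nm) {
    if (model$representation == "raw_clinical") {
      predict(model, meta)$prob
    } else {
      if (!nm %in% names(tables)) {
        abort(sprintf("missing table for block '%s'", nm))
      }
      predict(model, tables[[nm]])$prob
    }
  })
  P <- do.call(cbind, comp)
  prob <- if (object$combiner == "mean_probability") {
    rowMeans(P)
  } else {
    plogis(object$intercept + drop(P %*% object$weights))
  }
  bind_cols(tibble(sample_id = meta$sample_id), as_tibble(comp),
            tibble(prob = prob))
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf("<ensemble_model> %d component(s) [%s], combiner %s\n",
              length(x$components),
              paste(names(x$components), collapse = ", "), x$combiner))
  invisible(x)
}

#' Tidy and glance methods for ensembles
#'
#' `tidy()` returns combiner weights (empty for `mean_probability`);
#' `glance()` a one-row summary.
#'
#' @param x An `ensemble_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ensemble_model <- function(x, ...) {
  if (x$combiner == "mean_probability") {
    return(tibble(term = character(), estimate = numeric()))
  }
  tibble(term = c("(Intercept)", names(x$weights)),
         estimate = c(x$intercept, unname(x$weights)))
}

#' @rdname tidy.ensemble_model
#' @export
glance.ensemble_model <- function(x, ...) {
  tibble(combiner = x$combiner, n_components = length(x$components),
         components = paste(names(x$components), collapse = "+"))
}
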