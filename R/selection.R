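#' Wilcoxon rank-sum pre-selection of features
#'
#' Tests each feature for an AD-vs-HC location shift with the two-sided
#' Wilcoxon rank-sum test: exact enumeration when the combined sample size is
#' at most 20 and there are no ties, otherwise the tie-corrected normal
#' approximation (no continuity correction). Features with `p < alpha` are
#' returned ordered by p-value.
#'
#' @param x An `abund_tbl`.
#' @param diagnosis `"AD"`/`"HC"` labels aligned with the table rows.
#' @param alpha Unadjusted significance threshold (default 0.05).
#' @return A tibble with columns `feature_id`, `p_value`, `selected`, ordered
#'   by p-value.
#' @export
wilcoxon_preselect <- function(x, diagnosis, alpha = 0.05) {
  m <- abund_matrix(x)
  if (length(diagnosis) != nrow(m)) abort("diagnosis must align with table rows")
  g1 <- diagnosis == "AD"
  if (!any(g1) || all(g1)) abort("need samples from both groups")
  p <- vapply(seq_len(ncol(m)), function(j) {
    wilcoxon_p(m[g1, j], m[!g1, j])
  }, numeric(1))
  out <- tibble(feature_id = colnames(m), p_value = p) |>
    arrange(.data$p_value, .data$feature_id) |>
    mutate(selected = .data$p_value < alpha)
  out
}

wilcoxon_p <- function(a, b) {
  n <- length(a) + length(b)
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- n <= 20 && !ties
  p <- suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = FALSE)$p.value
  )
  # zero rank variance (every value identical) carries no evidence
  if (is.na(p)) 1 else p
}

#' Repeated stratified cross-validation specification
#'
#' @param folds Number of folds (default 5).
#' @param repeats Number of repeats (default 30).
#' @param seed Integer seed from which all fold assignments derive.
#' @return A list of class `cv_spec`.
#' @export
cv_spec <- function(folds = 5, repeats = 30, seed = 1) {
  if (folds < 2) abort("folds must be at least 2")
  if (repeats < 1) abort("repeats must be at least 1")
  structure(list(folds = folds, repeats = repeats, seed = seed),
            class = "cv_spec")
}

# Stratified fold assignments: a repeats-column matrix of fold indices,
# fully determined by spec$seed.
make_folds <- function(y, spec) {
  n <- length(y)
  cls <- split(seq_len(n), y)
  small <- min(lengths(cls))
  if (small < spec$folds) {
    abort(sprintf("smallest class has %d samples; cannot stratify into %d folds",
                  small, spec$folds))
  }
  with_seed(spec$seed, {
    sapply(seq_len(spec$repeats), function(r) {
      fold <- integer(n)
      for (idx in cls) {
        fold[sample(idx)] <- rep_len(seq_len(spec$folds), length(idx))
      }
      fold
    })
  })
}

# Cross-validated AUROC for a fixed design matrix. Each of folds x repeats
# held-out folds is scored by a logistic fit on the remaining samples.
cv_auroc_design <- function(design, y, spec, ridge = 1e-4, folds = NULL) {
  design <- as.matrix(design)
  if (is.null(folds)) folds <- make_folds(y, spec)
  aucs <- numeric(0)
  for (r in seq_len(ncol(folds))) {
    for (k in seq_len(spec$folds)) {
      test <- folds[, r] == k
      fit <- fit_logistic(design[!test, , drop = FALSE], y[!test], ridge = ridge)
      pr <- predict_logistic(fit, design[test, , drop = FALSE])
      aucs <- c(aucs, auroc(pr, y[test]))
    }
  }
  list(mean = mean(aucs), sd = sd(aucs), fold_aurocs = aucs)
}

#' Cross-validated AUROC of a feature set
#'
#' Scores a candidate feature set by repeated stratified cross-validation:
#' the set is represented either as a single two-group balance (numerator =
#' features higher in AD, denominator = features higher in HC, signs taken
#' from the training-set difference of log10 medians) or as log-abundance
#' columns, a logistic model is fitted on each training fold, and the
#' held-out fold's AUROC is recorded. With the default 5 folds x 30 repeats
#' this yields 150 fold-level AUROCs.
#'
#' @param x A strictly positive `abund_tbl` (HPM after [replace_zeros()]).
#' @param diagnosis `"AD"`/`"HC"` labels aligned with rows.
#' @param features Character vector of feature ids to use.
#' @param spec A [cv_spec()].
#' @param representation `"balance"` or `"log_features"`.
#' @param ridge Ridge penalty for the per-fold logistic fits.
#' @return A list with `mean`, `sd` and the 150 `fold_aurocs`.
#' @export
cv_auroc <- function(x, diagnosis, features, spec = cv_spec(),
                     representation = c("balance", "log_features"),
                     ridge = 1e-4) {
  representation <- match.arg(representation)
  y <- diagnosis_to_binary(diagnosis)
  design <- build_design(x, diagnosis, features, representation)
  cv_auroc_design(design, y, spec, ridge = ridge)
}

# Design matrix for a feature set under a representation. For "balance" the
# single column is the two-group balance with signs from the full supplied
# data (the training set in pipeline use); a side with no features falls back
# to the complement of the selected set, keeping a proper contrast.
build_design <- function(x, diagnosis, features, representation) {
  make_design_factory(x, diagnosis, representation)(features)
}

# Precomputes the log matrix and median-difference signs once so that
# backward elimination can score hundreds of candidate sets cheaply.
make_design_factory <- function(x, diagnosis, representation) {
  m <- abund_matrix(x)
  lm <- log(m)
  all_feats <- colnames(m)
  sign_pos <- NULL
  if (representation == "balance") {
    eff <- diff_log_medians(x, diagnosis)
    sign_pos <- setNames(eff$effect > 0, eff$feature_id)
  }
  function(features) {
    if (representation == "log_features") {
      return(lm[, features, drop = FALSE] / log(10))
    }
    num <- features[sign_pos[features]]
    den <- setdiff(features, num)
    if (!length(num)) num <- setdiff(all_feats, features)
    if (!length(den)) den <- setdiff(all_feats, features)
    if (!length(num) || !length(den)) {
      abort("cannot form a balance: no features available for one side")
    }
    r <- length(num); s <- length(den)
    v <- sqrt(r * s / (r + s)) *
      (rowMeans(lm[, num, drop = FALSE]) - rowMeans(lm[, den, drop = FALSE]))
    matrix(v, ncol = 1, dimnames = list(NULL, "balance"))
  }
}

#' Two-group balance for a selected feature set
#'
#' Splits `features` into those with higher median in AD (numerator) and
#' those with higher median in HC (denominator), by the sign of the
#' difference of log10 medians, and returns the corresponding [balance()].
#' If every selected feature is associated with the same group, the other
#' side of the contrast falls back to all remaining features of the table.
#'
#' @inheritParams cv_auroc
#' @return A [balance()].
#' @export
group_balance <- function(x, diagnosis, features) {
  eff <- diff_log_medians(x, diagnosis)
  eff <- eff[match(features, eff$feature_id), ]
  num <- eff$feature_id[eff$effect > 0]
  den <- eff$feature_id[eff$effect <= 0]
  if (!length(num)) num <- setdiff(abund_features(x), features)
  if (!length(den)) den <- setdiff(abund_features(x), features)
  if (!length(num) || !length(den)) {
    abort("cannot form a balance: no features available for one side")
  }
  balance(num, den)
}

#' Backward feature shrinkage under repeated cross-validation
#'
#' Starting from the pre-selected features, repeatedly removes the feature
#' whose removal maximises the mean cross-validated AUROC, recording the
#' trajectory (feature count, mean CV AUROC, sd) down to a single feature.
#' Removal ties are broken towards the feature with the larger pre-selection
#' p-value, then lexicographically. The chosen model is, under the default
#' one-standard-deviation rule, the smallest feature set whose mean CV AUROC
#' is within one sd of the trajectory maximum (`choose = "max"` picks the
#' plain maximum, larger sets winning ties only if strictly better).
#'
#' @param x A strictly positive `abund_tbl` (training samples).
#' @param diagnosis `"AD"`/`"HC"` labels aligned with rows.
#' @param preselected Tibble from [wilcoxon_preselect()] (or a character
#'   vector of feature ids).
#' @param spec A [cv_spec()].
#' @param representation `"balance"` or `"log_features"`.
#' @param choose Model-choice rule: `"one_sd"` (default) or `"max"`.
#' @param ridge Ridge penalty for logistic fits.
#' @param max_features Cap on the number of features entering elimination
#'   (taken in pre-selection p-value order).
#' @return A `block_model`.
#' @export
shrink_features <- function(x, diagnosis, preselected, spec = cv_spec(),
                            representation = c("balance", "log_features"),
                            choose = c("one_sd", "max"), ridge = 1e-4,
                            max_features = 25) {
  representation <- match.arg(representation)
  choose <- match.arg(choose)
  if (is.character(preselected)) {
    preselected <- tibble(feature_id = preselected,
                          p_value = rep(NA_real_, length(preselected)))
  }
  feats <- head(preselected$feature_id, max_features)
  if (!length(feats)) abort("no pre-selected features to shrink")
  pvals <- setNames(preselected$p_value[match(feats, preselected$feature_id)], feats)
  y <- diagnosis_to_binary(diagnosis)
  folds <- make_folds(y, spec)
  m_design <- make_design_factory(x, diagnosis, representation)
  score_set <- function(set) {
    cv_auroc_design(m_design(set), y, spec, ridge = ridge, folds = folds)
  }

  current <- feats
  sc <- score_set(current)
  traj <- list(tibble(n_features = length(current), cv_auroc_mean = sc$mean,
                      cv_auroc_sd = sc$sd, features = list(current)))
  while (length(current) > 1L) {
    cand <- purrr::map(current, ~ score_set(setdiff(current, .x)))
    means <- purrr::map_dbl(cand, "mean")
    best <- max(means)
    tied <- which(means >= best - 1e-12)
    if (length(tied) > 1L) {
      tp <- pvals[current[tied]]
      tp[is.na(tp)] <- -Inf
      tied <- tied[order(-tp, current[tied])]
    }
    drop_idx <- tied[1]
    current <- setdiff(current, current[drop_idx])
    sc <- cand[[drop_idx]]
    traj <- c(traj, list(tibble(n_features = length(current),
                                cv_auroc_mean = sc$mean,
                                cv_auroc_sd = sc$sd,
                                features = list(current))))
  }
  trajectory <- bind_rows(traj)
  chosen_row <- choose_model(trajectory, choose)
  chosen_feats <- trajectory$features[[chosen_row]]
  new_block_model(x, diagnosis, chosen_feats, representation, ridge,
                  trajectory = trajectory, chosen_row = chosen_row,
                  preselection = preselected, spec = spec)
}

choose_model <- function(trajectory, choose) {
  i_max <- which.max(trajectory$cv_auroc_mean)
  if (choose == "max") return(i_max)
  thr <- trajectory$cv_auroc_mean[i_max] - trajectory$cv_auroc_sd[i_max]
  ok <- which(trajectory$cv_auroc_mean >= thr)
  ok[which.min(trajectory$n_features[ok])]
}

# Fit the final logistic model for a chosen feature set and wrap everything
# into a block_model.
new_block_model <- function(x, diagnosis, features, representation, ridge,
                            trajectory, chosen_row, preselection = NULL,
                            spec = NULL) {
  y <- diagnosis_to_binary(diagnosis)
  design <- build_design(x, diagnosis, features, representation)
  fit <- fit_logistic(design, y, ridge = ridge)
  bal <- if (representation == "balance") group_balance(x, diagnosis, features)
  structure(list(block = abund_block(x),
                 representation = representation,
                 features = features,
                 balance = bal,
                 intercept = fit$intercept,
                 coefficients = fit$coefficients,
                 ridge = ridge,
                 cv_trajectory = trajectory,
                 chosen_row = chosen_row,
                 cv_auroc_mean = trajectory$cv_auroc_mean[chosen_row],
                 cv_auroc_sd = trajectory$cv_auroc_sd[chosen_row],
                 preselection = preselection,
                 spec = spec),
            class = "block_model")
}

#' Fit a block model: pre-selection plus shrinkage
#'
#' Convenience wrapper running [wilcoxon_preselect()] on the training table
#' and [shrink_features()] on the surviving features.
#'
#' @inheritParams shrink_features
#' @param alpha Pre-selection significance threshold.
#' @return A `block_model`.
#' @export
fit_block_model <- function(x, diagnosis, spec = cv_spec(), alpha = 0.05,
                            representation = c("balance", "log_features"),
                            choose = c("one_sd", "max"), ridge = 1e-4,
                            max_features = 25) {
  pre <- wilcoxon_preselect(x, diagnosis, alpha = alpha)
  sel <- pre[pre$selected, ]
  if (!nrow(sel)) {
    inform(sprintf("block %s: no feature passed pre-selection at alpha = %g; using the smallest p-value",
                   abund_block(x), alpha))
    sel <- pre[1, ]
  }
  shrink_features(x, diagnosis, sel, spec = spec,
                  representation = match.arg(representation),
                  choose = match.arg(choose), ridge = ridge,
                  max_features = max_features)
}

#' Fit the clinical block model
#'
#' Logistic regression of diagnosis on the four clinical covariates used by
#' the study: age, gender (indicator for male), BMI and ApoE epsilon-4 allele
#' count. No feature shrinkage is applied. Samples with missing ApoE are
#' dropped with a message.
#'
#' @param meta A `cohort_meta` tibble.
#' @param spec A [cv_spec()] used to report the model's CV AUROC.
#' @param ridge Ridge penalty.
#' @return A `block_model` with representation `"raw_clinical"`.
#' @export
build_clinical_model <- function(meta, spec = cv_spec(), ridge = 1e-4) {
  need <- c("age", "gender", "bmi", "apoe_e4_count")
  miss <- setdiff(need, names(meta))
  if (length(miss)) abort(paste0("clinical covariates missing: ",
                                 paste(miss, collapse = ", ")))
  keep <- !is.na(meta$apoe_e4_count)
  if (!any(keep)) abort("ApoE allele count missing for every sample")
  if (any(!keep)) {
    inform(sprintf("dropping %d sample(s) with missing ApoE", sum(!keep)))
  }
  meta <- meta[keep, ]
  design <- clinical_design(meta)
  y <- diagnosis_to_binary(meta$diagnosis)
  fit <- fit_logistic(design, y, ridge = ridge)
  sc <- cv_auroc_design(design, y, spec, ridge = ridge)
  trajectory <- tibble(n_features = ncol(design), cv_auroc_mean = sc$mean,
                       cv_auroc_sd = sc$sd, features = list(colnames(design)))
  structure(list(block = "clinical",
                 representation = "raw_clinical",
                 features = colnames(design),
                 balance = NULL,
                 intercept = fit$intercept,
                 coefficients = fit$coefficients,
                 ridge = ridge,
                 cv_trajectory = trajectory,
                 chosen_row = 1L,
                 cv_auroc_mean = sc$mean,
                 cv_auroc_sd = sc$sd,
                 preselection = NULL,
                 spec = spec),
            class = "block_model")
}

clinical_design <- function(meta) {
  cbind(age = meta$age,
        gender_m = as.numeric(meta$gender == "m"),
        bmi = meta$bmi,
        apoe_e4_count = as.numeric(meta$apoe_e4_count))
}

#' Predict case probabilities from a block model
#'
#' @param object A `block_model`.
#' @param newdata For abundance blocks, a strictly positive `abund_tbl`
#'   containing the model's features; for the clinical block, a `cohort_meta`
#'   tibble.
#' @param ... Unused.
#' @return A tibble with `sample_id` and `prob` (probability of AD).
#' @export
predict.block_model <- function(object, newdata, ...) {
  if (object$representation == "raw_clinical") {
    X <- clinical_design(newdata)
    ids <- newdata$sample_id
  } else if (object$representation == "balance") {
    m <- abund_matrix(newdata)
    X <- matrix(balance_value_matrix(m, object$balance), ncol = 1)
    ids <- newdata$sample_id
  } else {
    m <- abund_matrix(newdata)
    X <- log10(m[, object$features, drop = FALSE])
    ids <- newdata$sample_id
  }
  prob <- plogis(object$intercept + drop(X %*% object$coefficients))
  tibble(sample_id = ids, prob = prob)
}

#' @export
print.block_model <- function(x, ...) {
  cat(sprintf("<block_model> block %s (%s): %d feature(s), CV AUROC %.3f (sd %.3f)\n",
              x$block, x$representation, length(x$features),
              x$cv_auroc_mean, x$cv_auroc_sd))
  invisible(x)
}

#' Tidy and glance methods for block models
#'
#' `tidy()` returns the fitted coefficients (one row per model term);
#' `glance()` a one-row model summary.
#'
#' @param x A `block_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.block_model <- function(x, ...) {
  tibble(term = c("(Intercept)", names(x$coefficients)),
         estimate = c(x$intercept, unname(x$coefficients)))
}

#' @rdname tidy.block_model
#' @export
glance.block_model <- function(x, ...) {
  tibble(block = x$block, representation = x$representation,
         n_features = length(x$features),
         cv_auroc_mean = x$cv_auroc_mean, cv_auroc_sd = x$cv_auroc_sd)
}
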