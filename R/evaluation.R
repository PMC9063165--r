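#' Stratified train/validation split
#'
#' Splits samples into a training and a validation set, drawing within each
#' diagnosis class so both classes appear in both parts. The per-class
#' training count is `round-half-up(class n * train_fraction)` unless
#' `counts` overrides it (the published cohort's realized 59/73 training
#' split is such an override). Deterministic under `seed`.
#'
#' @param meta A `cohort_meta` tibble.
#' @param train_fraction Fraction of each class assigned to training
#'   (default 0.75, the study's 3:1 ratio).
#' @param seed Integer seed.
#' @param counts Optional named vector of per-class training counts, e.g.
#'   `c(AD = 59, HC = 73)`, overriding the fraction.
#' @return A list of class `data_split` with `train_ids`, `validation_ids`.
#' @export
stratified_split <- function(meta, train_fraction = 0.75, seed = 1,
                             counts = NULL) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("train_fraction must lie strictly between 0 and 1")
  }
  cls <- split(meta$sample_id, meta$diagnosis)
  if (any(lengths(cls) < 2)) abort("each class needs at least 2 samples")
  with_seed(seed, {
    train <- unlist(lapply(names(cls), function(g) {
      ids <- cls[[g]]
      k <- if (!is.null(counts) && g %in% names(counts)) counts[[g]]
           else floor(length(ids) * train_fraction + 0.5)
      k <- min(max(k, 1L), length(ids) - 1L)
      sample(ids, k)
    }), use.names = FALSE)
  })
  structure(list(train_ids = sort(train),
                 validation_ids = sort(setdiff(meta$sample_id, train)),
                 train_fraction = train_fraction, seed = seed),
            class = "data_split")
}

#' @export
print.data_split <- function(x, ...) {
  cat(sprintf("<data_split> %d training / %d validation samples (seed %d)\n",
              length(x$train_ids), length(x$validation_ids), x$seed))
  invisible(x)
}

#' Area under the ROC curve (Mann-Whitney estimator)
#'
#' The probability that a randomly chosen case outscores a randomly chosen
#' control, with ties counted one half; equals the trapezoidal area under the
#' empirical ROC curve.
#'
#' @param scores Numeric scores (higher = more case-like).
#' @param labels Binary labels (0/1, logical, or `"AD"`/`"HC"` with AD = 1).
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  if (is.character(labels)) labels <- diagnosis_to_binary(labels)
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) abort("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC curve
#'
#' Sensitivity/specificity at every distinct score threshold (classify as
#' case when `score >= threshold`), with the midpoint tie convention implied
#' by scoring at the observed score values.
#'
#' @inheritParams auroc
#' @return A tibble with `threshold`, `sensitivity`, `specificity`, starting
#'   at (sens 1, spec 0) and ending at (sens 0, spec 1).
#' @export
roc_curve <- function(scores, labels) {
  if (is.character(labels)) labels <- diagnosis_to_binary(labels)
  labels <- as.integer(as.logical(labels))
  thr <- c(-Inf, sort(unique(scores)), Inf)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  tibble(
    threshold = thr,
    sensitivity = vapply(thr, function(t) sum(scores >= t & labels == 1L) / n1,
                         numeric(1)),
    specificity = vapply(thr, function(t) sum(scores < t & labels == 0L) / n0,
                         numeric(1))
  )
}

#' Confidence interval for the AUROC
#'
#' DeLong's asymptotic interval by default; a stratified bootstrap interval
#' as the alternative. If the DeLong variance degenerates (e.g. perfect
#' separation), the bootstrap is used instead with a message.
#'
#' @inheritParams auroc
#' @param method `"delong"` or `"bootstrap"`.
#' @param level Confidence level (default 0.95).
#' @param boot_n Bootstrap replicates (default 2000).
#' @param seed Seed for the bootstrap.
#' @return Numeric vector `c(low, high)`, truncated to `[0, 1]`.
#' @export
auroc_ci <- function(scores, labels, method = c("delong", "bootstrap"),
                     level = 0.95, boot_n = 2000, seed = 1) {
  method <- match.arg(method)
  if (is.character(labels)) labels <- diagnosis_to_binary(labels)
  labels <- as.integer(as.logical(labels))
  roc <- pROC::roc(response = labels, predictor = scores,
                   levels = c(0, 1), direction = "<", quiet = TRUE)
  ci <- if (method == "delong") {
    v <- suppressWarnings(pROC::var(roc, method = "delong"))
    if (!is.finite(v) || v <= 0) {
      inform("DeLong variance degenerate; falling back to bootstrap")
      with_seed(seed, suppressWarnings(
        pROC::ci.auc(roc, conf.level = level, method = "bootstrap",
                     boot.n = boot_n)))
    } else {
      pROC::ci.auc(roc, conf.level = level, method = "delong")
    }
  } else {
    with_seed(seed, suppressWarnings(
      pROC::ci.auc(roc, conf.level = level, method = "bootstrap",
                   boot.n = boot_n)))
  }
  c(low = max(0, ci[1]), high = min(1, ci[3]))
}

#' Full ROC evaluation of a score vector
#'
#' Bundles the ROC curve, the Mann-Whitney AUROC, its confidence interval and
#' the Youden-optimal cutpoint into one result object.
#'
#' @inheritParams auroc_ci
#' @return An object of class `roc_result`.
#' @export
evaluate_scores <- function(scores, labels, method = c("delong", "bootstrap"),
                            level = 0.95, boot_n = 2000, seed = 1) {
  method <- match.arg(method)
  if (is.character(labels)) labels <- diagnosis_to_binary(labels)
  a <- auroc(scores, labels)
  ci <- auroc_ci(scores, labels, method = method, level = level,
                 boot_n = boot_n, seed = seed)
  res <- structure(list(curve = roc_curve(scores, labels), auroc = a,
                        ci_low = unname(ci[1]), ci_high = unname(ci[2]),
                        ci_method = method, level = level,
                        n_case = sum(labels == 1), n_control = sum(labels == 0)),
                   class = "roc_result")
  res$cutpoint <- optimal_cutpoint(res)
  res
}

#' Optimal classification cutpoint on a ROC curve
#'
#' Maximises the Youden index (sensitivity + specificity - 1); ties go to the
#' lowest threshold.
#'
#' @param roc A `roc_result` (or the curve tibble from [roc_curve()]).
#' @param criterion Only `"youden"` is implemented.
#' @return A one-row tibble with `threshold`, `sensitivity`, `specificity`,
#'   `youden`.
#' @export
optimal_cutpoint <- function(roc, criterion = c("youden")) {
  criterion <- match.arg(criterion)
  curve <- if (inherits(roc, "roc_result")) roc$curve else roc
  finite <- is.finite(curve$threshold)
  curve <- curve[finite | curve$threshold == -Inf, ]
  j <- curve$sensitivity + curve$specificity - 1
  best <- which(j >= max(j) - 1e-12)
  pick <- best[which.min(curve$threshold[best])]
  tibble(threshold = curve$threshold[pick],
         sensitivity = curve$sensitivity[pick],
         specificity = curve$specificity[pick],
         youden = j[pick])
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUROC %.3f (%d%% CI %.3f-%.3f, %s), %d cases / %d controls\n",
              x$auroc, round(100 * x$level), x$ci_low, x$ci_high, x$ci_method,
              x$n_case, x$n_control))
  invisible(x)
}

#' Tidy and glance methods for ROC results
#'
#' `tidy()` returns the ROC curve points; `glance()` the AUROC with its
#' confidence interval and cutpoint.
#'
#' @param x A `roc_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.roc_result <- function(x, ...) x$curve

#' @rdname tidy.roc_result
#' @export
glance.roc_result <- function(x, ...) {
  bind_cols(tibble(auroc = x$auroc, ci_low = x$ci_low, ci_high = x$ci_high,
                   ci_method = x$ci_method),
            x$cutpoint)
}
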