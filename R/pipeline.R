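# Row-subset an abundance table by sample id, preserving attributes.
subset_samples <- function(x, ids) {
  idx <- match(ids, x$sample_id)
  if (anyNA(idx)) abort("some requested sample ids are not in the table")
  abundance_table(as_tibble(x)[idx, ], unit = abund_unit(x),
                  block = abund_block(x), annotations = abund_annotations(x))
}

#' Run the full discrimination pipeline
#'
#' End-to-end analysis on a cohort bundle (as produced by
#' [simulate_study_cohort()], or assembled from read-in tables): the cohort
#' is split into training and validation sets stratified by diagnosis; each
#' abundance block is HPM-normalised and zero-replaced; per block, features
#' are pre-selected by Wilcoxon test on the training set and shrunk by
#' backward elimination under repeated stratified cross-validation into a
#' balance-logistic block model; a clinical logistic model (age, gender, BMI,
#' ApoE) is added; the blocks are stacked into an ensemble on out-of-fold
#' probabilities; and every model is evaluated by ROC analysis on both the
#' training set (resubstitution, labelled as such) and the held-out
#' validation set.
#'
#' @param bundle A list with `meta`, `tables` (named list of raw-hit or HPM
#'   `abund_tbl`s) and optionally `read_counts` (named list of per-sample
#'   read-count vectors).
#' @param seed Integer seed driving the split; the CV seed defaults to
#'   `seed + 1`.
#' @param train_fraction Training fraction per class (default 0.75).
#' @param cv A [cv_spec()].
#' @param alpha Wilcoxon pre-selection threshold.
#' @param max_features Cap on features entering backward elimination.
#' @param representation Block design: `"balance"` or `"log_features"`.
#' @param combiner Ensemble combiner, `"stacked_logistic"` or
#'   `"mean_probability"`.
#' @param ridge Ridge penalty for all logistic fits.
#' @param counts Optional per-class training-count override for the split.
#' @return An object of class `ad_pipeline`: `split`, `models` (named list of
#'   `block_model`s incl. `clinical`), `ensemble`, `oof`, `roc` (nested list
#'   of `roc_result`s by model and split), and `evaluation` (tidy tibble of
#'   AUROCs).
#' @export
run_discrimination_pipeline <- function(bundle, seed = 1,
                                        train_fraction = 0.75,
                                        cv = cv_spec(5, 30, seed + 1),
                                        alpha = 0.05, max_features = 25,
                                        representation = c("balance", "log_features"),
                                        combiner = c("stacked_logistic", "mean_probability"),
                                        ridge = 1e-4, counts = NULL) {
  representation <- match.arg(representation)
  combiner <- match.arg(combiner)
  meta <- bundle$meta
  split <- stratified_split(meta, train_fraction, seed = seed, counts = counts)
  meta_train <- meta[match(split$train_ids, meta$sample_id), ]
  meta_valid <- meta[match(split$validation_ids, meta$sample_id), ]

  prep <- purrr::imap(bundle$tables, function(tab, nm) {
    rc <- bundle$read_counts[[nm]]
    pos <- replace_zeros(to_hpm(tab, read_counts = rc))
    list(train = subset_samples(pos, split$train_ids),
         valid = subset_samples(pos, split$validation_ids))
  })

  models <- purrr::imap(prep, function(pr, nm) {
    fit_block_model(pr$train, meta_train$diagnosis, spec = cv, alpha = alpha,
                    representation = representation, ridge = ridge,
                    max_features = max_features)
  })
  models$clinical <- build_clinical_model(meta_train, spec = cv, ridge = ridge)

  train_tables <- purrr::map(prep, "train")
  valid_tables <- purrr::map(prep, "valid")
  oof <- out_of_fold_probs(models, train_tables, meta_train, spec = cv)
  ens <- fit_ensemble(models, oof, combiner = combiner, ridge = ridge)

  score_one <- function(model, nm, tables, m) {
    if (model$representation == "raw_clinical") predict(model, m)$prob
    else predict(model, tables[[nm]])$prob
  }
  roc <- purrr::imap(models, function(model, nm) {
    list(training = evaluate_scores(score_one(model, nm, train_tables, meta_train),
                                    meta_train$diagnosis),
         validation = evaluate_scores(score_one(model, nm, valid_tables, meta_valid),
                                      meta_valid$diagnosis))
  })
  roc$ensemble <- list(
    training = evaluate_scores(predict(ens, train_tables, meta_train)$prob,
                               meta_train$diagnosis),
    validation = evaluate_scores(predict(ens, valid_tables, meta_valid)$prob,
                                 meta_valid$diagnosis)
  )

  evaluation <- purrr::imap(roc, function(rr, nm) {
    purrr::imap(rr, function(r, sp) {
      tibble(model = nm, split = sp, auroc = r$auroc,
             ci_low = r$ci_low, ci_high = r$ci_high,
             n_features = if (nm == "ensemble") NA_integer_
                          else length(models[[nm]]$features),
             cv_auroc_mean = if (nm == "ensemble") NA_real_
                             else models[[nm]]$cv_auroc_mean)
    }) |> bind_rows()
  }) |> bind_rows()

  structure(list(split = split, models = models, ensemble = ens, oof = oof,
                 roc = roc, evaluation = evaluation, cv = cv, seed = seed),
            class = "ad_pipeline")
}

#' @export
print.ad_pipeline <- function(x, ...) {
  cat(sprintf("<ad_pipeline> %d training / %d validation samples\n",
              length(x$split$train_ids), length(x$split$validation_ids)))
  print(x$evaluation, n = Inf)
  invisible(x)
}

#' Tidy method for a fitted pipeline
#'
#' Returns the evaluation table: one row per model and split with the AUROC
#' and its confidence interval.
#'
#' @param x An `ad_pipeline`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ad_pipeline <- function(x, ...) x$evaluation
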