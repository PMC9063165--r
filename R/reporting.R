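#' Construct an effect table
#'
#' An effect table summarises per-feature group differences as the difference
#' of logarithmised medians, `log(median in AD) - log(median in HC)`:
#' negative values mean higher levels in healthy controls, positive values
#' higher levels in AD patients.
#'
#' @param x A data frame with columns `feature_id`, `effect` and optionally
#'   `annotation` (phylum or function label).
#' @param block Feature block label.
#' @param log_base Base of the logarithm used (default 10).
#' @return A tibble of class `effect_tbl`.
#' @export
effect_table <- function(x, block = "genera", log_base = 10) {
  x <- as_tibble(x)
  if (!all(c("feature_id", "effect") %in% names(x))) {
    abort("effect table needs `feature_id` and `effect` columns")
  }
  if (!"annotation" %in% names(x)) x$annotation <- NA_character_
  if (any(!is.finite(x$effect))) abort("effects must be finite")
  x <- x[c("feature_id", "annotation", "effect")]
  structure(x, class = c("effect_tbl", class(tibble())),
            block = block, log_base = log_base)
}

#' Difference of logarithmised medians between groups
#'
#' For each feature, `log10(median over AD samples) - log10(median over HC
#' samples)` of the abundance values (HPM recommended; run [replace_zeros()]
#' first so group medians are positive). Negative effects mean higher levels
#' in healthy controls.
#'
#' @param x An `abund_tbl`.
#' @param diagnosis `"AD"`/`"HC"` labels aligned with the table rows.
#' @param log_base Logarithm base (default 10).
#' @return An `effect_tbl` carrying any feature annotations of `x`.
#' @export
diff_log_medians <- function(x, diagnosis, log_base = 10) {
  m <- abund_matrix(x)
  if (length(diagnosis) != nrow(m)) abort("diagnosis must align with table rows")
  ad <- diagnosis == "AD"
  if (!any(ad) || all(ad)) abort("need samples from both groups")
  med_ad <- apply(m[ad, , drop = FALSE], 2, median)
  med_hc <- apply(m[!ad, , drop = FALSE], 2, median)
  if (any(med_ad <= 0) || any(med_hc <= 0)) {
    abort("non-positive group medians; run replace_zeros() first")
  }
  eff <- (log(med_ad) - log(med_hc)) / log(log_base)
  ann <- abund_annotations(x)
  out <- tibble(feature_id = colnames(m), effect = unname(eff))
  if (!is.null(ann)) {
    acol <- intersect(c("phylum", "function_label"), names(ann))[1]
    if (!is.na(acol)) {
      out$annotation <- ann[[acol]][match(out$feature_id, ann$feature_id)]
    }
  }
  effect_table(out, block = abund_block(x), log_base = log_base)
}

#' Phylum attribution of model features
#'
#' Counts how the features of a (genus-block) effect table distribute over
#' phyla, overall and within each effect sign, with the share of each sign
#' group: `percentage = 100 * (phylum-and-sign count) / (sign count)`.
#' Features without an annotation are counted under `"unannotated"`.
#'
#' @param effects An `effect_tbl`.
#' @return A tibble with one row per phylum: `phylum`, `n_total`,
#'   `n_ad_elevated`, `n_hc_elevated`, `pct_of_ad_elevated`,
#'   `pct_of_hc_elevated`.
#' @export
phylum_breakdown <- function(effects) {
  x <- as_tibble(effects)
  if (!nrow(x)) {
    return(tibble(phylum = character(), n_total = integer(),
                  n_ad_elevated = integer(), n_hc_elevated = integer(),
                  pct_of_ad_elevated = numeric(), pct_of_hc_elevated = numeric()))
  }
  x$phylum <- ifelse(is.na(x$annotation), "unannotated", x$annotation)
  n_ad <- sum(x$effect > 0); n_hc <- sum(x$effect < 0)
  x |>
    group_by(.data$phylum) |>
    summarise(n_total = dplyr::n(),
              n_ad_elevated = sum(.data$effect > 0),
              n_hc_elevated = sum(.data$effect < 0),
              .groups = "drop") |>
    mutate(pct_of_ad_elevated = if (n_ad > 0) 100 * .data$n_ad_elevated / n_ad else 0,
           pct_of_hc_elevated = if (n_hc > 0) 100 * .data$n_hc_elevated / n_hc else 0) |>
    arrange(desc(.data$n_total), .data$phylum)
}

#' Most AD- and HC-elevated features
#'
#' Returns the features with the largest positive (most elevated in AD) and
#' most negative (most elevated in healthy controls) effect; ties break to
#' the lexicographically smallest feature id.
#'
#' @param effects A non-empty `effect_tbl`.
#' @return A two-row tibble with `direction` (`"ad_elevated"`,
#'   `"hc_elevated"`), `feature_id`, `annotation`, `effect`.
#' @export
extreme_features <- function(effects) {
  x <- as_tibble(effects)
  if (!nrow(x)) abort("effect table is empty")
  x <- x[order(x$feature_id), ]
  i_max <- which(x$effect >= max(x$effect) - 0)[1]
  i_min <- which(x$effect <= min(x$effect) + 0)[1]
  bind_rows(
    tibble(direction = "ad_elevated", feature_id = x$feature_id[i_max],
           annotation = x$annotation[i_max], effect = x$effect[i_max]),
    tibble(direction = "hc_elevated", feature_id = x$feature_id[i_min],
           annotation = x$annotation[i_min], effect = x$effect[i_min])
  )
}

#' Correlate model features with clinical and biomarker variables
#'
#' Spearman (default) or Pearson correlation of each feature's abundance with
#' age, MMSE, ApoE epsilon-4 allele count and the CSF markers. CSF columns
#' are computed over AD samples only (controls have no CSF in this design);
#' the remaining variables use all samples with pairwise-complete
#' observations. Entries with fewer than 3 complete pairs are `NA`.
#'
#' @param x An `abund_tbl` (HPM recommended).
#' @param meta A `cohort_meta` tibble covering the table's samples.
#' @param features Feature ids to correlate (default: all).
#' @param method `"spearman"` or `"pearson"`.
#' @return A tibble with `feature_id` and one column per clinical variable.
#' @export
correlate_with_clinical <- function(x, meta, features = abund_features(x),
                                    method = c("spearman", "pearson")) {
  method <- match.arg(method)
  meta <- meta[match(x$sample_id, meta$sample_id), ]
  if (anyNA(meta$sample_id)) abort("metadata does not cover all table samples")
  m <- abund_matrix(x)
  miss <- setdiff(features, colnames(m))
  if (length(miss)) abort(paste0("features not in table: ",
                                 paste(head(miss, 5), collapse = ", ")))
  vars_all <- intersect(c("age", "mmse", "apoe_e4_count"), names(meta))
  vars_csf <- intersect(c("csf_abeta42", "csf_ttau", "csf_ptau"), names(meta))
  ad <- meta$diagnosis == "AD"
  one_cor <- function(a, b) {
    ok <- complete.cases(a, b)
    if (sum(ok) < 3) return(NA_real_)
    suppressWarnings(cor(a[ok], b[ok], method = method))
  }
  out <- tibble(feature_id = features)
  for (v in vars_all) {
    out[[v]] <- unname(vapply(features, function(f) {
      one_cor(m[, f], as.numeric(meta[[v]]))
    }, numeric(1)))
  }
  for (v in vars_csf) {
    out[[v]] <- unname(vapply(features, function(f) {
      one_cor(m[ad, f], as.numeric(meta[[v]][ad]))
    }, numeric(1)))
  }
  out
}
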