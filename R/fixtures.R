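#' Published effect-size tables shipped with the package
#'
#' The package ships transcriptions of the published per-feature effect
#' summaries for the three best-performing feature blocks: 18 genera (with
#' phylum annotation), 17 Gene Ontology terms and 26 KEGG orthologs, each
#' reported as the difference of logarithmised medians between AD patients and
#' healthy controls (negative = higher in healthy controls, positive = higher
#' in AD).
#'
#' @param name Which table: `"genera"`, `"GO"` or `"KO"`.
#' @return An effect tibble (class `effect_tbl`) with columns `feature_id`,
#'   `annotation` (phylum or function label) and `effect`.
#' @export
#' @examples
#' load_effect_fixture("genera")
load_effect_fixture <- function(name = c("genera", "GO", "KO")) {
  name <- match.arg(name)
  file <- switch(name,
                 genera = "table2_genera.tsv",
                 GO = "table3_go.tsv",
                 KO = "table4_ko.tsv")
  path <- system.file("extdata", file, package = "adbalance", mustWork = TRUE)
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  ann_col <- if (name == "genera") "phylum" else "function_label"
  effect_table(tibble(feature_id = x$feature_id,
                      annotation = x[[ann_col]],
                      effect = x$effect),
               block = name)
}

#' Published cohort margins shipped with the package
#'
#' Group-level summaries of the study cohort (100 healthy controls, 75
#' amyloid-positive AD patients): means and standard deviations for the
#' continuous variables and per-level counts for the categorical ones,
#' including the gender and ApoE epsilon-4 contingency tables.
#'
#' @return A tibble with columns `variable`, `statistic` (`mean`, `sd` or
#'   `count`), `level`, `hc`, `ad`.
#' @export
load_cohort_margins <- function() {
  path <- system.file("extdata", "table1_cohort_margins.tsv",
                      package = "adbalance", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(level = readr::col_character()))
}

#' Expand categorical cohort margins into per-sample records
#'
#' Reconstructs a metadata tibble whose categorical variables exactly
#' reproduce the published contingency tables (gender, ApoE allele count,
#' medication flags). Continuous variables are not filled in; this
#' reconstruction exists so the cohort group-comparison tests can be run
#' against the printed counts.
#'
#' @param margins Output of [load_cohort_margins()].
#' @return A `cohort_meta` tibble with 175 rows.
#' @export
metadata_from_margins <- function(margins = load_cohort_margins()) {
  counts <- margins[margins$statistic == "count" & margins$variable != "n", ]
  n_hc <- margins$hc[margins$variable == "n"]
  n_ad <- margins$ad[margins$variable == "n"]
  meta <- tibble(
    sample_id = c(sprintf("HC%03d", seq_len(n_hc)), sprintf("AD%03d", seq_len(n_ad))),
    diagnosis = c(rep("HC", n_hc), rep("AD", n_ad))
  )
  expand_var <- function(var) {
    rows <- counts[counts$variable == var, ]
    vals <- rep(NA_character_, n_hc + n_ad)
    # Fill group-wise in level order; missing counts (e.g. ApoE not typed for
    # everyone) leave trailing NAs within the group.
    hc_lv <- rep(rows$level, ifelse(is.na(rows$hc), 0L, rows$hc))
    ad_lv <- rep(rows$level, ifelse(is.na(rows$ad), 0L, rows$ad))
    vals[seq_along(hc_lv)] <- hc_lv
    vals[n_hc + seq_along(ad_lv)] <- ad_lv
    vals
  }
  for (var in unique(counts$variable)) {
    v <- expand_var(var)
    if (var == "apoe_e4_count") v <- as.integer(v)
    if (all(stats::na.omit(v) %in% c("yes", "no"))) v <- v == "yes"
    meta[[var]] <- v
  }
  cohort_metadata(meta)
}
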