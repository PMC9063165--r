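#' Validate (or read) cohort metadata
#'
#' Cohort metadata is one row per sample with the clinical record used by the
#' discrimination pipeline: diagnosis (`AD` or `HC`), age in years, gender
#' (`m`/`f`), body-mass index, ApoE epsilon-4 allele count (0/1/2, may be
#' missing), MMSE (0-30), GDS, logical medication flags, and optional
#' cerebrospinal-fluid markers (`csf_abeta42`, `csf_ttau`, `csf_ptau`, pg/ml),
#' which are typically available only for AD patients.
#'
#' @param x A data frame with at least `sample_id` and `diagnosis` columns.
#' @return A validated tibble of class `cohort_meta`.
#' @export
cohort_metadata <- function(x) {
  x <- as_tibble(x)
  if (!all(c("sample_id", "diagnosis") %in% names(x))) {
    abort("metadata needs `sample_id` and `diagnosis` columns")
  }
  if (anyDuplicated(x$sample_id)) abort("duplicate sample ids in metadata")
  x$diagnosis <- as.character(x$diagnosis)
  bad <- setdiff(unique(x$diagnosis), c("AD", "HC"))
  if (length(bad) || anyNA(x$diagnosis)) {
    abort(paste0("diagnosis must be 'AD' or 'HC'; found: ",
                 paste(bad, collapse = ", ")))
  }
  if ("gender" %in% names(x)) {
    badg <- setdiff(unique(stats::na.omit(x$gender)), c("m", "f"))
    if (length(badg)) abort("gender must be 'm' or 'f'")
  }
  if ("mmse" %in% names(x)) {
    mm <- stats::na.omit(x$mmse)
    if (any(mm < 0 | mm > 30)) abort("mmse must lie in [0, 30]")
  }
  if ("apoe_e4_count" %in% names(x)) {
    ap <- stats::na.omit(x$apoe_e4_count)
    if (any(!ap %in% 0:2)) abort("apoe_e4_count must be 0, 1 or 2")
  }
  if ("gds" %in% names(x)) {
    gg <- stats::na.omit(x$gds)
    if (any(gg < 0)) abort("gds must be non-negative")
  }
  class(x) <- c("cohort_meta", class(tibble()))
  x
}

#' @rdname cohort_metadata
#' @param path Path to a metadata TSV (columns as above).
#' @export
read_metadata <- function(path) {
  cohort_metadata(readr::read_tsv(path, show_col_types = FALSE, progress = FALSE))
}

#' @rdname cohort_metadata
#' @export
write_metadata <- function(x, path) {
  readr::write_tsv(as_tibble(x), path, progress = FALSE)
  invisible(path)
}

# 0/1 response used throughout: AD = 1 (case), HC = 0 (control).
diagnosis_to_binary <- function(diagnosis) {
  as.integer(diagnosis == "AD")
}
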