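#' Construct an abundance table
#'
#' An abundance table is a tibble with one row per sample: a `sample_id`
#' column followed by one numeric column per feature (genus, GO term, KEGG
#' ortholog, ...). The measurement unit (`"raw_hits"` or `"HPM"`, hits per
#' million reads) and the feature block (`"genera"`, `"GO"`, `"KO"`, ...)
#' travel as attributes so downstream steps can refuse, e.g., to log-transform
#' raw counts.
#'
#' @param x A data frame whose first column is `sample_id` and whose remaining
#'   columns are non-negative numeric feature abundances.
#' @param unit Measurement unit, `"raw_hits"` or `"HPM"`.
#' @param block Feature block label, e.g. `"genera"`, `"GO"`, `"KO"`.
#' @param annotations Optional tibble of feature annotations with columns
#'   `feature_id` and any of `phylum`, `function_label`. Every `feature_id`
#'   must name a feature column of `x`.
#'
#' @return A tibble of class `abund_tbl` with attributes `unit`, `block`, and
#'   `annotations`.
#' @export
#' @examples
#' abundance_table(
#'   tibble::tibble(sample_id = c("S1", "S2"), gA = c(0, 1), gB = c(5, 2)),
#'   unit = "raw_hits", block = "genera"
#' )
abundance_table <- function(x, unit = c("raw_hits", "HPM"), block = "genera",
                            annotations = NULL) {
  unit <- match.arg(unit)
  x <- as_tibble(x)
  if (ncol(x) < 2L || names(x)[1] != "sample_id") {
    abort("first column must be `sample_id` followed by at least one feature column")
  }
  ids <- as.character(x$sample_id)
  if (anyDuplicated(ids)) abort("duplicate sample ids")
  feats <- names(x)[-1]
  if (anyDuplicated(feats)) abort("duplicate feature ids")
  vals <- as.matrix(x[-1])
  if (!is.numeric(vals)) abort("feature columns must be numeric")
  if (anyNA(vals)) abort("missing cells are not allowed; encode absence as 0")
  if (any(vals < 0)) abort("negative abundance values are not allowed")
  if (unit == "HPM" && any(vals > 1e6)) {
    abort("HPM values cannot exceed 1e6")
  }
  if (!is.null(annotations)) {
    annotations <- as_tibble(annotations)
    if (!"feature_id" %in% names(annotations)) {
      abort("annotations need a `feature_id` column")
    }
    bad <- setdiff(annotations$feature_id, feats)
    if (length(bad)) {
      abort(paste0("annotation ids not present in table: ",
                   paste(head(bad, 5), collapse = ", ")))
    }
  }
  x$sample_id <- ids
  structure(x,
            class = c("abund_tbl", class(tibble())),
            unit = unit, block = block, annotations = annotations)
}

#' @export
print.abund_tbl <- function(x, ...) {
  cat(sprintf("# Abundance table: block %s, unit %s, %d samples x %d features\n",
              abund_block(x), abund_unit(x), nrow(x), ncol(x) - 1L))
  NextMethod()
}

#' Accessors for abundance-table attributes
#'
#' @param x An `abund_tbl`.
#' @return `abund_unit()` and `abund_block()` return the stored labels;
#'   `abund_matrix()` the numeric samples-by-features matrix with sample ids
#'   as row names; `abund_features()` the feature ids;
#'   `abund_annotations()` the annotation tibble (or `NULL`).
#' @export
abund_unit <- function(x) attr(x, "unit") %||% "raw_hits"

#' @rdname abund_unit
#' @export
abund_block <- function(x) attr(x, "block") %||% "unknown"

#' @rdname abund_unit
#' @export
abund_matrix <- function(x) {
  m <- as.matrix(x[setdiff(names(x), "sample_id")])
  rownames(m) <- x$sample_id
  m
}

#' @rdname abund_unit
#' @export
abund_features <- function(x) setdiff(names(x), "sample_id")

#' @rdname abund_unit
#' @export
abund_annotations <- function(x) attr(x, "annotations")

#' Read and write abundance tables as TSV
#'
#' The on-disk dialect is tab-separated UTF-8 with `.` as the decimal
#' separator; the first column is headed `sample_id` and the remaining header
#' fields are feature ids. An optional side-car annotation TSV holds
#' `feature_id`, `annotation_type`, `annotation_value` triples
#' (`annotation_type` one of `phylum`, `function_label`).
#'
#' @param path Path to the TSV file.
#' @param unit,block Passed to [abundance_table()].
#' @param annotation_path Optional side-car annotation TSV.
#' @return An `abund_tbl`.
#' @export
read_abundance_table <- function(path, unit = c("raw_hits", "HPM"),
                                 block = "genera", annotation_path = NULL) {
  unit <- match.arg(unit)
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(x)[1] <- "sample_id"
  ann <- NULL
  if (!is.null(annotation_path)) {
    long <- readr::read_tsv(annotation_path, show_col_types = FALSE, progress = FALSE)
    need <- c("feature_id", "annotation_type", "annotation_value")
    if (!all(need %in% names(long))) {
      abort("annotation side-car needs columns feature_id, annotation_type, annotation_value")
    }
    ann <- tidyr::pivot_wider(long, names_from = "annotation_type",
                              values_from = "annotation_value")
  }
  abundance_table(x, unit = unit, block = block, annotations = ann)
}

#' @rdname read_abundance_table
#' @param x An `abund_tbl` to write.
#' @export
write_abundance_table <- function(x, path, annotation_path = NULL) {
  readr::write_tsv(as_tibble(x), path, progress = FALSE)
  ann <- abund_annotations(x)
  if (!is.null(annotation_path) && !is.null(ann)) {
    long <- tidyr::pivot_longer(ann, -"feature_id",
                                names_to = "annotation_type",
                                values_to = "annotation_value")
    readr::write_tsv(long, annotation_path, progress = FALSE)
  }
  invisible(path)
}

#' Normalise raw hit counts to hits per million reads (HPM)
#'
#' HPM divides each feature's hit count by the sample's total read count and
#' multiplies by 10^6, the standard per-sample depth normalisation for
#' shotgun-metagenomic hit tables.
#'
#' @param x An `abund_tbl` in `raw_hits`.
#' @param read_counts Per-sample total read counts: either a single positive
#'   number recycled to all samples, or a numeric vector named by sample id
#'   (or in table order). Defaults to each sample's row sum, appropriate when
#'   the table's features partition all classified reads.
#' @return An `abund_tbl` in `HPM`.
#' @export
to_hpm <- function(x, read_counts = NULL) {
  if (abund_unit(x) == "HPM") return(x)
  m <- abund_matrix(x)
  if (is.null(read_counts)) read_counts <- rowSums(m)
  if (length(read_counts) == 1L) read_counts <- rep(read_counts, nrow(m))
  if (!is.null(names(read_counts))) read_counts <- read_counts[rownames(m)]
  if (length(read_counts) != nrow(m) || anyNA(read_counts)) {
    abort("read_counts must cover every sample")
  }
  if (any(read_counts <= 0)) abort("read counts must be positive")
  hpm <- sweep(m, 1, read_counts, "/") * 1e6
  out <- bind_cols(tibble(sample_id = rownames(m)), as_tibble(hpm))
  abundance_table(out, unit = "HPM", block = abund_block(x),
                  annotations = abund_annotations(x))
}

#' Replace zeros before log-ratio analysis
#'
#' Log-ratio transforms need strictly positive parts. Under the default
#' `multiplicative` strategy, zeros are imputed as `epsilon` and non-zero
#' values are left untouched; under `pseudocount`, `epsilon` is added to every
#' cell. `epsilon` defaults to 0.65 times the smallest non-zero value in the
#' table, a standard multiplicative-replacement choice. Features that are zero
#' in every sample carry no log-ratio information and are dropped with a
#' warning.
#'
#' @param x An `abund_tbl` (any unit).
#' @param strategy `"multiplicative"` or `"pseudocount"`.
#' @param epsilon Replacement value; default `0.65 * min(nonzero)`.
#' @return A strictly positive `abund_tbl`.
#' @export
replace_zeros <- function(x, strategy = c("multiplicative", "pseudocount"),
                          epsilon = NULL) {
  strategy <- match.arg(strategy)
  m <- abund_matrix(x)
  all_zero <- colSums(m > 0) == 0
  if (any(all_zero)) {
    warn(sprintf("dropping %d all-zero feature(s)", sum(all_zero)))
    m <- m[, !all_zero, drop = FALSE]
    if (ncol(m) == 0L) abort("all features are zero everywhere")
  }
  if (is.null(epsilon)) epsilon <- 0.65 * min(m[m > 0])
  if (strategy == "multiplicative") {
    m[m == 0] <- epsilon
  } else {
    m <- m + epsilon
  }
  ann <- abund_annotations(x)
  if (!is.null(ann)) ann <- ann[ann$feature_id %in% colnames(m), , drop = FALSE]
  out <- bind_cols(tibble(sample_id = rownames(m)), as_tibble(m))
  abundance_table(out, unit = abund_unit(x), block = abund_block(x),
                  annotations = ann)
}
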