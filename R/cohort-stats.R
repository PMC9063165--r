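#' Group comparisons of cohort characteristics
#'
#' Compares AD vs HC for every clinical variable present, using the test
#' conventional for its type: age and BMI (and CSF markers, when both groups
#' have them) by independent-samples t-test, pooled- or Welch-variance
#' according to Levene's test (mean-centred) at alpha 0.05; MMSE and GDS by
#' the Mann-Whitney U test (tie-corrected normal approximation); gender, ApoE
#' allele count and medication flags by Pearson's chi-square test without
#' continuity correction. Variables absent from the metadata are skipped.
#'
#' @param meta A `cohort_meta` tibble with both diagnosis groups present.
#' @return A tibble with one row per variable: `variable`, `test`,
#'   `statistic`, `df`, `p_value`, `hc_summary`, `ad_summary`.
#' @export
compare_groups <- function(meta) {
  if (length(unique(meta$diagnosis)) < 2) abort("both diagnosis groups must be present")
  g <- factor(meta$diagnosis, levels = c("HC", "AD"))
  t_vars <- intersect(c("age", "bmi"), names(meta))
  u_vars <- intersect(c("mmse", "gds"), names(meta))
  cat_vars <- intersect(c("gender", "apoe_e4_count", "arterial_hypertension",
                          "diabetes_mellitus", "rheumatoid_arthritis", "nsaids",
                          "anticoagulants", "antihypertensives", "antidiabetics",
                          "statins", "antidepressants", "ache_inhibitors"),
                        names(meta))
  msd <- function(v, grp) {
    x <- meta[[v]][g == grp & !is.na(meta[[v]])]
    sprintf("%.1f (%.1f)", mean(x), sd(x))
  }
  rows <- list()
  for (v in t_vars) {
    ok <- !is.na(meta[[v]])
    lev <- car::leveneTest(meta[[v]][ok] ~ g[ok], center = mean)
    pooled <- lev[["Pr(>F)"]][1] >= 0.05
    tt <- t.test(meta[[v]][ok] ~ g[ok], var.equal = pooled)
    rows[[v]] <- tibble(variable = v,
                        test = if (pooled) "t (pooled)" else "t (Welch)",
                        statistic = unname(tt$statistic),
                        df = unname(tt$parameter), p_value = tt$p.value,
                        hc_summary = msd(v, "HC"), ad_summary = msd(v, "AD"))
  }
  for (v in u_vars) {
    ok <- !is.na(meta[[v]])
    wt <- suppressWarnings(wilcox.test(meta[[v]][ok] ~ g[ok], exact = FALSE,
                                       correct = FALSE))
    rows[[v]] <- tibble(variable = v, test = "Mann-Whitney U",
                        statistic = unname(wt$statistic), df = NA_real_,
                        p_value = wt$p.value,
                        hc_summary = msd(v, "HC"), ad_summary = msd(v, "AD"))
  }
  for (v in cat_vars) {
    ok <- !is.na(meta[[v]])
    tab <- table(g[ok], as.character(meta[[v]][ok]))
    if (any(dim(tab) < 2)) next
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    summ <- function(grp) paste(tab[grp, ], collapse = "/")
    rows[[v]] <- tibble(variable = v, test = "Pearson chi-square",
                        statistic = unname(ct$statistic),
                        df = unname(ct$parameter), p_value = ct$p.value,
                        hc_summary = summ("HC"), ad_summary = summ("AD"))
  }
  bind_rows(rows)
}

#' Principal components capturing a variance fraction
#'
#' Column-centres `X` (no scaling), runs PCA and keeps the smallest number of
#' components whose cumulative explained variance reaches `threshold`.
#'
#' @param X Numeric matrix (samples x variables), e.g. ilr coordinates.
#' @param threshold Variance fraction in (0, 1]; `1` keeps all components
#'   with non-negligible variance (the matrix rank).
#' @return A list with `k`, `scores` (n x k), and `explained` (cumulative
#'   variance fractions for all components).
#' @export
pcs_for_variance <- function(X, threshold = 0.95) {
  if (threshold <= 0 || threshold > 1) abort("threshold must lie in (0, 1]")
  X <- as.matrix(X)
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  tot <- sum(ev)
  if (tot <= 0) abort("matrix has zero variance")
  keep <- ev / tot > 1e-12
  cum <- cumsum(ev) / tot
  k <- if (threshold == 1) sum(keep) else which(cum >= threshold - 1e-12)[1]
  list(k = k, scores = pc$x[, seq_len(k), drop = FALSE],
       explained = cum)
}

#' Two-sample Hotelling T-squared test
#'
#' The multivariate generalisation of the two-sample t-test:
#' `T2 = (n1*n2/(n1+n2)) * d' S^-1 d` with `d` the mean difference and `S`
#' the pooled covariance, referred to an F distribution with
#' `(k, n1+n2-k-1)` degrees of freedom. At `k = 1` the statistic equals the
#' squared pooled-variance t statistic.
#'
#' @param scores Numeric n x k matrix (e.g. principal-component scores).
#' @param groups Two-level grouping vector of length n.
#' @return A one-row tibble: `test`, `statistic` (T2), `f`, `df1`, `df2`,
#'   `p_value`, `n1`, `n2`, `k`.
#' @export
hotelling_t2 <- function(scores, groups) {
  X <- as.matrix(scores)
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) != 2) abort("groups must have exactly 2 populated levels")
  groups <- droplevels(groups)
  idx <- split(seq_len(nrow(X)), groups)
  n1 <- length(idx[[1]]); n2 <- length(idx[[2]]); k <- ncol(X)
  if (n1 + n2 - 2 <= k) {
    abort("pooled covariance not invertible: n1 + n2 - 2 must exceed k; reduce the variance threshold")
  }
  x1 <- X[idx[[1]], , drop = FALSE]; x2 <- X[idx[[2]], , drop = FALSE]
  d <- colMeans(x1) - colMeans(x2)
  S <- ((n1 - 1) * stats::cov(x1) + (n2 - 1) * stats::cov(x2)) / (n1 + n2 - 2)
  Sd <- tryCatch(solve(S, d), error = function(e) {
    abort("singular pooled covariance; use a smaller variance threshold")
  })
  t2 <- (n1 * n2 / (n1 + n2)) * sum(d * Sd)
  f <- (n1 + n2 - k - 1) / (k * (n1 + n2 - 2)) * t2
  tibble(test = "Hotelling T2", statistic = t2, f = f,
         df1 = k, df2 = n1 + n2 - k - 1,
         p_value = pf(f, k, n1 + n2 - k - 1, lower.tail = FALSE),
         n1 = n1, n2 = n2, k = k)
}

#' Covariate influence on genus composition
#'
#' Tests whether a binary covariate (e.g. antidepressant use) is associated
#' with overall genus composition: the table is HPM-normalised if needed,
#' zeros are replaced, the composition is ilr-transformed, principal
#' components capturing `threshold` of the variance are extracted, and a
#' Hotelling T-squared test compares the two covariate groups on those
#' components.
#'
#' @param x An `abund_tbl` (raw hits or HPM).
#' @param meta A `cohort_meta` tibble with the flag column.
#' @param flag Name of a two-level (logical or yes/no) metadata column.
#' @param threshold Variance fraction for the PCA step (default 0.95).
#' @param read_counts Optional per-sample read counts for HPM normalisation.
#' @return The one-row tibble from [hotelling_t2()], with a `flag` column.
#' @export
medication_influence <- function(x, meta, flag, threshold = 0.95,
                                 read_counts = NULL) {
  if (!flag %in% names(meta)) abort(sprintf("flag '%s' not in metadata", flag))
  meta <- meta[match(x$sample_id, meta$sample_id), ]
  if (anyNA(meta$sample_id)) abort("metadata does not cover all table samples")
  grp <- meta[[flag]]
  if (length(unique(stats::na.omit(grp))) != 2) {
    abort(sprintf("flag '%s' must have exactly 2 populated levels", flag))
  }
  keep <- !is.na(grp)
  x <- abundance_table(as_tibble(x)[keep, ], unit = abund_unit(x),
                       block = abund_block(x))
  grp <- grp[keep]
  hpm <- to_hpm(x, read_counts = read_counts)
  pos <- replace_zeros(hpm)
  ilr <- ilr_transform(pos)
  pcs <- pcs_for_variance(as.matrix(ilr[-1]), threshold = threshold)
  out <- hotelling_t2(pcs$scores, grp)
  bind_cols(tibble(flag = flag), out)
}
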