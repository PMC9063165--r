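# Independent oracles used to cross-check the package implementations.

# Exact two-sided Wilcoxon rank-sum p-value by full enumeration of group
# assignments (no ties assumed).
enumerate_wilcoxon_p <- function(a, b) {
  vals <- c(a, b)
  n1 <- length(a)
  r <- rank(vals)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(vals), n1)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p_lo <- mean(w_all <= w_obs)
  p_hi <- mean(w_all >= w_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# AUROC by explicit case-control pair counting, ties worth one half.
paircount_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Trapezoidal area under the empirical ROC curve.
trapezoid_auroc <- function(curve) {
  x <- 1 - curve$specificity
  y <- curve$sensitivity
  o <- order(x, y)
  x <- x[o]; y <- y[o]
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

# Tiny abundance-table maker for unit tests.
make_abund <- function(values, unit = "HPM", block = "genera",
                       annotations = NULL) {
  m <- as.matrix(values)
  if (is.null(colnames(m))) colnames(m) <- paste0("f", seq_len(ncol(m)))
  tab <- tibble::as_tibble(m)
  tab <- dplyr::bind_cols(
    tibble::tibble(sample_id = sprintf("S%03d", seq_len(nrow(m)))), tab)
  abundance_table(tab, unit = unit, block = block, annotations = annotations)
}
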