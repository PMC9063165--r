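test_that("stratified splits honour per-class round-half-up counts", {
  meta <- metadata_from_margins()   # 100 HC / 75 AD
  sp <- stratified_split(meta, 0.75, seed = 3)
  tr <- meta$diagnosis[meta$sample_id %in% sp$train_ids]
  expect_equal(sum(tr == "HC"), 75)
  expect_equal(sum(tr == "AD"), 56)   # round-half-up(75 * 0.75) = 56
  expect_length(intersect(sp$train_ids, sp$validation_ids), 0)
  expect_setequal(c(sp$train_ids, sp$validation_ids), meta$sample_id)

  sp2 <- stratified_split(meta, 0.75, seed = 3)
  expect_identical(sp, sp2)

  # published realized counts via override
  sp3 <- stratified_split(meta, 0.75, seed = 3, counts = c(AD = 59, HC = 73))
  tr3 <- meta$diagnosis[meta$sample_id %in% sp3$train_ids]
  expect_equal(as.integer(table(tr3)[c("AD", "HC")]), c(59L, 73L))

  small <- cohort_metadata(tibble::tibble(
    sample_id = as.character(1:8),
    diagnosis = rep(c("AD", "HC"), each = 4)))
  sps <- stratified_split(small, 0.75, seed = 1)
  expect_equal(as.integer(table(small$diagnosis[small$sample_id %in% sps$train_ids])),
               c(3L, 3L))

  expect_error(stratified_split(meta, 1.2), "between 0 and 1")
})

test_that("AUROC is the Mann-Whitney estimator with half-weight ties", {
  expect_equal(auroc(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0)), 0.75)
  expect_equal(auroc(c(1, 2, 3, 10), c(0, 0, 1, 1)), 1)
  expect_equal(auroc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(auroc(1:3, c(1, 1, 1)), "both classes")

  set.seed(17)
  for (i in 1:10) {
    sc <- sample(seq(0, 1, 0.1), 30, TRUE)   # forces ties
    y <- rbinom(30, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(auroc(sc, y), paircount_auroc(sc, y))
    expect_equal(auroc(sc, y), trapezoid_auroc(roc_curve(sc, y)))
    # complement identity and monotone invariance
    expect_identical(auroc(sc, y) + auroc(sc, 1 - y), 1)
    expect_equal(auroc(exp(3 * sc), y), auroc(sc, y))
  }
})

test_that("ROC curves are monotone and span both corners", {
  set.seed(19)
  sc <- rnorm(50)
  y <- rbinom(50, 1, 0.5)
  curve <- roc_curve(sc, y)
  expect_true(all(diff(curve$sensitivity) <= 0))
  expect_true(all(diff(curve$specificity) >= 0))
  expect_equal(curve$sensitivity[1], 1)
  expect_equal(curve$specificity[nrow(curve)], 1)
})

test_that("DeLong and bootstrap intervals agree and contain the estimate", {
  set.seed(23)
  sc <- c(rnorm(100, 1), rnorm(100, 0))
  y <- rep(c(1, 0), each = 100)
  ci_d <- auroc_ci(sc, y, "delong")
  ci_b <- auroc_ci(sc, y, "bootstrap", boot_n = 2000, seed = 7)
  expect_lt(max(abs(ci_d - ci_b)), 0.03)
  a <- auroc(sc, y)
  expect_true(ci_d["low"] <= a && a <= ci_d["high"])
  expect_true(ci_b["low"] <= a && a <= ci_b["high"])

  # degenerate DeLong variance falls back to the bootstrap
  sep <- c(rep(1, 20), rep(0, 20))
  expect_message(ci_s <- auroc_ci(sep + seq_along(sep) * 0, rep(c(1, 0), each = 20),
                                  "delong"),
                 "bootstrap")
})

test_that("interval width shrinks with sample size", {
  widths <- sapply(c(50, 200, 800), function(n) {
    set.seed(n)
    sc <- c(rnorm(n, 0.8), rnorm(n, 0))
    y <- rep(c(1, 0), each = n)
    ci <- auroc_ci(sc, y, "delong")
    ci["high"] - ci["low"]
  })
  expect_true(all(diff(widths) < 0))
})

test_that("the Youden cutpoint matches a brute-force threshold scan", {
  sc <- c(0.1, 0.3, 0.35, 0.6, 0.7, 0.9)
  y <- c(0, 0, 1, 0, 1, 1)
  res <- evaluate_scores(sc, y)
  cut <- res$cutpoint
  # brute force over candidate thresholds
  cand <- sort(unique(sc))
  j <- sapply(cand, function(t) {
    mean(sc[y == 1] >= t) + mean(sc[y == 0] < t) - 1
  })
  expect_equal(cut$youden, max(j))
  expect_equal(cut$threshold, min(cand[j >= max(j) - 1e-12]))

  # perfect separation: sens = spec = 1 at the optimum
  res2 <- evaluate_scores(c(1, 2, 3, 11, 12, 13), c(0, 0, 0, 1, 1, 1))
  expect_equal(res2$cutpoint$sensitivity, 1)
  expect_equal(res2$cutpoint$specificity, 1)

  # symmetric null: Youden index near zero
  set.seed(29)
  resn <- evaluate_scores(rnorm(400), rbinom(400, 1, 0.5))
  expect_lt(resn$cutpoint$youden, 0.25)
})

test_that("roc_result tidiers expose the curve and the summary", {
  res <- evaluate_scores(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0))
  expect_equal(glance(res)$auroc, 0.75)
  expect_true(all(c("threshold", "sensitivity", "specificity") %in%
                  names(tidy(res))))
  expect_s3_class(autoplot(res), "ggplot")
})
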