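test_that("group comparisons use the conventional test per variable type", {
  meta <- metadata_from_margins()
  set.seed(3)
  meta$age <- rnorm(175, 70, 5)
  meta$bmi <- rnorm(175, 25, 4)
  meta$mmse <- pmin(30, pmax(0, round(rnorm(175, 27, 3))))
  res <- compare_groups(meta)
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  expect_equal(res$test[res$variable == "gender"], "Pearson chi-square")
  expect_equal(res$test[res$variable == "mmse"], "Mann-Whitney U")
  expect_match(res$test[res$variable == "age"], "^t ")

  # identical groups: t statistic 0, p = 1
  m2 <- cohort_metadata(tibble::tibble(
    sample_id = as.character(1:20),
    diagnosis = rep(c("AD", "HC"), each = 10),
    age = rep(c(60, 65, 70, 75, 80), 4)))
  r2 <- compare_groups(m2)
  expect_equal(r2$statistic[r2$variable == "age"], 0)
  expect_equal(r2$p_value[r2$variable == "age"], 1)
})

test_that("PCA keeps the smallest component set reaching the variance target", {
  set.seed(5)
  X <- matrix(rnorm(400 * 4), ncol = 4)
  X <- scale(X)   # 4 uncorrelated unit-variance columns
  p <- pcs_for_variance(X, 0.95)
  expect_equal(p$k, 4)

  # one dominant direction (variance ratio ~100:1:1)
  set.seed(6)
  Z <- cbind(rnorm(500, sd = 10), rnorm(500), rnorm(500))
  expect_equal(pcs_for_variance(Z, 0.9)$k, 1)

  # threshold 1 keeps the full rank
  R <- matrix(rnorm(50 * 3), ncol = 3)
  R <- cbind(R, R[, 1] + R[, 2])   # rank 3
  expect_equal(pcs_for_variance(R, 1)$k, 3)

  expect_error(pcs_for_variance(X, 0), "threshold")
  expect_error(pcs_for_variance(matrix(1, 5, 2), 0.5), "zero variance")
})

test_that("Hotelling T2 reduces to the squared t statistic at k = 1", {
  set.seed(7)
  x <- c(rnorm(30, 1), rnorm(40, 0))
  g <- rep(c("a", "b"), c(30, 40))
  ht <- hotelling_t2(matrix(x, ncol = 1), g)
  tt <- t.test(x ~ g, var.equal = TRUE)
  expect_equal(ht$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(ht$p_value, tt$p.value, tolerance = 1e-10)

  # identical groups (same sample values in both groups)
  X0 <- matrix(rnorm(16), 8, 2)
  same <- rbind(X0, X0)
  ht0 <- hotelling_t2(same, rep(c("a", "b"), each = 8))
  expect_equal(ht0$statistic, 0)
  expect_equal(ht0$p_value, 1)

  expect_error(hotelling_t2(matrix(rnorm(12), ncol = 6),
                            rep(c("a", "b"), 1)),
               "exactly 2|invertible")
})

test_that("Hotelling T2 is invariant under invertible linear maps", {
  set.seed(9)
  X <- matrix(rnorm(80 * 4), ncol = 4)
  g <- rep(c("a", "b"), each = 40)
  A <- matrix(rnorm(16), 4)
  while (abs(det(A)) < 0.1) A <- matrix(rnorm(16), 4)
  h1 <- hotelling_t2(X, g)
  h2 <- hotelling_t2(X %*% A, g)
  expect_equal(h1$statistic, h2$statistic, tolerance = 1e-8)
  expect_equal(h1$p_value, h2$p_value, tolerance = 1e-8)
})

test_that("medication influence detects confounded shifts and rejects bad flags", {
  n <- 100
  lab <- c(rep("AD", n), rep("HC", n))
  cfg <- sim_config(n_ad = n, n_hc = n, n_features = 30,
                    planted = tibble::tibble(feature_id = "plant", delta = 1.0),
                    depth = 1e5, base_logsd = 0.5)
  g <- simulate_abundance_block(cfg, lab, seed = 11)
  meta <- cohort_metadata(tibble::tibble(
    sample_id = g$table$sample_id, diagnosis = lab,
    flag_conf = lab == "AD",
    flag_null = rep(c(TRUE, FALSE), n),
    flag_empty = TRUE))
  conf <- medication_influence(g$table, meta, "flag_conf")
  expect_lt(conf$p_value, 0.01)
  expect_error(medication_influence(g$table, meta, "flag_empty"), "2 populated")
  expect_error(medication_influence(g$table, meta, "nope"), "not in metadata")
})

test_that("medication influence p-values are uniform under the null", {
  ps <- sapply(1:100, function(s) {
    n <- 30
    lab <- c(rep("AD", n), rep("HC", n))
    cfg <- sim_config(n_ad = n, n_hc = n, n_features = 25, depth = 1e4,
                      base_logsd = 0.5)
    g <- simulate_abundance_block(cfg, lab, seed = 1000 + s)
    meta <- cohort_metadata(tibble::tibble(
      sample_id = g$table$sample_id, diagnosis = lab,
      flag = rep(c(TRUE, FALSE), n)))
    medication_influence(g$table, meta, "flag", threshold = 0.9)$p_value
  })
  ks <- stats::ks.test(ps, "punif")
  expect_gt(ks$p.value, 0.01)
})
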