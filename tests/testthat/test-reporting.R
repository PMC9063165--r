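test_that("differences of logarithmised medians follow the sign convention", {
  # HC median 100, AD median 10 -> effect -1 (higher in HC is negative)
  m <- rbind(matrix(rep(c(10, 5), 5), 5, 2, byrow = TRUE),
             matrix(rep(c(100, 5), 5), 5, 2, byrow = TRUE))
  colnames(m) <- c("a", "b")
  tab <- make_abund(m)
  lab <- rep(c("AD", "HC"), each = 5)
  eff <- diff_log_medians(tab, lab)
  expect_equal(eff$effect[eff$feature_id == "a"], -1)
  expect_equal(eff$effect[eff$feature_id == "b"], 0)

  # exact antisymmetry under label flip
  set.seed(13)
  m2 <- matrix(runif(60, 1, 100), 10)
  tab2 <- make_abund(m2)
  lab2 <- rep(c("AD", "HC"), 5)
  flipped <- ifelse(lab2 == "AD", "HC", "AD")
  expect_identical(diff_log_medians(tab2, lab2)$effect,
                   -diff_log_medians(tab2, flipped)$effect)

  expect_error(diff_log_medians(tab, rep("AD", 10)), "both groups")
  z <- make_abund(matrix(c(0, 0, 1, 2), 2))
  expect_error(diff_log_medians(z, c("AD", "HC")), "replace_zeros")
})

test_that("planted effects are recovered by the reporting pipeline", {
  lab <- c(rep("AD", 500), rep("HC", 500))
  cfg <- sim_config(n_ad = 500, n_hc = 500, n_features = 100,
                    planted = tibble::tibble(feature_id = "plant", delta = 0.3),
                    depth = 1e5)
  g <- simulate_abundance_block(cfg, lab, seed = 15)
  eff <- diff_log_medians(replace_zeros(to_hpm(g$table, 1e5)), lab)
  expect_equal(eff$effect[eff$feature_id == "plant"], 0.3, tolerance = 0.1 / 0.3)
})

test_that("phylum breakdown counts and percentages are consistent", {
  eff <- effect_table(tibble::tibble(
    feature_id = letters[1:6],
    annotation = c("P", "P", "Q", "Q", NA, "P"),
    effect = c(0.5, -0.2, 0.1, -0.3, 0.4, 0.2)))
  bd <- phylum_breakdown(eff)
  expect_equal(sum(bd$n_total), 6)
  expect_equal(bd$phylum[1], "P")
  expect_equal(sum(bd$pct_of_ad_elevated), 100)
  expect_equal(sum(bd$pct_of_hc_elevated), 100)
  expect_true("unannotated" %in% bd$phylum)

  empty <- effect_table(tibble::tibble(feature_id = character(),
                                       effect = numeric()))
  expect_equal(nrow(phylum_breakdown(empty)), 0)
})

test_that("extreme features break ties lexicographically", {
  eff <- effect_table(tibble::tibble(
    feature_id = c("b", "a", "c"),
    effect = c(0.5, 0.5, -0.1)))
  ex <- extreme_features(eff)
  expect_equal(ex$feature_id[ex$direction == "ad_elevated"], "a")
  expect_equal(ex$feature_id[ex$direction == "hc_elevated"], "c")

  single <- effect_table(tibble::tibble(feature_id = "x", effect = 0.2))
  exs <- extreme_features(single)
  expect_equal(unique(exs$feature_id), "x")
  expect_error(extreme_features(effect_table(
    tibble::tibble(feature_id = character(), effect = numeric()))), "empty")
})

test_that("clinical correlations respect direction, nulls and CSF scoping", {
  n <- 1000
  set.seed(17)
  meta <- cohort_metadata(tibble::tibble(
    sample_id = sprintf("S%04d", 1:n),
    diagnosis = rep(c("AD", "HC"), each = n / 2),
    age = runif(n, 55, 90),
    mmse = pmin(30, pmax(0, round(rnorm(n, 25, 3)))),
    apoe_e4_count = sample(0:2, n, TRUE),
    csf_ttau = c(runif(n / 2, 100, 2000), rep(NA, n / 2))))
  m <- cbind(agecopy = meta$age,
             antiage = max(meta$age) - meta$age + 1,
             noise = runif(n, 1, 10),
             taucopy = ifelse(is.na(meta$csf_ttau), 1, meta$csf_ttau))
  tab <- abundance_table(
    dplyr::bind_cols(tibble::tibble(sample_id = meta$sample_id),
                     tibble::as_tibble(m)),
    unit = "HPM", block = "genera")
  ct <- correlate_with_clinical(tab, meta)
  expect_equal(ct$age[ct$feature_id == "agecopy"], 1)
  expect_equal(ct$age[ct$feature_id == "antiage"], -1)
  expect_lt(max(abs(ct$age[ct$feature_id == "noise"]),
                abs(ct$mmse[ct$feature_id == "noise"])), 0.1)
  # CSF correlation computed over AD samples only
  expect_equal(ct$csf_ttau[ct$feature_id == "taucopy"], 1)

  # too few complete pairs yields NA
  meta2 <- meta
  meta2$csf_ttau[1:(n / 2 - 2)] <- NA
  ct2 <- correlate_with_clinical(tab, meta2)
  expect_true(is.na(ct2$csf_ttau[ct2$feature_id == "taucopy"]))
})

test_that("effect fixtures expose annotations and plot cleanly", {
  fx <- load_effect_fixture("genera")
  expect_s3_class(autoplot(fx), "ggplot")
  expect_equal(attr(fx, "block"), "genera")
})
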