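test_that("wilcoxon pre-selection ranks and thresholds features", {
  m <- cbind(sep = c(1, 2, 3, 4, 5, 6), flat = rep(2, 6))
  tab <- make_abund(m)
  lab <- c(rep("HC", 3), rep("AD", 3))
  res <- wilcoxon_preselect(tab, lab, alpha = 0.5)
  expect_equal(res$p_value[res$feature_id == "sep"], 0.1)
  expect_equal(res$p_value[res$feature_id == "flat"], 1)
  expect_true(res$selected[res$feature_id == "sep"])
  expect_false(res$selected[res$feature_id == "flat"])
  expect_error(wilcoxon_preselect(tab, rep("AD", 6)), "both groups")
})

test_that("logistic fits match glm and the closed-form log odds ratio", {
  # 2x2 grouped data: slope is the log odds ratio
  X <- matrix(c(rep(0, 30), rep(1, 30)), ncol = 1)
  y <- c(rep(1, 10), rep(0, 20), rep(1, 20), rep(0, 10))
  f <- fit_logistic(X, y)
  expect_equal(unname(f$coefficients), log((20 * 20) / (10 * 10)),
               tolerance = 1e-8)

  # antisymmetric data: intercept is exactly 0
  Xa <- matrix(c(-2, -1, 1, 2), ncol = 1)
  ya <- c(0, 0, 1, 1)
  expect_error(fit_logistic(Xa, ya), "separation")
  fa <- fit_logistic(Xa, ya, ridge = 1e-2)
  expect_equal(fa$intercept, 0, tolerance = 1e-8)

  # cross-check against glm on a noisy problem
  set.seed(31)
  Xn <- matrix(rnorm(200), ncol = 2)
  yn <- rbinom(100, 1, plogis(0.3 + Xn %*% c(1, -0.5)))
  fn <- fit_logistic(Xn, yn)
  gl <- glm(yn ~ Xn, family = binomial())
  expect_equal(c(fn$intercept, unname(fn$coefficients)),
               unname(coef(gl)), tolerance = 1e-6)

  # duplicating the data leaves the fit unchanged
  fd <- fit_logistic(rbind(Xn, Xn), c(yn, yn))
  expect_equal(fd$coefficients, fn$coefficients, tolerance = 1e-8)
})

test_that("cross-validated AUROC behaves at the null and under separation", {
  set.seed(41)
  n <- 60
  lab <- c(rep("AD", 30), rep("HC", 30))
  noise <- make_abund(matrix(runif(n * 3, 1, 10), n))
  spec <- cv_spec(5, 30, seed = 2)
  r <- cv_auroc(noise, lab, abund_features(noise), spec,
                representation = "log_features")
  expect_length(r$fold_aurocs, 150)
  expect_lt(abs(r$mean - 0.5), 0.05)

  sep <- make_abund(matrix(c(10 + (lab == "AD") * 10), n,
                           dimnames = list(NULL, "s")))
  rs <- cv_auroc(sep, lab, "s", spec, representation = "log_features")
  expect_equal(rs$mean, 1.0)

  r2 <- cv_auroc(noise, lab, abund_features(noise), spec,
                 representation = "log_features")
  expect_identical(r$fold_aurocs, r2$fold_aurocs)

  tiny <- make_abund(matrix(runif(12), 6))
  expect_error(cv_auroc(tiny, c("AD", rep("HC", 5)), "f1", cv_spec(5, 2, 1)),
               "stratify")
})

test_that("backward shrinkage recovers a planted feature among noise", {
  set.seed(55)
  n <- 200
  lab <- c(rep("AD", n / 2), rep("HC", n / 2))
  cfg <- sim_config(n_ad = n / 2, n_hc = n / 2, n_features = 10,
                    planted = tibble::tibble(feature_id = "plant", delta = 1.0),
                    depth = 1e5, base_logsd = 0.5)
  g <- simulate_abundance_block(cfg, lab, seed = 56)
  pos <- replace_zeros(to_hpm(g$table, 1e5))
  pre <- wilcoxon_preselect(pos, lab, alpha = 0.05)
  model <- shrink_features(pos, lab, pre[pre$selected, ],
                           spec = cv_spec(5, 5, seed = 57))
  expect_true("plant" %in% model$features)
  # trajectory runs from the full set down to one feature
  expect_equal(model$cv_trajectory$n_features,
               seq(sum(pre$selected), 1))
})

test_that("a single pre-selected feature yields a one-entry trajectory", {
  set.seed(61)
  lab <- c(rep("AD", 20), rep("HC", 20))
  tab <- make_abund(matrix(runif(40 * 3, 1, 10), 40))
  model <- shrink_features(tab, lab, "f1", spec = cv_spec(5, 3, 1))
  expect_equal(nrow(model$cv_trajectory), 1)
  expect_equal(model$features, "f1")
})

test_that("the clinical model uses exactly the four published covariates", {
  set.seed(71)
  n <- 120
  meta <- cohort_metadata(tibble::tibble(
    sample_id = sprintf("S%03d", 1:n),
    diagnosis = ifelse(seq_len(n) <= 60, "AD", "HC"),
    age = c(rnorm(60, 75, 3), rnorm(60, 65, 3)),
    gender = sample(c("m", "f"), n, TRUE),
    bmi = rnorm(n, 25, 3),
    apoe_e4_count = sample(0:2, n, TRUE)
  ))
  model <- build_clinical_model(meta, spec = cv_spec(5, 5, 3))
  expect_length(model$coefficients, 4)
  expect_named(model$coefficients, c("age", "gender_m", "bmi", "apoe_e4_count"))
  # age separates the groups nearly perfectly here
  expect_gt(model$cv_auroc_mean, 0.95)

  meta$apoe_e4_count[1:5] <- NA
  expect_message(m2 <- build_clinical_model(meta, spec = cv_spec(5, 2, 3)),
                 "ApoE")
  meta$apoe_e4_count <- NA_integer_
  expect_error(build_clinical_model(meta), "every sample")
})

test_that("clinical covariates independent of diagnosis give null AUROC", {
  set.seed(81)
  n <- 200
  meta <- cohort_metadata(tibble::tibble(
    sample_id = sprintf("S%03d", 1:n),
    diagnosis = sample(c(rep("AD", 100), rep("HC", 100))),
    age = rnorm(n, 70, 5), gender = sample(c("m", "f"), n, TRUE),
    bmi = rnorm(n, 25, 4), apoe_e4_count = sample(0:2, n, TRUE)
  ))
  model <- build_clinical_model(meta, spec = cv_spec(5, 10, 4))
  expect_lt(abs(model$cv_auroc_mean - 0.5), 0.1)
})
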