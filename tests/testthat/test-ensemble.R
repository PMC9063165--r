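make_block_bundle <- function(n = 80, seed = 1, delta = 2) {
  # one informative block, one noise block, plus clinical metadata
  set.seed(seed)
  lab <- sample(c(rep("AD", n / 2), rep("HC", n / 2)))
  ids <- sprintf("S%03d", seq_len(n))
  sig <- matrix(10^(rnorm(n, 0, 0.3) + (lab == "AD") * delta), ncol = 1,
                dimnames = list(NULL, "sig"))
  noise <- matrix(runif(n * 2, 1, 10), n, dimnames = list(NULL, c("n1", "n2")))
  tab_sig <- abundance_table(
    dplyr::bind_cols(tibble::tibble(sample_id = ids),
                     tibble::as_tibble(cbind(sig, noise))),
    unit = "HPM", block = "genera")
  meta <- cohort_metadata(tibble::tibble(
    sample_id = ids, diagnosis = lab, age = rnorm(n, 70, 5),
    gender = sample(c("m", "f"), n, TRUE), bmi = rnorm(n, 25, 3),
    apoe_e4_count = sample(0:2, n, TRUE)))
  list(tab = tab_sig, meta = meta, lab = lab)
}

test_that("out-of-fold probabilities are deterministic and rank components", {
  bb <- make_block_bundle(seed = 2)
  spec <- cv_spec(5, 3, seed = 9)
  model <- shrink_features(bb$tab, bb$lab, c("sig", "n1"), spec = spec)
  clin <- build_clinical_model(bb$meta, spec = spec)
  models <- list(genera = model, clinical = clin)
  oof <- out_of_fold_probs(models, list(genera = bb$tab), bb$meta, spec)
  expect_true(all(oof$genera >= 0 & oof$genera <= 1))
  # the separating block scores (near) perfectly out of fold
  expect_gt(auroc(oof$genera, oof$diagnosis), 0.99)
  expect_lt(auroc(oof$clinical, oof$diagnosis), 0.75)

  oof2 <- out_of_fold_probs(models, list(genera = bb$tab), bb$meta, spec)
  expect_identical(oof, oof2)

  shuffled <- bb$tab[c(2, 1, seq(3, nrow(bb$tab))), ]
  shuffled <- abundance_table(tibble::as_tibble(shuffled), unit = "HPM")
  expect_error(out_of_fold_probs(models, list(genera = shuffled), bb$meta, spec),
               "sample ids")
})

test_that("single-component and mean-probability combiners are exact", {
  bb <- make_block_bundle(seed = 3)
  spec <- cv_spec(5, 3, seed = 10)
  model <- shrink_features(bb$tab, bb$lab, c("sig", "n1"), spec = spec)
  models <- list(genera = model)
  oof <- out_of_fold_probs(models, list(genera = bb$tab), bb$meta, spec)
  ens <- fit_ensemble(models, oof)
  pr <- predict(ens, list(genera = bb$tab), bb$meta)
  # one component: stacking is a monotone transform, AUROC is unchanged
  expect_equal(auroc(pr$prob, bb$lab),
               auroc(predict(model, bb$tab)$prob, bb$lab))

  clin <- build_clinical_model(bb$meta, spec = spec)
  two <- list(genera = model, clinical = clin)
  oof2 <- out_of_fold_probs(two, list(genera = bb$tab), bb$meta, spec)
  mens <- fit_ensemble(two, oof2, combiner = "mean_probability")
  prm <- predict(mens, list(genera = bb$tab), bb$meta)
  expect_equal(prm$prob, (prm$genera + prm$clinical) / 2, tolerance = 1e-12)

  # two identical components: same AUROC as either alone
  dup <- list(a = model, b = model)
  oofd <- out_of_fold_probs(dup, list(a = bb$tab, b = bb$tab), bb$meta, spec)
  ensd <- fit_ensemble(dup, oofd)
  prd <- predict(ensd, list(a = bb$tab, b = bb$tab), bb$meta)
  expect_equal(auroc(prd$prob, bb$lab),
               auroc(predict(model, bb$tab)$prob, bb$lab))

  expect_error(predict(ens, list(), bb$meta), "genera")
})

test_that("stacking two complementary components beats either alone", {
  wins <- 0L
  for (s in 1:10) {
    set.seed(100 + s)
    n <- 200
    y <- rep(c(1, 0), n / 2)
    half <- seq_len(n) <= n / 2
    x1 <- ifelse(half, (2 * y - 1) * 1.5 + rnorm(n, 0, 0.7), rnorm(n))
    x2 <- ifelse(!half, (2 * y - 1) * 1.5 + rnorm(n, 0, 0.7), rnorm(n))
    oof <- tibble::tibble(sample_id = as.character(seq_len(n)),
                          diagnosis = ifelse(y == 1, "AD", "HC"),
                          a = plogis(x1), b = plogis(x2))
    ens <- fit_ensemble(list(a = structure(list(), class = "block_model"),
                             b = structure(list(), class = "block_model")),
                        oof)
    w <- tidy(ens)
    probs <- plogis(w$estimate[1] + as.matrix(oof[c("a", "b")]) %*% w$estimate[-1])
    best <- max(auroc(oof$a, y), auroc(oof$b, y))
    if (auroc(drop(probs), y) >= best) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})
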