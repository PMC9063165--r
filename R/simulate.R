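# Seed hygiene: every generator takes an explicit seed and leaves the global
# RNG stream as it found it.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Truncated normal via inverse CDF, with the location shifted (uniroot on the
# closed-form truncated mean) so the realized mean equals `mean` despite the
# truncation. Asymmetric bounds would otherwise bias the group means away
# from the cohort targets the generator is meant to reproduce.
rtruncnorm_cal <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd < 0) abort("sd must be non-negative")
  if (sd == 0) return(rep(mean, n))
  if (mean <= lower || mean >= upper) {
    abort("target mean must lie strictly inside the truncation bounds")
  }
  trunc_mean <- function(mu) {
    a <- (lower - mu) / sd; b <- (upper - mu) / sd
    # Deep-tail guards (Mills-ratio approximation) keep the bracket finite.
    if (a > 6) return(lower + sd / a)
    if (b < -6) return(upper + sd / b)
    den <- pnorm(b) - pnorm(a)
    mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / den
  }
  lo <- mean - 6 * sd; hi <- mean + 6 * sd
  for (i in 1:8) if (trunc_mean(lo) > mean) lo <- lo - 6 * sd else break
  for (i in 1:8) if (trunc_mean(hi) < mean) hi <- hi + 6 * sd else break
  mu <- uniroot(function(m) trunc_mean(m) - mean, lower = lo, upper = hi,
                tol = 1e-8)$root
  u <- runif(n, pnorm(lower, mu, sd), pnorm(upper, mu, sd))
  pmin(pmax(qnorm(u, mu, sd), lower), upper)
}

#' Simulation configuration for synthetic case-control cohorts
#'
#' Defines a two-group (AD vs HC) cohort: group sizes, per-block feature
#' count, planted per-feature effects (differences of log10 medians, positive
#' = higher in AD), the latent log-normal abundance model, sequencing depth,
#' and clinical covariate distributions. Clinical defaults reproduce the
#' published cohort margins (group means/SDs, gender and ApoE frequencies,
#' medication rates); the default depth of 1e5 reads is a desk-scale stand-in
#' for the study's 40-50 million reads per sample — HPM normalisation makes
#' expected abundances depth-invariant.
#'
#' @param n_ad,n_hc Group sizes (default 75 AD / 100 HC as in the study).
#' @param n_features Features per block.
#' @param planted Tibble with columns `feature_id`, `delta` (difference of
#'   log10 medians to plant) and optionally `annotation`; `NULL` for a null
#'   cohort.
#' @param depth Reads per sample for the multinomial count draw.
#' @param base_logmean,base_logsd Mean and SD of the per-feature baseline
#'   log10 relative abundance; planted features sit at `base_logmean` so the
#'   planted effect is observable above the zero floor.
#' @param sample_logsd Between-sample SD of log10 abundance per feature
#'   (default 0.2, chosen so that planted effects of the magnitude the study
#'   reports remain recoverable at the study's sample sizes).
#' @param clinical Named list of clinical distribution parameters; see
#'   [clinical_defaults()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_ad = 75, n_hc = 100, n_features = 300,
                       planted = NULL, depth = 1e5,
                       base_logmean = 0, base_logsd = 1,
                       sample_logsd = 0.2,
                       clinical = clinical_defaults()) {
  if (n_ad < 2 || n_hc < 2) abort("need at least 2 samples per group")
  if (depth < 1e3) abort("depth must be at least 1e3 reads")
  if (base_logsd < 0 || sample_logsd < 0) abort("log-sd parameters must be non-negative")
  if (!is.null(planted)) {
    planted <- as_tibble(planted)
    if (!all(c("feature_id", "delta") %in% names(planted))) {
      abort("planted needs `feature_id` and `delta` columns")
    }
    if (nrow(planted) > n_features) abort("more planted features than n_features")
  }
  structure(list(n_ad = n_ad, n_hc = n_hc, n_features = n_features,
                 planted = planted, depth = depth,
                 base_logmean = base_logmean, base_logsd = base_logsd,
                 sample_logsd = sample_logsd, clinical = clinical),
            class = "sim_config")
}

#' Default clinical distribution parameters
#'
#' Group-wise normal means/SDs for age, BMI, MMSE and GDS, gender and ApoE
#' epsilon-4 genotype frequencies, per-group medication rates and AD-only CSF
#' marker distributions, all taken from the published cohort margins. Healthy
#' controls have MMSE truncated at 27 and above, mirroring the study's
#' inclusion criterion; ages are truncated to [50, 95].
#'
#' @param margins Output of [load_cohort_margins()].
#' @return A named list of distribution parameters.
#' @export
clinical_defaults <- function(margins = load_cohort_margins()) {
  ms <- function(var, grp) {
    m <- margins[margins$variable == var & margins$statistic == "mean", ][[grp]]
    s <- margins[margins$variable == var & margins$statistic == "sd", ][[grp]]
    c(mean = m, sd = s)
  }
  cnt <- function(var, grp) {
    rows <- margins[margins$variable == var & margins$statistic == "count", ]
    setNames(rows[[grp]], rows$level)
  }
  meds <- c("arterial_hypertension", "diabetes_mellitus", "rheumatoid_arthritis",
            "nsaids", "anticoagulants", "antihypertensives", "antidiabetics",
            "statins", "antidepressants", "ache_inhibitors")
  med_rate <- function(grp) {
    vapply(meds, function(v) {
      k <- cnt(v, grp); unname(k["yes"] / sum(k))
    }, numeric(1))
  }
  apoe_freq <- function(grp) {
    k <- cnt("apoe_e4_count", grp)
    k / sum(k)
  }
  list(
    age = list(hc = ms("age", "hc"), ad = ms("age", "ad"), bounds = c(50, 95)),
    bmi = list(hc = ms("bmi", "hc"), ad = ms("bmi", "ad"), bounds = c(14, 50)),
    mmse = list(hc = ms("mmse", "hc"), ad = ms("mmse", "ad"),
                bounds_hc = c(27, 30), bounds_ad = c(0, 30)),
    gds = list(hc = ms("gds", "hc"), ad = ms("gds", "ad"), bounds = c(0, 15)),
    gender_p_m = list(hc = unname(cnt("gender", "hc")["m"] / sum(cnt("gender", "hc"))),
                      ad = unname(cnt("gender", "ad")["m"] / sum(cnt("gender", "ad")))),
    apoe = list(hc = apoe_freq("hc"), ad = apoe_freq("ad")),
    medications = list(hc = med_rate("hc"), ad = med_rate("ad")),
    csf = list(abeta42 = c(ms("csf_abeta42", "ad"), lower = 225, upper = 600),
               ttau = c(ms("csf_ttau", "ad"), lower = 40, upper = Inf),
               ptau = c(ms("csf_ptau", "ad"), lower = 15, upper = Inf))
  )
}

#' Simulate per-sample clinical metadata
#'
#' Draws a metadata tibble under the configured group-wise distributions:
#' truncated normals (mean-calibrated) for age/BMI/MMSE/GDS, Bernoulli gender
#' and medication flags, categorical ApoE epsilon-4 allele counts, and CSF
#' markers for AD samples only. Every generated HC satisfies the MMSE >= 27
#' inclusion rule.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @return A `cohort_meta` tibble with `cfg$n_hc + cfg$n_ad` rows.
#' @export
simulate_metadata <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  cl <- cfg$clinical
  with_seed(seed, {
    n <- cfg$n_hc + cfg$n_ad
    is_ad <- c(rep(FALSE, cfg$n_hc), rep(TRUE, cfg$n_ad))
    draw_cont <- function(par, bounds_hc, bounds_ad = bounds_hc) {
      out <- numeric(n)
      out[!is_ad] <- rtruncnorm_cal(cfg$n_hc, par$hc["mean"], par$hc["sd"],
                                    bounds_hc[1], bounds_hc[2])
      out[is_ad] <- rtruncnorm_cal(cfg$n_ad, par$ad["mean"], par$ad["sd"],
                                   bounds_ad[1], bounds_ad[2])
      out
    }
    age <- draw_cont(cl$age, cl$age$bounds)
    bmi <- draw_cont(cl$bmi, cl$bmi$bounds)
    mmse <- round(draw_cont(cl$mmse, cl$mmse$bounds_hc, cl$mmse$bounds_ad))
    gds <- round(draw_cont(cl$gds, cl$gds$bounds))
    p_m <- ifelse(is_ad, cl$gender_p_m$ad, cl$gender_p_m$hc)
    gender <- ifelse(runif(n) < p_m, "m", "f")
    apoe <- integer(n)
    lev <- as.integer(names(cl$apoe$hc))
    apoe[!is_ad] <- sample(lev, cfg$n_hc, replace = TRUE, prob = cl$apoe$hc)
    apoe[is_ad] <- sample(lev, cfg$n_ad, replace = TRUE, prob = cl$apoe$ad)
    meta <- tibble(
      sample_id = sprintf("S%04d", seq_len(n)),
      diagnosis = ifelse(is_ad, "AD", "HC"),
      age = age, gender = gender, bmi = bmi,
      apoe_e4_count = apoe, mmse = mmse, gds = gds
    )
    for (med in names(cl$medications$hc)) {
      p <- ifelse(is_ad, cl$medications$ad[med], cl$medications$hc[med])
      meta[[med]] <- runif(n) < p
    }
    csf_draw <- function(par) {
      v <- rep(NA_real_, n)
      v[is_ad] <- rtruncnorm_cal(cfg$n_ad, par["mean"], par["sd"],
                                 par["lower"], par["upper"])
      v
    }
    meta$csf_abeta42 <- csf_draw(cl$csf$abeta42)
    meta$csf_ttau <- csf_draw(cl$csf$ttau)
    meta$csf_ptau <- csf_draw(cl$csf$ptau)
    cohort_metadata(meta)
  })
}

#' Simulate one compositional count block with planted effects
#'
#' Latent model: feature f has baseline log10 relative abundance `a_f` (drawn
#' once per block from `Normal(base_logmean, base_logsd)`; planted features
#' sit at `base_logmean`), each sample adds `Normal(0, sample_logsd)` noise,
#' and AD samples add the planted `delta_f`. Latent abundances are closed to
#' the simplex (softmax on the log10 scale) and counts are drawn multinomially
#' at the configured depth, so per-sample counts always sum exactly to the
#' depth. Because the shift enters the latent log10 median of feature f, the
#' difference of log10 medians of the resulting HPM values recovers `delta_f`
#' (up to closure, which is negligible when planted effects are small relative
#' to the whole composition).
#'
#' @param cfg A [sim_config()].
#' @param diagnosis Character vector of `"AD"`/`"HC"` labels, one per sample
#'   (e.g. `meta$diagnosis`).
#' @param seed Integer seed.
#' @param block Block label for the output table.
#' @param feature_prefix Prefix for unplanted (noise) feature ids.
#' @return A list with `table` (an `abund_tbl` of raw hits), `truth` (an
#'   `effect_tbl` of the planted deltas, 0 for noise features), and
#'   `read_counts` (per-sample depth).
#' @export
simulate_abundance_block <- function(cfg, diagnosis, seed = 1,
                                     block = "genera",
                                     feature_prefix = "feat") {
  stopifnot(inherits(cfg, "sim_config"))
  n <- length(diagnosis)
  is_ad <- diagnosis == "AD"
  planted <- cfg$planted
  n_planted <- if (is.null(planted)) 0L else nrow(planted)
  n_noise <- cfg$n_features - n_planted
  feat_ids <- c(if (n_planted) planted$feature_id,
                if (n_noise > 0) sprintf("%s_noise_%04d", feature_prefix, seq_len(n_noise)))
  delta <- c(if (n_planted) planted$delta, rep(0, max(n_noise, 0)))
  with_seed(seed, {
    base <- c(rep(cfg$base_logmean, n_planted),
              rnorm(max(n_noise, 0), cfg$base_logmean, cfg$base_logsd))
    # Expected relative share of each planted feature, ignoring noise: used
    # only to warn when the depth cannot represent it.
    if (n_planted) {
      share <- 10^base / sum(10^base)
      if (any(cfg$depth * share[seq_len(n_planted)] < 5)) {
        warn("sequencing depth may be too small to represent some planted features")
      }
    }
    lat <- matrix(rnorm(n * cfg$n_features, 0, cfg$sample_logsd),
                  nrow = n)
    lat <- sweep(lat, 2, base, "+")
    lat[is_ad, ] <- sweep(lat[is_ad, , drop = FALSE], 2, delta, "+")
    # Closure via softmax on the log10 scale (row-max subtracted for stability).
    counts <- matrix(0L, n, cfg$n_features)
    for (i in seq_len(n)) {
      w <- 10^(lat[i, ] - max(lat[i, ]))
      counts[i, ] <- rmultinom(1, cfg$depth, w / sum(w))[, 1]
    }
    colnames(counts) <- feat_ids
    tab <- bind_cols(tibble(sample_id = sprintf("S%04d", seq_len(n))),
                     as_tibble(counts))
    ann <- NULL
    if (n_planted && "annotation" %in% names(planted)) {
      ann_col <- if (block == "genera") "phylum" else "function_label"
      ann <- tibble(feature_id = planted$feature_id)
      ann[[ann_col]] <- planted$annotation
    }
    truth <- effect_table(tibble(feature_id = feat_ids,
                                 annotation = NA_character_,
                                 effect = delta), block = block)
    if (n_planted && "annotation" %in% names(planted)) {
      truth$annotation[match(planted$feature_id, truth$feature_id)] <-
        planted$annotation
    }
    list(table = abundance_table(tab, unit = "raw_hits", block = block,
                                 annotations = ann),
         truth = truth,
         read_counts = setNames(rep(cfg$depth, n), tab$sample_id))
  })
}

#' Simulate a full study-like dataset
#'
#' Generates a bundle mirroring the study design: 100 HC and 75 AD samples
#' with clinical metadata, plus three abundance blocks (genera, GO, KO) in
#' which the published per-feature effects (18 genera, 17 GO terms, 26 KEGG
#' orthologs, with their printed differences of logarithmised medians) are
#' planted among noise features.
#'
#' @param seed Integer seed driving metadata and all three blocks.
#' @param n_features Features per block (default 300).
#' @param depth Reads per sample (default 1e5).
#' @param n_ad,n_hc Group sizes.
#' @return A list with `meta`, `tables` (named list of `abund_tbl`s), `truth`
#'   (named list of `effect_tbl`s) and `read_counts`.
#' @export
#' @examples
#' \donttest{
#' bundle <- simulate_study_cohort(seed = 1, n_features = 50, depth = 1e4)
#' }
simulate_study_cohort <- function(seed = 1, n_features = 300, depth = 1e5,
                                  n_ad = 75, n_hc = 100) {
  blocks <- c("genera", "GO", "KO")
  planted <- lapply(blocks, function(b) {
    fx <- load_effect_fixture(b)
    tibble(feature_id = fx$feature_id, delta = fx$effect,
           annotation = fx$annotation)
  })
  names(planted) <- blocks
  cfg0 <- sim_config(n_ad = n_ad, n_hc = n_hc, n_features = n_features,
                     depth = depth)
  meta <- simulate_metadata(cfg0, seed = seed)
  out <- lapply(seq_along(blocks), function(k) {
    b <- blocks[k]
    cfg <- sim_config(n_ad = n_ad, n_hc = n_hc, n_features = n_features,
                      planted = planted[[b]], depth = depth)
    simulate_abundance_block(cfg, meta$diagnosis, seed = seed + k,
                             block = b, feature_prefix = b)
  })
  names(out) <- blocks
  list(meta = meta,
       tables = lapply(out, `[[`, "table"),
       truth = lapply(out, `[[`, "truth"),
       read_counts = lapply(out, `[[`, "read_counts"))
}
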