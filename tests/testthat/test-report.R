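# near-noiseless data with known group means on the model scale
sim_known_means <- function(seed, mu_by_lu, family = "gaussian") {
  withr::with_seed(seed, {
    lu <- names(mu_by_lu)
    purrr::map_dfr(1:6, function(s) {
      land <- rep(lu, each = 6)
      mu <- mu_by_lu[land]
      y <- if (family == "gaussian") mu + rnorm(length(mu), 0, 0.005) else
        rpois(length(mu), exp(mu))
      tibble::tibble(study_id = sprintf("S%d", s),
                     land_use = factor(land, levels = lu), y = y)
    })
  })
}

test_that("square-root back-transform recovers known percentage changes", {
  s0 <- 0.8
  mu <- c(PriMin = s0, Pasture = s0 * sqrt(0.68), Urban = s0 * sqrt(2))
  d <- sim_known_means(1, mu)
  fit <- fit_mixed(d, model_spec("y", "land_use", random = "study"))
  eff <- percent_change_sqrt(fit)
  expect_equal(eff$percent_change[eff$land_use == "PriMin"], 0)
  expect_equal(eff$ci_low[eff$land_use == "PriMin"], 0)
  expect_equal(eff$ci_high[eff$land_use == "PriMin"], 0)
  expect_equal(eff$percent_change[eff$land_use == "Pasture"], -32,
               tolerance = 0.02)
  expect_equal(eff$percent_change[eff$land_use == "Urban"], 100,
               tolerance = 0.02)
  expect_true(all(eff$ci_low <= eff$percent_change &
                    eff$percent_change <= eff$ci_high))
})

test_that("log back-transform recovers known percentage changes", {
  mu <- c(PriMin = log(20), Pasture = log(20) + log(0.35),
          Cropland = log(20) + log(2))
  d <- sim_known_means(2, mu, family = "poisson")
  fit <- fit_mixed(d, model_spec("y", "land_use", random = "study",
                                 family = "poisson"))
  eff <- percent_change_log(fit)
  expect_equal(eff$percent_change[eff$land_use == "PriMin"], 0)
  expect_equal(eff$percent_change[eff$land_use == "Pasture"], -65,
               tolerance = 0.1)
  expect_equal(eff$percent_change[eff$land_use == "Cropland"], 100,
               tolerance = 0.1)

  # exact inverse identity: beta = ln(1 + p/100) maps back to p
  for (p in c(-65, -32, -12, 40, 100)) {
    expect_equal(100 * (exp(log(1 + p / 100)) - 1), p)
  }
})

test_that("similarity contrasts are reported relative to PriMin-PriMin", {
  cfg <- sim_config(n_studies = 10, sites_per_study = 8, seed = 14,
                    decay_rate_geo = 0.5,
                    land_use_probs = c(0.4, 0, 0.3, 0, 0.3, 0, 0))
  sim <- simulate_dataset(cfg)
  pt <- build_pair_table(sim$assemblage, transform_pressures(sim$sites))
  fit <- fit_mixed(pt, model_spec(
    "logit_j_r", c("status", "landuse_contrast", "geo_dist_t",
                   "status:landuse_contrast"),
    random = "study", weights = "weight"))
  tab <- similarity_contrast_table(fit, pt)
  base <- tab[tab$contrast == "PriMin-PriMin", ]
  expect_equal(base$logit_diff, rep(0, nrow(base)))
  expect_equal(base$similarity, base$baseline_similarity)
  # land uses absent from the simulation come back as missing, not errors
  expect_true(all(is.na(tab$logit_diff[tab$contrast == "Urban-Urban"])))
  # reliability flag reflects the study counts behind each contrast
  expect_true(all(tab$reliable[tab$n_studies >= 3]))
  expect_false(any(tab$reliable[tab$n_studies < 3]))
})

test_that("alien share summarises classified species and individuals", {
  div <- tibble::tibble(
    site_id = rep(c("a", "b"), each = 2),
    status = rep(c("native", "alien"), 2),
    total_abundance = c(40, 10, 30, 10),
    species_richness = c(4L, 1L, 4L, 1L),
    land_use = "PriMin")
  sh <- percent_alien_share(div)
  expect_equal(sh$share_richness, 20)
  expect_equal(sh$share_abundance, mean(c(20, 25)))

  div$species_richness <- c(4L, 0L, 4L, 0L)
  div$total_abundance <- c(40, 0, 30, 0)
  expect_equal(percent_alien_share(div)$share_richness, 0)
  expect_equal(percent_alien_share(div, "Urban")$n_sites, 0)
})

test_that("estimated alien share tracks the generating share in PriMin", {
  sim <- simulate_dataset(sim_config(seed = 5))
  div <- rescale_abundance(site_diversity(sim$assemblage))
  sh <- percent_alien_share(div, "PriMin", sites = sim$sites)
  tt <- sim$truth$site_truth
  tt <- tt[tt$land_use == "PriMin", ]
  wide <- tidyr::pivot_wider(tt[, c("site_id", "status",
                                    "expected_richness")],
                             names_from = "status",
                             values_from = "expected_richness")
  truth <- 100 * mean(wide$alien / (wide$alien + wide$native))
  expect_lt(abs(sh$share_richness - truth), 3)
})

test_that("the pipeline runs end to end, writes artefacts, and reproduces", {
  cfg <- sim_config(n_studies = 6, sites_per_study = 6, seed = 33,
                    land_use_probs = c(0.4, 0, 0.3, 0, 0.3, 0, 0))
  out_dir <- withr::local_tempdir()
  run <- run_pipeline(cfg, out_dir = out_dir, permutations = TRUE,
                      n_perm = 9)
  expect_s3_class(run$effects, "tbl_df")
  expect_true(all(c("assemblage.csv", "sites.csv", "islands.csv",
                    "site_diversity.csv", "pair_table.csv", "effects.csv",
                    "similarity_contrasts.csv", "alien_share.csv",
                    "permutation_results.json", "manifest.json") %in%
                    list.files(out_dir)))
  manifest <- jsonlite::read_json(file.path(out_dir, "manifest.json"))
  expect_equal(manifest$seed, 33)
  expect_equal(length(run$permutation_tests), 3)

  # same config, permutations off: identical fits, no permutation output
  run2 <- run_pipeline(cfg, permutations = FALSE)
  expect_null(run2$permutation_tests)
  expect_equal(run2$fits$abundance$coefficients,
               run$fits$abundance$coefficients)
  expect_equal(run2$effects$percent_change, run$effects$percent_change)

  run3 <- run_pipeline(cfg, permutations = FALSE)
  expect_identical(run2$effects, run3$effects)
})

test_that("tidiers and plots expose the expected shapes", {
  d <- sim_zero_variance_gaussian(3)
  fit <- fit_mixed(d, model_spec("y", c("x1", "x2"), random = "study",
                                 weights = "w"))
  td <- tidy(fit)
  expect_setequal(names(td), c("term", "estimate", "std.error", "statistic",
                               "conf.low", "conf.high"))
  gl <- glance(fit)
  expect_equal(gl$nobs, nrow(d))
  expect_equal(gl$family, "gaussian")

  mu <- c(PriMin = 0.8, Pasture = 0.66)
  dd <- sim_known_means(4, mu)
  f2 <- fit_mixed(dd, model_spec("y", "land_use", random = "study"))
  eff <- percent_change_sqrt(f2)
  p <- autoplot(eff)
  expect_s3_class(p, "ggplot")
})
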