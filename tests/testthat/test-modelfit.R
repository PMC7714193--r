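test_that("gaussian fit with boundary-zero variance reproduces weighted least squares", {
  d <- sim_zero_variance_gaussian(42)
  spec <- model_spec("y", c("x1", "x2"), random = "study", weights = "w")
  fit <- fit_mixed(d, spec, estimation = "ML")
  X <- cbind(1, d$x1, d$x2)
  beta_wls <- solve(t(X) %*% (d$w * X), t(X) %*% (d$w * d$y))
  expect_lt(max(abs(fit$coefficients - beta_wls)), 1e-6)
  expect_true(fit$singular)
  expect_true(fit$converged)
})

test_that("intercept-only Poisson fit recovers the log mean count", {
  d <- withr::with_seed(8, tibble::tibble(
    study_id = rep(sprintf("S%02d", 1:20), each = 100),
    y = rpois(2000, 5)))
  fit <- fit_mixed(d, model_spec("y", character(0), random = "study",
                                 family = "poisson"))
  expect_lt(abs(fit$coefficients[["(Intercept)"]] - log(5)), 0.05)
})

test_that("rank-deficient fixed effects raise an error naming aliased terms", {
  d <- sim_zero_variance_gaussian(1)
  d$x_dup <- d$x1
  expect_error(
    fit_mixed(d, model_spec("y", c("x1", "x_dup"), random = "study")),
    regexp = "aliased.*x_dup", class = "islandiv_rank_error")
})

# balanced three-land-use data with controllable random structure
sim_landuse_data <- function(seed, n_studies = 24, slope_sd = 0,
                             island_sd = 0, study_sd = 0.4, sigma = 0.5) {
  withr::with_seed(seed, {
    lu <- c("PriMin", "Cropland", "Pasture")
    isl <- sprintf("I%d", rep_len(1:6, n_studies))
    purrr::map_dfr(seq_len(n_studies), function(s) {
      sl <- setNames(rnorm(3, 0, slope_sd), lu)
      land <- rep(lu, 3)
      tibble::tibble(
        study_id = sprintf("S%02d", s),
        block_id = sprintf("S%02d_B%d", s, rep(1:3, each = 3)),
        island_id = isl[s],
        land_use = factor(land, levels = lu),
        y = rnorm(1, 0, study_sd) +
          rnorm(6, 0, island_sd)[match(isl[s], sprintf("I%d", 1:6))] +
          sl[land] + rnorm(9, 0, sigma))
    })
  })
}

test_that("random-structure selection favours slopes when slope variance dominates", {
  d <- sim_landuse_data(101, slope_sd = 1.2)
  spec <- model_spec("y", "land_use", random = "study")
  sel <- select_random_structure(d, spec)
  expect_equal(sel$random, "slopes_study_block_island")
  expect_s3_class(attr(sel, "selection"), "tbl_df")
  expect_s3_class(attr(sel, "fit"), "ln_fit")
})

test_that("zero island variance drops the island intercept in most replicates", {
  picks <- vapply(1:7, function(i) {
    d <- sim_landuse_data(200 + i, island_sd = 0)
    sel <- select_random_structure(
      d, model_spec("y", "land_use", random = "study"),
      candidates = c("study_block_island", "study_block"))
    sel$random
  }, character(1))
  expect_gt(sum(picks == "study_block"), 3)
})

test_that("a single candidate structure is returned unchanged", {
  d <- sim_landuse_data(5)
  sel <- select_random_structure(
    d, model_spec("y", "land_use", random = "study"),
    candidates = "study")
  expect_equal(sel$random, "study")
})

test_that("backward simplification drops null terms and keeps real interactions", {
  # no interaction in truth: the two-way term is dropped, main effects kept
  d <- withr::with_seed(31, {
    n <- 300
    tibble::tibble(
      study_id = rep(sprintf("S%02d", 1:20), each = 15),
      a = factor(sample(c("u", "v"), n, TRUE)),
      b = rnorm(n)) |>
      dplyr::mutate(y = rep(rnorm(20, 0, 0.4), each = 15) +
                      0.8 * (a == "v") + 0.6 * b + rnorm(n, 0, 0.8))
  })
  res <- backward_simplify(d, model_spec("y", c("a", "b", "a:b"),
                                         random = "study"))
  expect_false("a:b" %in% res$spec$fixed)
  expect_true(all(c("a", "b") %in% res$spec$fixed))
  expect_true(all(res$trail$lr >= 0))

  # strong interaction: retained, and marginality protects the main effects
  d$y <- d$y + 1.5 * (d$a == "v") * d$b
  res2 <- backward_simplify(d, model_spec("y", c("a", "b", "a:b"),
                                          random = "study"))
  expect_true("a:b" %in% res2$spec$fixed)
  expect_true(all(c("a", "b") %in% res2$spec$fixed))
  # main effects inside a retained interaction are never tested for dropping
  expect_false(any(res2$trail$term %in% c("a", "b")))
})

test_that("a strong interaction is retained across replicates (power)", {
  kept <- vapply(1:20, function(i) {
    d <- withr::with_seed(400 + i, {
      n <- 200
      tibble::tibble(
        study_id = rep(sprintf("S%02d", 1:10), each = 20),
        a = factor(sample(c("u", "v"), n, TRUE)),
        b = rnorm(n)) |>
        dplyr::mutate(y = rep(rnorm(10, 0, 0.3), each = 20) +
                        1.2 * (a == "v") * b + rnorm(n, 0, 0.7))
    })
    res <- backward_simplify(d, model_spec("y", c("a", "b", "a:b"),
                                           random = "study"))
    "a:b" %in% res$spec$fixed
  }, logical(1))
  expect_gte(sum(kept), 19)
})

test_that("GVIF matches closed forms and the standard lm-based oracle", {
  # orthogonal single-df predictors -> GVIF exactly 1
  d <- sim_zero_variance_gaussian(7)
  qx <- qr.Q(qr(cbind(1, d$x1, d$x2)))   # orthonormal, incl. to the intercept
  d$o1 <- qx[, 2]; d$o2 <- qx[, 3]
  d$w <- 1
  e <- rnorm(nrow(d))
  for (s in unique(d$study_id)) {
    i <- d$study_id == s
    e[i] <- e[i] - mean(e[i])
  }
  d$y2 <- d$o1 - d$o2 + e
  fit <- fit_mixed(d, model_spec("y2", c("o1", "o2"), random = "study"))
  g <- gvif(fit)
  expect_lt(max(abs(g$gvif - 1)), 1e-8)

  # two predictors with correlation 0.8 -> VIF = 1 / (1 - 0.64) = 2.778
  d$c1 <- d$o1
  d$c2 <- 0.8 * d$o1 + sqrt(1 - 0.64) * d$o2
  fit2 <- fit_mixed(d, model_spec("y2", c("c1", "c2"), random = "study"))
  g2 <- gvif(fit2)
  expect_equal(g2$gvif, rep(1 / (1 - 0.64), 2), tolerance = 1e-6)

  # grouped (multi-df) term agrees with car::vif on the equivalent lm
  skip_if_not_installed("car")
  d$f <- factor(rep_len(c("p", "q", "r"), nrow(d)))
  d$y3 <- d$o1 + (d$f == "q") * 0.5 + e
  fit3 <- fit_mixed(d, model_spec("y3", c("o1", "f"), random = "study"))
  g3 <- gvif(fit3)
  ref <- car::vif(stats::lm(y3 ~ o1 + f, data = d))
  expect_equal(g3$gvif, unname(ref[, "GVIF"]), tolerance = 1e-4)
})

test_that("post-hoc slopes: the reference level equals the main-effect coefficient", {
  d <- sim_landuse_data(77, slope_sd = 0)
  d <- withr::with_seed(78, {
    slm_i <- runif(6, 0.2, 1.2)
    d$slm <- slm_i[as.integer(factor(d$island_id))]
    d$y <- d$y - 2 * d$slm * (d$land_use == "PriMin")
    d
  })
  fit <- fit_mixed(d, model_spec(
    "y", c("land_use", "slm", "land_use:slm"), random = "study"))
  ph <- posthoc_slopes(fit, "slm")
  expect_equal(ph$estimate[ph$level == "PriMin"],
               unname(fit$coefficients[["slm"]]), tolerance = 1e-10)
  expect_error(posthoc_slopes(fit, "nope"), "interaction")
})

test_that("a strong isolation slope on alien richness is detected post hoc", {
  hits <- vapply(1:5, function(i) {
    d <- withr::with_seed(900 + i, {
      n_st <- 30; nsite <- 10
      isl <- rep_len(1:10, n_st)
      slm_i <- runif(10, 0.2, 1.2)
      purrr::map_dfr(seq_len(n_st), function(s) {
        lu <- sample(c("PriMin", "Cropland"), nsite, TRUE)
        slm <- slm_i[isl[s]]
        eta <- 2.2 + (-2.9) * (slm - 0.7) * (lu == "PriMin") +
          (-0.5) * (slm - 0.7) * (lu == "Cropland") - 0.3 * (lu == "Cropland")
        tibble::tibble(
          study_id = sprintf("S%02d", s),
          island_id = sprintf("I%02d", isl[s]),
          land_use = factor(lu, levels = c("PriMin", "Cropland")),
          slm = slm, y = rpois(nsite, exp(eta + rnorm(1, 0, 0.2))))
      })
    })
    fit <- fit_mixed(d, model_spec(
      "y", c("land_use", "slm", "land_use:slm"),
      random = "study_island", family = "poisson"))
    ph <- posthoc_slopes(fit, "slm")
    ph$p_value[ph$level == "PriMin"] < 0.001
  }, logical(1))
  expect_gte(sum(hits), 3)
})

test_that("OLRE absorbs overdispersion in the synthetic richness channel", {
  positive <- vapply(1:6, function(i) {
    sim <- simulate_dataset(sim_config(n_studies = 10, sites_per_study = 10,
                                       overdispersion = 2, seed = 500 + i))
    div <- site_diversity(sim$assemblage)
    dn <- div[div$status == "native", ]
    fit <- fit_mixed(dn, model_spec("species_richness", character(0),
                                    random = "study", family = "poisson",
                                    olre = TRUE))
    vc <- as.data.frame(lme4::VarCorr(fit$model))
    vc$vcov[vc$grp == ".obs"] > 1e-4
  }, logical(1))
  expect_gte(sum(positive), 6)
})
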