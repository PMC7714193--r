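test_that("asymmetric Jaccard indices follow their defining formulas", {
  expect_equal(jaccard_richness_asym(c("A", "B"), c("A", "B", "C")), 2 / 3)
  expect_equal(jaccard_richness_asym(c("A", "B"), c("A", "B")), 1)
  expect_equal(jaccard_richness_asym(c("A", "B", "Z"), c("A", "B")), 1)
  expect_equal(jaccard_richness_asym(c("A"), c("B")), 0)
  expect_true(is.na(jaccard_richness_asym(c("A"), character(0))))

  expect_equal(jaccard_abundance_asym(c(A = 1, B = 9),
                                      c(A = 2, B = 3, C = 5)), 0.5)
  expect_equal(jaccard_abundance_asym(c(A = 1, B = 1, Z = 50),
                                      c(A = 2, B = 3)), 1)
  expect_true(is.na(jaccard_abundance_asym(numeric(0), numeric(0))))
  expect_error(jaccard_abundance_asym(c(A = -1), c(A = 2)))
})

test_that("Jaccard indices agree with a brute-force oracle on random assemblages", {
  withr::with_seed(2024, {
    pool <- sprintf("t%02d", 1:20)
    for (k in 1:200) {
      ti <- sample(pool, sample(0:12, 1))
      tj <- sample(pool, sample(0:12, 1))
      expect_identical(jaccard_richness_asym(ti, tj), oracle_jr(ti, tj))
      ai <- setNames(runif(length(ti), 0.5, 5), ti)
      aj <- setNames(runif(length(tj), 0.5, 5), tj)
      expect_equal(jaccard_abundance_asym(ai, aj), oracle_ja(ai, aj))
    }
  })
})

test_that("haversine distance matches closed forms and metric properties", {
  r <- 6378137
  expect_equal(geographic_distance(12, -3, 12, -3), 0)
  expect_equal(geographic_distance(0, 0, 180, 0), pi * r, tolerance = 1e-9)
  expect_equal(geographic_distance(0, 0, 90, 0), pi / 2 * r,
               tolerance = 1e-9)
  withr::with_seed(11, {
    for (k in 1:50) {
      lon <- runif(3, -180, 180); lat <- runif(3, -89, 89)
      dab <- geographic_distance(lon[1], lat[1], lon[2], lat[2])
      dba <- geographic_distance(lon[2], lat[2], lon[1], lat[1])
      dbc <- geographic_distance(lon[2], lat[2], lon[3], lat[3])
      dac <- geographic_distance(lon[1], lat[1], lon[3], lat[3])
      expect_equal(dab, dba)
      expect_lte(dac, dab + dbc + 1e-6)
    }
  })
})

test_that("geographic transform is referenced to the median maximum linear extent", {
  expect_equal(transform_geo(100, 100), 0)
  expect_equal(transform_geo(100 * exp(1), 100), 1)
  expect_equal(transform_geo(100 / exp(1), 100), -1)
  expect_error(transform_geo(0, 100), "excluded upstream")
})

test_that("Gower distance averages range-scaled differences over five variables", {
  ranges <- list(altitude = 100, tmax = 10, tmin = 10,
                 precip_wet = 200, precip_dry = 50)
  a <- list(altitude = 0, tmax = 25, tmin = 15, precip_wet = 100,
            precip_dry = 20)
  expect_equal(environmental_distance(a, a, ranges), 0)
  b <- a; b$altitude <- 100
  expect_equal(environmental_distance(a, b, ranges), 0.2)
  opposite <- list(altitude = 100, tmax = 35, tmin = 25, precip_wet = 300,
                   precip_dry = 70)
  expect_equal(environmental_distance(a, opposite, ranges), 1)
  miss <- a; miss$tmax <- NA
  expect_true(is.na(environmental_distance(a, miss, ranges)))
  # zero-range variables are dropped from the mean
  r0 <- ranges; r0$altitude <- 0
  expect_equal(environmental_distance(a, b, r0), 0)
})

test_that("Gower distance matches vegan on complete site data", {
  skip_if_not_installed("vegan")
  sites <- toy_sites()
  ranges <- gower_ranges(sites)
  mine <- environmental_distance(sites[1, ], sites[2, ], ranges)
  env <- as.data.frame(sites[, c("altitude", "tmax", "tmin",
                                 "precip_wet", "precip_dry")])
  ref <- as.matrix(vegan::vegdist(env, method = "gower"))[1, 2]
  expect_equal(mine, ref, tolerance = 1e-10)
})

test_that("adjusted logit compresses [0,1] to avoid infinities", {
  expect_equal(logit_adjusted(0.5), 0)
  expect_equal(logit_adjusted(1), qlogis(0.99))
  expect_equal(logit_adjusted(0), -qlogis(0.99))
  expect_equal(qlogis(0.99), 4.59512, tolerance = 1e-5)
  expect_error(logit_adjusted(1.2))
  y <- seq(0, 1, by = 0.05)
  expect_equal(inv_logit_adjusted(logit_adjusted(y)), y, tolerance = 1e-12)
})

test_that("pair table builds all ordered within-study pairs with transforms", {
  occ <- toy_assemblage()
  sites <- toy_sites()
  pt <- build_pair_table(occ, sites)
  # 3 eligible sites -> 6 ordered pairs; alien pairs all defined here too
  expect_equal(sum(pt$status == "native"), 6)
  expect_true(all(pt$site_i != pt$site_j))
  expect_true(all(pt$j_r >= 0 & pt$j_r <= 1))
  expect_true(all(pt$j_a >= 0 & pt$j_a <= 1))
  expect_equal(attr(pt, "median_mle_m"), 100)
  expect_equal(pt$geo_dist_t, log(pt$geo_dist_m / 100))
  expect_equal(pt$env_dist_t, pt$env_dist^(1 / 3))

  # land-use contrast is ordered (site i, site j)
  r <- pt[pt$site_i == "s1" & pt$site_j == "s2" & pt$status == "native", ]
  expect_equal(as.character(r$landuse_contrast), "PriMin-Cropland")
  # weight is the classified proportion at site j (all classified here)
  expect_true(all(pt$weight == 1))

  # hand-checked similarity: s1 {A,B} vs s2 {A,C} natives
  expect_equal(r$j_r, 0.5)           # shared {A} of s2's {A, C}
  expect_equal(r$j_a, 4 / 5)         # abundance 4 of 5 at s2 shared
})

test_that("study- and pair-level exclusion rules are applied and logged", {
  occ <- toy_assemblage()
  sites <- toy_sites()

  occ_kind <- occ; occ_kind$metric_kind <- "occurrence"
  pt <- build_pair_table(occ_kind, sites)
  expect_equal(nrow(pt), 0)
  expect_equal(unname(attr(pt, "exclusions")["study_occurrence_only"]), 1L)

  occ_eff <- occ; occ_eff$sampling_effort <- c(2, 2, 2, 1, 1, 1, 1, 1)
  expect_equal(nrow(build_pair_table(occ_eff, sites)), 0)

  occ_single <- occ[occ$taxon_id == "X", ]
  pt1 <- build_pair_table(occ_single, sites)
  expect_equal(nrow(pt1), 0)
  expect_equal(unname(attr(pt1, "exclusions")["study_single_species"]), 1L)

  # coincident coordinates: the pair disappears, others remain
  sites0 <- sites
  sites0$longitude[2] <- sites0$longitude[1]
  sites0$latitude[2] <- sites0$latitude[1]
  pt0 <- build_pair_table(occ, sites0)
  expect_false(any(pt0$site_i == "s1" & pt0$site_j == "s2"))
  expect_gt(unname(attr(pt0, "exclusions")["pair_zero_geo_dist"]), 0)

  # empty site j for a status: that direction is dropped, reverse kept
  occ_nat <- occ[!(occ$site_id == "s3" & occ$status == "native"), ]
  pt_n <- build_pair_table(occ_nat, sites)
  nat <- pt_n[pt_n$status == "native", ]
  expect_false(any(nat$site_j == "s3"))
  expect_true(any(nat$site_i == "s3"))
})
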