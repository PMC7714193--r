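# in-code fixtures shared across test files

# a minimal, fully classified two-status assemblage in one study
toy_assemblage <- function() {
  tibble::tibble(
    source_id = "P1", study_id = "S1", block_id = "S1_B1",
    site_id = rep(c("s1", "s2", "s3"), times = c(3, 3, 2)),
    taxon_id = c("A", "B", "X", "A", "C", "X", "B", "X"),
    status = c("native", "native", "alien",
               "native", "native", "alien",
               "native", "alien"),
    measurement = c(2, 3, 5, 4, 1, 2, 6, 1),
    metric_kind = "abundance",
    sampling_effort = 1)
}

toy_sites <- function() {
  tibble::tibble(
    site_id = c("s1", "s2", "s3"),
    study_id = "S1", block_id = "S1_B1", island_id = "I1",
    longitude = c(10, 10.02, 10.05),
    latitude = c(-5, -5.01, -5.03),
    land_use = c("PriMin", "Cropland", "Pasture"),
    hpd_raw = c(2, 40, 15), dist_road_raw = c(5000, 300, 900),
    altitude = c(100, 220, 150), tmax = c(28, 27, 27.5),
    tmin = c(18, 17, 17.2), precip_wet = c(300, 280, 310),
    precip_dry = c(40, 55, 45), max_linear_extent = 100)
}

# balanced hierarchical gaussian data: study random intercepts plus one
# covariate; beta = 0 gives a generative null that is exchangeable within
# studies
sim_study_gaussian <- function(seed, n_studies = 20, sites = 10, beta = 0,
                               study_sd = 0.5, sigma = 1) {
  withr::with_seed(seed, {
    n <- n_studies * sites
    tibble::tibble(
      study_id = rep(sprintf("S%02d", seq_len(n_studies)), each = sites),
      x = rnorm(n),
      x2 = rnorm(n),
      y = rep(rnorm(n_studies, 0, study_sd), each = sites) +
        beta * x + rnorm(n, 0, sigma))
  })
}

# gaussian data whose study variance component is exactly on the zero
# boundary: residuals are (weighted-)centred within studies
sim_zero_variance_gaussian <- function(seed, n_studies = 10, sites = 15) {
  withr::with_seed(seed, {
    n <- n_studies * sites
    d <- tibble::tibble(
      study_id = rep(sprintf("S%02d", seq_len(n_studies)), each = sites),
      x1 = rnorm(n), x2 = rnorm(n), w = runif(n, 0.3, 1))
    e <- rnorm(n, 0, 0.7)
    for (s in unique(d$study_id)) {
      i <- d$study_id == s
      e[i] <- e[i] - sum(d$w[i] * e[i]) / sum(d$w[i])
    }
    d$y <- 1 + 0.5 * d$x1 - 0.3 * d$x2 + e
    d
  })
}

# brute-force asymmetric Jaccard oracles (independent of the implementation)
oracle_jr <- function(taxa_i, taxa_j) {
  taxa_i <- unique(taxa_i); taxa_j <- unique(taxa_j)
  if (length(taxa_j) == 0) return(NA_real_)
  shared <- 0
  for (t in taxa_j) {
    hit <- FALSE
    for (u in taxa_i) if (identical(t, u)) hit <- TRUE
    if (hit) shared <- shared + 1
  }
  shared / length(taxa_j)
}

oracle_ja <- function(ab_i, ab_j) {
  tot <- 0
  for (v in ab_j) tot <- tot + v
  if (length(ab_j) == 0 || tot == 0) return(NA_real_)
  s <- 0
  for (t in names(ab_j)) {
    hit <- FALSE
    for (u in names(ab_i)) if (identical(t, u) && ab_i[[u]] > 0) hit <- TRUE
    if (hit) s <- s + ab_j[[t]]
  }
  s / tot
}
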