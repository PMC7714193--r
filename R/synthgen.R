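#' Configure a synthetic island metacommunity simulation
#'
#' Builds the parameter set for [simulate_dataset()]. The generator emulates
#' the statistical structure of hierarchical land-use comparison datasets:
#' studies containing blocks containing sites on islands, separate native and
#' alien species pools per island, multiplicative land-use effects on
#' expected total abundance and on expected species richness (baseline
#' `PriMin` = 1), overdispersed counts, compositional similarity that decays
#' with ln geographic distance, an island-isolation effect on alien
#' occupancy, and a configurable fraction of species left unclassified.
#'
#' @param n_studies,sites_per_study,n_islands,blocks_per_study Integers
#'   setting the sampling hierarchy.
#' @param land_use_probs Probabilities (length 7, ordered
#'   PriMin/Primary/Secondary/Plantation/Cropland/Pasture/Urban, summing
#'   to 1) with which sites are assigned to land uses.
#' @param native_pool_size,alien_pool_size Species-pool sizes per island.
#' @param base_occupancy_native,base_occupancy_alien Baseline per-species
#'   occupancy probabilities before land-use, decay and isolation modifiers.
#' @param base_abundance_native,base_abundance_alien Expected site-level
#'   total abundance (individuals) of each status at baseline conditions.
#' @param effect_landuse_native,effect_landuse_alien Length-7 multiplicative
#'   effects on expected total abundance (PriMin entry must equal 1).
#' @param richness_effect_native,richness_effect_alien Length-7
#'   multiplicative effects on expected species richness (PriMin = 1).
#' @param overdispersion Quadratic overdispersion coefficient `theta` of the
#'   gamma-Poisson count model (`Var = mu + theta * mu^2`; 0 gives Poisson).
#'   The same `theta` scales gamma-distributed site-level occupancy
#'   heterogeneity, so species richness is overdispersed too.
#' @param study_sd,block_sd,island_sd,slope_sd Standard deviations (natural
#'   log scale) of the random study, block, island and study-level land-use
#'   slope deviations applied to expected abundance.
#' @param decay_rate_geo Compositional distance-decay rate: a species
#'   anchored at distance `d` (m) from a site is retained with probability
#'   `(1 + d / 100)^(-decay_rate_geo)`, i.e. exponential in ln distance.
#' @param unclassified_fraction Probability that a species' status is
#'   relabelled `unknown` (classification failure).
#' @param island_isolation_effect_alien Log-linear effect of surrounding
#'   landmass on alien occupancy; negative values mean more aliens on more
#'   isolated islands (default mirrors a strong observed isolation slope).
#' @param occurrence_fraction Fraction of studies that record
#'   presence/absence only (no abundance).
#' @param seed Integer seed; the same config yields identical output tables.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_studies = 20,
                       sites_per_study = 12,
                       n_islands = 6,
                       blocks_per_study = 2,
                       land_use_probs = c(0.22, 0.12, 0.15, 0.13,
                                          0.13, 0.15, 0.10),
                       native_pool_size = 80,
                       alien_pool_size = 30,
                       base_occupancy_native = 0.5,
                       base_occupancy_alien = 0.2,
                       base_abundance_native = 120,
                       base_abundance_alien = 40,
                       effect_landuse_native = c(1, 0.97, 0.88, 0.70,
                                                 0.79, 0.68, 0.92),
                       effect_landuse_alien = c(1, 1.6, 2.2, 3.5,
                                                2.8, 2.6, 4.0),
                       richness_effect_native = c(1, 0.95, 0.85, 0.70,
                                                  0.50, 0.35, 0.60),
                       richness_effect_alien = c(1, 1.4, 1.7, 2.4,
                                                 1.9, 2.3, 2.2),
                       overdispersion = 0.35,
                       study_sd = 0.25,
                       block_sd = 0.1,
                       island_sd = 0.1,
                       slope_sd = 0.08,
                       decay_rate_geo = 0.15,
                       unclassified_fraction = 0.2,
                       island_isolation_effect_alien = -2.9,
                       occurrence_fraction = 0,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (abs(sum(cfg$land_use_probs) - 1) > 1e-9) {
    stop_islandiv("land_use_probs must sum to 1 (within 1e-9)")
  }
  if (length(cfg$land_use_probs) != 7) {
    stop_islandiv("land_use_probs must have length 7")
  }
  for (nm in c("effect_landuse_native", "effect_landuse_alien",
               "richness_effect_native", "richness_effect_alien")) {
    v <- cfg[[nm]]
    if (length(v) != 7 || any(v <= 0)) {
      stop_islandiv(sprintf("%s must be 7 positive multipliers", nm))
    }
    if (abs(v[1] - 1) > 1e-12) {
      stop_islandiv(sprintf("%s: the PriMin (first) entry is the baseline and must be 1", nm))
    }
    cfg[[nm]] <- setNames(v, LAND_USES)
  }
  if (cfg$native_pool_size < 1 || cfg$alien_pool_size < 1) {
    stop_islandiv("species pool sizes must be >= 1")
  }
  if (cfg$overdispersion < 0) stop_islandiv("overdispersion must be >= 0")
  if (cfg$unclassified_fraction < 0 || cfg$unclassified_fraction > 1) {
    stop_islandiv("unclassified_fraction must lie in [0, 1]")
  }
  if (max(cfg$land_use_probs) >= 1 - 1e-12 && cfg$sites_per_study < 2) {
    rlang::warn("degenerate config: single land use with < 2 sites per study")
  }
  structure(cfg, class = "sim_config")
}

#' Overdispersed count draws (gamma-Poisson)
#'
#' The count primitive of the generator: negative-binomial draws
#' parameterised by mean `mu` and quadratic overdispersion `theta`
#' (`Var = mu + theta * mu^2`). `theta = 0` is exactly Poisson.
#'
#' @param n Number of draws.
#' @param mu Mean(s), recycled to length `n`.
#' @param theta Overdispersion coefficient (>= 0).
#' @return Integer-valued numeric vector of counts.
#' @export
rcount_overdispersed <- function(n, mu, theta) {
  if (theta < 0) stop_islandiv("theta must be >= 0")
  if (theta == 0) return(rpois(n, mu))
  rnbinom(n, mu = mu, size = 1 / theta)
}

# zero-truncated gamma-Poisson draws by rejection; as mu -> 0 the truncated
# distribution degenerates to a point mass at 1, so tiny means short-circuit
r_ztcount <- function(mu, theta) {
  n <- length(mu)
  if (n == 0) return(numeric(0))
  out <- numeric(n)
  tiny <- mu < 1e-3
  out[tiny] <- 1
  todo <- which(!tiny)
  iter <- 0L
  while (length(todo) > 0 && iter < 1000L) {
    iter <- iter + 1L
    draw <- rcount_overdispersed(length(todo), mu[todo], theta)
    out[todo] <- draw
    todo <- todo[draw == 0]
  }
  out[todo] <- 1
  out
}

# invert the zero-truncated mean: find NB mean m with m / (1 - P0(m)) = target
# (vectorised bisection; targets below 1 are floored, truncation forces >= 1)
ztnb_mean_param <- function(target, theta) {
  target <- pmax(target, 1 + 1e-8)
  lo <- rep(1e-12, length(target))
  hi <- target
  p0 <- function(m) if (theta > 0) (1 + theta * m)^(-1 / theta) else exp(-m)
  for (i in seq_len(80)) {
    mid <- (lo + hi) / 2
    below <- mid / (1 - p0(mid)) < target
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  (lo + hi) / 2
}

#' Simulate a hierarchical island assemblage dataset
#'
#' Draws a full synthetic dataset in the canonical format: an assemblage
#' table, a site table and an island table, plus a truth record storing
#' every generating parameter and the per-site expected abundance and
#' richness for each status.
#'
#' Expected site-level total abundance equals
#' `baseline * land-use effect * exp(study + block + island + slope deviations)`
#' exactly: the expected total is allocated across the species actually
#' present, and counts for present species are zero-truncated gamma-Poisson
#' with conditional means scaled to preserve the site total in expectation.
#' Species presence is Bernoulli with probability proportional to the
#' richness effect, a geographic distance-decay retention (species are
#' anchored at random points; retention declines in ln distance from the
#' anchor at rate `decay_rate_geo`, which induces distance decay of
#' compositional similarity), an island-isolation multiplier for aliens, and
#' gamma site-level heterogeneity tied to `overdispersion`.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `sim_dataset` with elements `assemblage`, `sites`,
#'   `islands` (canonical tibbles) and `truth`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  lu <- LAND_USES

  islands <- tibble::tibble(
    island_id = sprintf("I%02d", seq_len(config$n_islands)),
    area_km2 = rlnorm(config$n_islands, log(2000), 1.2),
    surrounding_landmass = runif(config$n_islands, 0.2, 1.2),
    gdp_per_capita = rlnorm(config$n_islands, log(20000), 0.6),
    center_lon = runif(config$n_islands, -160, 160),
    center_lat = runif(config$n_islands, -40, 40)
  )
  slm_center <- mean(islands$surrounding_landmass)
  iso_mult <- exp(config$island_isolation_effect_alien *
                    (islands$surrounding_landmass - slm_center))

  # species pools per island; classification failure at the species level
  pools <- purrr::map(seq_len(config$n_islands), function(i) {
    n_n <- config$native_pool_size
    n_a <- config$alien_pool_size
    tibble::tibble(
      taxon_id = c(sprintf("%s_N%03d", islands$island_id[i], seq_len(n_n)),
                   sprintf("%s_A%03d", islands$island_id[i], seq_len(n_a))),
      true_status = rep(c("native", "alien"), c(n_n, n_a)),
      obs_status = ifelse(
        runif(n_n + n_a) < config$unclassified_fraction,
        "unknown", rep(c("native", "alien"), c(n_n, n_a))),
      abund_mult = rlnorm(n_n + n_a, -0.125, 0.5)
    )
  })

  n_st <- config$n_studies
  study_island <- sample(rep_len(seq_len(config$n_islands), n_st))
  studies <- tibble::tibble(
    study_id = sprintf("S%02d", seq_len(n_st)),
    source_id = sprintf("P%02d", ceiling(seq_len(n_st) / 2)),
    island_idx = study_island,
    island_id = islands$island_id[study_island],
    metric_kind = ifelse(runif(n_st) < config$occurrence_fraction,
                         "occurrence", "abundance"),
    max_linear_extent = exp(runif(n_st, log(20), log(500))),
    study_int = rnorm(n_st, 0, config$study_sd),
    island_int = rnorm(config$n_islands, 0, config$island_sd)[study_island]
  )
  slope_dev <- matrix(rnorm(n_st * 7, 0, config$slope_sd), n_st, 7,
                      dimnames = list(studies$study_id, lu))

  site_rows <- list()
  occ_rows <- list()
  truth_rows <- list()

  for (s in seq_len(n_st)) {
    nsite <- config$sites_per_study
    center_lon <- islands$center_lon[studies$island_idx[s]] + runif(1, -0.4, 0.4)
    center_lat <- islands$center_lat[studies$island_idx[s]] + runif(1, -0.4, 0.4)
    blocks <- sprintf("%s_B%d", studies$study_id[s],
                      rep_len(seq_len(config$blocks_per_study), nsite))
    block_int <- rnorm(config$blocks_per_study, 0, config$block_sd)
    names(block_int) <- sprintf("%s_B%d", studies$study_id[s],
                                seq_len(config$blocks_per_study))
    site <- tibble::tibble(
      site_id = sprintf("%s_s%02d", studies$study_id[s], seq_len(nsite)),
      study_id = studies$study_id[s],
      block_id = blocks,
      island_id = studies$island_id[s],
      longitude = center_lon + runif(nsite, -0.5, 0.5),
      latitude = pmax(pmin(center_lat + runif(nsite, -0.5, 0.5), 89), -89),
      land_use = sample(lu, nsite, replace = TRUE,
                        prob = config$land_use_probs),
      altitude = runif(nsite, 0, 800)
    )
    site$hpd_raw <- rlnorm(nsite, log(5) + 2 * (site$land_use == "Urban") +
                             (site$land_use %in% c("Cropland", "Pasture")), 1)
    site$dist_road_raw <- rlnorm(nsite, log(3000) -
                                   1.5 * (site$land_use == "Urban") -
                                   0.7 * (site$land_use %in%
                                            c("Cropland", "Pasture")), 0.8)
    site$tmax <- 32 - 0.006 * site$altitude - 0.15 * abs(site$latitude) +
      rnorm(nsite, 0, 1)
    site$tmin <- site$tmax - runif(nsite, 6, 12)
    site$precip_wet <- rlnorm(nsite, log(320), 0.3)
    site$precip_dry <- rlnorm(nsite, log(60), 0.5)
    site$max_linear_extent <- studies$max_linear_extent[s]

    pool <- pools[[studies$island_idx[s]]]
    n_sp <- nrow(pool)
    anchor_lon <- runif(n_sp, min(site$longitude), max(site$longitude))
    anchor_lat <- runif(n_sp, min(site$latitude), max(site$latitude))
    # sites x species great-circle distances to each species' anchor point
    dmat <- sapply(seq_len(n_sp), function(k) {
      geographic_distance(site$longitude, site$latitude,
                          anchor_lon[k], anchor_lat[k])
    })
    retention <- (1 + dmat / 100)^(-config$decay_rate_geo)
    # normalise within species so decay concentrates occurrences near the
    # anchor without changing the species' mean occupancy across sites
    retention <- sweep(retention, 2, colMeans(retention), "/")

    theta <- config$overdispersion
    for (st_lab in c("native", "alien")) {
      is_st <- pool$true_status == st_lab
      base_occ <- if (st_lab == "native") config$base_occupancy_native else
        config$base_occupancy_alien
      base_ab <- if (st_lab == "native") config$base_abundance_native else
        config$base_abundance_alien
      rich_eff <- config[[paste0("richness_effect_", st_lab)]]
      ab_eff <- config[[paste0("effect_landuse_", st_lab)]]
      iso <- if (st_lab == "alien") iso_mult[studies$island_idx[s]] else 1
      # gamma site-level occupancy heterogeneity (mean 1, CV^2 = theta / 4)
      # -> overdispersed richness, so an observation-level random effect has
      # signal to absorb
      g_site <- if (theta > 0) {
        rgamma(nsite, shape = 4 / theta, rate = 4 / theta)
      } else rep(1, nsite)

      p_occ <- pmin((base_occ * rich_eff[site$land_use] * iso * g_site) *
                      retention[, is_st, drop = FALSE], 0.98)
      present <- matrix(rbinom(length(p_occ), 1, p_occ), nrow = nsite)

      a_target <- base_ab * ab_eff[site$land_use] *
        exp(studies$study_int[s] + block_int[site$block_id] +
              studies$island_int[s] +
              slope_dev[studies$study_id[s], site$land_use])

      mult <- pool$abund_mult[is_st]
      txid <- pool$taxon_id[is_st]
      obs_status <- pool$obs_status[is_st]

      truth_rows[[length(truth_rows) + 1]] <- tibble::tibble(
        site_id = site$site_id, study_id = studies$study_id[s],
        status = st_lab, land_use = site$land_use,
        expected_abundance = a_target,
        expected_richness = rowSums(p_occ))

      idx <- which(present == 1, arr.ind = TRUE)
      if (nrow(idx) == 0) next
      if (studies$metric_kind[s] == "occurrence") {
        meas <- rep(1, nrow(idx))
      } else {
        # allocate the site expected total across the *classified* species
        # present, so the classified total abundance the analysis sees has
        # expectation a_target exactly; unclassified species ride along at
        # the same per-capita scale
        classified <- obs_status != "unknown"
        sum_mult_cl <- as.vector(present[, classified, drop = FALSE] %*%
                                   mult[classified])
        sum_mult_all <- as.vector(present %*% mult)
        denom <- ifelse(sum_mult_cl > 0, sum_mult_cl, sum_mult_all)
        t_k <- a_target[idx[, 1]] * mult[idx[, 2]] / denom[idx[, 1]]
        meas <- r_ztcount(ztnb_mean_param(t_k, theta), theta)
      }
      occ_rows[[length(occ_rows) + 1]] <- tibble::tibble(
        source_id = studies$source_id[s],
        study_id = studies$study_id[s],
        block_id = site$block_id[idx[, 1]],
        site_id = site$site_id[idx[, 1]],
        taxon_id = txid[idx[, 2]],
        status = obs_status[idx[, 2]],
        measurement = meas,
        metric_kind = studies$metric_kind[s],
        sampling_effort = 1)
    }
    site_rows[[s]] <- site
  }

  sites <- as_sites(dplyr::bind_rows(site_rows))
  assemblage <- as_assemblage(dplyr::bind_rows(occ_rows))
  truth <- list(
    config = config,
    islands = dplyr::mutate(islands, iso_mult = iso_mult),
    slm_center = slm_center,
    studies = studies,
    slope_dev = slope_dev,
    site_truth = dplyr::bind_rows(truth_rows),
    pools = dplyr::bind_rows(pools)
  )
  structure(list(assemblage = assemblage,
                 sites = dplyr::select(sites, -dplyr::any_of(c("center_lon",
                                                               "center_lat"))),
                 islands = dplyr::select(islands, -"center_lon", -"center_lat"),
                 truth = truth),
            class = "sim_dataset")
}

#' Tabulate generating effects on the analysis scale
#'
#' Expresses the generator's land-use effects both as multiplicative factors
#' and as percentage change versus the `PriMin` baseline, for direct
#' comparison with back-transformed model estimates.
#'
#' @param truth The `truth` element of a [simulate_dataset()] result.
#' @return A tibble with columns `status`, `channel` (abundance/richness),
#'   `land_use`, `multiplier`, `percent_change`.
#' @export
truth_report <- function(truth) {
  cfg <- truth$config
  grids <- expand.grid(status = c("native", "alien"),
                       channel = c("abundance", "richness"),
                       stringsAsFactors = FALSE)
  purrr::pmap_dfr(grids, function(status, channel) {
    eff <- if (channel == "abundance") {
      cfg[[paste0("effect_landuse_", status)]]
    } else {
      cfg[[paste0("richness_effect_", status)]]
    }
    tibble::tibble(status = status, channel = channel,
                   land_use = LAND_USES, multiplier = unname(eff),
                   percent_change = 100 * (unname(eff) - 1))
  })
}
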