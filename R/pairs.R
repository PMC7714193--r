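#' Richness-based asymmetric Jaccard similarity
#'
#' `J_R = S_ij / S_j`: the share of site j's taxa that also occur at site i.
#' Equals 1 when all taxa at site j are present at site i (including
#' nestedness of j within i), 0 when the sites share no taxa, and is
#' undefined (`NA`) when site j has no taxa.
#'
#' @param taxa_i,taxa_j Character vectors of taxon identifiers present at
#'   sites i and j.
#' @return A number in `[0, 1]`, or `NA` when undefined.
#' @export
jaccard_richness_asym <- function(taxa_i, taxa_j) {
  taxa_i <- unique(taxa_i)
  taxa_j <- unique(taxa_j)
  if (length(taxa_j) == 0) return(NA_real_)
  length(intersect(taxa_i, taxa_j)) / length(taxa_j)
}

#' Abundance-based asymmetric Jaccard similarity
#'
#' `J_A = A_ij / A_j`, where `A_ij` is the summed abundance at site j of taxa
#' common to both sites and `A_j` the total abundance at site j. Undefined
#' (`NA`) when site j has zero total abundance.
#'
#' @param abund_i,abund_j Named numeric vectors (taxon -> abundance >= 0) for
#'   sites i and j.
#' @return A number in `[0, 1]`, or `NA` when undefined.
#' @export
jaccard_abundance_asym <- function(abund_i, abund_j) {
  if (any(abund_i < 0, na.rm = TRUE) || any(abund_j < 0, na.rm = TRUE)) {
    stop_islandiv("abundances must be >= 0")
  }
  total_j <- sum(abund_j)
  if (length(abund_j) == 0 || total_j == 0) return(NA_real_)
  shared <- intersect(names(abund_i)[abund_i > 0], names(abund_j))
  sum(abund_j[shared]) / total_j
}

#' Great-circle distance between coordinates
#'
#' Haversine distance on a sphere of radius 6,378,137 m (vectorised).
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in WGS84 decimal degrees.
#' @return Distance(s) in metres.
#' @export
geographic_distance <- function(lon1, lat1, lon2, lat2) {
  n <- max(length(lon1), length(lat1), length(lon2), length(lat2))
  p1 <- cbind(rep_len(lon1, n), rep_len(lat1, n))
  p2 <- cbind(rep_len(lon2, n), rep_len(lat2, n))
  geosphere::distHaversine(p1, p2, r = 6378137)
}

#' Transform geographic distance to the adjacency-referenced log scale
#'
#' Distances are divided by the median maximum linear extent of the sites in
#' the dataset (which reflects site size) and ln-transformed, so a
#' transformed distance of zero corresponds to adjacent sites.
#'
#' @param geo_dist_m Pairwise distance(s) in metres (> 0; zero-distance pairs
#'   must have been excluded upstream).
#' @param median_mle_m Median maximum linear extent in metres (> 0).
#' @return `ln(geo_dist_m / median_mle_m)`.
#' @export
transform_geo <- function(geo_dist_m, median_mle_m) {
  if (any(geo_dist_m <= 0)) {
    stop_islandiv("zero or negative geographic distance reached transform_geo; such pairs must be excluded upstream")
  }
  if (median_mle_m <= 0) stop_islandiv("median_mle_m must be > 0")
  log(geo_dist_m / median_mle_m)
}

# the five environmental variables entering Gower's distance
ENV_VARS <- c("altitude", "tmax", "tmin", "precip_wet", "precip_dry")

#' Gower environmental distance between two sites
#'
#' Mean over altitude and four bioclimatic variables of the absolute
#' difference divided by the variable's range across the modelling dataset;
#' zero-range variables are dropped from the mean. Undefined (`NA`) when any
#' variable is missing for either site.
#'
#' @param site_a,site_b Single-row site data (lists or 1-row data frames with
#'   the five environmental variables).
#' @param ranges Named list/vector of variable ranges (max - min) computed
#'   over the modelling dataset, as produced by [gower_ranges()].
#' @return A number in `[0, 1]`, or `NA`.
#' @export
environmental_distance <- function(site_a, site_b, ranges) {
  vals_a <- vapply(ENV_VARS, function(v) as.numeric(site_a[[v]]), numeric(1))
  vals_b <- vapply(ENV_VARS, function(v) as.numeric(site_b[[v]]), numeric(1))
  if (anyNA(vals_a) || anyNA(vals_b)) return(NA_real_)
  rng <- vapply(ENV_VARS, function(v) as.numeric(ranges[[v]]), numeric(1))
  keep <- rng > 0
  if (!any(keep)) return(NA_real_)
  mean(abs(vals_a[keep] - vals_b[keep]) / rng[keep])
}

#' Variable ranges for Gower distance
#'
#' @param sites The modelling site table.
#' @return Named list of ranges (max - min) of the five environmental
#'   variables.
#' @export
gower_ranges <- function(sites) {
  setNames(lapply(ENV_VARS, function(v) {
    r <- range(sites[[v]], na.rm = TRUE)
    r[2] - r[1]
  }), ENV_VARS)
}

#' Logit transform with boundary adjustment
#'
#' Compresses `[0, 1]` to `[0.01, 0.99]` (`y -> 0.01 + 0.98 y`, strictly
#' monotone) before applying the logit, so similarities of exactly 0 or 1
#' stay finite.
#'
#' @param y Numeric vector in `[0, 1]`.
#' @return Logit-transformed values.
#' @export
logit_adjusted <- function(y) {
  if (any(y < 0 | y > 1, na.rm = TRUE)) {
    stop_islandiv("logit_adjusted input must lie in [0, 1]")
  }
  qlogis(0.01 + 0.98 * y)
}

#' Inverse of [logit_adjusted()]
#' @param l Values on the adjusted logit scale.
#' @return Similarities in `[0, 1]` (clamped).
#' @export
inv_logit_adjusted <- function(l) {
  pmin(pmax((plogis(l) - 0.01) / 0.98, 0), 1)
}

#' Build the ordered pairwise comparison table
#'
#' Constructs all ordered within-study site pairs (forward and reverse) with
#' asymmetric Jaccard similarities per status, land-use contrasts, geographic
#' and environmental distances, transforms and weights, applying the
#' study- and pair-level exclusion rules:
#' studies recording presence/absence only, studies whose sampling effort
#' varies among sites, and studies that sampled a single species contribute
#' no pairs (so richness- and abundance-based models use the same studies);
#' pairs with zero geographic distance (coordinate imprecision), undefined
#' environmental distance (missing data) or an undefined similarity (site j
#' empty for that status) are dropped.
#'
#' @param occurrences A validated assemblage tibble with statuses attached.
#' @param sites A validated site tibble.
#' @param statuses Statuses to build comparisons for.
#' @return A tibble with one row per (ordered pair, status): `study_id`,
#'   `site_i`, `site_j`, `status`, `j_r`, `j_a`, `logit_j_r`, `logit_j_a`,
#'   `landuse_contrast` (`"<land use of i>-<land use of j>"`, 49 levels,
#'   baseline `PriMin-PriMin`), `geo_dist_m`, `geo_dist_t`, `env_dist`,
#'   `env_dist_t` (cube root), `weight` (proportion of classified species at
#'   site j). Attributes: `exclusions` (counts per rule), `median_mle_m`,
#'   `gower_ranges`.
#' @export
build_pair_table <- function(occurrences, sites,
                             statuses = c("native", "alien")) {
  occ <- tibble::as_tibble(occurrences)
  sites <- tibble::as_tibble(sites)
  check_columns(sites, c("site_id", "study_id", "land_use", "longitude",
                         "latitude", "max_linear_extent"), "sites")

  excl <- c(study_occurrence_only = 0L, study_varying_effort = 0L,
            study_single_species = 0L, pair_zero_geo_dist = 0L,
            pair_missing_env = 0L, pair_undefined_similarity = 0L)

  study_tab <- dplyr::summarise(
    dplyr::group_by(occ, .data$study_id),
    metric_kind = .data$metric_kind[1],
    effort_varies = dplyr::n_distinct(.data$sampling_effort) > 1,
    n_species = dplyr::n_distinct(.data$taxon_id),
    .groups = "drop")
  excl["study_occurrence_only"] <-
    sum(study_tab$metric_kind == "occurrence")
  excl["study_varying_effort"] <-
    sum(study_tab$effort_varies & study_tab$metric_kind == "abundance")
  excl["study_single_species"] <-
    sum(study_tab$n_species < 2 & study_tab$metric_kind == "abundance" &
          !study_tab$effort_varies)
  eligible <- study_tab$study_id[study_tab$metric_kind == "abundance" &
                                   !study_tab$effort_varies &
                                   study_tab$n_species >= 2]

  occ <- dplyr::filter(occ, .data$study_id %in% eligible)
  weights <- site_weight(occ)
  occ <- dplyr::filter(occ, .data$measurement > 0)
  model_sites <- dplyr::filter(sites, .data$study_id %in% eligible,
                               .data$site_id %in% unique(occ$site_id))
  if (nrow(model_sites) == 0) {
    out <- tibble::tibble(
      study_id = character(), site_i = character(), site_j = character(),
      status = character(), j_r = numeric(), j_a = numeric(),
      logit_j_r = numeric(), logit_j_a = numeric(),
      landuse_contrast = factor(character()), geo_dist_m = numeric(),
      geo_dist_t = numeric(), env_dist = numeric(), env_dist_t = numeric(),
      weight = numeric())
    attr(out, "exclusions") <- excl
    return(out)
  }

  ranges <- gower_ranges(model_sites)
  median_mle <- median(model_sites$max_linear_extent, na.rm = TRUE)

  # per (site, status): taxa sets and abundance vectors of classified taxa
  comp <- dplyr::filter(occ, .data$status %in% statuses)
  comp_split <- split(comp, list(comp$site_id, comp$status), drop = TRUE)

  contrast_levels <- as.vector(outer(LAND_USES, LAND_USES,
                                     function(a, b) paste(a, b, sep = "-")))
  contrast_levels <- c("PriMin-PriMin",
                       setdiff(contrast_levels, "PriMin-PriMin"))

  rows <- list()
  for (sid in unique(model_sites$study_id)) {
    ss <- model_sites[model_sites$study_id == sid, , drop = FALSE]
    n <- nrow(ss)
    if (n < 2) next
    idx <- which(outer(seq_len(n), seq_len(n), "!="), arr.ind = TRUE)
    i <- idx[, 1]; j <- idx[, 2]
    gd <- geographic_distance(ss$longitude[i], ss$latitude[i],
                              ss$longitude[j], ss$latitude[j])
    zero_gd <- gd <= 0
    excl["pair_zero_geo_dist"] <- excl["pair_zero_geo_dist"] +
      sum(zero_gd) * length(statuses)
    ed <- vapply(seq_along(i), function(k) {
      environmental_distance(ss[i[k], ], ss[j[k], ], ranges)
    }, numeric(1))
    na_ed <- is.na(ed) & !zero_gd
    excl["pair_missing_env"] <- excl["pair_missing_env"] +
      sum(na_ed) * length(statuses)
    keep <- !zero_gd & !na_ed

    for (st in statuses) {
      get_comp <- function(site) comp_split[[paste(site, st, sep = ".")]]
      for (k in which(keep)) {
        ci <- get_comp(ss$site_id[i[k]])
        cj <- get_comp(ss$site_id[j[k]])
        taxa_i <- if (is.null(ci)) character(0) else ci$taxon_id
        taxa_j <- if (is.null(cj)) character(0) else cj$taxon_id
        jr <- jaccard_richness_asym(taxa_i, taxa_j)
        ab_i <- if (is.null(ci)) setNames(numeric(0), character(0)) else
          setNames(ci$measurement, ci$taxon_id)
        ab_j <- if (is.null(cj)) setNames(numeric(0), character(0)) else
          setNames(cj$measurement, cj$taxon_id)
        ja <- jaccard_abundance_asym(ab_i, ab_j)
        if (is.na(jr) || is.na(ja)) {
          excl["pair_undefined_similarity"] <-
            excl["pair_undefined_similarity"] + 1L
          next
        }
        wj <- weights$weight[match(ss$site_id[j[k]], weights$site_id)]
        rows[[length(rows) + 1]] <- tibble::tibble(
          study_id = sid,
          site_i = ss$site_id[i[k]], site_j = ss$site_id[j[k]],
          status = st, j_r = jr, j_a = ja,
          landuse_contrast = paste(as.character(ss$land_use[i[k]]),
                                   as.character(ss$land_use[j[k]]),
                                   sep = "-"),
          geo_dist_m = gd[k], env_dist = ed[k],
          weight = ifelse(is.na(wj), 1, wj))
      }
    }
  }

  out <- if (length(rows) > 0) dplyr::bind_rows(rows) else
    tibble::tibble(study_id = character(), site_i = character(),
                   site_j = character(), status = character(),
                   j_r = numeric(), j_a = numeric(),
                   landuse_contrast = character(), geo_dist_m = numeric(),
                   env_dist = numeric(), weight = numeric())
  out$landuse_contrast <- factor(out$landuse_contrast,
                                 levels = contrast_levels)
  out$status <- factor(out$status, levels = c("native", "alien"))
  if (nrow(out) > 0) {
    out$geo_dist_t <- transform_geo(out$geo_dist_m, median_mle)
    out$env_dist_t <- out$env_dist^(1 / 3)
    out$logit_j_r <- logit_adjusted(out$j_r)
    out$logit_j_a <- logit_adjusted(out$j_a)
  } else {
    out$geo_dist_t <- numeric(0)
    out$env_dist_t <- numeric(0)
    out$logit_j_r <- numeric(0)
    out$logit_j_a <- numeric(0)
  }
  out <- dplyr::select(
    out, "study_id", "site_i", "site_j", "status", "j_r", "j_a",
    "logit_j_r", "logit_j_a", "landuse_contrast", "geo_dist_m", "geo_dist_t",
    "env_dist", "env_dist_t", "weight")
  attr(out, "exclusions") <- excl
  attr(out, "median_mle_m") <- median_mle
  attr(out, "gower_ranges") <- ranges
  out
}
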