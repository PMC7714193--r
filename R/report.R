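z_crit <- function(conf_level) qnorm(1 - (1 - conf_level) / 2)

new_effects <- function(df, scale) {
  structure(df, class = c("islandiv_effects", class(df)), scale = scale)
}

#' Percentage change in abundance from a square-root-scale fit
#'
#' Back-transforms a gaussian abundance fit (response on the square-root
#' scale) into percentage changes relative to the baseline land use. With
#' `s0` the predicted baseline value and `s1` the predicted group value on
#' the square-root scale, the change is `(s1^2 / s0^2 - 1) * 100`; confidence
#' limits apply the same back-transform to the Wald limits of the group
#' contrast, so intervals are asymmetric. Numeric covariates (including
#' orthogonal polynomial columns) sit at zero.
#'
#' @param fit An `ln_fit` of a square-root-scale abundance response.
#' @param status Status level(s) to report (present in the fit), or `NULL`
#'   for fits without a status term.
#' @param baseline Baseline land-use level (default `"PriMin"`).
#' @param conf_level Confidence level for the Wald intervals.
#' @return An effects tibble: `status`, `land_use`, `percent_change`,
#'   `ci_low`, `ci_high`, `scale`. The baseline row is exactly 0 with a
#'   zero-width interval.
#' @export
percent_change_sqrt <- function(fit, status = NULL, baseline = "PriMin",
                                conf_level = 0.95) {
  stopifnot(inherits(fit, "ln_fit"))
  z <- z_crit(conf_level)
  statuses <- if (is.null(status)) NA_character_ else status
  lus <- fit$xlev[["land_use"]]
  if (is.null(lus)) stop_islandiv("fit has no land_use term")
  out <- purrr::map_dfr(statuses, function(st) {
    at0 <- list(land_use = baseline)
    if (!is.na(st)) at0$status <- st
    x0 <- design_row(fit, at = at0)
    s0 <- sum(x0 * fit$coefficients)
    if (s0 <= 0) {
      stop_islandiv("degenerate baseline: predicted square-root-scale value <= 0")
    }
    purrr::map_dfr(lus, function(lu) {
      at1 <- at0
      at1$land_use <- lu
      x1 <- design_row(fit, at = at1)
      d <- x1 - x0
      delta <- sum(d * fit$coefficients)
      se <- sqrt(drop(t(d) %*% fit$vcov %*% d))
      s1 <- s0 + delta
      lims <- s0 + delta + c(-1, 1) * z * se
      tibble::tibble(
        status = st, land_use = lu, baseline = baseline,
        percent_change = 100 * (s1^2 / s0^2 - 1),
        ci_low = 100 * (lims[1]^2 / s0^2 - 1),
        ci_high = 100 * (lims[2]^2 / s0^2 - 1))
    })
  })
  new_effects(out, scale = "sqrt_abundance")
}

#' Percentage change in richness from a log-link fit
#'
#' Back-transforms a Poisson log-link richness fit into percentage changes
#' versus the baseline land use: `(exp(beta) - 1) * 100` for the group's
#' log-scale contrast `beta`, with the Wald interval exponentiated
#' (asymmetric on the percentage scale).
#'
#' @inheritParams percent_change_sqrt
#' @return An effects tibble as in [percent_change_sqrt()].
#' @export
percent_change_log <- function(fit, status = NULL, baseline = "PriMin",
                               conf_level = 0.95) {
  stopifnot(inherits(fit, "ln_fit"))
  z <- z_crit(conf_level)
  statuses <- if (is.null(status)) NA_character_ else status
  lus <- fit$xlev[["land_use"]]
  if (is.null(lus)) stop_islandiv("fit has no land_use term")
  out <- purrr::map_dfr(statuses, function(st) {
    at0 <- list(land_use = baseline)
    if (!is.na(st)) at0$status <- st
    x0 <- design_row(fit, at = at0)
    purrr::map_dfr(lus, function(lu) {
      at1 <- at0
      at1$land_use <- lu
      x1 <- design_row(fit, at = at1)
      d <- x1 - x0
      beta <- sum(d * fit$coefficients)
      se <- sqrt(drop(t(d) %*% fit$vcov %*% d))
      tibble::tibble(
        status = st, land_use = lu, baseline = baseline,
        percent_change = 100 * (exp(beta) - 1),
        ci_low = 100 * (exp(beta - z * se) - 1),
        ci_high = 100 * (exp(beta + z * se) - 1))
    })
  })
  new_effects(out, scale = "log_richness")
}

#' Compositional-similarity contrasts versus the PriMin-PriMin baseline
#'
#' From a similarity fit with a land-use-contrast term, extracts the 13 focal
#' contrasts per status — `PriMin` to each land use (how composition changes
#' when one site of the pair is converted) and each land use with itself
#' (within-land-use homogeneity) — relative to `PriMin-PriMin`, on the
#' adjusted-logit scale and back-transformed to similarity. Contrasts whose
#' data come from fewer than `min_studies` studies are flagged unreliable;
#' contrasts absent from the fit are returned as missing rows.
#'
#' @param fit An `ln_fit` of a logit-similarity response with
#'   `landuse_contrast` (and optionally `status`) terms.
#' @param pair_data The pair table used for fitting (to count contributing
#'   studies per contrast).
#' @param min_studies Reliability threshold (default 3).
#' @param conf_level Confidence level.
#' @return A tibble with `status`, `contrast`, `logit_diff`, `se`, `ci_low`,
#'   `ci_high` (logit scale), `similarity`, `baseline_similarity`,
#'   `n_studies`, `reliable`.
#' @export
similarity_contrast_table <- function(fit, pair_data, min_studies = 3,
                                      conf_level = 0.95) {
  stopifnot(inherits(fit, "ln_fit"))
  z <- z_crit(conf_level)
  statuses <- fit$xlev[["status"]] %||% NA_character_
  focal <- unique(c(paste("PriMin", LAND_USES, sep = "-"),
                    paste(LAND_USES, LAND_USES, sep = "-")))
  counts <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(pair_data), .data$status,
                    .data$landuse_contrast),
    n_studies = dplyr::n_distinct(.data$study_id), .groups = "drop")
  purrr::map_dfr(statuses, function(st) {
    at0 <- list(landuse_contrast = "PriMin-PriMin")
    if (!is.na(st)) at0$status <- st
    x0 <- design_row(fit, at = at0)
    l0 <- sum(x0 * fit$coefficients)
    purrr::map_dfr(focal, function(ct) {
      ns <- counts$n_studies[counts$status == st &
                               counts$landuse_contrast == ct]
      ns <- if (length(ns) == 0) 0L else ns
      at1 <- at0
      at1$landuse_contrast <- ct
      row <- tryCatch({
        x1 <- design_row(fit, at = at1)
        d <- x1 - x0
        delta <- sum(d * fit$coefficients)
        se <- sqrt(drop(t(d) %*% fit$vcov %*% d))
        tibble::tibble(
          status = st, contrast = ct, logit_diff = delta, se = se,
          ci_low = delta - z * se, ci_high = delta + z * se,
          similarity = inv_logit_adjusted(l0 + delta),
          baseline_similarity = inv_logit_adjusted(l0))
      }, islandiv_missing_level = function(e) {
        tibble::tibble(status = st, contrast = ct, logit_diff = NA_real_,
                       se = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                       similarity = NA_real_,
                       baseline_similarity = inv_logit_adjusted(l0))
      })
      row$n_studies <- ns
      row$reliable <- ns >= min_studies
      row
    })
  })
}

#' Share of aliens among classified species and individuals
#'
#' Raw data summary: the mean over sites in a land use of the alien share of
#' classified species richness and of classified total abundance, as
#' percentages.
#'
#' @param diversity Output of [site_diversity()]; must carry a `land_use`
#'   column (join with the site table first, or pass `sites`).
#' @param land_use Land-use level to summarise (default `"PriMin"`).
#' @param sites Optional site table supplying `land_use` per site.
#' @return A tibble with `land_use`, `share_richness`, `share_abundance`
#'   (percent), `n_sites`; shares are `NA` when no site qualifies.
#' @export
percent_alien_share <- function(diversity, land_use = "PriMin",
                                sites = NULL) {
  div <- tibble::as_tibble(diversity)
  if (!"land_use" %in% names(div)) {
    if (is.null(sites)) {
      stop_islandiv("diversity lacks land_use; supply `sites` to join it")
    }
    div <- dplyr::left_join(
      div, dplyr::select(tibble::as_tibble(sites), "site_id", "land_use"),
      by = "site_id")
  }
  lu <- land_use
  wide <- tidyr::pivot_wider(
    dplyr::select(dplyr::filter(div, .data$land_use == lu),
                  "site_id", "status", "total_abundance",
                  "species_richness"),
    names_from = "status",
    values_from = c("total_abundance", "species_richness"))
  if (nrow(wide) == 0) {
    return(tibble::tibble(land_use = lu, share_richness = NA_real_,
                          share_abundance = NA_real_, n_sites = 0L))
  }
  rich_tot <- wide$species_richness_native + wide$species_richness_alien
  rich_share <- ifelse(rich_tot > 0,
                       100 * wide$species_richness_alien / rich_tot, NA)
  ab_tot <- wide$total_abundance_native + wide$total_abundance_alien
  ab_share <- ifelse(!is.na(ab_tot) & ab_tot > 0,
                     100 * wide$total_abundance_alien / ab_tot, NA)
  tibble::tibble(
    land_use = lu,
    share_richness = mean(rich_share, na.rm = TRUE),
    share_abundance = mean(ab_share, na.rm = TRUE),
    n_sites = nrow(wide))
}

#' Run the full analysis pipeline on synthetic data
#'
#' Orchestrates simulate -> site metrics -> pair table -> model fits ->
#' permutation tests -> report tables, and returns every artefact plus a
#' manifest sufficient to reproduce the run (config, seeds, exclusion
#' counts, transform constants). With `out_dir` set, writes the canonical
#' CSVs, report tables and `manifest.json`.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional output directory.
#' @param permutations Run the permutation tests of the similarity model's
#'   status interactions (the slow stage).
#' @param n_perm Permutations per test.
#' @param alpha Retention threshold for backward simplification.
#' @return A list of class `islandiv_run` with elements `data`, `diversity`,
#'   `pairs`, `fits`, `effects`, `similarity`, `alien_share`,
#'   `permutation_tests`, `manifest`.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         permutations = TRUE, n_perm = 199, alpha = 0.05) {
  sim <- simulate_dataset(config)
  sites <- transform_pressures(sim$sites)

  div <- site_diversity(sim$assemblage)
  targets <- setNames(rep("whole_assemblage",
                          dplyr::n_distinct(div$study_id)),
                      unique(div$study_id))
  div <- apply_status_scope_rule(div, targets)
  div <- rescale_abundance(div)
  div <- dplyr::left_join(
    div, dplyr::select(sites, "site_id", "land_use", "hpd_t", "dist_t"),
    by = "site_id")
  div$status <- factor(div$status, levels = c("native", "alien"))
  div$land_use <- land_use_factor(div$land_use)

  abund_spec <- model_spec(
    response = "sqrt_rescaled_abundance",
    fixed = c("land_use", "status", "land_use:status"),
    random = "study_block", family = "gaussian", weights = "weight")
  rich_spec <- model_spec(
    response = "species_richness",
    fixed = c("land_use", "status", "land_use:status"),
    random = "study_block", family = "poisson", olre = TRUE,
    weights = "weight")
  abund_fit <- fit_mixed(div, abund_spec)
  rich_fit <- fit_mixed(div, rich_spec)

  pair_tab <- build_pair_table(sim$assemblage, sites)
  sim_spec <- model_spec(
    response = "logit_j_r",
    fixed = c("status", "landuse_contrast", "geo_dist_t", "env_dist_t",
              "status:landuse_contrast", "status:geo_dist_t",
              "status:env_dist_t"),
    random = "study", family = "gaussian", weights = "weight")
  sim_fit <- fit_mixed(pair_tab, sim_spec)

  perm_tests <- NULL
  if (permutations) {
    perm_seeds <- spawn_seeds(config$seed, 3)
    interactions <- c("status:landuse_contrast", "status:geo_dist_t",
                      "status:env_dist_t")
    perm_tests <- purrr::map(setNames(interactions, interactions),
                             function(tm) {
      red <- sim_spec
      red$fixed <- setdiff(sim_spec$fixed, tm)
      permutation_lr_test(pair_tab, sim_spec, red, n_perm = n_perm,
                          seed = perm_seeds[match(tm, interactions)])
    })
  }

  effects <- dplyr::bind_rows(
    dplyr::mutate(percent_change_sqrt(abund_fit,
                                      status = c("native", "alien")),
                  channel = "abundance"),
    dplyr::mutate(percent_change_log(rich_fit,
                                     status = c("native", "alien")),
                  channel = "richness"))
  similarity <- similarity_contrast_table(sim_fit, pair_tab)
  alien_share <- purrr::map_dfr(LAND_USES, function(lu) {
    percent_alien_share(div, land_use = lu)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("islandiv")),
    seed = config$seed,
    n_perm = if (permutations) n_perm else 0L,
    alpha = alpha,
    config = unclass(config),
    exclusions = as.list(attr(pair_tab, "exclusions")),
    median_mle_m = attr(pair_tab, "median_mle_m"),
    gower_ranges = attr(pair_tab, "gower_ranges"),
    pressure_scaling = attr(sites, "pressure_scaling"),
    n_sites = nrow(sim$sites),
    n_pairs = nrow(pair_tab))

  out <- structure(list(
    data = sim, diversity = div, pairs = pair_tab,
    fits = list(abundance = abund_fit, richness = rich_fit,
                similarity = sim_fit),
    effects = effects, similarity = similarity, alien_share = alien_share,
    permutation_tests = perm_tests, manifest = manifest),
    class = "islandiv_run")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_canonical(sim$assemblage, file.path(out_dir, "assemblage.csv"))
    write_canonical(sim$sites, file.path(out_dir, "sites.csv"))
    write_canonical(sim$islands, file.path(out_dir, "islands.csv"))
    write_canonical(div, file.path(out_dir, "site_diversity.csv"))
    write_canonical(pair_tab, file.path(out_dir, "pair_table.csv"))
    write_canonical(effects, file.path(out_dir, "effects.csv"))
    write_canonical(similarity, file.path(out_dir,
                                          "similarity_contrasts.csv"))
    write_canonical(alien_share, file.path(out_dir, "alien_share.csv"))
    if (!is.null(perm_tests)) {
      perm_json <- purrr::map(perm_tests, function(p) {
        list(observed = p$observed, p_value = p$p_value, n_perm = p$n_perm,
             tails = p$tails, null_values = p$null_values)
      })
      jsonlite::write_json(perm_json,
                           file.path(out_dir, "permutation_results.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  out
}
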