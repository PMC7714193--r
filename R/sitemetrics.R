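#' Per-site, per-status diversity responses
#'
#' Computes each site's total abundance (sum of measurements of taxa of the
#' given status, divided by the site's sampling effort when effort varies
#' among sites within the study) and species richness (number of distinct
#' taxa of that status with measurement > 0). Occurrence-only studies yield
#' missing abundance. Sites are listed for every requested status even when
#' no taxon of that status was recorded (zero richness / zero or missing
#' abundance), so downstream scope rules can act on complete site x status
#' grids.
#'
#' @param occurrences A validated assemblage tibble.
#' @param status Statuses to compute, subset of
#'   `c("native", "alien", "unknown")`.
#' @return A tibble with columns `site_id`, `study_id`, `block_id`,
#'   `island_id` (if present), `status`, `total_abundance`,
#'   `species_richness`, `weight` (proportion of the site's recorded taxa
#'   that are classified), `metric_kind`.
#' @export
site_diversity <- function(occurrences, status = c("native", "alien")) {
  status <- match.arg(status, STATUS_LEVELS, several.ok = TRUE)
  occ <- tibble::as_tibble(occurrences)
  check_columns(occ, c("study_id", "site_id", "taxon_id", "status",
                       "measurement", "metric_kind", "sampling_effort"),
                "occurrences")

  effort_varies <- dplyr::summarise(
    dplyr::group_by(occ, .data$study_id),
    effort_varies = dplyr::n_distinct(.data$sampling_effort) > 1,
    .groups = "drop")

  site_info <- dplyr::distinct(
    occ, .data$study_id, .data$site_id,
    dplyr::across(dplyr::any_of(c("block_id", "island_id"))),
    .data$metric_kind, .data$sampling_effort)
  site_info <- dplyr::left_join(site_info, effort_varies, by = "study_id")

  w <- site_weight(occ)

  per_status <- purrr::map_dfr(status, function(st) {
    sub <- dplyr::filter(occ, .data$status == st)
    agg <- dplyr::summarise(
      dplyr::group_by(sub, .data$study_id, .data$site_id),
      raw_abundance = sum(.data$measurement),
      species_richness = dplyr::n_distinct(
        .data$taxon_id[.data$measurement > 0]),
      .groups = "drop")
    out <- dplyr::left_join(site_info, agg, by = c("study_id", "site_id"))
    out$raw_abundance[is.na(out$raw_abundance)] <- 0
    out$species_richness[is.na(out$species_richness)] <- 0L
    out$total_abundance <- ifelse(
      out$metric_kind == "occurrence", NA_real_,
      ifelse(out$effort_varies,
             out$raw_abundance / out$sampling_effort,
             out$raw_abundance))
    out$status <- st
    out
  })

  per_status$weight <- w$weight[match(per_status$site_id, w$site_id)]
  dplyr::select(
    per_status,
    dplyr::any_of(c("site_id", "study_id", "block_id", "island_id")),
    "status", "total_abundance", "species_richness", "weight", "metric_kind")
}

#' Proportion of classified species per site
#'
#' A site's analysis weight is the share of its recorded taxa whose status
#' could be classified (status not `unknown`); sites keeping data for most of
#' their originally sampled species get more weight. Sites with no recorded
#' taxa get weight 1.
#'
#' @param occurrences A validated assemblage tibble.
#' @return A tibble with `site_id`, `n_recorded`, `n_classified`, `weight`.
#' @export
site_weight <- function(occurrences) {
  occ <- tibble::as_tibble(occurrences)
  check_columns(occ, c("site_id", "taxon_id", "status"), "occurrences")
  out <- dplyr::summarise(
    dplyr::group_by(occ, .data$site_id),
    n_recorded = dplyr::n_distinct(.data$taxon_id),
    n_classified = dplyr::n_distinct(
      .data$taxon_id[.data$status != "unknown"]),
    .groups = "drop")
  out$weight <- ifelse(out$n_recorded == 0, 1,
                       out$n_classified / out$n_recorded)
  out
}

#' Apply per-study status scope rules
#'
#' Studies that targeted the whole assemblage but whose classified records
#' all turned out to be one status get zero diversity metrics for the absent
#' status (for the metrics the study originally reported); studies that
#' deliberately targeted one status get missing metrics for the other.
#'
#' @param diversity Output of [site_diversity()].
#' @param study_targets Named character vector or two-column data frame
#'   (`study_id`, `target`) mapping each study to one of
#'   `"whole_assemblage"`, `"natives_only"`, `"aliens_only"`.
#' @return `diversity` with zeros / missings applied.
#' @export
apply_status_scope_rule <- function(diversity, study_targets) {
  if (is.data.frame(study_targets)) {
    targets <- setNames(as.character(study_targets$target),
                        study_targets$study_id)
  } else {
    targets <- study_targets
  }
  unknown <- setdiff(unique(diversity$study_id), names(targets))
  if (length(unknown) > 0) {
    stop_islandiv(sprintf("no target scope declared for study: %s",
                          paste(unknown, collapse = ", ")))
  }
  bad <- setdiff(unique(targets),
                 c("whole_assemblage", "natives_only", "aliens_only"))
  if (length(bad) > 0) {
    stop_islandiv(sprintf("unknown target scope: %s",
                          paste(bad, collapse = ", ")))
  }
  div <- tibble::as_tibble(diversity)
  present <- dplyr::summarise(
    dplyr::group_by(div, .data$study_id, .data$status),
    any_data = any(.data$species_richness > 0 |
                     (!is.na(.data$total_abundance) &
                        .data$total_abundance > 0)),
    .groups = "drop")

  out <- div
  for (sid in unique(div$study_id)) {
    tgt <- targets[[sid]]
    rows_n <- out$study_id == sid & out$status == "native"
    rows_a <- out$study_id == sid & out$status == "alien"
    if (tgt == "natives_only") {
      out$total_abundance[rows_a] <- NA_real_
      out$species_richness[rows_a] <- NA_integer_
    } else if (tgt == "aliens_only") {
      out$total_abundance[rows_n] <- NA_real_
      out$species_richness[rows_n] <- NA_integer_
    } else {
      has_n <- any(present$any_data[present$study_id == sid &
                                      present$status == "native"])
      has_a <- any(present$any_data[present$study_id == sid &
                                      present$status == "alien"])
      # whole-assemblage study whose classified records are all one status:
      # the absent status earns genuine zeros (for metrics the study reports)
      fill_zero <- function(rows) {
        abund_metric <- out$metric_kind[rows] != "occurrence"
        out$total_abundance[rows] <<- ifelse(abund_metric, 0, NA_real_)
        out$species_richness[rows] <<- 0L
      }
      if (has_n && !has_a) fill_zero(rows_a)
      if (has_a && !has_n) fill_zero(rows_n)
    }
  }
  out
}

#' Rescale abundance within studies and square-root transform
#'
#' Site total abundance is rescaled to `[0, 1]` within each study by dividing
#' by the study's maximum (a single shared scale across native and alien
#' rows), then square-root transformed. All-zero studies keep zeros.
#'
#' @param diversity Output of [site_diversity()] (possibly after
#'   [apply_status_scope_rule()]).
#' @return `diversity` with `rescaled_abundance` and
#'   `sqrt_rescaled_abundance` columns added.
#' @export
rescale_abundance <- function(diversity) {
  div <- tibble::as_tibble(diversity)
  check_columns(div, c("study_id", "total_abundance"), "diversity")
  mx <- dplyr::summarise(
    dplyr::group_by(div, .data$study_id),
    study_max = ifelse(all(is.na(.data$total_abundance)), NA_real_,
                       max(.data$total_abundance, na.rm = TRUE)),
    .groups = "drop")
  out <- dplyr::left_join(div, mx, by = "study_id")
  out$rescaled_abundance <- ifelse(
    is.na(out$total_abundance) | is.na(out$study_max), NA_real_,
    ifelse(out$study_max == 0, 0, out$total_abundance / out$study_max))
  out$sqrt_rescaled_abundance <- sqrt(out$rescaled_abundance)
  dplyr::select(out, -"study_max")
}

#' Transform human-pressure covariates for modelling
#'
#' `ln(x + 1)`-transforms human population density, ln-transforms distance to
#' nearest road (switching to `ln(x + 1)` when any zero distance occurs),
#' min-max rescales both to `[0, 1]` over the supplied modelling dataset, and
#' expands each into a 2-column orthonormal quadratic polynomial basis
#' (`stats::poly` contract: columns orthogonal with unit norm).
#'
#' @param sites A site tibble (needs `hpd_raw`, `dist_road_raw`).
#' @return `sites` with `hpd_t`, `dist_t` (rescaled ln transforms) added.
#'   The rescaling constants are attached as attribute `pressure_scaling`
#'   so later predictions can reproduce the transforms. Quadratic orthogonal
#'   polynomial terms are specified in model formulas as `poly(hpd_t, 2)` /
#'   `poly(dist_t, 2)`.
#' @export
transform_pressures <- function(sites) {
  out <- tibble::as_tibble(sites)
  check_columns(out, c("hpd_raw", "dist_road_raw"), "sites")
  hpd_ln <- log(out$hpd_raw + 1)
  dist_offset <- if (any(out$dist_road_raw == 0, na.rm = TRUE)) 1 else 0
  dist_ln <- log(out$dist_road_raw + dist_offset)
  rescale01 <- function(x, nm) {
    r <- range(x, na.rm = TRUE)
    if (diff(r) == 0) {
      stop_islandiv(sprintf(
        "cannot min-max rescale '%s': all values equal", nm))
    }
    (x - r[1]) / diff(r)
  }
  out$hpd_t <- rescale01(hpd_ln, "hpd_raw")
  out$dist_t <- rescale01(dist_ln, "dist_road_raw")
  attr(out, "pressure_scaling") <- list(
    hpd_range_ln = range(hpd_ln, na.rm = TRUE),
    dist_range_ln = range(dist_ln, na.rm = TRUE),
    dist_offset = dist_offset)
  out
}
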