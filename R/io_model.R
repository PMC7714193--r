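#' Read a long-format assemblage table
#'
#' Reads and validates taxon-by-site records: one row is a single abundance
#' measure or occurrence record of one taxon at one site within a study.
#' Records are organised hierarchically (source > study > block > site).
#'
#' @param path Path to a CSV file (UTF-8, comma-separated, header row).
#' @param schema Optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(site_id = "SSS", measurement = "Effort_corrected_measurement")`.
#' @return A validated tibble with columns `source_id`, `study_id`,
#'   `block_id`, `site_id`, `taxon_id`, `status`, `measurement`,
#'   `metric_kind`, `sampling_effort`.
#' @details Rows violating the data-model invariants (negative measurements,
#'   non-positive effort, duplicate `(study_id, site_id, taxon_id)` keys, a
#'   study mixing abundance and occurrence rows) are rejected with
#'   row-indexed diagnostics rather than silently dropped.
#' @export
read_assemblage <- function(path, schema = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      if (schema[[canon]] %in% names(raw)) {
        names(raw)[names(raw) == schema[[canon]]] <- canon
      }
    }
  }
  as_assemblage(raw)
}

#' Coerce and validate an in-memory assemblage table
#'
#' @param df A data frame with the canonical assemblage columns.
#' @return A validated tibble (see [read_assemblage()]).
#' @export
as_assemblage <- function(df) {
  required <- c("source_id", "study_id", "site_id", "taxon_id",
                "measurement", "metric_kind", "sampling_effort")
  check_columns(df, required, "assemblage table")
  out <- tibble::as_tibble(df)
  if (!"block_id" %in% names(out)) out$block_id <- NA_character_
  if (!"status" %in% names(out)) out$status <- "unknown"
  out <- dplyr::mutate(
    out,
    dplyr::across(c("source_id", "study_id", "block_id", "site_id",
                    "taxon_id"), as.character),
    status = as.character(.data$status),
    measurement = as.numeric(.data$measurement),
    metric_kind = as.character(.data$metric_kind),
    sampling_effort = as.numeric(.data$sampling_effort)
  )
  out$status[is.na(out$status)] <- "unknown"

  bad <- which(is.na(out$measurement) | out$measurement < 0)
  if (length(bad) > 0) {
    stop_islandiv(
      sprintf("invalid measurement (< 0 or NA) in row(s): %s",
              paste(head(bad, 10), collapse = ", ")),
      class = "islandiv_validation_error"
    )
  }
  bad <- which(is.na(out$sampling_effort) | out$sampling_effort <= 0)
  if (length(bad) > 0) {
    stop_islandiv(
      sprintf("invalid sampling_effort (<= 0 or NA) in row(s): %s",
              paste(head(bad, 10), collapse = ", ")),
      class = "islandiv_validation_error"
    )
  }
  bad <- which(!out$status %in% STATUS_LEVELS)
  if (length(bad) > 0) {
    stop_islandiv(
      sprintf("status must be one of %s; offending row(s): %s",
              paste(STATUS_LEVELS, collapse = "/"),
              paste(head(bad, 10), collapse = ", ")),
      class = "islandiv_validation_error"
    )
  }
  bad <- which(!out$metric_kind %in% c("abundance", "occurrence"))
  if (length(bad) > 0) {
    stop_islandiv(
      sprintf("metric_kind must be abundance/occurrence; offending row(s): %s",
              paste(head(bad, 10), collapse = ", ")),
      class = "islandiv_validation_error"
    )
  }
  dup <- duplicated(out[, c("study_id", "site_id", "taxon_id")])
  if (any(dup)) {
    stop_islandiv(
      sprintf("duplicate (study_id, site_id, taxon_id) in row(s): %s",
              paste(head(which(dup), 10), collapse = ", ")),
      class = "islandiv_validation_error"
    )
  }
  mixed <- dplyr::summarise(dplyr::group_by(out, .data$study_id),
                            n_kind = dplyr::n_distinct(.data$metric_kind))
  mixed <- mixed$study_id[mixed$n_kind > 1]
  if (length(mixed) > 0) {
    stop_islandiv(
      sprintf("metric_kind must be constant within a study; offending: %s",
              paste(mixed, collapse = ", ")),
      class = "islandiv_validation_error"
    )
  }
  out[, c("source_id", "study_id", "block_id", "site_id", "taxon_id",
          "status", "measurement", "metric_kind", "sampling_effort")]
}

#' Read and validate a site metadata table
#'
#' @param path Path to a CSV with one row per site: identifiers, WGS84
#'   decimal-degree coordinates, one of the seven land-use classes, raw
#'   human population density (persons per km2) and distance to nearest road
#'   (m), altitude (m), four bioclimatic variables (`tmax`, `tmin` in deg C;
#'   `precip_wet`, `precip_dry` in mm), and optionally the site's maximum
#'   linear extent (m).
#' @param schema Optional column-name map as in [read_assemblage()].
#' @return A validated tibble of sites.
#' @export
read_sites <- function(path, schema = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      if (schema[[canon]] %in% names(raw)) {
        names(raw)[names(raw) == schema[[canon]]] <- canon
      }
    }
  }
  as_sites(raw)
}

#' Coerce and validate an in-memory site table
#' @param df A data frame with the canonical site columns.
#' @return A validated tibble.
#' @export
as_sites <- function(df) {
  required <- c("site_id", "study_id", "island_id", "longitude", "latitude",
                "land_use", "hpd_raw", "dist_road_raw", "altitude",
                "tmax", "tmin", "precip_wet", "precip_dry")
  check_columns(df, required, "site table")
  out <- tibble::as_tibble(df)
  if (!"block_id" %in% names(out)) out$block_id <- NA_character_
  if (!"max_linear_extent" %in% names(out)) out$max_linear_extent <- NA_real_
  out <- dplyr::mutate(
    out,
    dplyr::across(c("site_id", "study_id", "block_id", "island_id"),
                  as.character),
    dplyr::across(c("longitude", "latitude", "hpd_raw", "dist_road_raw",
                    "altitude", "tmax", "tmin", "precip_wet", "precip_dry",
                    "max_linear_extent"), as.numeric)
  )
  if (any(abs(out$latitude) > 90, na.rm = TRUE) ||
      any(abs(out$longitude) > 180, na.rm = TRUE)) {
    stop_islandiv("coordinates outside WGS84 bounds",
                  class = "islandiv_validation_error")
  }
  bad_lu <- setdiff(unique(as.character(out$land_use)), LAND_USES)
  if (length(bad_lu) > 0) {
    stop_islandiv(
      sprintf("unknown land_use value(s): %s (expected %s)",
              paste(bad_lu, collapse = ", "),
              paste(LAND_USES, collapse = ", ")),
      class = "islandiv_validation_error"
    )
  }
  out$land_use <- land_use_factor(out$land_use)
  if (any(out$hpd_raw < 0, na.rm = TRUE) ||
      any(out$dist_road_raw < 0, na.rm = TRUE)) {
    stop_islandiv("hpd_raw and dist_road_raw must be >= 0",
                  class = "islandiv_validation_error")
  }
  if (anyDuplicated(out$site_id) > 0) {
    stop_islandiv("duplicate site_id in site table",
                  class = "islandiv_validation_error")
  }
  out
}

#' Read and validate an island-trait table
#'
#' @param path Path to a CSV with one row per island: `island_id`, `area_km2`
#'   (> 0), `surrounding_landmass` (sum of landmass proportions within 100,
#'   1,000 and 10,000 km buffers, in `[0, 3]`; smaller = more isolated) and
#'   `gdp_per_capita` (current USD, > 0).
#' @return A validated tibble of island traits.
#' @export
read_islands <- function(path) {
  as_islands(readr::read_csv(path, show_col_types = FALSE, progress = FALSE))
}

#' Coerce and validate an in-memory island table
#' @param df A data frame with the canonical island columns.
#' @return A validated tibble.
#' @export
as_islands <- function(df) {
  check_columns(df, c("island_id", "area_km2", "surrounding_landmass",
                      "gdp_per_capita"), "island table")
  out <- tibble::as_tibble(df)
  out$island_id <- as.character(out$island_id)
  if (any(out$area_km2 <= 0, na.rm = TRUE)) {
    stop_islandiv("area_km2 must be > 0", class = "islandiv_validation_error")
  }
  slm <- out$surrounding_landmass
  if (any(slm < 0 | slm > 3, na.rm = TRUE)) {
    stop_islandiv("surrounding_landmass must lie in [0, 3]",
                  class = "islandiv_validation_error")
  }
  out
}

#' Write a canonical table to CSV
#'
#' UTF-8, comma-separated; the canonical interchange format. Reading the file
#' back with the matching reader round-trips identifiers and statuses
#' bit-exactly and numeric values value-exactly.
#'
#' @param x A tibble produced by this package.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_canonical <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}

#' Attach alien/native status to assemblage records
#'
#' Joins externally-sourced status classifications onto occurrence records.
#' Island-scope classifications take precedence over country-scope ones,
#' mirroring pipelines that query island-specific databases before
#' country-level ones; unmatched taxa are labelled `unknown`.
#'
#' @param occurrences An assemblage tibble (needs `taxon_id`; scope joins may
#'   also use `island_id` / `country_id` columns if present).
#' @param status_table A tibble with columns `taxon_id`, `status`, `scope`
#'   (values among `precedence`) and the scope's key column (`island_id` for
#'   island scope, `country_id` for country scope) when the join is keyed;
#'   rows with no key column are matched on `taxon_id` alone.
#' @param precedence Character vector ordering scopes from highest to lowest
#'   precedence. Default: island before country.
#' @return `occurrences` with its `status` column filled from the
#'   highest-precedence matching scope. Idempotent and independent of row
#'   order.
#' @export
attach_status <- function(occurrences,
                          status_table,
                          precedence = c("island", "country")) {
  check_columns(occurrences, "taxon_id", "occurrences")
  occurrences <- tibble::as_tibble(occurrences)
  out <- occurrences
  out$status <- "unknown"
  if (is.null(status_table) || nrow(status_table) == 0) return(out)
  check_columns(status_table, c("taxon_id", "status", "scope"),
                "status table")

  scope_key <- c(island = "island_id", country = "country_id")
  assigned <- rep(FALSE, nrow(out))
  for (sc in precedence) {
    st <- status_table[status_table$scope == sc, , drop = FALSE]
    if (nrow(st) == 0) next
    key <- scope_key[[sc]] %||% NA_character_
    use_key <- !is.na(key) && key %in% names(st) && key %in% names(out)
    keys <- if (use_key) c("taxon_id", key) else "taxon_id"
    dup_mask <- duplicated(st[, keys, drop = FALSE]) |
      duplicated(st[, keys, drop = FALSE], fromLast = TRUE)
    dups_any <- st[dup_mask, , drop = FALSE]
    if (nrow(dups_any) > 0) {
      conf <- dplyr::summarise(
        dplyr::group_by(dups_any, dplyr::across(dplyr::all_of(keys))),
        n_status = dplyr::n_distinct(.data$status), .groups = "drop")
      conf <- conf[conf$n_status > 1, , drop = FALSE]
      if (nrow(conf) > 0) {
        stop_islandiv(
          sprintf("conflicting duplicate status keys in scope '%s': %s",
                  sc, paste(conf$taxon_id, collapse = ", ")),
          class = "islandiv_status_conflict"
        )
      }
      st <- st[!duplicated(st[, keys, drop = FALSE]), , drop = FALSE]
    }
    idx <- if (use_key) {
      match(paste(out$taxon_id, out[[key]]), paste(st$taxon_id, st[[key]]))
    } else {
      match(out$taxon_id, st$taxon_id)
    }
    hit <- !assigned & !is.na(idx)
    out$status[hit] <- st$status[idx[hit]]
    assigned <- assigned | hit
  }
  out
}

#' Check the source/study/block/site hierarchy
#'
#' Report-only consistency checks between an assemblage table and a site
#' table: occurrences at sites missing from the site table, sites never
#' observed, blocks spanning more than one study, and studies mixing
#' abundance and occurrence records.
#'
#' @param occurrences An assemblage tibble.
#' @param sites A site tibble.
#' @return A tibble with columns `check`, `id`, `detail`; zero rows when the
#'   hierarchy is consistent.
#' @export
validate_hierarchy <- function(occurrences, sites) {
  issues <- list()
  orphan_occ <- setdiff(unique(occurrences$site_id), sites$site_id)
  if (length(orphan_occ) > 0) {
    issues[[length(issues) + 1]] <- tibble::tibble(
      check = "orphan_occurrence_site", id = orphan_occ,
      detail = "site_id present in occurrences but absent from site table")
  }
  orphan_site <- setdiff(unique(sites$site_id), occurrences$site_id)
  if (length(orphan_site) > 0) {
    issues[[length(issues) + 1]] <- tibble::tibble(
      check = "unobserved_site", id = orphan_site,
      detail = "site in site table with no occurrence records")
  }
  blk <- dplyr::filter(occurrences, !is.na(.data$block_id))
  if (nrow(blk) > 0) {
    bad_blocks <- dplyr::summarise(
      dplyr::group_by(blk, .data$block_id),
      n_study = dplyr::n_distinct(.data$study_id), .groups = "drop")
    bad_blocks <- bad_blocks$block_id[bad_blocks$n_study > 1]
    if (length(bad_blocks) > 0) {
      issues[[length(issues) + 1]] <- tibble::tibble(
        check = "block_spans_studies", id = bad_blocks,
        detail = "block_id appears in more than one study")
    }
  }
  mk <- dplyr::summarise(dplyr::group_by(occurrences, .data$study_id),
                         n_kind = dplyr::n_distinct(.data$metric_kind),
                         .groups = "drop")
  mixed <- mk$study_id[mk$n_kind > 1]
  if (length(mixed) > 0) {
    issues[[length(issues) + 1]] <- tibble::tibble(
      check = "mixed_metric_kind", id = mixed,
      detail = "study mixes abundance and occurrence records")
  }
  if (length(issues) == 0) {
    return(tibble::tibble(check = character(), id = character(),
                          detail = character()))
  }
  dplyr::bind_rows(issues)
}
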