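#' Deduplicate species occurrence records on a degree grid
#'
#' Within each species, at most one occurrence record is kept per grid cell
#' of `tolerance_deg` x `tolerance_deg` degrees (cells are
#' `floor(lat / tol), floor(lon / tol)`), keeping the first record seen.
#' Records with out-of-range or non-finite coordinates are skipped with a
#' warning. The operation is idempotent and never adds records.
#'
#' @param occ data.frame with columns `species`, `latitude`, `longitude`.
#' @param tolerance_deg positive grid size in degrees (default 1).
#' @return a subset of `occ`.
#' @export
dedup_occurrences <- function(occ, tolerance_deg = 1) {
    stopifnot(tolerance_deg > 0,
              all(c("species", "latitude", "longitude") %in% names(occ)))
    ok <- is.finite(occ$latitude) & is.finite(occ$longitude) &
        occ$latitude >= -90 & occ$latitude <= 90 &
        occ$longitude >= -180 & occ$longitude <= 180
    if (any(!ok)) {
        warning(sum(!ok), " occurrence record(s) with out-of-range ",
                "coordinates skipped")
        occ <- occ[ok, , drop = FALSE]
    }
    cell <- paste(occ$species,
                  floor(occ$latitude / tolerance_deg),
                  floor(occ$longitude / tolerance_deg))
    out <- occ[!duplicated(cell), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Occurrence records near a sampling site
#'
#' Counts (deduplicated) occurrence records of a species within a box
#' distance of the site: `max(|dlat|, |dlon|) <= radius_deg`, with the
#' longitude difference wrapped across the antimeridian. The box metric is
#' consistent with the degree-grid deduplication.
#'
#' @param species species name.
#' @param site numeric `c(lat, lon)` of the sampling site.
#' @param occ occurrence data.frame (see [dedup_occurrences()]).
#' @param radius_deg positive radius in degrees.
#' @return list with `has_records` (logical) and `n_within` (integer).
#' @export
occurrence_proximity <- function(species, site, occ, radius_deg = 1) {
    stopifnot(radius_deg > 0, length(site) == 2L)
    rec <- occ[occ$species == species, , drop = FALSE]
    if (nrow(rec) == 0L) return(list(has_records = FALSE, n_within = 0L))
    dlat <- abs(rec$latitude - site[1])
    dlon <- abs(rec$longitude - site[2])
    dlon <- pmin(dlon, 360 - dlon)          # wrap at the antimeridian
    n <- sum(pmax(dlat, dlon) <= radius_deg)
    list(has_records = n > 0L, n_within = as.integer(n))
}

#' Habitat profile categories
#'
#' The controlled vocabularies of the three habitat features carried in the
#' reference database: a single water-column position (`demers_pelag`), and
#' possibly multi-valued `salinity` and `climate_zone` sets.
#' @return named list of character vectors.
#' @export
habitat_categories <- function() {
    list(demers_pelag = c("Bathydemersal", "Bathypelagic", "Benthopelagic",
                          "Demersal", "Pelagic", "Pelagic-neritic",
                          "Pelagic-oceanic", "Reef-associated"),
         salinity = c("Freshwater", "Brackish water", "Saltwater"),
         climate_zone = c("Subtropical", "Temperate", "Tropical", "Boreal",
                          "Deep-water", "High altitude", "Polar"))
}

#' Look up habitat profiles for a set of species
#'
#' @param species character vector (e.g. the members of a species complex).
#' @param habitat data.frame with columns `species`, `demers_pelag`,
#'   `salinity`, `climate_zone`; the last two semicolon-joined when
#'   multi-valued. Species absent from the table get an all-`unknown`
#'   profile.
#' @return list of profiles, one per input species, each a list with
#'   `demers_pelag` (length-1) and character vectors `salinity`,
#'   `climate_zone`.
#' @export
annotate_habitat <- function(species, habitat) {
    lapply(species, function(sp) {
        i <- match(sp, habitat$species)
        if (is.na(i))
            return(list(species = sp, demers_pelag = "unknown",
                        salinity = character(0), climate_zone = character(0)))
        list(species = sp,
             demers_pelag = habitat$demers_pelag[i],
             salinity = strsplit(habitat$salinity[i], ";", fixed = TRUE)[[1]],
             climate_zone = strsplit(habitat$climate_zone[i], ";",
                                     fixed = TRUE)[[1]])
    })
}
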