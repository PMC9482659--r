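#' Write a climate stack to CSV
#'
#' Long-format plain-text raster: one row per cell with `cell`, `lon`,
#' `lat` and one column per layer.
#'
#' @param stack a [climate_stack()].
#' @param path output file path.
#' @export
write_climate_csv <- function(stack, path) {
  cc <- cell_center(stack$grid)
  utils::write.csv(cbind(cc, as.data.frame(stack$values)), path,
                   row.names = FALSE)
}

#' Write a world mask to CSV
#' @param mask a [generate_world()] mask.
#' @param path output file path.
#' @export
write_mask_csv <- function(mask, path) {
  cc <- cell_center(mask$grid)
  utils::write.csv(
    cbind(cc, country_id = mask$country_id, ecoregion_id = mask$ecoregion_id),
    path, row.names = FALSE)
}

#' Write occurrence records to CSV
#'
#' Header `species_id,lon,lat`, one row per record.
#'
#' @param occs list of `occurrence_set`s (or a single one).
#' @param path output file path.
#' @export
write_occurrences_csv <- function(occs, path) {
  if (inherits(occs, "occurrence_set")) occs <- list(occs)
  df <- do.call(rbind, lapply(occs, function(o)
    data.frame(species_id = o$species_id, lon = o$records$lon,
               lat = o$records$lat)))
  utils::write.csv(df, path, row.names = FALSE)
}

#' Read occurrence records from CSV
#'
#' Expects columns `species_id,lon,lat`; returns one `occurrence_set` per
#' species.
#'
#' @param path input file path.
#' @return named list of `occurrence_set`s.
#' @export
read_occurrences_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("species_id", "lon", "lat") %in% names(df)))
  lapply(split(df, df$species_id), function(d)
    structure(list(species_id = d$species_id[1],
                   records = data.frame(lon = d$lon, lat = d$lat),
                   cells = NULL, grid_cells = NULL),
              class = "occurrence_set"))
}

#' Write virtual-species truth to CSV
#'
#' One row per species with the niche parameters and true range size; the
#' per-cell true range is reproducible from the parameters and the baseline
#' stack.
#'
#' @param species list of `virtual_species`.
#' @param path output file path.
#' @export
write_species_truth_csv <- function(species, path) {
  df <- do.call(rbind, lapply(species, function(sp)
    data.frame(species_id = sp$species_id, country_id = sp$country_id,
               niche_vars = paste(sp$niche_vars, collapse = ";"),
               mu = paste(signif(sp$mu, 8), collapse = ";"),
               sigma = paste(signif(sp$sigma, 8), collapse = ";"),
               tau = sp$tau, true_range_cells = length(sp$true_range))))
  utils::write.csv(df, path, row.names = FALSE)
}
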