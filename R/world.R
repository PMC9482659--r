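#' Generate a synthetic political/ecological mask
#'
#' Partitions the grid into `n_countries` contiguous "countries" by
#' nearest-seed-point (Voronoi) growth on cell centres, and subdivides each
#' country into ecoregions by a second nearest-seed partition restricted to
#' the country's cells. Ecoregion ids are globally unique and nest within
#' countries. All cells are land by default (country_id 0 is reserved for
#' ocean/none but unused here; small fixtures stay simple without a coast).
#'
#' @param grid a [grid_spec()].
#' @param n_countries number of countries (default 12, the megadiverse set).
#' @param ecoregions_per_country target ecoregions per country (reduced if a
#'   country has fewer cells than ecoregion seeds).
#' @param seed integer seed; the mask is a pure function of (inputs, seed).
#' @return an object of class `world_mask` with per-cell integer vectors
#'   `country_id` (0 = none) and `ecoregion_id` (0 = none), plus
#'   `country_count`.
#' @export
generate_world <- function(grid, n_countries = 12L, ecoregions_per_country = 3L,
                           seed = 1L) {
  stopifnot(inherits(grid, "grid_spec"))
  n_countries <- as.integer(n_countries)
  ecoregions_per_country <- as.integer(ecoregions_per_country)
  if (n_countries < 1L) stop("n_countries must be >= 1")
  nc <- n_cells(grid)
  if (n_countries > nc) stop("more countries than grid cells")
  if (ecoregions_per_country < 1L) stop("ecoregions_per_country must be >= 1")
  set.seed(as.integer(seed))
  rc <- cell_rowcol(grid, seq_len(nc))

  nearest_seed <- function(rows, cols, seed_rows, seed_cols) {
    # squared Euclidean distance in cell coordinates; ties -> lowest seed id
    d2 <- outer(rows, seed_rows, "-")^2 + outer(cols, seed_cols, "-")^2
    max.col(-d2, ties.method = "first")
  }

  country_seeds <- sort(sample.int(nc, n_countries))
  cs_rc <- cell_rowcol(grid, country_seeds)
  country_id <- nearest_seed(rc[, "row"], rc[, "col"],
                             cs_rc[, "row"], cs_rc[, "col"])

  ecoregion_id <- integer(nc)
  for (cty in seq_len(n_countries)) {
    cells <- which(country_id == cty)
    k <- min(ecoregions_per_country, length(cells))
    eco_seeds <- sort(cells[sample.int(length(cells), k)])
    es_rc <- cell_rowcol(grid, eco_seeds)
    sub_rc <- cell_rowcol(grid, cells)
    local_id <- nearest_seed(sub_rc[, "row"], sub_rc[, "col"],
                             es_rc[, "row"], es_rc[, "col"])
    ecoregion_id[cells] <- (cty - 1L) * ecoregions_per_country + local_id
  }

  structure(
    list(grid = grid,
         country_id = as.integer(country_id),
         ecoregion_id = as.integer(ecoregion_id),
         country_count = n_countries),
    class = "world_mask")
}

#' @export
print.world_mask <- function(x, ...) {
  cat(sprintf("world_mask: %d countries, %d ecoregions on %d x %d grid\n",
              x$country_count, length(unique(x$ecoregion_id[x$ecoregion_id > 0])),
              x$grid$n_rows, x$grid$n_cols))
  invisible(x)
}

#' Land cells of a mask
#' @param mask a [generate_world()] mask.
#' @return integer cell indices with a country assigned.
#' @export
land_cells <- function(mask) which(mask$country_id > 0L)

#' Cells of one country
#' @param mask a [generate_world()] mask.
#' @param country country id.
#' @return integer cell indices.
#' @export
country_cells <- function(mask, country) which(mask$country_id == country)
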