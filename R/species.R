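# Standardize a stack's layers over a reference cell set (z-scores). Virtual
# niches are defined in this standardized space so that niche breadths are
# comparable across temperature- and precipitation-scaled layers.
standardize_env <- function(stack, cells = seq_len(n_cells(stack$grid))) {
  v <- stack$values
  mu <- colMeans(v[cells, , drop = FALSE])
  sd <- apply(v[cells, , drop = FALSE], 2, stats::sd)
  sd[sd == 0] <- 1
  list(center = mu, scale = sd,
       z = sweep(sweep(v, 2, mu, "-"), 2, sd, "/"))
}

#' Gaussian niche suitability
#'
#' Bell-shaped suitability around per-variable optima in standardized climate
#' space: `exp(-sum_v (z_v - mu_v)^2 / (2 sigma_v^2))`. Equals 1 exactly at
#' the optimum and decays smoothly with climatic distance.
#'
#' @param z standardized environment matrix (cells x layers, named columns).
#' @param mu named numeric optima (names select the niche variables).
#' @param sigma named positive numeric breadths, same names as `mu`.
#' @return numeric vector in \[0, 1\], one value per row of `z`.
#' @export
niche_suitability <- function(z, mu, sigma) {
  stopifnot(identical(names(mu), names(sigma)), all(sigma > 0))
  d <- sweep(z[, names(mu), drop = FALSE], 2, mu, "-")
  q <- sweep(d^2, 2, 2 * sigma^2, "/")
  exp(-rowSums(q))
}

#' Generate endemic virtual species with known niches
#'
#' Each virtual species is endemic to one country and has a Gaussian niche
#' over 2-3 bioclim-like layers: optima are anchored at the standardized
#' climate of a randomly chosen cell inside the country (so the optimum is
#' attainable and suitability there is exactly 1), breadths and the occupancy
#' threshold tau are drawn from configurable ranges. The true range is the
#' set of country cells with suitability >= tau; this known truth is what
#' model-recovery tests measure against. Draws whose true range has fewer
#' than `min_range_cells` cells are re-drawn (bounded retries).
#'
#' @param stack the baseline [climate_stack()].
#' @param mask a [generate_world()] mask.
#' @param n_species number of species to generate.
#' @param niche_config list with elements `n_vars` (candidate niche variable
#'   counts, default `2:3`), `sigma` (range for breadths, default
#'   `c(0.6, 1.2)` standardized units), `tau` (range for the occupancy
#'   threshold, default `c(0.3, 0.6)`), `min_range_cells` (default 1;
#'   shrunk to half the country for small countries) and `max_range_frac`
#'   (default 0.8: an endemic never occupies more than this fraction of its
#'   country, which also guarantees a pseudo-absence pool).
#' @param seed integer seed.
#' @param countries optional integer vector of country ids, one per species
#'   (recycled); defaults to cycling through all countries.
#' @param max_retries redraw budget per species.
#' @return list of `virtual_species` objects with fields `species_id`,
#'   `country_id`, `niche_vars`, `mu`, `sigma`, `tau`, `true_suitability`
#'   (all cells), `true_range` (cell indices), `country_cells`, `grid`.
#' @export
generate_virtual_species <- function(stack, mask, n_species,
                                     niche_config = list(), seed = 1L,
                                     countries = NULL, max_retries = 200L) {
  stopifnot(inherits(stack, "climate_stack"), inherits(mask, "world_mask"))
  cfg <- utils::modifyList(
    list(n_vars = 2:3, sigma = c(0.6, 1.2), tau = c(0.3, 0.6),
         min_range_cells = 1L, max_range_frac = 0.8),
    niche_config)
  if (is.null(countries))
    countries <- rep_len(seq_len(mask$country_count), n_species)
  countries <- rep_len(as.integer(countries), n_species)
  land <- land_cells(mask)
  std <- standardize_env(stack, land)
  layers <- stack_layers(stack)
  set.seed(as.integer(seed))
  out <- vector("list", n_species)
  for (i in seq_len(n_species)) {
    cty <- countries[i]
    ccells <- country_cells(mask, cty)
    if (length(ccells) < 25L)
      stop(sprintf("country %d has fewer than 25 land cells", cty))
    # an endemic's range must be a proper subset of its country: at least
    # min_range_cells (shrunk for small countries) and at most
    # max_range_frac of the country's cells
    min_eff <- max(1L, min(as.integer(cfg$min_range_cells),
                           as.integer(floor(0.5 * length(ccells)))))
    max_eff <- max(min_eff + 1L,
                   as.integer(floor(cfg$max_range_frac * length(ccells))))
    sp <- NULL
    for (try in seq_len(max_retries)) {
      k <- if (length(cfg$n_vars) == 1L) cfg$n_vars else sample(cfg$n_vars, 1L)
      vars <- sample(layers, k)
      anchor <- ccells[sample.int(length(ccells), 1L)]
      mu <- stats::setNames(std$z[anchor, vars], vars)
      sigma <- stats::setNames(stats::runif(k, cfg$sigma[1], cfg$sigma[2]), vars)
      tau <- stats::runif(1L, cfg$tau[1], cfg$tau[2])
      suit <- niche_suitability(std$z, mu, sigma)
      range_cells <- ccells[suit[ccells] >= tau]
      if (length(range_cells) >= min_eff && length(range_cells) <= max_eff) {
        sp <- structure(
          list(species_id = sprintf("vsp%03d", i), country_id = cty,
               niche_vars = vars, mu = mu, sigma = sigma, tau = tau,
               true_suitability = suit, true_range = range_cells,
               country_cells = ccells, grid = stack$grid),
          class = "virtual_species")
        break
      }
    }
    if (is.null(sp))
      stop(sprintf("retry budget exhausted for a viable niche in country %d", cty))
    out[[i]] <- sp
  }
  out
}

#' @export
print.virtual_species <- function(x, ...) {
  cat(sprintf("virtual_species %s: country %d, niche on {%s}, tau=%.2f, range %d cells\n",
              x$species_id, x$country_id, paste(x$niche_vars, collapse = ", "),
              x$tau, length(x$true_range)))
  invisible(x)
}

#' Sample occurrence records for a virtual species
#'
#' Draws `n` records (with replacement) from the species' true range, with
#' per-cell probability proportional to true suitability; records are placed
#' at cell centres. With probability `detection_noise` a record is displaced
#' to a uniformly random cell of the species' country (label noise emulating
#' misidentification / georeferencing error).
#'
#' @param sp a `virtual_species`.
#' @param n number of records (>= 1).
#' @param detection_noise displacement probability in \[0, 1\].
#' @param seed integer seed.
#' @return an `occurrence_set`: `species_id`, `records` (data.frame
#'   `lon`, `lat`), `cells` (the drawn cells, in record order),
#'   `grid_cells` (NULL until deduplication).
#' @export
sample_occurrences <- function(sp, n, detection_noise = 0, seed = 1L) {
  stopifnot(inherits(sp, "virtual_species"), n >= 1,
            detection_noise >= 0, detection_noise <= 1)
  set.seed(as.integer(seed))
  w <- sp$true_suitability[sp$true_range]
  cells <- sp$true_range[sample.int(length(sp$true_range), n,
                                    replace = TRUE, prob = w)]
  noisy <- stats::runif(n) < detection_noise
  if (any(noisy))
    cells[noisy] <- sp$country_cells[
      sample.int(length(sp$country_cells), sum(noisy), replace = TRUE)]
  centers <- cell_center(sp$grid, cells)
  structure(
    list(species_id = sp$species_id,
         records = data.frame(lon = centers$lon, lat = centers$lat),
         cells = cells, grid_cells = NULL),
    class = "occurrence_set")
}
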