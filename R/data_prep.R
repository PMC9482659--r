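#' Snap, deduplicate and filter occurrence records
#'
#' Records are snapped to grid cells and collapsed to unique cells; a species
#' is retained only if it has at least `min_records` unique cells (the
#' minimum needed for a defensible presence/pseudo-absence model at this
#' resolution). Records falling outside the grid extent are an input error.
#'
#' @param occ an `occurrence_set` (see [sample_occurrences()]).
#' @param grid a [grid_spec()].
#' @param min_records minimum unique cells to retain a species (default 25).
#' @return a `species_record_set`: `species_id`, `unique_cells`, `n_raw`,
#'   `retained`, `exclusion_reason` (`"none"`, `"too_few_records"` or
#'   `"not_endemic"`).
#' @export
dedupe_and_filter <- function(occ, grid, min_records = 25L) {
  stopifnot(inherits(occ, "occurrence_set"), inherits(grid, "grid_spec"))
  cells <- lonlat_to_cell(grid, occ$records$lon, occ$records$lat)
  if (anyNA(cells)) {
    bad <- which(is.na(cells))
    stop(sprintf("%d record(s) outside the grid extent (rows: %s)",
                 length(bad), paste(utils::head(bad, 10L), collapse = ", ")))
  }
  uc <- sort(unique(cells))
  retained <- length(uc) >= min_records
  structure(
    list(species_id = occ$species_id,
         unique_cells = uc,
         n_raw = nrow(occ$records),
         retained = retained,
         exclusion_reason = if (retained) "none" else "too_few_records"),
    class = "species_record_set")
}

#' Cap the number of records per species
#'
#' If a species has more than `max_n` unique cells, keep a uniform random
#' subset of exactly `max_n` (controls compute cost and spatial redundancy
#' for range-polygon-derived records); otherwise unchanged. Idempotent for a
#' fixed seed.
#'
#' @param s a retained `species_record_set`.
#' @param max_n maximum records to keep (default 500).
#' @param seed integer seed.
#' @return the (possibly thinned) `species_record_set`.
#' @export
cap_records <- function(s, max_n = 500L, seed = 1L) {
  stopifnot(inherits(s, "species_record_set"))
  if (!s$retained) stop("cap_records expects a retained species")
  if (length(s$unique_cells) > max_n) {
    set.seed(as.integer(seed))
    s$unique_cells <- sort(sample(s$unique_cells, max_n))
  }
  s
}

#' Endemicity check against a country mask
#'
#' TRUE iff every occurrence cell lies within a single country's cells
#' dilated by `buffer_deg` (converted to whole cells by ceiling). The small
#' default buffer tolerates records on the border without admitting
#' genuinely multi-country species.
#'
#' @param s a `species_record_set`.
#' @param mask a [generate_world()] mask.
#' @param buffer_deg buffer width in degrees (default 0.08333, i.e. 5 arc-min).
#' @return logical.
#' @export
endemicity_check <- function(s, mask, buffer_deg = 0.08333) {
  stopifnot(inherits(s, "species_record_set"), inherits(mask, "world_mask"))
  r <- buffer_cells(mask$grid, buffer_deg)
  candidates <- unique(mask$country_id[s$unique_cells])
  candidates <- candidates[candidates > 0L]
  for (cty in candidates) {
    buf <- dilate_cells(mask$grid, country_cells(mask, cty), r)
    if (all(s$unique_cells %in% buf)) return(TRUE)
  }
  FALSE
}

# variance inflation factor of each column of E (regress on the others, OLS)
vif_values <- function(E) {
  p <- ncol(E)
  if (p == 1L) return(stats::setNames(1, colnames(E)))
  out <- numeric(p)
  for (j in seq_len(p)) {
    fit <- stats::lm.fit(cbind(1, E[, -j, drop = FALSE]), E[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((E[, j] - mean(E[, j]))^2)
    out[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  stats::setNames(out, colnames(E))
}

#' Collinearity-based predictor selection
#'
#' Iterative pairwise-correlation / VIF filter over the candidate layers,
#' evaluated on a sample of cells (typically the species' calibration
#' region): while any kept pair has `|r| >= r_threshold`, the worst pair
#' (largest `|r|`) loses its member with the higher VIF among the currently
#' kept layers; VIF ties are broken by dropping the later layer in input
#' order. The kept set therefore has all pairwise `|r| < r_threshold`.
#'
#' @param stack a [climate_stack()].
#' @param sample_cells cells over which correlations/VIFs are computed
#'   (at least 3).
#' @param r_threshold absolute Pearson correlation threshold (default 0.8).
#' @param layers candidate layer names (default all).
#' @return a `predictor_selection`: `candidate_layers`, `kept_layers`,
#'   `correlation_matrix` (final, among kept), `vif_values` (final, among
#'   kept).
#' @export
select_predictors <- function(stack, sample_cells, r_threshold = 0.8,
                              layers = stack_layers(stack)) {
  stopifnot(length(sample_cells) >= 3L)
  E <- env_at(stack, sample_cells, layers)
  sds <- apply(E, 2, stats::sd)
  if (any(sds == 0))
    stop("constant layer(s) over sample cells: ",
         paste(colnames(E)[sds == 0], collapse = ", "))
  kept <- layers
  repeat {
    C <- stats::cor(E[, kept, drop = FALSE])
    A <- abs(C); diag(A) <- 0
    if (max(A) < r_threshold) break
    worst <- which(A == max(A), arr.ind = TRUE)[1L, ]
    pair <- kept[sort(worst)]
    v <- vif_values(E[, kept, drop = FALSE])
    # drop the pair member with higher VIF; ties -> later layer order
    drop <- if (v[pair[1L]] > v[pair[2L]]) pair[1L]
            else if (v[pair[2L]] > v[pair[1L]]) pair[2L]
            else pair[which.max(match(pair, layers))]
    kept <- setdiff(kept, drop)
    if (length(kept) == 1L) break
  }
  structure(
    list(candidate_layers = layers,
         kept_layers = kept,
         correlation_matrix = stats::cor(E[, kept, drop = FALSE]),
         vif_values = vif_values(E[, kept, drop = FALSE])),
    class = "predictor_selection")
}
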