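#' Range change of one species between two binary maps
#'
#' @param present_binary,future_binary logical vectors over the same cells
#'   (an `ensemble_prediction$binary`), or integer cell sets.
#' @param species_id,scenario,horizon optional labels carried into the
#'   record.
#' @return a `range_change_record`: `n_present`, `n_future`, `delta`
#'   (`(n_future - n_present) / n_present`), `complete_loss`, `category`
#'   (see [classify_change()]).
#' @export
range_change <- function(present_binary, future_binary, species_id = NA,
                         scenario = NA, horizon = NA) {
  n_present <- sum(as.logical(present_binary))
  n_future <- sum(as.logical(future_binary))
  if (n_present == 0L)
    stop("species has no present-day range (was never modeled)")
  delta <- (n_future - n_present) / n_present
  structure(
    list(species_id = species_id, scenario = scenario, horizon = horizon,
         n_present = n_present, n_future = n_future, delta = delta,
         complete_loss = n_future == 0L,
         category = classify_change(delta)),
    class = "range_change_record")
}

#' Classify a range-change delta into five categories
#'
#' Default bins (closed on the loss side): complete loss (`delta = -1`),
#' severe loss (`-1 < delta <= -0.5`), moderate loss (`-0.5 < delta < 0`),
#' stable/gain (`0 <= delta <= 0.5`), strong gain (`delta > 0.5`).
#'
#' @param delta numeric range-change delta(s), each >= -1.
#' @param edges length-2 numeric: the severe-loss and strong-gain edges
#'   (default `c(-0.5, 0.5)`).
#' @return character vector of categories.
#' @export
classify_change <- function(delta, edges = c(-0.5, 0.5)) {
  stopifnot(all(delta >= -1), edges[1] < 0, edges[2] > 0)
  out <- character(length(delta))
  out[delta == -1] <- "complete_loss"
  out[delta > -1 & delta <= edges[1]] <- "severe_loss"
  out[delta > edges[1] & delta < 0] <- "moderate_loss"
  out[delta >= 0 & delta <= edges[2]] <- "stable_gain"
  out[delta > edges[2]] <- "strong_gain"
  out
}

#' Build a presence-absence matrix (PAM)
#'
#' @param predictions list of `ensemble_prediction`s for one
#'   scenario/horizon (one per species).
#' @param n_total_cells total grid cell count; cells never inside any
#'   species' projected M are 0.
#' @return a `pam`: logical matrix species x cells (rownames = species ids),
#'   plus `scenario_id` and `horizon` attributes.
#' @export
build_pam <- function(predictions, n_total_cells) {
  ids <- vapply(predictions, `[[`, character(1), "species_id")
  m <- matrix(FALSE, length(predictions), n_total_cells,
              dimnames = list(ids, NULL))
  for (i in seq_along(predictions)) {
    p <- predictions[[i]]
    m[i, p$cells[p$binary]] <- TRUE
  }
  structure(m, class = c("pam", "matrix"),
            scenario_id = if (length(predictions)) predictions[[1]]$scenario_id else NA,
            horizon = if (length(predictions)) predictions[[1]]$horizon else NA)
}

#' Species richness maps from a PAM
#'
#' SR is the per-cell count of species present (the column sums of the PAM).
#' Standardized SR rescales SR to \[0, 1\] within each country by the
#' country's maximum SR (0 where a country's maximum is 0).
#'
#' @param pam a [build_pam()] matrix.
#' @param mask a [generate_world()] mask.
#' @return a `richness_maps` list: `sr` (integer per cell),
#'   `sr_standardized`, `max_sr` (named per-country vector).
#' @export
richness <- function(pam, mask) {
  sr <- as.integer(colSums(unclass(pam)))
  max_sr <- stats::setNames(integer(mask$country_count),
                            seq_len(mask$country_count))
  std <- numeric(length(sr))
  for (cty in seq_len(mask$country_count)) {
    cells <- country_cells(mask, cty)
    m <- if (length(cells)) max(sr[cells]) else 0L
    max_sr[cty] <- m
    if (m > 0) std[cells] <- sr[cells] / m
  }
  structure(list(sr = sr, sr_standardized = std, max_sr = max_sr),
            class = "richness_maps")
}

#' Temporal difference in species richness
#'
#' Positive values are richness gains (future minus present).
#'
#' @param sr_present,sr_future integer per-cell SR vectors.
#' @return integer per-cell delta-SR vector.
#' @export
delta_richness <- function(sr_present, sr_future) {
  stopifnot(length(sr_present) == length(sr_future))
  as.integer(sr_future) - as.integer(sr_present)
}

#' Define potential species hotspots (PSH) from present-day richness
#'
#' Per country, the PSH cutoff is `factor * maxSR` computed on present-day
#' SR; PSH cells are those with SR strictly above the cutoff. The cutoff
#' value is frozen and reused when measuring future PSH extent (see
#' [hotspot_extent()]), so shrinking richness is measured against a fixed
#' bar rather than a drifting one.
#'
#' @param sr_present per-cell present-day SR.
#' @param mask a [generate_world()] mask.
#' @param factor threshold factor in (0, 1) (default 0.6; 0.2 and 0.9 as
#'   sensitivity settings).
#' @param countries country ids to define hotspots for (default all); a
#'   country in this set with maxSR = 0 is an error, countries outside it
#'   get an empty PSH and an `NA` cutoff.
#' @return a `hotspot_def` list: `factor`, `countries`, `cutoff` (per
#'   country), `psh_cells` (per-country list of cell indices), `all_cells`
#'   (their union).
#' @export
hotspots <- function(sr_present, mask, factor = 0.6,
                     countries = seq_len(mask$country_count)) {
  stopifnot(factor > 0, factor < 1)
  cutoff <- stats::setNames(rep(NA_real_, mask$country_count),
                            seq_len(mask$country_count))
  psh <- rep(list(integer(0)), mask$country_count)
  for (cty in countries) {
    cells <- country_cells(mask, cty)
    m <- if (length(cells)) max(sr_present[cells]) else 0
    if (m == 0) stop(sprintf("country %d has maxSR = 0; no hotspot is defined", cty))
    cutoff[cty] <- factor * m
    psh[[cty]] <- cells[sr_present[cells] > cutoff[cty]]
  }
  structure(list(factor = factor, countries = countries, cutoff = cutoff,
                 psh_cells = psh, all_cells = sort(unlist(psh))),
            class = "hotspot_def")
}

#' Future hotspot extent against the frozen present-day cutoff
#'
#' @param hs a [hotspots()] definition (present day).
#' @param sr_future per-cell SR under a future scenario/horizon.
#' @param mask a [generate_world()] mask.
#' @return data.frame `country`, `n_present`, `n_future`, `extent_ratio`
#'   (`n_future / n_present`).
#' @export
hotspot_extent <- function(hs, sr_future, mask) {
  stopifnot(inherits(hs, "hotspot_def"))
  out <- lapply(hs$countries, function(cty) {
    cells <- country_cells(mask, cty)
    n_f <- sum(sr_future[cells] > hs$cutoff[cty])
    n_p <- length(hs$psh_cells[[cty]])
    data.frame(country = cty, n_present = n_p, n_future = n_f,
               extent_ratio = if (n_p > 0) n_f / n_p else NA_real_)
  })
  do.call(rbind, out)
}

#' Temporal Sorensen dissimilarity per cell
#'
#' For each cell, with a = species shared between the periods, b = species
#' present only now, c = species present only in the future:
#' `beta_SOR = (b + c) / (2a + b + c)`. Cells empty in both periods (a = b =
#' c = 0) are no-data. 0 means identical composition; 1 means complete
#' turnover.
#'
#' @param pam_present,pam_future two [build_pam()] matrices with identical
#'   species rows and cell columns.
#' @param cells cell indices to evaluate (non-empty), e.g. PSH cells.
#' @return list with `bsor` (per requested cell, `NA` = no-data), `cells`,
#'   and `median` (over valid cells).
#' @export
temporal_sorensen <- function(pam_present, pam_future, cells) {
  stopifnot(length(cells) > 0,
            identical(dim(pam_present), dim(pam_future)))
  P <- unclass(pam_present)[, cells, drop = FALSE]
  Fu <- unclass(pam_future)[, cells, drop = FALSE]
  a <- colSums(P & Fu)
  b <- colSums(P & !Fu)
  c_ <- colSums(!P & Fu)
  tot <- 2 * a + b + c_
  bsor <- ifelse(tot == 0, NA_real_, (b + c_) / tot)
  list(bsor = bsor, cells = cells,
       median = stats::median(bsor, na.rm = TRUE))
}
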