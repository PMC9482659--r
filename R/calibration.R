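#' Build the accessible area (M) of a species
#'
#' M is the spatial intersection of (i) the cells within a `buffer_deg`
#' buffer of any occurrence cell (degrees converted to a whole-cell
#' Chebyshev radius by ceiling) and (ii) the cells of the ecoregions that
#' contain at least one occurrence, restricted to land. If M is too small to
#' support pseudo-absence sampling (`|M| <= |presences| + 1`, the insular
#' case), M falls back to the species' whole country and `fallback_used` is
#' set.
#'
#' @param s a retained `species_record_set`.
#' @param mask a [generate_world()] mask.
#' @param buffer_deg occurrence buffer in degrees (default 4).
#' @return a `calibration_region`: `species_id`, `m_cells`,
#'   `projected_m_cells` (initially equal to `m_cells`; see
#'   [build_projected_m()]), `fallback_used`.
#' @export
build_m <- function(s, mask, buffer_deg = 4.0) {
  stopifnot(inherits(s, "species_record_set"), inherits(mask, "world_mask"))
  if (!s$retained) stop("build_m expects a retained species")
  occ <- s$unique_cells
  r <- buffer_cells(mask$grid, buffer_deg)
  buf <- dilate_cells(mask$grid, occ, r)
  ecos <- unique(mask$ecoregion_id[occ])
  ecos <- ecos[ecos > 0L]
  eco_cells <- which(mask$ecoregion_id %in% ecos)
  m <- intersect(intersect(buf, eco_cells), land_cells(mask))
  fallback <- FALSE
  if (length(m) <= length(occ) + 1L) {
    cty <- mask$country_id[occ[1L]]
    m <- country_cells(mask, cty)
    fallback <- TRUE
  }
  m <- sort(union(m, occ))  # M always contains the occurrence cells
  structure(
    list(species_id = s$species_id, m_cells = m, projected_m_cells = m,
         fallback_used = fallback),
    class = "calibration_region")
}

#' Dilate M into the projected accessible area
#'
#' The projected M — the area a species could plausibly reach under the
#' full-dispersal assumption when projecting to future climates — is M
#' dilated by `buffer_deg` (whole-cell Chebyshev radius, ceiling), clipped
#' to the grid and to land.
#'
#' @param cr a `calibration_region` from [build_m()].
#' @param mask a [generate_world()] mask.
#' @param buffer_deg projection buffer in degrees (default 2).
#' @return the `calibration_region` with `projected_m_cells` filled.
#' @export
build_projected_m <- function(cr, mask, buffer_deg = 2.0) {
  stopifnot(inherits(cr, "calibration_region"), inherits(mask, "world_mask"))
  r <- buffer_cells(mask$grid, buffer_deg)
  pm <- dilate_cells(mask$grid, cr$m_cells, r)
  cr$projected_m_cells <- sort(intersect(pm, land_cells(mask)))
  cr
}

#' Draw pseudo-absences and balance class weights
#'
#' Samples up to `n` pseudo-absence cells uniformly without replacement from
#' `M \ presences` (pseudo-absences never coincide with presence cells), and
#' assigns per-record weights so that total presence weight equals total
#' absence weight (prevalence 0.5): each absence has weight 1 and each
#' presence `n_absences / n_presences`.
#'
#' @param cr a `calibration_region`.
#' @param presences integer presence cell indices (subset of M).
#' @param n pseudo-absence budget (default 10000).
#' @param seed integer seed.
#' @return a `training_set`: `presence_cells`, `absence_cells`,
#'   `w_presence`, `w_absence` (scalar per-record weights).
#' @export
draw_pseudo_absences <- function(cr, presences, n = 10000L, seed = 1L) {
  stopifnot(inherits(cr, "calibration_region"))
  pool <- setdiff(cr$m_cells, presences)
  if (length(pool) == 0L)
    stop("empty pseudo-absence pool: M contains only presence cells")
  set.seed(as.integer(seed))
  k <- min(as.integer(n), length(pool))
  absences <- sort(sample(pool, k))
  structure(
    list(presence_cells = sort(unique(as.integer(presences))),
         absence_cells = absences,
         w_presence = k / length(unique(presences)),
         w_absence = 1),
    class = "training_set")
}

#' Stratified train/test replicate splits
#'
#' Produces `n_reps` independent random splits, stratified so that the
#' train fraction is applied within presences and within absences
#' separately (keeps prevalence stable across replicates).
#'
#' @param ts a `training_set`.
#' @param fraction train fraction in (0, 1) (default 0.7).
#' @param n_reps number of replicates (default 10).
#' @param seed integer seed; replicate r uses sub-seed `seed + r`.
#' @return list of length `n_reps`; each element has `train` (a
#'   `training_set`) and `test` (list of `presence_cells`, `absence_cells`).
#' @export
split_replicates <- function(ts, fraction = 0.7, n_reps = 10L, seed = 1L) {
  stopifnot(inherits(ts, "training_set"))
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must lie strictly between 0 and 1 (the test set may not be empty)")
  np <- length(ts$presence_cells)
  na <- length(ts$absence_cells)
  if (np < 2L || na < 2L) stop("need at least 2 presences and 2 absences")
  out <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(as.integer(seed) + r)
    ip <- sort(sample.int(np, max(1L, round(fraction * np))))
    ia <- sort(sample.int(na, max(1L, round(fraction * na))))
    if (length(ip) == np) ip <- ip[-np]  # guard: never an empty test stratum
    if (length(ia) == na) ia <- ia[-na]
    train <- ts
    train$presence_cells <- ts$presence_cells[ip]
    train$absence_cells <- ts$absence_cells[ia]
    train$w_presence <- length(train$absence_cells) / length(train$presence_cells)
    out[[r]] <- list(
      train = train,
      test = list(presence_cells = ts$presence_cells[-ip],
                  absence_cells = ts$absence_cells[-ia]))
  }
  out
}
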