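#' Build the AUC-weighted consensus ensemble for one species
#'
#' Members are (algorithm, replicate) fits; a member joins the ensemble only
#' if its held-out AUC exceeds `auc_min`. Consensus suitability over the
#' projected M is the AUC-weighted mean of member predictions. The ensemble
#' is evaluated by pooling all passing members' held-out test cells and
#' scoring them with the consensus suitability; the max-TSS threshold of
#' that pooled evaluation binarizes the map, and the same (frozen) threshold
#' is reused for every future projection.
#'
#' @param members list of members, each a list with `fit` (an `sdm_fit`),
#'   `eval` (the member's [evaluate()] result on its own test split), and
#'   `test` (list of `presence_cells`, `absence_cells`).
#' @param stack the calibration (present-day) [climate_stack()].
#' @param region a `calibration_region` with `projected_m_cells` filled.
#' @param auc_min member inclusion threshold on held-out AUC (default 0.7,
#'   strict inequality).
#' @return an `ensemble_model`, or `NULL` (with a message) when no member
#'   passes — the species is unmodelable and excluded downstream. Fields:
#'   `species_id`, `fits`, `weights`, `member_count`, `tss_threshold`,
#'   `ensemble_eval`, `pooled_test` (the pooled held-out cells), `region`,
#'   and the present-day `prediction` (an `ensemble_prediction`).
#' @export
build_ensemble <- function(members, stack, region, auc_min = 0.7) {
  stopifnot(inherits(region, "calibration_region"))
  aucs <- vapply(members, function(m) m$eval$auc, numeric(1))
  pass <- which(aucs > auc_min)
  if (length(pass) == 0L) {
    message(sprintf("species %s unmodelable: no member with AUC > %g (best %.3f)",
                    region$species_id, auc_min, max(aucs)))
    return(NULL)
  }
  members <- members[pass]
  weights <- aucs[pass]
  cells <- region$projected_m_cells
  P <- vapply(members, function(m) predict_sdm(m$fit, stack, cells),
              numeric(length(cells)))
  if (is.null(dim(P))) P <- matrix(P, nrow = length(cells))
  suit <- as.numeric(P %*% weights / sum(weights))
  # pooled held-out evaluation against the consensus scores
  idx <- stats::setNames(seq_along(cells), cells)
  pool_scores <- function(which_set) {
    unlist(lapply(members, function(m)
      suit[idx[as.character(m$test[[which_set]])]]), use.names = FALSE)
  }
  ens_eval <- evaluate(pool_scores("presence_cells"), pool_scores("absence_cells"))
  pooled_test <- list(
    presence_cells = unlist(lapply(members, function(m) m$test$presence_cells),
                            use.names = FALSE),
    absence_cells = unlist(lapply(members, function(m) m$test$absence_cells),
                           use.names = FALSE))
  ens <- structure(
    list(species_id = region$species_id,
         pooled_test = pooled_test,
         fits = lapply(members, `[[`, "fit"),
         weights = weights,
         member_count = length(members),
         tss_threshold = ens_eval$tss_threshold,
         ensemble_eval = ens_eval,
         region = region),
    class = "ensemble_model")
  ens$prediction <- project_ensemble(ens, stack)
  ens
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf(
    "ensemble_model %s: %d members, pooled AUC %.3f, TSS %.3f @ %.2f\n",
    x$species_id, x$member_count, x$ensemble_eval$auc, x$ensemble_eval$tss,
    x$tss_threshold))
  invisible(x)
}

#' Project an ensemble onto a climate stack
#'
#' Re-applies every member fit to `target_stack` over the projected M and
#' combines them with the calibration weights; the binary map uses the
#' present-day TSS threshold (thresholds are never re-fit on future data,
#' where no truth exists). Projecting onto the calibration stack reproduces
#' the present-day prediction exactly.
#'
#' @param ens an `ensemble_model`.
#' @param target_stack a [climate_stack()] supplying all kept layers (an
#'   error names any missing layer).
#' @return an `ensemble_prediction`: `species_id`, `scenario_id`, `horizon`,
#'   `cells` (projected M), `suitability`, `binary` (logical,
#'   `suitability >= tss_threshold`), `member_count`.
#' @export
project_ensemble <- function(ens, target_stack) {
  stopifnot(inherits(ens, "ensemble_model"),
            inherits(target_stack, "climate_stack"))
  cells <- ens$region$projected_m_cells
  P <- vapply(ens$fits, function(f) predict_sdm(f, target_stack, cells),
              numeric(length(cells)))
  if (is.null(dim(P))) P <- matrix(P, nrow = length(cells))
  suit <- as.numeric(P %*% ens$weights / sum(ens$weights))
  structure(
    list(species_id = ens$species_id,
         scenario_id = target_stack$scenario_id,
         horizon = target_stack$horizon,
         cells = cells,
         suitability = suit,
         binary = suit >= ens$tss_threshold,
         member_count = ens$member_count),
    class = "ensemble_prediction")
}

#' Per-algorithm consensus maps of an ensemble
#'
#' AUC-weighted consensus of the passing replicates within each algorithm,
#' over the projected M on the given stack. Input to
#' [cv_across_algorithms()].
#'
#' @param ens an `ensemble_model`.
#' @param stack a [climate_stack()].
#' @return matrix `length(projected M) x n_algorithms` with algorithm-id
#'   columns.
#' @export
algorithm_consensus <- function(ens, stack) {
  cells <- ens$region$projected_m_cells
  algs <- vapply(ens$fits, function(f) f$algorithm_id, character(1))
  out <- sapply(unique(algs), function(a) {
    k <- which(algs == a)
    P <- vapply(ens$fits[k], function(f) predict_sdm(f, stack, cells),
                numeric(length(cells)))
    if (is.null(dim(P))) P <- matrix(P, nrow = length(cells))
    as.numeric(P %*% ens$weights[k] / sum(ens$weights[k]))
  })
  if (is.null(dim(out))) out <- matrix(out, nrow = length(cells),
                                       dimnames = list(NULL, unique(algs)))
  out
}

#' Cross-algorithm coefficient of variation
#'
#' Per-cell agreement across algorithm-level consensus maps: CV = sample
#' standard deviation / mean of the per-algorithm suitabilities. Cells with
#' mean below `eps` are no-data (`NA`); `cv_summary` is the mean CV over
#' valid cells.
#'
#' @param alg_maps matrix cells x algorithms (>= 2 columns).
#' @param eps mean-suitability floor below which a cell is no-data.
#' @return list with `cv_map` (per-cell CV, `NA` = no-data) and
#'   `cv_summary`.
#' @export
cv_across_algorithms <- function(alg_maps, eps = 1e-6) {
  if (is.null(dim(alg_maps)) || ncol(alg_maps) < 2L)
    stop("need consensus maps from at least 2 algorithms")
  mu <- rowMeans(alg_maps)
  s <- apply(alg_maps, 1, stats::sd)
  cv <- ifelse(mu < eps, NA_real_, s / mu)
  list(cv_map = cv, cv_summary = mean(cv, na.rm = TRUE))
}
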