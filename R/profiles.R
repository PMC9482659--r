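# quartile summary of one variable over a cell set (linear interpolation,
# quantile type 7)
profile_row <- function(values, label, variable) {
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  data.frame(region_label = label, variable = variable,
             mean = mean(values), q1 = q[1], median = q[2], q3 = q[3],
             n_cells = length(values))
}

#' Default variable sets for climate profiling
#'
#' `scenario_delta`: annual mean temperature, annual precipitation, max
#' temperature of warmest month, precipitation of driest month (the
#' variables whose change separates the melting family from plain warming).
#' `gain_loss`: annual mean temperature, temperature seasonality, annual
#' precipitation, precipitation seasonality (annual trends + seasonality).
#'
#' @param which `"scenario_delta"` or `"gain_loss"`.
#' @return character vector of 4 layer names.
#' @export
profile_variables <- function(which = c("scenario_delta", "gain_loss")) {
  switch(match.arg(which),
         scenario_delta = c("bio01", "bio12", "bio05", "bio14"),
         gain_loss = c("bio01", "bio04", "bio12", "bio15"))
}

#' Climate-change profile of a scenario
#'
#' Summarizes the per-cell difference (future minus baseline) of the chosen
#' variables over land cells: mean, median and quartiles.
#'
#' @param baseline,future two [climate_stack()]s on the same grid.
#' @param variables layer names (default [profile_variables()]
#'   `"scenario_delta"`).
#' @param cells cells to summarize over (default all).
#' @return a `climate_profile` data.frame: `region_label`, `variable`,
#'   `mean`, `q1`, `median`, `q3`, `n_cells`.
#' @export
scenario_delta_profile <- function(baseline, future,
                                   variables = profile_variables("scenario_delta"),
                                   cells = seq_len(n_cells(baseline$grid))) {
  d <- env_at(future, cells, variables) - env_at(baseline, cells, variables)
  out <- do.call(rbind, lapply(variables, function(v)
    profile_row(d[, v], "scenario_delta", v)))
  out$scenario_id <- future$scenario_id
  out$horizon <- future$horizon
  structure(out, class = c("climate_profile", "data.frame"))
}

#' Climate profiles of richness-gain vs richness-loss areas
#'
#' Identifies the cells with the largest richness gains (delta-SR strictly
#' above the third quartile of the delta-SR distribution over its valid
#' support) and largest losses (strictly below the first quartile), then
#' summarizes the *current* climate of each set. The valid support is the
#' set of cells with at least one species present in either period; zero
#' deltas inside that support count toward the quartiles.
#'
#' @param delta_sr per-cell delta-SR (see [delta_richness()]).
#' @param stack the present-day [climate_stack()].
#' @param support cell indices of the valid delta-SR support (>= 8 cells).
#' @param variables layer names (default [profile_variables()]
#'   `"gain_loss"`).
#' @return list with `gain` and `loss` `climate_profile` data.frames and the
#'   selected `gain_cells` / `loss_cells` (always disjoint).
#' @export
gain_loss_profiles <- function(delta_sr, stack, support,
                               variables = profile_variables("gain_loss")) {
  stopifnot(length(support) >= 8L)
  d <- delta_sr[support]
  q <- stats::quantile(d, c(0.25, 0.75), names = FALSE, type = 7)
  if (q[1] == q[2])
    stop("degenerate delta-SR distribution (Q1 = Q3); use a larger fixture")
  gain_cells <- support[d > q[2]]
  loss_cells <- support[d < q[1]]
  prof <- function(cells, label) {
    E <- env_at(stack, cells, variables)
    out <- do.call(rbind, lapply(variables, function(v)
      profile_row(E[, v], label, v)))
    structure(out, class = c("climate_profile", "data.frame"))
  }
  list(gain = prof(gain_cells, "gain_Q4"),
       loss = prof(loss_cells, "loss_Q1"),
       gain_cells = gain_cells, loss_cells = loss_cells)
}
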