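#' Canonical bioclim-like layer names
#'
#' The 19 layer names used throughout the package, mirroring the usual
#' bioclim set (bio01 = annual mean temperature, bio04 = temperature
#' seasonality, bio05 = max temperature of warmest month, bio12 = annual
#' precipitation, bio14 = precipitation of driest month, bio15 =
#' precipitation seasonality, ...).
#'
#' @return character vector of 19 names, with long descriptions as the
#'   vector's `names` attribute.
#' @export
bioclim_layer_names <- function() {
  long <- c(
    "annual mean temperature", "mean diurnal range", "isothermality",
    "temperature seasonality", "max temperature of warmest month",
    "min temperature of coldest month", "temperature annual range",
    "mean temperature of wettest quarter", "mean temperature of driest quarter",
    "mean temperature of warmest quarter", "mean temperature of coldest quarter",
    "annual precipitation", "precipitation of wettest month",
    "precipitation of driest month", "precipitation seasonality",
    "precipitation of wettest quarter", "precipitation of driest quarter",
    "precipitation of warmest quarter", "precipitation of coldest quarter")
  stats::setNames(sprintf("bio%02d", 1:19), long)
}

# location/scale used to put the standardized random fields on plausible
# bioclim-like scales (deg C for bio01-bio11 style layers, mm for bio12-bio19,
# unitless for seasonality) -- cosmetic only, all modeling standardizes again.
bioclim_scales <- function() {
  data.frame(
    layer = unname(bioclim_layer_names()),
    loc = c(18, 10, 45, 400, 30, 5, 25, 20, 16, 24, 12,
            1200, 220, 20, 60, 550, 80, 300, 250),
    scale = c(6, 3, 10, 150, 5, 6, 6, 6, 6, 6, 7,
              600, 120, 15, 25, 280, 60, 180, 150))
}

# Smoothed standardized Gaussian random field on the grid: white noise
# convolved with a separable Gaussian kernel of sd = autocorr_length cells.
# Returns an n_rows x n_cols matrix with mean 0, sd 1 across cells.
smooth_field <- function(n_rows, n_cols, autocorr_length) {
  p <- as.integer(ceiling(3 * autocorr_length))
  z <- matrix(stats::rnorm((n_rows + 2L * p) * (n_cols + 2L * p)),
              n_rows + 2L * p, n_cols + 2L * p)
  k <- stats::dnorm(-p:p, sd = autocorr_length)
  k <- k / sum(k)
  # separable convolution via banded matrices, then crop the padding
  A <- matrix(0, n_rows, n_rows + 2L * p)
  for (i in seq_len(n_rows)) A[i, i:(i + 2L * p)] <- k
  B <- matrix(0, n_cols, n_cols + 2L * p)
  for (j in seq_len(n_cols)) B[j, j:(j + 2L * p)] <- k
  f <- A %*% z %*% t(B)
  (f - mean(f)) / stats::sd(f)
}

#' Generate a synthetic baseline climate stack
#'
#' Produces 19 correlated, spatially autocorrelated bioclim-like layers on a
#' grid. Each layer is a smoothed Gaussian random field; cross-layer
#' correlation of approximately `cross_corr` is induced by mixing every layer
#' with one shared latent field with weights `sqrt(cross_corr)` and
#' `sqrt(1 - cross_corr)`. Layers are then placed on plausible bioclim scales
#' (degrees / millimetres); all downstream modeling re-standardizes, so the
#' scales are cosmetic.
#'
#' @param grid a [grid_spec()].
#' @param autocorr_length spatial correlation length in cells (Gaussian kernel
#'   sd); must be >= 1 and small enough for the grid (the kernel half-width
#'   `3 * autocorr_length` must fit inside the shorter grid edge).
#' @param cross_corr target pairwise correlation between layers, in \[0, 1).
#' @param seed integer seed; the stack is a pure function of (inputs, seed).
#' @return an object of class `climate_stack` with fields `grid`, `values`
#'   (an `n_cells x 19` matrix with layer-name columns), `scenario_id`
#'   (`"baseline"`) and `horizon` (`"T0"`).
#' @export
generate_climate <- function(grid, autocorr_length = 3, cross_corr = 0.6,
                             seed = 1L) {
  stopifnot(inherits(grid, "grid_spec"))
  if (autocorr_length < 1)
    stop("autocorr_length must be >= 1 cell")
  if (cross_corr < 0 || cross_corr >= 1)
    stop("cross_corr must lie in [0, 1)")
  if (min(grid$n_rows, grid$n_cols) < 3 * autocorr_length)
    stop(sprintf(
      "grid too small for autocorr_length %g: need at least %d cells per side",
      autocorr_length, as.integer(ceiling(3 * autocorr_length))))
  set.seed(as.integer(seed))
  shared <- smooth_field(grid$n_rows, grid$n_cols, autocorr_length)
  sc <- bioclim_scales()
  vals <- matrix(NA_real_, n_cells(grid), nrow(sc),
                 dimnames = list(NULL, sc$layer))
  w_shared <- sqrt(cross_corr)
  w_own <- sqrt(1 - cross_corr)
  for (i in seq_len(nrow(sc))) {
    own <- smooth_field(grid$n_rows, grid$n_cols, autocorr_length)
    f <- w_shared * shared + w_own * own
    f <- (f - mean(f)) / stats::sd(f)
    vals[, i] <- sc$loc[i] + sc$scale[i] * as.vector(t(f))  # row-major cells
  }
  climate_stack(grid, vals, scenario_id = "baseline", horizon = "T0")
}

#' Construct a climate stack
#'
#' @param grid a [grid_spec()].
#' @param values numeric matrix `n_cells(grid) x n_layers` with unique column
#'   names; no missing values.
#' @param scenario_id one of `"baseline"`, `"control"`, `"melting"`.
#' @param horizon one of `"T0"`, `"T1"`, `"T2"`, `"T3"`.
#' @return an object of class `climate_stack`.
#' @export
climate_stack <- function(grid, values,
                          scenario_id = c("baseline", "control", "melting"),
                          horizon = c("T0", "T1", "T2", "T3")) {
  stopifnot(inherits(grid, "grid_spec"), is.matrix(values))
  scenario_id <- match.arg(scenario_id)
  horizon <- match.arg(horizon)
  if (nrow(values) != n_cells(grid))
    stop("values must have one row per grid cell")
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop("layer names must be present and unique")
  if (anyNA(values))
    stop("climate layers may not contain missing values")
  structure(
    list(grid = grid, values = values, scenario_id = scenario_id,
         horizon = horizon),
    class = "climate_stack")
}

#' @export
print.climate_stack <- function(x, ...) {
  cat(sprintf("climate_stack [%s/%s]: %d layers on %d x %d grid\n",
              x$scenario_id, x$horizon, ncol(x$values),
              x$grid$n_rows, x$grid$n_cols))
  invisible(x)
}

#' Layer names of a climate stack
#' @param stack a [climate_stack()].
#' @return character vector.
#' @export
stack_layers <- function(stack) colnames(stack$values)

#' Extract layer values at cells
#' @param stack a [climate_stack()].
#' @param cells integer cell indices.
#' @param layers layer names (default all).
#' @return numeric matrix `length(cells) x length(layers)`.
#' @export
env_at <- function(stack, cells, layers = stack_layers(stack)) {
  missing <- setdiff(layers, stack_layers(stack))
  if (length(missing) > 0)
    stop("stack is missing layer(s): ", paste(missing, collapse = ", "))
  stack$values[cells, layers, drop = FALSE]
}

#' Per-layer standard deviations of a stack
#' @param stack a [climate_stack()].
#' @return named numeric vector.
#' @export
layer_sds <- function(stack) apply(stack$values, 2, stats::sd)

#' Mean per-cell climatic distance between two stacks
#'
#' Euclidean distance per cell in standardized layer space (each layer scaled
#' by its standard deviation in `ref`, which defaults to `a`), averaged over
#' cells. This is the dissimilarity measure used to order scenario families.
#'
#' @param a,b two [climate_stack()]s on the same grid and layers.
#' @param ref stack whose layer standard deviations define the scaling.
#' @return a single non-negative number.
#' @export
climate_distance <- function(a, b, ref = a) {
  stopifnot(identical(stack_layers(a), stack_layers(b)))
  s <- layer_sds(ref)
  s[s == 0] <- 1
  d <- sweep(a$values - b$values, 2, s, "/")
  mean(sqrt(rowSums(d^2)))
}

#' Lag-1 spatial autocorrelation of a layer
#'
#' Correlation between each cell and its east neighbour (a Moran's-I style
#' lag-1 measure on the regular grid).
#'
#' @param stack a [climate_stack()].
#' @param layer layer name.
#' @return correlation in \[-1, 1\].
#' @export
lag1_autocor <- function(stack, layer) {
  g <- stack$grid
  m <- matrix(stack$values[, layer], g$n_rows, g$n_cols, byrow = TRUE)
  stats::cor(as.vector(m[, -g$n_cols]), as.vector(m[, -1]))
}

#' Generate future scenario stacks from a baseline
#'
#' Builds two scenario families ("control", the plain high-emission warming
#' pathway, and "melting", warming plus an ice-sheet meltwater perturbation)
#' at three horizons T1 < T2 < T3. Each family is defined by per-layer drift
#' magnitudes expressed in units of the baseline layer's standard deviation;
#' the drift at horizon k is `k / horizons` of the full magnitude, so change
#' accumulates monotonically and the stated magnitudes are reached at T3.
#'
#' The melting family must be strictly more climatically dissimilar from the
#' baseline than the control family: the mean per-cell standardized Euclidean
#' distance to baseline is validated to be strictly larger for melting at
#' every horizon, and generation fails otherwise. This constructed ordering
#' is the synthetic analogue of a meltwater-weakened overturning circulation
#' increasing climatic dissimilarity even while damping mean warming.
#'
#' @param baseline a baseline [climate_stack()].
#' @param control_shift,melting_shift named numeric vectors: full-horizon
#'   drift per layer in baseline-sd units (layers not named drift by 0).
#' @param horizons number of future horizons (fixed at 3).
#' @param seed integer seed (kept for interface symmetry; the drift field is
#'   deterministic).
#' @return named list of 6 `climate_stack`s: `control_T1` ... `melting_T3`.
#' @export
generate_scenarios <- function(baseline, control_shift, melting_shift,
                               horizons = 3L, seed = 1L) {
  stopifnot(inherits(baseline, "climate_stack"), horizons == 3L)
  layers <- stack_layers(baseline)
  expand <- function(shift) {
    bad <- setdiff(names(shift), layers)
    if (length(bad) > 0)
      stop("unknown layer(s) in shift: ", paste(bad, collapse = ", "))
    full <- stats::setNames(numeric(length(layers)), layers)
    full[names(shift)] <- as.numeric(shift)
    full
  }
  cs <- expand(control_shift)
  ms <- expand(melting_shift)
  degenerate <- all(ms == 0) && all(cs == 0)  # null run: all stacks = baseline
  if (!degenerate && sqrt(sum(ms^2)) <= sqrt(sum(cs^2)))
    stop(paste0(
      "melting_shift must be strictly more dissimilar than control_shift ",
      "(standardized L2 norm ", round(sqrt(sum(ms^2)), 3), " vs ",
      round(sqrt(sum(cs^2)), 3), ")"))
  sds <- layer_sds(baseline)
  out <- list()
  for (fam in c("control", "melting")) {
    shift <- if (fam == "control") cs else ms
    for (k in seq_len(horizons)) {
      delta <- (k / horizons) * shift * sds
      vals <- sweep(baseline$values, 2, delta, "+")
      out[[paste0(fam, "_T", k)]] <-
        climate_stack(baseline$grid, vals, scenario_id = fam,
                      horizon = paste0("T", k))
    }
  }
  # the ordering is a postcondition, not an assumption: verify on the output
  if (!degenerate) {
    for (k in seq_len(horizons)) {
      dc <- climate_distance(baseline, out[[paste0("control_T", k)]])
      dm <- climate_distance(baseline, out[[paste0("melting_T", k)]])
      if (!(dm > dc))
        stop(sprintf("scenario dissimilarity ordering violated at T%d", k))
    }
  }
  out
}
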