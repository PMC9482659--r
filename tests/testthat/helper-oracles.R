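# Independent brute-force oracles the fast implementations are checked
# against. These deliberately use the most literal definitions possible.

# AUC by enumerating every presence-absence pair, ties count 1/2
auc_oracle <- function(pres, abs) {
  s <- 0
  for (p in pres) for (a in abs)
    s <- s + if (p > a) 1 else if (p == a) 0.5 else 0
  s / (length(pres) * length(abs))
}

# max TSS by looping the full 101-point threshold grid; lowest threshold
# wins ties
tss_oracle <- function(pres, abs) {
  best <- list(tss = -Inf, threshold = NA)
  for (t in (0:100) / 100) {
    sens <- mean(pres >= t)
    spec <- mean(abs < t)
    tss <- sens + spec - 1
    if (tss > best$tss) best <- list(tss = tss, threshold = t)
  }
  best
}

# Sorensen dissimilarity from explicit species sets
bsor_oracle <- function(species_present, species_future) {
  a <- length(intersect(species_present, species_future))
  b <- length(setdiff(species_present, species_future))
  c_ <- length(setdiff(species_future, species_present))
  if (a + b + c_ == 0) return(NA_real_)
  (b + c_) / (2 * a + b + c_)
}

# small all-land world shared by fixture-based tests
tiny_world <- function(n = 20, countries = 2, ecos = 2, seed = 7) {
  g <- grid_spec(n, n, cell_size = 0.5)
  list(grid = g,
       mask = generate_world(g, countries, ecos, seed = seed),
       stack = generate_climate(g, autocorr_length = 2, cross_corr = 0.5,
                                seed = seed))
}

# a hand-made climate stack from explicit layer columns
stack_from <- function(grid, ...) {
  cols <- list(...)
  climate_stack(grid, do.call(cbind, cols))
}

# a species_record_set built directly from cells (bypassing occurrence CSVs)
record_set <- function(cells, id = "spX", retained = TRUE) {
  structure(list(species_id = id, unique_cells = sort(unique(cells)),
                 n_raw = length(cells), retained = retained,
                 exclusion_reason = if (retained) "none" else "too_few_records"),
            class = "species_record_set")
}
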