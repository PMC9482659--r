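#!/usr/bin/env Rscript
# Stage 2 — occurrence filtering and predictor pre-selection.
#
# Applies the data-preparation rules: snap records to cells and deduplicate,
# keep species with >= 25 unique cells, check endemicity against a
# one-cell-buffered country mask, cap at 500 records, and per species run
# the |r| < 0.8 + VIF collinearity filter over the accessible area M.

library(endemicshift)

st <- readRDS("scratch/01_simulated.rds")
cfg <- st$cfg; th <- cfg$thresholds

prep <- list(); rows <- list()
for (i in seq_along(st$species)) {
  s <- dedupe_and_filter(st$occurrences[[i]], st$grid, th$min_records)
  if (s$retained && !endemicity_check(s, st$mask, th$endemic_buffer)) {
    s$retained <- FALSE; s$exclusion_reason <- "not_endemic"
  }
  if (s$retained)
    s <- cap_records(s, th$max_records,
                     seed = sub_seed(cfg$seed, s$species_id, "cap"))
  prep[[s$species_id]] <- s
  rows[[i]] <- data.frame(species_id = s$species_id, n_raw = s$n_raw,
                          n_unique = length(s$unique_cells),
                          retained = s$retained, reason = s$exclusion_reason)
}
report <- do.call(rbind, rows)
write.csv(report, "results/exclusion_report.csv", row.names = FALSE)
cat(sprintf("%d/%d species retained (reasons: %s)\n",
            sum(report$retained), nrow(report),
            paste(names(table(report$reason)), table(report$reason),
                  collapse = ", ", sep = "=")))

# predictor selection on each retained species' calibration region
selections <- list()
for (s in Filter(function(x) x$retained, prep)) {
  cr <- build_projected_m(build_m(s, st$mask, th$m_buffer), st$mask,
                          th$proj_buffer)
  sel <- select_predictors(st$baseline, cr$m_cells, th$r_threshold)
  selections[[s$species_id]] <- list(region = cr, selection = sel)
}
kept_n <- sapply(selections, function(x) length(x$selection$kept_layers))
cat(sprintf("predictor selection keeps %d-%d of 19 layers (median %d)\n",
            min(kept_n), max(kept_n), as.integer(median(kept_n))))

saveRDS(list(prep = prep, selections = selections),
        "scratch/02_prepared.rds")
cat("state saved to scratch/02_prepared.rds\n")
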