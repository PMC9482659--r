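#' Default pipeline configuration
#'
#' All tunable constants of the pipeline in one list: grid and world
#' geometry, climate-field parameters, scenario drifts, virtual-species
#' niche ranges, and the modeling thresholds (minimum 25 unique records,
#' 500-record cap, |r| < 0.8 predictor screening, 10,000 pseudo-absences at
#' prevalence 0.5, 70/30 splits x 10 replicates, AUC > 0.7 ensemble
#' membership, PSH factor 0.6, 0.08333 deg endemicity buffer, 4 deg
#' accessible-area buffer, 2 deg projection buffer). Every value can be
#' overridden, e.g. via [load_config()].
#'
#' @param seed top-level integer seed; all stage and per-species seeds are
#'   derived from it with [sub_seed()].
#' @return a `run_config` list.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    grid = list(n_rows = 60L, n_cols = 60L, cell_size = 0.5,
                origin = c(-100, 30)),
    n_countries = 12L,
    ecoregions_per_country = 3L,
    climate = list(autocorr_length = 4, cross_corr = 0.6),
    scenarios = list(
      # full-horizon (T3) drifts in baseline-sd units. The control family is
      # plain warming; the melting family damps mean warming (bio01) but
      # perturbs seasonal extremes (bio04, bio05, bio14) and precipitation
      # harder, making it strictly more dissimilar from baseline.
      control_shift = c(bio01 = 1.5, bio05 = 1.2, bio12 = -0.8, bio14 = -0.6),
      melting_shift = c(bio01 = 1.0, bio04 = 1.2, bio05 = 3.0,
                        bio12 = -1.8, bio14 = -3.0)),
    n_species = 30L,
    species_countries = NULL,
    niche = list(n_vars = 2:3, sigma = c(0.6, 1.2), tau = c(0.3, 0.6),
                 min_range_cells = 40L),
    occurrences = list(n_per_species = 300L, detection_noise = 0),
    thresholds = list(min_records = 25L, max_records = 500L,
                      r_threshold = 0.8, pa_n = 10000L,
                      train_fraction = 0.7, n_reps = 10L, auc_min = 0.7,
                      psh_factor = 0.6, endemic_buffer = 0.08333,
                      m_buffer = 4.0, proj_buffer = 2.0),
    roster = sdm_algorithms(),
    output_dir = NULL),
    class = "run_config")
}

#' Load a configuration from YAML
#'
#' Reads a YAML file and merges it over [default_config()]; nested lists
#' merge element-wise, so a file needs to state only the values it changes.
#'
#' @param path YAML file path.
#' @param seed optional seed override (takes precedence over the file).
#' @return a `run_config`.
#' @export
load_config <- function(path, seed = NULL) {
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_config(), user)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  for (nm in c("control_shift", "melting_shift"))
    cfg$scenarios[[nm]] <- unlist(cfg$scenarios[[nm]])
  class(cfg) <- "run_config"
  validate_config(cfg)
  cfg
}

#' Validate a run configuration
#' @param cfg a `run_config`.
#' @return the config, invisibly; errors on invalid values.
#' @export
validate_config <- function(cfg) {
  th <- cfg$thresholds
  stopifnot(
    is.numeric(cfg$seed), cfg$n_countries >= 1, cfg$n_species >= 1,
    th$min_records >= 1, th$max_records >= th$min_records,
    th$r_threshold > 0, th$r_threshold <= 1,
    th$train_fraction > 0, th$train_fraction < 1,
    th$n_reps >= 1, th$psh_factor > 0, th$psh_factor < 1,
    all(cfg$roster %in% sdm_algorithms()), length(cfg$roster) >= 1)
  invisible(cfg)
}

#' Deterministic sub-seed derivation
#'
#' Hashes the top-level seed together with any number of string labels
#' (stage, species id, algorithm, replicate ...) into a 31-bit integer.
#' Adding species or stages never perturbs the seeds of existing ones.
#'
#' @param seed top-level integer seed.
#' @param ... labels, coerced to character and joined.
#' @return integer in \[0, 2^31 - 12\].
#' @export
sub_seed <- function(seed, ...) {
  key <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  h <- as.numeric(seed) %% 2147483629
  for (c in utf8ToInt(key)) h <- (h * 31 + c) %% 2147483629
  as.integer(h)
}

# fit + evaluate all roster x replicate members for one species
fit_members <- function(splits, stack, kept, roster, seed, species_id) {
  members <- list()
  for (alg in roster) {
    for (r in seq_along(splits)) {
      sp <- splits[[r]]
      fit <- fit_algorithm(sp$train, stack, kept, alg,
                           seed = sub_seed(seed, species_id, alg, r))
      ev <- evaluate(
        predict_sdm(fit, stack, sp$test$presence_cells),
        predict_sdm(fit, stack, sp$test$absence_cells))
      members[[length(members) + 1L]] <-
        list(fit = fit, eval = ev, test = sp$test,
             algorithm = alg, replicate = r)
    }
  }
  members
}

#' Run the full pipeline
#'
#' Generate (world, climate, scenarios, species, occurrences) -> prepare
#' (filtering, endemicity, record cap, predictor selection) -> model
#' (accessible areas, pseudo-absences, replicate fits, AUC-weighted
#' ensembles, TSS binarization) -> project (all scenario/horizon stacks) ->
#' metrics (range change, PAM/SR/delta-SR, PSH extent, temporal Sorensen,
#' cross-algorithm CV) -> climate profiles. Two runs with an identical
#' config produce identical outputs.
#'
#' @param cfg a `run_config` (see [default_config()], [load_config()]).
#' @param quiet suppress progress messages.
#' @return a `pipeline_run` list with elements `world` (grid, mask,
#'   baseline, scenarios), `species`, `prep`, `models`, `predictions`,
#'   `metrics`, `profiles`, `summary` and `manifest`. If
#'   `cfg$output_dir` is set, all tabular outputs are written there as CSV
#'   plus a JSON manifest.
#' @export
run_pipeline <- function(cfg = default_config(), quiet = FALSE) {
  validate_config(cfg)
  say <- function(...) if (!quiet) message(sprintf(...))
  th <- cfg$thresholds

  ## ---- generate ----
  grid <- grid_spec(cfg$grid$n_rows, cfg$grid$n_cols, cfg$grid$cell_size,
                    cfg$grid$origin)
  mask <- generate_world(grid, cfg$n_countries, cfg$ecoregions_per_country,
                         seed = sub_seed(cfg$seed, "world"))
  baseline <- generate_climate(grid, cfg$climate$autocorr_length,
                               cfg$climate$cross_corr,
                               seed = sub_seed(cfg$seed, "climate"))
  scen <- generate_scenarios(baseline, cfg$scenarios$control_shift,
                             cfg$scenarios$melting_shift,
                             seed = sub_seed(cfg$seed, "scenarios"))
  species <- generate_virtual_species(
    baseline, mask, cfg$n_species, cfg$niche,
    seed = sub_seed(cfg$seed, "species"), countries = cfg$species_countries)
  occs <- lapply(species, function(sp)
    sample_occurrences(sp, cfg$occurrences$n_per_species,
                       cfg$occurrences$detection_noise,
                       seed = sub_seed(cfg$seed, sp$species_id, "occ")))
  say("generated %d species on a %dx%d grid, %d countries",
      length(species), grid$n_rows, grid$n_cols, cfg$n_countries)

  ## ---- prepare ----
  prep <- list(); exclusions <- list()
  for (i in seq_along(species)) {
    s <- dedupe_and_filter(occs[[i]], grid, th$min_records)
    if (s$retained && !endemicity_check(s, mask, th$endemic_buffer)) {
      s$retained <- FALSE
      s$exclusion_reason <- "not_endemic"
    }
    if (s$retained)
      s <- cap_records(s, th$max_records,
                       seed = sub_seed(cfg$seed, s$species_id, "cap"))
    prep[[s$species_id]] <- s
    if (!s$retained)
      exclusions[[s$species_id]] <- s$exclusion_reason
  }
  retained <- Filter(function(s) s$retained, prep)
  say("prepared: %d/%d species retained", length(retained), length(prep))

  ## ---- model ----
  ensembles <- list(); report_rows <- list(); contrib <- list()
  for (s in retained) {
    sid <- s$species_id
    cr <- build_m(s, mask, th$m_buffer)
    cr <- build_projected_m(cr, mask, th$proj_buffer)
    sel <- select_predictors(baseline, cr$m_cells, th$r_threshold)
    ts <- draw_pseudo_absences(cr, s$unique_cells, th$pa_n,
                               seed = sub_seed(cfg$seed, sid, "pa"))
    splits <- split_replicates(ts, th$train_fraction, th$n_reps,
                               seed = sub_seed(cfg$seed, sid, "split"))
    members <- fit_members(splits, baseline, sel$kept_layers, cfg$roster,
                           cfg$seed, sid)
    ens <- build_ensemble(members, baseline, cr, th$auc_min)
    if (is.null(ens)) {
      exclusions[[sid]] <- "unmodelable"
      next
    }
    ens$kept_layers <- sel$kept_layers
    ensembles[[sid]] <- ens
    # top-2 variable contributions, once per algorithm (first passing member)
    algs <- vapply(ens$fits, function(f) f$algorithm_id, character(1))
    top2 <- lapply(unique(algs), function(a) {
      f <- ens$fits[[which(algs == a)[1L]]]
      vc <- variable_contributions(f, ts, baseline,
                                   seed = sub_seed(cfg$seed, sid, a, "vc"))
      utils::head(vc$layer, 2L)
    })
    names(top2) <- unique(algs)
    contrib[[sid]] <- top2
    for (m in members) {
      tv <- top2[[m$algorithm]]
      report_rows[[length(report_rows) + 1L]] <- data.frame(
        species_id = sid, algorithm = m$algorithm, replicate = m$replicate,
        auc = m$eval$auc, tss = m$eval$tss,
        tss_threshold = m$eval$tss_threshold,
        top_var1 = if (is.null(tv)) NA_character_ else tv[1L],
        top_var2 = if (is.null(tv) || length(tv) < 2L) NA_character_ else tv[2L],
        fallback_used = cr$fallback_used)
    }
    say("modeled %s: %d/%d members pass, pooled AUC %.3f",
        sid, ens$member_count, length(members), ens$ensemble_eval$auc)
  }
  model_report <- if (length(report_rows)) do.call(rbind, report_rows)
                  else data.frame()

  ## ---- project ----
  predictions <- list()
  if (length(ensembles) > 0) {
    predictions[["baseline_T0"]] <- lapply(ensembles, `[[`, "prediction")
    for (nm in names(scen))
      predictions[[nm]] <- lapply(ensembles, project_ensemble,
                                  target_stack = scen[[nm]])
  } else {
    warning("no modelable species; metrics are empty")
  }

  ## ---- metrics ----
  metrics <- compute_metrics(predictions, ensembles, species, mask, baseline,
                             th$psh_factor)

  ## ---- profiles ----
  profiles <- compute_profiles(baseline, scen, metrics, mask)

  ## ---- summary + manifest ----
  summary_tabs <- summarize_run(metrics)
  manifest <- list(
    package = "endemicshift",
    version = as.character(utils::packageVersion("endemicshift")),
    seed = cfg$seed,
    grid = list(n_rows = grid$n_rows, n_cols = grid$n_cols,
                cell_size = grid$cell_size),
    n_species_generated = length(species),
    n_species_retained = length(retained),
    n_species_modeled = length(ensembles),
    exclusions = exclusions,
    scenarios = names(scen),
    roster = cfg$roster)

  run <- structure(
    list(config = cfg,
         world = list(grid = grid, mask = mask, baseline = baseline,
                      scenarios = scen),
         species = species, occurrences = occs, prep = prep,
         models = list(ensembles = ensembles, report = model_report,
                       contributions = contrib),
         predictions = predictions, metrics = metrics, profiles = profiles,
         summary = summary_tabs, manifest = manifest),
    class = "pipeline_run")
  if (!is.null(cfg$output_dir)) write_run(run, cfg$output_dir)
  run
}

# all downstream biodiversity accounting for a set of projections
compute_metrics <- function(predictions, ensembles, species, mask, baseline,
                            psh_factor) {
  if (length(ensembles) == 0L)
    return(list(range_change = data.frame(), pams = list(),
                richness = list(), psh = NULL, psh_extent = data.frame(),
                bsor = data.frame(), cv = data.frame()))
  nc <- n_cells(mask$grid)
  sp_country <- stats::setNames(
    vapply(species, `[[`, integer(1), "country_id"),
    vapply(species, `[[`, character(1), "species_id"))

  pams <- lapply(predictions, build_pam, n_total_cells = nc)
  rich <- lapply(pams, function(p) richness(p, mask))
  sr0 <- rich$baseline_T0$sr

  rc_rows <- list()
  for (nm in setdiff(names(predictions), "baseline_T0")) {
    for (sid in names(ensembles)) {
      pres <- predictions$baseline_T0[[sid]]
      fut <- predictions[[nm]][[sid]]
      if (sum(pres$binary) == 0L) next  # never achieved a present-day range
      r <- range_change(pres$binary, fut$binary, sid,
                        fut$scenario_id, fut$horizon)
      rc_rows[[length(rc_rows) + 1L]] <- data.frame(
        species_id = sid, country = sp_country[[sid]],
        scenario = r$scenario, horizon = r$horizon,
        n_present = r$n_present, n_future = r$n_future, delta = r$delta,
        complete_loss = r$complete_loss, category = r$category)
    }
  }
  range_change_df <- if (length(rc_rows)) do.call(rbind, rc_rows)
                     else data.frame()

  # hotspots are defined only where present-day richness exists at all
  occupied <- which(rich$baseline_T0$max_sr > 0L)
  psh <- hotspots(sr0, mask, psh_factor, countries = occupied)
  ext_rows <- list(); bsor_rows <- list()
  for (nm in setdiff(names(predictions), "baseline_T0")) {
    ext <- hotspot_extent(psh, rich[[nm]]$sr, mask)
    ext$scenario <- sub("_T[0-9]$", "", nm)
    ext$horizon <- sub("^.*_(T[0-9])$", "\\1", nm)
    ext_rows[[nm]] <- ext
    bs <- temporal_sorensen(pams$baseline_T0, pams[[nm]], psh$all_cells)
    per_cty <- vapply(seq_len(mask$country_count), function(cty) {
      cells <- psh$psh_cells[[cty]]
      if (length(cells) == 0L) return(NA_real_)
      stats::median(bs$bsor[match(cells, psh$all_cells)], na.rm = TRUE)
    }, numeric(1))
    bsor_rows[[nm]] <- data.frame(
      scenario = sub("_T[0-9]$", "", nm),
      horizon = sub("^.*_(T[0-9])$", "\\1", nm),
      median_bsor = bs$median,
      country = NA_integer_)
    bsor_rows[[paste0(nm, "_cty")]] <- data.frame(
      scenario = sub("_T[0-9]$", "", nm),
      horizon = sub("^.*_(T[0-9])$", "\\1", nm),
      median_bsor = per_cty,
      country = seq_len(mask$country_count))
  }

  cv_rows <- lapply(names(ensembles), function(sid) {
    cv <- cv_across_algorithms(algorithm_consensus(ensembles[[sid]], baseline))
    data.frame(species_id = sid, cv = cv$cv_summary)
  })

  list(range_change = range_change_df,
       pams = pams,
       richness = rich,
       psh = psh,
       psh_extent = do.call(rbind, ext_rows),
       bsor = do.call(rbind, bsor_rows),
       cv = do.call(rbind, cv_rows))
}

# scenario climate deltas + gain/loss profiles per scenario family x horizon
compute_profiles <- function(baseline, scen, metrics, mask) {
  land <- land_cells(mask)
  deltas <- do.call(rbind, lapply(scen, function(s)
    scenario_delta_profile(baseline, s, cells = land)))
  gl <- list()
  if (length(metrics$richness) > 1L) {
    sr0 <- metrics$richness$baseline_T0$sr
    for (nm in setdiff(names(metrics$richness), "baseline_T0")) {
      srf <- metrics$richness[[nm]]$sr
      support <- which(sr0 + srf > 0L)
      if (length(support) < 8L) next
      res <- tryCatch(
        gain_loss_profiles(delta_richness(sr0, srf), baseline, support),
        error = function(e) NULL)
      if (is.null(res)) next
      g <- rbind(res$gain, res$loss)
      g$scenario_id <- sub("_T[0-9]$", "", nm)
      g$horizon <- sub("^.*_(T[0-9])$", "\\1", nm)
      gl[[nm]] <- g
    }
  }
  list(scenario_deltas = deltas,
       gain_loss = if (length(gl)) do.call(rbind, gl) else data.frame())
}

#' Summary tables of a pipeline run
#'
#' Median range-change delta and complete-loss proportion per country x
#' scenario x horizon (and pooled across countries), the PSH extent table,
#' and the temporal-Sorensen median table.
#'
#' @param metrics the `metrics` element of a `pipeline_run` (or the run
#'   itself).
#' @return list of data.frames `range_change_summary`, `psh_extent`,
#'   `bsor`, `category_counts`.
#' @export
summarize_run <- function(metrics) {
  if (inherits(metrics, "pipeline_run")) metrics <- metrics$metrics
  rc <- metrics$range_change
  if (is.null(rc) || nrow(rc) == 0L)
    return(list(range_change_summary = data.frame(),
                psh_extent = metrics$psh_extent %||% data.frame(),
                bsor = metrics$bsor %||% data.frame(),
                category_counts = data.frame()))
  agg <- function(df) data.frame(
    median_delta = stats::median(df$delta),
    complete_loss_prop = mean(df$complete_loss),
    n_species = nrow(df))
  groups_all <- split(rc, list(rc$scenario, rc$horizon), drop = TRUE)
  by_all <- do.call(rbind, lapply(groups_all, agg))
  keys <- do.call(rbind, strsplit(names(groups_all), ".", fixed = TRUE))
  by_all <- cbind(data.frame(scenario = keys[, 1], horizon = keys[, 2]),
                  by_all, country = NA_integer_)
  groups_cty <- split(rc, list(rc$scenario, rc$horizon, rc$country),
                      drop = TRUE)
  by_cty <- do.call(rbind, lapply(groups_cty, agg))
  keys <- do.call(rbind, strsplit(names(groups_cty), ".", fixed = TRUE))
  by_cty <- cbind(data.frame(scenario = keys[, 1], horizon = keys[, 2]),
                  by_cty, country = as.integer(keys[, 3]))
  rcs <- rbind(by_all, by_cty)
  rownames(rcs) <- NULL
  cat_counts <- as.data.frame(table(scenario = rc$scenario,
                                    horizon = rc$horizon,
                                    category = rc$category))
  names(cat_counts)[4] <- "n_species"
  list(range_change_summary = rcs,
       psh_extent = metrics$psh_extent,
       bsor = metrics$bsor,
       category_counts = cat_counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# write all tabular outputs + manifest of a run
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    if (!is.null(df) && is.data.frame(df) && nrow(df) > 0)
      utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  }
  excl <- do.call(rbind, lapply(names(run$prep), function(sid) {
    s <- run$prep[[sid]]
    data.frame(species_id = sid, n_raw = s$n_raw,
               n_unique = length(s$unique_cells),
               retained = s$retained && is.null(run$manifest$exclusions[[sid]]),
               reason = run$manifest$exclusions[[sid]] %||% s$exclusion_reason)
  }))
  w(excl, "exclusion_report.csv")
  w(run$models$report, "model_report.csv")
  w(run$metrics$range_change, "range_change.csv")
  w(run$metrics$psh_extent, "psh_extent.csv")
  w(run$metrics$bsor, "bsor.csv")
  w(run$metrics$cv, "cv.csv")
  w(run$summary$range_change_summary, "range_change_summary.csv")
  w(run$summary$category_counts, "category_counts.csv")
  w(run$profiles$scenario_deltas, "profiles_scenario_deltas.csv")
  w(run$profiles$gain_loss, "profiles_gain_loss.csv")
  if (length(run$metrics$richness) > 0) {
    sr <- data.frame(cell = seq_len(n_cells(run$world$grid)))
    for (nm in names(run$metrics$richness))
      sr[[paste0("sr_", nm)]] <- run$metrics$richness[[nm]]$sr
    w(sr, "species_richness.csv")
  }
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(run)
}
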