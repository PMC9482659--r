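# a hand-made envelope fit that predicts a constant 0 or 1 everywhere
const_fit <- function(value, layers = c("A", "B")) {
  lo <- if (value == 1) rep(-Inf, length(layers)) else rep(Inf, length(layers))
  structure(list(algorithm_id = "sre", kept_layers = layers,
                 center = stats::setNames(rep(0, length(layers)), layers),
                 scale = stats::setNames(rep(1, length(layers)), layers),
                 model = list(type = "sre", lo = lo,
                              hi = rep(Inf, length(layers)))),
            class = "sdm_fit")
}

fake_member <- function(fit, auc, test_p = 1:3, test_a = 4:6) {
  list(fit = fit, eval = list(auc = auc),
       test = list(presence_cells = test_p, absence_cells = test_a))
}

tiny_region <- function(cells = 1:20) {
  structure(list(species_id = "sp", m_cells = cells,
                 projected_m_cells = cells, fallback_used = FALSE),
            class = "calibration_region")
}

test_that("ensemble weighting follows member AUCs", {
  g <- grid_spec(10, 10)
  set.seed(1)
  st <- stack_from(g, A = rnorm(100), B = rnorm(100))
  region <- tiny_region()

  # a failing member (AUC 0.65) contributes nothing
  ens <- build_ensemble(list(fake_member(const_fit(0), 0.65),
                             fake_member(const_fit(1), 0.9)),
                        st, region, auc_min = 0.7)
  expect_identical(ens$member_count, 1L)
  expect_equal(ens$prediction$suitability, rep(1, 20))

  # equal weights average the predictions
  ens2 <- build_ensemble(list(fake_member(const_fit(0), 0.8),
                              fake_member(const_fit(1), 0.8)),
                         st, region, auc_min = 0.7)
  expect_equal(ens2$prediction$suitability, rep(0.5, 20))

  # AUC-weighted mean: weights {0.8, 0.9}, predictions {0, 1} -> 0.9/1.7
  ens3 <- build_ensemble(list(fake_member(const_fit(0), 0.8),
                              fake_member(const_fit(1), 0.9)),
                         st, region, auc_min = 0.7)
  expect_equal(ens3$prediction$suitability, rep(0.9 / 1.7, 20),
               tolerance = 1e-12)

  # nobody passes -> unmodelable
  expect_message(
    none <- build_ensemble(list(fake_member(const_fit(1), 0.5)), st, region),
    "unmodelable")
  expect_null(none)
})

# one real small ensemble reused by several blocks
real_ensemble <- function(n_reps = 4, auc_min = 0.7) {
  tw <- tiny_world(24, 2, 2, seed = 13)
  sp <- generate_virtual_species(tw$stack, tw$mask, 1,
                                 list(min_range_cells = 50), seed = 21)[[1]]
  occ <- sample_occurrences(sp, 250, 0, seed = 3)
  s <- dedupe_and_filter(occ, tw$grid)
  cr <- build_projected_m(build_m(s, tw$mask), tw$mask)
  sel <- select_predictors(tw$stack, cr$m_cells)
  ts <- draw_pseudo_absences(cr, s$unique_cells, seed = 5)
  splits <- split_replicates(ts, n_reps = n_reps, seed = 6)
  members <- list()
  for (alg in c("glm", "rf", "sre")) for (r in seq_len(n_reps)) {
    fit <- fit_algorithm(splits[[r]]$train, tw$stack, sel$kept_layers, alg,
                         seed = r)
    ev <- evaluate(predict_sdm(fit, tw$stack, splits[[r]]$test$presence_cells),
                   predict_sdm(fit, tw$stack, splits[[r]]$test$absence_cells))
    members[[length(members) + 1]] <-
      list(fit = fit, eval = ev, test = splits[[r]]$test)
  }
  list(members = members, stack = tw$stack, region = cr, world = tw, sp = sp)
}

test_that("consensus lies within member range and binarization is TSS-optimal", {
  rs <- real_ensemble()
  ens <- build_ensemble(rs$members, rs$stack, rs$region, auc_min = 0.7)
  expect_gte(ens$member_count, 1L)
  cells <- ens$region$projected_m_cells
  P <- sapply(ens$fits, function(f) predict_sdm(f, rs$stack, cells))
  expect_true(all(ens$prediction$suitability >= apply(P, 1, min) - 1e-12))
  expect_true(all(ens$prediction$suitability <= apply(P, 1, max) + 1e-12))

  # the frozen threshold maximizes TSS over the whole grid (oracle check)
  idx <- match(cells, cells)
  pool_p <- unlist(lapply(rs$members[sapply(rs$members, function(m) m$eval$auc > 0.7)],
                          function(m) ens$prediction$suitability[match(m$test$presence_cells, cells)]))
  pool_a <- unlist(lapply(rs$members[sapply(rs$members, function(m) m$eval$auc > 0.7)],
                          function(m) ens$prediction$suitability[match(m$test$absence_cells, cells)]))
  or <- tss_oracle(pool_p, pool_a)
  expect_equal(ens$tss_threshold, or$threshold)
  expect_equal(ens$ensemble_eval$tss, or$tss, tolerance = 1e-12)
  expect_identical(ens$prediction$binary,
                   ens$prediction$suitability >= ens$tss_threshold)

  # raising auc_min never increases membership
  counts <- sapply(c(0, 0.5, 0.7, 0.8, 0.95), function(a) {
    e <- suppressMessages(build_ensemble(rs$members, rs$stack, rs$region, a))
    if (is.null(e)) 0L else e$member_count
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("projection reuses weights and threshold and checks layers", {
  rs <- real_ensemble()
  ens <- build_ensemble(rs$members, rs$stack, rs$region)

  again <- project_ensemble(ens, rs$stack)
  expect_equal(again$suitability, ens$prediction$suitability)
  expect_identical(again$binary, ens$prediction$binary)

  clone <- climate_stack(rs$stack$grid, rs$stack$values,
                         scenario_id = "control", horizon = "T2")
  fut <- project_ensemble(ens, clone)
  expect_identical(fut$binary, ens$prediction$binary)
  expect_identical(fut$scenario_id, "control")
  expect_identical(fut$horizon, "T2")

  dropped <- rs$stack
  dropped$values <- dropped$values[, setdiff(stack_layers(rs$stack),
                                             ens$fits[[1]]$kept_layers[1]),
                                   drop = FALSE]
  expect_error(project_ensemble(ens, dropped), "missing layer")
})

test_that("a stack shifted beyond every envelope bound predicts absence", {
  rs <- real_ensemble()
  sre_members <- Filter(function(m) m$fit$algorithm_id == "sre", rs$members)
  for (m in sre_members) m$eval$auc <- max(m$eval$auc, 0.71)
  sre_members <- lapply(sre_members, function(m) { m$eval$auc <- 0.9; m })
  ens <- build_ensemble(sre_members, rs$stack, rs$region)
  shifted <- rs$stack
  shifted$values <- rs$stack$values + 1e6
  out <- project_ensemble(ens, shifted)
  expect_true(all(out$suitability == 0))
  expect_true(all(!out$binary))
})

test_that("cross-algorithm CV follows the sample-sd definition", {
  same <- cbind(a = c(0.2, 0.5), b = c(0.2, 0.5))
  cv0 <- cv_across_algorithms(same)
  expect_equal(cv0$cv_map, c(0, 0))
  expect_equal(cv0$cv_summary, 0)

  two <- cbind(a = c(0.4), b = c(0.6))
  expect_equal(cv_across_algorithms(two)$cv_map,
               sd(c(0.4, 0.6)) / 0.5, tolerance = 1e-12)

  dead <- cbind(a = c(0, 0.4), b = c(0, 0.6))
  cvd <- cv_across_algorithms(dead)
  expect_true(is.na(cvd$cv_map[1]))

  expect_error(cv_across_algorithms(cbind(a = c(0.1, 0.2))), "at least 2")
})
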