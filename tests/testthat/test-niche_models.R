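test_that("accessible area M is buffer intersect occupied ecoregions", {
  tw <- tiny_world(20, 2, 2)
  mask <- tw$mask
  # occurrences confined to one ecoregion
  eco <- mask$ecoregion_id[land_cells(mask)[1]]
  eco_cells <- which(mask$ecoregion_id == eco)
  s <- record_set(eco_cells[seq(1, min(60, length(eco_cells)), by = 2)])
  cr <- build_m(s, mask, buffer_deg = 1.0)
  expect_true(all(cr$m_cells %in% eco_cells))
  expect_true(all(s$unique_cells %in% cr$m_cells))

  # a huge buffer reduces M to the union of occupied ecoregions
  cr_big <- build_m(s, mask, buffer_deg = 100)
  expect_setequal(cr_big$m_cells, eco_cells)

  # exhaustive check of the intersection rule at a modest buffer
  r <- buffer_cells(mask$grid, 1.0)
  buf <- dilate_cells(mask$grid, s$unique_cells, r)
  expect_setequal(cr$m_cells, intersect(buf, eco_cells))
  out_of_buffer <- setdiff(eco_cells, buf)
  expect_true(all(!out_of_buffer %in% cr$m_cells))
})

test_that("small M falls back to the whole country", {
  tw <- tiny_world(20, 2, 2)
  cty <- tw$mask$country_id[1]
  cells <- country_cells(tw$mask, cty)
  s <- record_set(cells[1:30])
  cr <- build_m(s, tw$mask, buffer_deg = 0)  # buffer 0 -> M == occurrences
  expect_true(cr$fallback_used)
  expect_setequal(cr$m_cells, cells)
})

test_that("projected M is a clipped Chebyshev dilation of M", {
  tw <- tiny_world(16, 2, 1)
  s <- record_set(land_cells(tw$mask)[1:30])
  cr <- build_m(s, tw$mask, buffer_deg = 1.0)
  same <- build_projected_m(cr, tw$mask, buffer_deg = 0)
  expect_identical(same$projected_m_cells, sort(cr$m_cells))

  proj <- build_projected_m(cr, tw$mask, buffer_deg = 2.0)
  r <- buffer_cells(tw$grid, 2.0)
  expect_true(all(proj$m_cells %in% proj$projected_m_cells))
  expect_true(all(proj$projected_m_cells <= n_cells(tw$grid)))
  rc_m <- cell_rowcol(tw$grid, cr$m_cells)
  rc_p <- cell_rowcol(tw$grid, proj$projected_m_cells)
  for (i in seq_len(nrow(rc_p))) {
    d <- min(pmax(abs(rc_p[i, "row"] - rc_m[, "row"]),
                  abs(rc_p[i, "col"] - rc_m[, "col"])))
    expect_lte(d, r)
  }
})

test_that("pseudo-absence draw is pool-limited, disjoint and weight-balanced", {
  cr <- structure(list(species_id = "s", m_cells = 1:70,
                       projected_m_cells = 1:70, fallback_used = FALSE),
                  class = "calibration_region")
  ts <- draw_pseudo_absences(cr, presences = 1:20, n = 10000, seed = 1)
  expect_length(ts$absence_cells, 50)  # pool-limited
  expect_length(intersect(ts$absence_cells, ts$presence_cells), 0)
  # total presence weight == total absence weight (prevalence 0.5)
  expect_equal(ts$w_presence * 20, ts$w_absence * 50)

  ts80 <- draw_pseudo_absences(cr, presences = 1:20, n = 40, seed = 1)
  expect_equal(ts80$w_presence, 2)  # 40 absences / 20 presences

  cr_full <- cr; cr_full$m_cells <- 1:20
  expect_error(draw_pseudo_absences(cr_full, presences = 1:20), "empty")
})

test_that("replicate splits are stratified, distinct and guarded", {
  cr <- structure(list(species_id = "s", m_cells = 1:500,
                       projected_m_cells = 1:500, fallback_used = FALSE),
                  class = "calibration_region")
  ts <- draw_pseudo_absences(cr, presences = 1:100, n = 300, seed = 3)
  expect_error(split_replicates(ts, fraction = 1.0), "strictly between")
  reps <- split_replicates(ts, fraction = 0.7, n_reps = 10, seed = 5)
  expect_length(reps, 10)
  for (r in reps) {
    expect_lte(abs(length(r$train$presence_cells) - 70), 1)
    expect_lte(abs(length(r$train$absence_cells) - 0.7 * 300), 1)
    expect_length(intersect(r$train$presence_cells, r$test$presence_cells), 0)
    expect_setequal(c(r$train$absence_cells, r$test$absence_cells),
                    ts$absence_cells)
  }
  expect_false(identical(reps[[1]]$train$presence_cells,
                         reps[[2]]$train$presence_cells))
})

test_that("the envelope algorithm is the presence percentile box", {
  g <- grid_spec(10, 10)
  set.seed(1)
  st <- stack_from(g, A = runif(100, -2, 2), B = runif(100, -2, 2))
  pres <- which(abs(st$values[, "A"]) < 1 & abs(st$values[, "B"]) < 1)[1:20]
  abs_ <- setdiff(1:100, pres)[1:30]
  ts <- structure(list(presence_cells = pres, absence_cells = abs_,
                       w_presence = 1.5, w_absence = 1),
                  class = "training_set")
  fit <- fit_algorithm(ts, st, c("A", "B"), "sre")
  p <- predict_sdm(fit, st, 1:100)
  expect_true(all(p %in% c(0, 1)))
  # the box in raw units, via the same percentile rule
  qa <- quantile(st$values[pres, "A"], c(0.025, 0.975), names = FALSE)
  qb <- quantile(st$values[pres, "B"], c(0.025, 0.975), names = FALSE)
  inside <- st$values[, "A"] >= qa[1] & st$values[, "A"] <= qa[2] &
            st$values[, "B"] >= qb[1] & st$values[, "B"] <= qb[2]
  expect_equal(p, as.numeric(inside))
})

test_that("widening the envelope percentile window never shrinks the range", {
  set.seed(2)
  Z <- matrix(rnorm(400), 200, 2, dimnames = list(NULL, c("A", "B")))
  y <- rep(c(1L, 0L), each = 100)
  narrow <- endemicshift:::fit_sre(Z, y, q = c(0.1, 0.9))
  wide <- endemicshift:::fit_sre(Z, y, q = c(0.025, 0.975))
  count_inside <- function(m) {
    fit <- structure(list(algorithm_id = "sre", kept_layers = c("A", "B"),
                          center = c(A = 0, B = 0), scale = c(A = 1, B = 1),
                          model = m),
                     class = "sdm_fit")
    sum(endemicshift:::predict_sdm_env(fit, Z))
  }
  expect_lte(count_inside(narrow), count_inside(wide))
})

test_that("every algorithm fits a separable problem and stays in [0,1]", {
  g <- grid_spec(10, 20)
  set.seed(7)
  x <- c(rnorm(100, 3), rnorm(100, -3))
  st <- stack_from(g, A = x, B = rnorm(200))
  ts <- structure(list(presence_cells = 1:80, absence_cells = 101:180,
                       w_presence = 1, w_absence = 1),
                  class = "training_set")
  test_p <- 81:100; test_a <- 181:200
  for (alg in sdm_algorithms()) {
    fit <- fit_algorithm(ts, st, c("A", "B"), alg, seed = 1)
    p_all <- predict_sdm(fit, st, 1:200)
    expect_true(all(p_all >= 0 & p_all <= 1), label = alg)
    ev <- evaluate(predict_sdm(fit, st, test_p), predict_sdm(fit, st, test_a))
    if (alg == "sre") {
      # the envelope clips its 2.5% tails by construction, so a few true
      # presences fall outside the box; it must still discriminate strongly
      expect_gte(ev$auc, 0.8)
    } else {
      expect_equal(ev$auc, 1.0, label = paste(alg, "separable AUC"))
    }
  }
  degen <- ts; degen$presence_cells <- 1L
  expect_error(fit_algorithm(degen, st, c("A", "B"), "glm"), "degenerate")
})

test_that("evaluation matches hand-computed AUC and max-TSS examples", {
  ev1 <- evaluate(c(0.9, 0.8), c(0.1, 0.2))
  expect_equal(ev1$auc, 1.0)
  expect_equal(ev1$tss, 1.0)

  ev2 <- evaluate(c(0.9, 0.4), c(0.6, 0.1))
  expect_equal(ev2$auc, 0.75)  # 3 of 4 concordant pairs

  ev3 <- evaluate(c(0.9, 0.7, 0.3), c(0.6, 0.4, 0.2))
  expect_equal(ev3$tss, 2 / 3, tolerance = 1e-12)
  expect_equal(ev3$tss_threshold, 0.61)  # lowest maximizing threshold
  expect_equal(ev3$tss, ev3$sensitivity + ev3$specificity - 1)
})

test_that("evaluation agrees with brute-force oracles on random instances", {
  set.seed(99)
  for (i in 1:50) {
    pres <- round(runif(sample(2:30, 1)), 2)  # rounding forces ties
    abs_ <- round(runif(sample(2:30, 1)), 2)
    ev <- evaluate(pres, abs_)
    expect_equal(ev$auc, auc_oracle(pres, abs_), tolerance = 1e-12)
    or <- tss_oracle(pres, abs_)
    expect_equal(ev$tss, or$tss, tolerance = 1e-12)
    expect_equal(ev$tss_threshold, or$threshold)
  }
})

test_that("permutation contributions rank the informative variable first", {
  g <- grid_spec(10, 20)
  set.seed(3)
  x <- c(rnorm(100, 2), rnorm(100, -2))
  st <- stack_from(g, SIG = x, NOISE = rnorm(200))
  ts <- structure(list(presence_cells = 1:100, absence_cells = 101:200,
                       w_presence = 1, w_absence = 1),
                  class = "training_set")
  fit <- fit_algorithm(ts, st, c("SIG", "NOISE"), "glm")
  vc <- variable_contributions(fit, ts, st, seed = 1)
  expect_identical(vc$layer[1], "SIG")
  expect_gt(vc$contribution[1], 0.2)
  expect_lt(abs(vc$contribution[vc$layer == "NOISE"]), 0.05)
})
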