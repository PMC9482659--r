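fake_pred <- function(id, cells, present, scenario = "baseline",
                      horizon = "T0") {
  structure(list(species_id = id, scenario_id = scenario, horizon = horizon,
                 cells = cells, suitability = as.numeric(cells %in% present),
                 binary = cells %in% present, member_count = 1L),
            class = "ensemble_prediction")
}

test_that("range change delta, complete loss and categories are consistent", {
  r <- range_change(rep(TRUE, 50), rep(TRUE, 60))
  expect_equal(r$delta, 0.2)
  expect_false(r$complete_loss)
  expect_identical(r$category, "stable_gain")

  gone <- range_change(rep(TRUE, 100), rep(FALSE, 100))
  expect_equal(gone$delta, -1)
  expect_true(gone$complete_loss)
  expect_identical(gone$category, "complete_loss")

  same <- range_change(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, FALSE))
  expect_equal(same$delta, 0)

  expect_error(range_change(logical(5), rep(TRUE, 5)), "no present-day range")

  expect_identical(classify_change(c(-1, -0.5, -0.2, 0, 0.2, 0.5, 0.7)),
                   c("complete_loss", "severe_loss", "moderate_loss",
                     "stable_gain", "stable_gain", "stable_gain",
                     "strong_gain"))
})

test_that("PAM rows are ranges, columns are richness, and SR is conserved", {
  preds <- list(fake_pred("s1", 1:10, present = 1:4),
                fake_pred("s2", 5:14, present = 5:8),
                fake_pred("s3", 1:20, present = c(1:2, 19:20)))
  pam <- build_pam(preds, 25)
  expect_identical(dim(unclass(pam)), c(3L, 25L))
  expect_equal(unname(rowSums(unclass(pam))), c(4, 4, 4))
  expect_equal(sum(unclass(pam)[, 1]), 2)  # s1 and s3 overlap at cell 1
  # conservation: sum of SR over cells == sum of range sizes
  expect_equal(sum(colSums(unclass(pam))), sum(rowSums(unclass(pam))))

  empty <- build_pam(list(), 25)
  expect_identical(dim(unclass(empty)), c(0L, 25L))
})

test_that("richness standardizes per country and delta-SR is future minus present", {
  g <- grid_spec(10, 10)
  mask <- structure(list(grid = g, country_id = rep(c(1L, 2L), each = 50),
                         ecoregion_id = rep(c(1L, 2L), each = 50),
                         country_count = 2L),
                    class = "world_mask")
  preds <- list(fake_pred("a", 1:100, present = 1:10),
                fake_pred("b", 1:100, present = c(1:5, 51:60)),
                fake_pred("c", 1:100, present = c(1, 51:55)))
  rm_ <- richness(build_pam(preds, 100), mask)
  expect_identical(rm_$sr[1], 3L)
  expect_identical(unname(rm_$max_sr), c(3L, 2L))
  expect_equal(rm_$sr_standardized[1], 1)
  expect_equal(rm_$sr_standardized[51], 1)  # country-2 max normalized to 1
  expect_equal(max(rm_$sr_standardized[1:50]), 1)

  dsr <- delta_richness(rm_$sr, rep(0L, 100))
  expect_identical(dsr[1], -3L)
  expect_true(all(abs(dsr) <= 3))
  expect_identical(delta_richness(c(5L, 2L), c(3L, 2L)), c(-2L, 0L))
})

test_that("conservation holds on random PAMs", {
  set.seed(5)
  for (i in 1:20) {
    m <- matrix(runif(30 * 40) < 0.2, 30, 40,
                dimnames = list(paste0("s", 1:30), NULL))
    pam <- structure(m, class = c("pam", "matrix"))
    expect_identical(sum(colSums(m)), sum(rowSums(m)))
  }
})

test_that("hotspots use a strict frozen cutoff and nest across factors", {
  g <- grid_spec(10, 10)
  mask <- structure(list(grid = g, country_id = rep(1L, 100),
                         ecoregion_id = rep(1L, 100), country_count = 1L),
                    class = "world_mask")
  sr <- integer(100); sr[1:4] <- c(10L, 7L, 6L, 5L)
  hs <- hotspots(sr, mask, factor = 0.6)
  expect_identical(hs$psh_cells[[1]], 1:2)  # 6 is excluded: strict inequality

  hs2 <- hotspots(sr, mask, factor = 0.2)
  hs9 <- hotspots(sr, mask, factor = 0.9)
  expect_true(all(hs9$psh_cells[[1]] %in% hs$psh_cells[[1]]))
  expect_true(all(hs$psh_cells[[1]] %in% hs2$psh_cells[[1]]))

  # extent against the frozen present-day cutoff
  sr_f <- integer(100); sr_f[1] <- 10L
  ext <- hotspot_extent(hs, sr_f, mask)
  expect_equal(ext$extent_ratio, 0.5)
  expect_equal(hotspot_extent(hs, sr, mask)$extent_ratio, 1)

  sr_gone <- integer(100)
  expect_error(hotspots(sr_gone, mask), "maxSR = 0")
})

test_that("temporal Sorensen matches set enumeration and vegan", {
  p1 <- build_pam(list(fake_pred("a", 1:5, 1:3), fake_pred("b", 1:5, 1:2),
                       fake_pred("c", 1:5, 2:3)), 5)
  p2 <- build_pam(list(fake_pred("a", 1:5, 1:3), fake_pred("b", 1:5, 3),
                       fake_pred("c", 1:5, integer(0))), 5)
  bs <- temporal_sorensen(p1, p2, 1:5)
  for (k in 1:5) {
    sp_now <- rownames(p1)[unclass(p1)[, k]]
    sp_fut <- rownames(p2)[unclass(p2)[, k]]
    expect_equal(bs$bsor[k], bsor_oracle(sp_now, sp_fut))
  }
  # identical -> 0; disjoint non-empty -> 1; a=2,b=1,c=1 -> 1/3
  expect_equal(temporal_sorensen(p1, p1, 1:5)$bsor[1], 0)
  d1 <- build_pam(list(fake_pred("a", 1:2, 1), fake_pred("b", 1:2, integer(0))), 2)
  d2 <- build_pam(list(fake_pred("a", 1:2, integer(0)), fake_pred("b", 1:2, 1)), 2)
  expect_equal(temporal_sorensen(d1, d2, 1)$bsor, 1)
  e1 <- build_pam(lapply(c("a","b","c"), fake_pred, cells = 1, present = 1), 1)
  e2 <- build_pam(list(fake_pred("a", 1, 1), fake_pred("b", 1, 1),
                       fake_pred("c", 1, integer(0)),
                       fake_pred("d", 1, 1))[c(1, 2, 3)], 1)
  # a={a,b}, b={c}, c={} against shared {a,b}: (1+0)/(2*2+1+0)
  expect_equal(temporal_sorensen(e1, e2, 1)$bsor, 1 / 5)

  # empty in both periods is no-data
  expect_true(is.na(temporal_sorensen(p1, p2, 5)$bsor))

  skip_if_not_installed("vegan")
  set.seed(11)
  m_now <- matrix(runif(8 * 6) < 0.4, 8, 6, dimnames = list(paste0("s", 1:8), NULL))
  m_fut <- matrix(runif(8 * 6) < 0.4, 8, 6, dimnames = list(paste0("s", 1:8), NULL))
  pamA <- structure(m_now, class = c("pam", "matrix"))
  pamB <- structure(m_fut, class = c("pam", "matrix"))
  got <- temporal_sorensen(pamA, pamB, 1:6)$bsor
  for (k in 1:6) {
    pair <- rbind(now = as.numeric(m_now[, k]), fut = as.numeric(m_fut[, k]))
    if (sum(pair) == 0) { expect_true(is.na(got[k])); next }
    ref <- as.numeric(vegan::vegdist(pair, method = "bray", binary = TRUE))
    expect_equal(got[k], ref, tolerance = 1e-12)
  }
})

test_that("beta_SOR is bounded, symmetric in gains/losses and zero iff identical", {
  set.seed(21)
  for (i in 1:30) {
    a <- sample(0:5, 1); b <- sample(0:5, 1); c_ <- sample(0:5, 1)
    if (a + b + c_ == 0) next
    v <- (b + c_) / (2 * a + b + c_)
    expect_gte(v, 0); expect_lte(v, 1)
    expect_equal(v, (c_ + b) / (2 * a + c_ + b))
    if (b + c_ == 0) expect_equal(v, 0)
    if (b + c_ > 0) expect_gt(v, 0)
  }
})
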