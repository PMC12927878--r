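test_that("biomass conversion handles linear and allometric modes", {
  expect_equal(biomass_from_volume(0), 0)
  expect_equal(biomass_from_volume(0.1, factor = 310), 31)
  expect_equal(biomass_from_volume(0.5, "allometric", scale = 100, exponent = 1),
               50)
  expect_error(biomass_from_volume(-1), "non-negative")
  # typical riverine volumes map onto the reported few-to-tens fgC per cell
  vols <- seq(0.02, 0.12, length.out = 20)
  bm <- biomass_from_volume(vols)
  expect_true(all(bm >= 6 & bm <= 37.5))
})

test_that("cell-specific production divides bulk BSP by TCC with unit scaling", {
  expect_equal(cell_specific_bsp(0, 1e9), 0)
  # survey medians: 0.32/1.71e9 and 1.15/13.9e9 reproduce the printed
  # per-cell medians at their printed precision
  expect_equal(round(cell_specific_bsp(0.32, 1.71e9), 2), 0.19)
  # the ratio of medians (0.0827) is order-consistent with the printed
  # per-site median 0.09 but not identical to it
  expect_equal(cell_specific_bsp(1.15, 13.9e9), 0.0827, tolerance = 1e-3)
  expect_lt(abs(cell_specific_bsp(1.15, 13.9e9) - 0.09), 0.015)
  expect_error(cell_specific_bsp(1, 0), "positive")
})

test_that("division rates scale inversely with biomass", {
  r <- division_rate(0.19, 37)
  expect_equal(r$cd_daily, 24 * 0.19 / 37)
  expect_equal(round(r$cd_daily, 3), 0.123)
  expect_equal(division_rate(0, 10)$cd_daily, 0)
  # doubling the biomass halves the daily rate exactly
  expect_equal(division_rate(0.19, 74)$cd_daily, r$cd_daily / 2)
  expect_error(division_rate(1, 0), "positive")
})

test_that("doubling time is the reciprocal of the division rate", {
  expect_equal(doubling_time(1), 1)
  expect_equal(round(doubling_time(0.124), 2), 8.06)
  expect_equal(round(doubling_time(0.121), 2), 8.26)
  expect_equal(doubling_time(2, convention = "ln2"), log(2) / 2)
  expect_error(doubling_time(0), "positive")
})

test_that("cumulative doublings multiply rate by journey time", {
  expect_equal(cumulative_divisions(0.5, 0), 0)
  expect_equal(round(cumulative_divisions(0.124, 33.7), 1), 4.2)
  expect_equal(round(cumulative_divisions(0.121, 53.6), 1), 6.5)
  expect_error(cumulative_divisions(-1, 2), "non-negative")
})

test_that("segment production uses mean BSP and upstream biomass", {
  s <- segment_cell_production(0.3, 0.5, 40, 10)
  expect_equal(s$acp_h, 1e7)
  expect_equal(s$cp_segment, 1e8)
  z <- segment_cell_production(0, 0, 40, 10)
  expect_equal(z$acp_h, 0)
  expect_error(segment_cell_production(1, 1, 0, 10), "positive")
  expect_error(segment_cell_production(1, 1, 40, 0), "positive")
})

test_that("whole-river production sums segments order-independently", {
  expect_equal(total_cell_production(c(1e8, 1e8)), 2e8)
  set.seed(3)
  v <- runif(10, 1e7, 1e9)
  expect_equal(total_cell_production(v), total_cell_production(sample(v)))
  expect_error(total_cell_production(numeric(0)), "segments")
})

test_that("standing-stock ratios reproduce the published comparisons", {
  expect_equal(standing_stock_ratio(5, 5), 1)
  expect_equal(round(standing_stock_ratio(9.21e9, 1.71e9), 1), 5.4)
  expect_equal(round(standing_stock_ratio(95.9e9, 13.9e9), 1), 6.9)
  expect_error(standing_stock_ratio(1, 0), "positive")
})

test_that("carbon-atom conversion is linear and matches hand arithmetic", {
  expect_equal(production_to_atoms(0), 0)
  expect_equal(production_to_atoms(12.011), 6.02214e23)
  a <- production_to_atoms(3e-21); b <- production_to_atoms(4e-21)
  expect_equal(production_to_atoms(7e-21), a + b)
  # published per-cell production slopes convert to ~21000 and ~6000 atoms
  expect_equal(round(production_to_atoms(422e-21) / 1000) * 1000, 21000)
  expect_equal(round(production_to_atoms(119e-21) / 1000) * 1000, 6000)
})

test_that("rate, doubling time and biomass satisfy the algebraic round trip", {
  set.seed(11)
  for (i in 1:25) {
    bsp_c <- runif(1, 0.01, 1)
    mbm <- runif(1, 5, 60)
    cd <- division_rate(bsp_c, mbm)$cd_daily
    expect_equal(doubling_time(cd) * bsp_c * 24, mbm, tolerance = 1e-12)
  }
})

test_that("whole-river production is additive under segment refinement", {
  # splitting a segment with linearly interpolated BSP and the upstream
  # biomass convention held fixed preserves cp_segment totals
  bsp_up <- 0.4; bsp_dn <- 0.8; mbm <- 30; tt <- 12
  whole <- segment_cell_production(bsp_up, bsp_dn, mbm, tt)$cp_segment
  bsp_mid <- (bsp_up + bsp_dn) / 2
  halves <- segment_cell_production(bsp_up, bsp_mid, mbm, tt / 2)$cp_segment +
    segment_cell_production(bsp_mid, bsp_dn, mbm, tt / 2)$cp_segment
  expect_equal(halves, whole, tolerance = 1e-12)
})

test_that("the transect-level profile is internally consistent", {
  tru <- synthetic_truth("jds3like", seed = 2)
  tr <- generate_transect(tru)
  prof <- production_profile(tr)
  expect_equal(prof$totals$cp_tot, sum(prof$segments$cp_segment))
  expect_equal(prof$totals$median_doubling_time,
               1 / prof$totals$median_cd_daily)
  expect_equal(prof$totals$cumulative_divisions,
               prof$totals$median_cd_daily * max(tr$tt_cum) / 24)
  expect_true(all(prof$sites$bsp_c >= 0))
  expect_true(all(prof$segments$acp_h >= 0))
  # per-segment estimator agrees with the median estimator on constant data
  tr0 <- generate_transect(synthetic_truth("jds3like", seed = 2,
                                           noise_sd = 0, tcc_slope = 0,
                                           bsp_slope = 0,
                                           volume_end = 0.11,
                                           tcc_intercept = 1e10,
                                           bsp_intercept = 1))
  p_med <- production_profile(tr0, estimator = "median")
  p_seg <- production_profile(tr0, estimator = "per_segment")
  expect_equal(p_med$totals$cumulative_divisions,
               p_seg$totals$cumulative_divisions, tolerance = 1e-6)
})
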