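test_that("packaged coefficient table matches the published regional values", {
  co <- load_coefficients()
  expect_equal(co["Food production", "farmland"], 822.500)
  expect_equal(co["Raw material", "forest"], 2451.050)
  expect_equal(co["Water conservation", "water"], 15438.325)
  expect_true(all(co[, "built-up"] == 0))
  expect_equal(dim(unclass(co)), c(9, 6))
})

test_that("benefit transfer reproduces the published ESV tables", {
  co <- load_coefficients()
  ar <- tongliao_areas()
  published_totals <- c(y2000 = 52364.56, y2005 = 51949.77, y2010 = 51832.47,
                        y2015 = 51684.48, y2020 = 51620.62, y2035 = 51541.12)
  snaps <- lapply(colnames(ar), function(yr)
    esv_from_areas(stats::setNames(ar[, yr], rownames(ar)), co))
  names(snaps) <- colnames(ar)
  for (yr in names(published_totals))
    expect_equal(esv_total(snaps[[yr]]), published_totals[[yr]],
                 tolerance = 0.5 / published_totals[[yr]])

  # per-service values for 2000 and 2020 within printed rounding (0.05%)
  published_2000 <- c(2540.07, 2525.36, 5943.37, 6542.77, 8531.88, 7862.90,
                      7154.01, 7765.49, 3498.70)
  published_2020 <- c(2547.66, 2506.66, 5890.00, 6480.04, 8478.95, 7625.80,
                      6992.26, 7678.41, 3420.83)
  expect_equal(as.numeric(snaps$y2000), published_2000, tolerance = 5e-4)
  expect_equal(as.numeric(snaps$y2020), published_2020, tolerance = 5e-4)

  # horizon-year change per service, Total -79.5
  published_change_2035 <- c(-7.01, -12.98, -16.27, -15.2, -17.68, 1.39,
                             2.46, -13.4, -0.8)
  ch <- esv_change(snaps$y2020, snaps$y2035)
  expect_equal(as.numeric(ch), published_change_2035, tolerance = 0.01)
  expect_equal(attr(ch, "total"), -79.5, tolerance = 0.01)
  ch20 <- esv_change(snaps$y2000, snaps$y2020)
  expect_equal(attr(ch20, "total"), -743.94, tolerance = 0.01)
})

test_that("valuation is linear and changes are antisymmetric", {
  co <- load_coefficients()
  areas <- c(farmland = 120, forest = 30, grassland = 200, water = 10,
             "built-up" = 15, unused = 60)
  s1 <- esv_from_areas(areas, co)
  s2 <- esv_from_areas(2 * areas, co)
  expect_equal(as.numeric(s2), 2 * as.numeric(s1))
  expect_equal(as.numeric(esv_change(s1, s2)),
               -as.numeric(esv_change(s2, s1)))
  expect_true(all(as.numeric(esv_change(s1, s1)) == 0))

  one_km2 <- esv_from_areas(c(farmland = 1), co)
  expect_equal(one_km2[["Food production"]], 0.08225)

  built_only <- esv_from_areas(c("built-up" = 500), co)
  expect_true(all(as.numeric(built_only) == 0))
  expect_error(esv_from_areas(c(swamp = 10), co), "no coefficient column")
  expect_error(esv_from_areas(c(farmland = -1), co), "nonnegative")
})

test_that("per-cell and aggregate valuation agree", {
  co <- load_coefficients()
  sc <- small_scene()
  lulc <- sc$t0
  lulc$legend <- six_legend
  grid <- esv_per_cell(lulc, co)
  # one 100 m cell of water = 1 ha worth the water column sum
  wcell <- which(lulc$values == 4L)[1]
  expect_equal(grid[wcell], sum(co[, "water"]))
  agg <- esv_total(esv_from_areas(area_table(lulc), co))
  expect_equal(sum(grid, na.rm = TRUE) / 1e6, agg, tolerance = 1e-9)

  lulc$values[1, 1] <- lulc$nodata
  grid2 <- esv_per_cell(lulc, co)
  expect_true(is.na(grid2[1, 1]))
  expect_equal(sum(grid2, na.rm = TRUE) / 1e6,
               esv_total(esv_from_areas(area_table(lulc), co)),
               tolerance = 1e-9)
})

test_that("esv_table assembles snapshots with totals and change columns", {
  co <- load_coefficients()
  ar <- tongliao_areas()
  s00 <- esv_from_areas(stats::setNames(ar[, "y2000"], rownames(ar)), co)
  s20 <- esv_from_areas(stats::setNames(ar[, "y2020"], rownames(ar)), co)
  tab <- esv_table(list("2000" = s00, "2020" = s20), changes = TRUE)
  expect_equal(nrow(tab), 10)
  expect_equal(tab["Total", "2000"], sum(tab[1:9, "2000"]), tolerance = 1e-6)
  expect_equal(tab["Total", "change_2000_2020"], -743.94, tolerance = 0.01)
})
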