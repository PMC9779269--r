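test_that("generated landscapes hit target proportions and are autocorrelated", {
  spec <- landscape_spec(300, 300, proportions = c(0.3, 0.4, 0.1, 0.02, 0.03, 0.15),
                         seed = 1)
  r <- generate_landscape(spec)
  props <- as.numeric(table(factor(r$values, levels = 1:6))) / (300 * 300)
  expect_true(all(abs(props - spec$proportions) <= 0.02))
  for (k in 1:3)
    expect_gt(morans_i((r$values == k) * 1), 0.2)
})

test_that("generators are deterministic under a fixed seed", {
  spec <- landscape_spec(80, 80, seed = 42)
  expect_identical(generate_landscape(spec)$values,
                   generate_landscape(spec)$values)
  r <- generate_landscape(spec)
  d1 <- generate_drivers(r, n_drivers = 3, signal = 0.5, seed = 9)
  d2 <- generate_drivers(r, n_drivers = 3, signal = 0.5, seed = 9)
  expect_identical(d1, d2)
  dyn <- true_dynamics(default_transition_matrix())
  expect_identical(evolve_landscape(r, dyn, seed = 3)$values,
                   evolve_landscape(r, dyn, seed = 3)$values)
  m1 <- generate_masks(r, 0.2, 0.1, seed = 4)
  m2 <- generate_masks(r, 0.2, 0.1, seed = 4)
  expect_identical(m1, m2)
})

test_that("single-class specs give uniform maps; bad parameters error", {
  r <- generate_landscape(landscape_spec(10, 10, n_classes = 1,
                                         proportions = 1, seed = 1))
  expect_true(all(r$values == 1L))
  expect_error(landscape_spec(10, 10, autocorr_range = -1), "nonnegative")
  expect_error(landscape_spec(10, 10, proportions = c(0.5, 0.4)),
               "sum to 1|length")
  expect_error(generate_drivers(r, n_drivers = 0), "at least 1")
})

test_that("driver signal controls class association", {
  r <- generate_landscape(landscape_spec(150, 150, seed = 5))
  # signal 0: per-class driver means statistically indistinguishable
  d0 <- generate_drivers(r, n_drivers = 2, signal = 0, seed = 6)
  grand_sd <- sd(d0[[1]])
  means <- tapply(as.vector(d0[[1]]), as.vector(r$values), mean)
  expect_lt(max(means) - min(means), 4 * grand_sd / sqrt(100))
  # signal 1: driver value determines the class exactly
  d1 <- generate_drivers(r, n_drivers = 1, signal = 1, seed = 6)
  cls_per_value <- tapply(as.vector(r$values), round(as.vector(d1[[1]]), 8),
                          function(x) length(unique(x)))
  expect_true(all(cls_per_value == 1))
})

test_that("evolution follows the supplied Markov law", {
  r <- generate_landscape(landscape_spec(60, 60, seed = 2))
  ident <- true_dynamics(diag(6))
  expect_identical(evolve_landscape(r, ident, seed = 1)$values, r$values)

  one <- toy_raster(matrix(1L, 300, 300), K = 2)
  tm <- matrix(c(0.9, 0.1, 0, 1), 2, 2, byrow = TRUE)
  dyn <- suppressWarnings(true_dynamics(tm))
  ev <- evolve_landscape(one, dyn, seed = 7)
  frac_changed <- mean(ev$values == 2L)
  expect_gt(frac_changed, 0.1 - 3 * sqrt(0.1 * 0.9 / 90000))
  expect_lt(frac_changed, 0.1 + 3 * sqrt(0.1 * 0.9 / 90000))

  swap_all <- matrix(c(0, 1, 1, 0), 2, 2)   # would change every cell
  frozen <- suppressWarnings(true_dynamics(swap_all, restriction_fraction = 1))
  expect_identical(evolve_landscape(one, frozen, seed = 3)$values, one$values)
  expect_error(true_dynamics(matrix(c(0.5, 0.4, 0.2, 0.8), 2, 2)),
               "sum to 1")
})

test_that("policy masks hit requested fractions and prefer their classes", {
  sc <- small_scene()
  masks <- generate_masks(sc$t0, eprl_fraction = 0.2, cf_fraction = 0.2,
                          seed = 3)
  expect_equal(mean(masks$eprl), 0.2, tolerance = 0.02)
  expect_equal(mean(masks$cf), 0.2, tolerance = 0.02)
  empty <- generate_masks(sc$t0, 0, 0, seed = 1)
  expect_equal(sum(empty$eprl) + sum(empty$cf), 0)
  # preferential overlap: inside-zone share of preferred classes exceeds the
  # map-wide share
  eprl_share <- mean(sc$t0$values[masks$eprl == 1] %in% c(2L, 3L))
  expect_gt(eprl_share, mean(sc$t0$values %in% c(2L, 3L)))
  cf_share <- mean(sc$t0$values[masks$cf == 1] == 1L)
  expect_gt(cf_share, mean(sc$t0$values == 1L))
})

test_that("transition-matrix recovery improves with grid size", {
  sc <- cached_scene(500, 500, 11)
  tmhat <- estimate_transition_matrix(crosstab(sc$t0, sc$t1))
  expect_lt(max(abs(tmhat$probs - sc$dynamics$transition_matrix)), 0.02)
})

test_that("fixture writer emits a readable scene", {
  dir <- withr::local_tempdir()
  write_fixture_scene(dir, scene = cached_scene(40, 40, 3))
  t0 <- read_asc(file.path(dir, "lulc_t0.asc"), "categorical")
  expect_identical(t0$values, cached_scene(40, 40, 3)$t0$values)
  expect_true(file.exists(file.path(dir, "mask_eprl.asc")))
  expect_true(file.exists(file.path(dir, "driver_1.asc")))
})
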