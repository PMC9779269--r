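test_that("cell sampling respects rate, strata and nodata", {
  sc <- small_scene()
  s_all <- sample_cells(sc$t0, sc$drivers, rate = 1, strategy = "uniform")
  expect_equal(nrow(s_all), sum(sc$t0$values != sc$t0$nodata))

  s10 <- sample_cells(sc$t0, sc$drivers, rate = 0.1, strategy = "uniform",
                      seed = 2)
  expect_equal(nrow(s10), round(0.1 * nrow(s_all)), tolerance = 2)

  strat <- sample_cells(sc$t0, sc$drivers, rate = 0.1,
                        strategy = "stratified", seed = 2)
  per_class <- table(strat$label)
  full <- table(factor(sc$t0$values, levels = 1:6))
  expect_true(all(abs(per_class - 0.1 * full) <= pmax(1, 0.01 * full)))

  expect_identical(sample_cells(sc$t0, sc$drivers, 0.05, "uniform", seed = 9),
                   sample_cells(sc$t0, sc$drivers, 0.05, "uniform", seed = 9))
  expect_error(sample_cells(sc$t0, sc$drivers, rate = 0), "in \\(0, 1\\]")
})

test_that("ANN separates separable drivers and degrades to baseline on noise", {
  r <- generate_landscape(landscape_spec(150, 150, seed = 4))
  d_sep <- generate_drivers(r, n_drivers = 3, signal = 1, seed = 5)
  train <- sample_cells(r, d_sep, rate = 0.05, strategy = "stratified",
                        seed = 6)
  fit <- train_ann(train, seed = 7)
  P <- predict_ann(fit, d_sep)
  # per-cell simplex normalisation
  tot <- Reduce(`+`, P)
  expect_lt(max(abs(tot - 1), na.rm = TRUE), 1e-6)
  # held-out accuracy on separable drivers
  test <- sample_cells(r, d_sep, rate = 0.05, strategy = "stratified",
                       seed = 8)
  pred <- max.col(sapply(P, function(m) m[test$cell]))
  expect_gt(mean(pred == as.integer(test$label)), 0.95)

  # pure-noise drivers: accuracy ~ majority-class share
  d_noise <- generate_drivers(r, n_drivers = 3, signal = 0, seed = 5)
  train_n <- sample_cells(r, d_noise, rate = 0.05, strategy = "stratified",
                          seed = 6)
  fit_n <- train_ann(train_n, seed = 7)
  P_n <- predict_ann(fit_n, d_noise)
  pred_n <- max.col(sapply(P_n, function(m) m[test$cell]))
  base_rate <- max(table(r$values)) / length(r$values)
  expect_lt(mean(pred_n == as.integer(test$label)), base_rate + 0.1)

  # single-class training set rejected
  one <- train[train$label == "1", ]
  expect_error(train_ann(one), "at least 2 classes")
})

test_that("expansion extraction flags newly converted cells only", {
  d1 <- toy_raster(matrix(c(1L, 2L, 1L, 2L), 2, 2, byrow = TRUE), K = 2)
  d2 <- toy_raster(matrix(c(1L, 2L, 2L, 2L), 2, 2, byrow = TRUE), K = 2)
  e2 <- extract_expansion(d1, d2, 2)
  expect_equal(sum(e2, na.rm = TRUE), 1)
  expect_equal(e2[2, 1], 1)   # the one cell that became class 2
  expect_true(all(extract_expansion(d1, d1, 1) == 0))
  expect_error(extract_expansion(d1, d2, 99), "not in the legend")

  # union over classes of expansion grids equals the changed-cell mask
  sc <- small_scene()
  grids <- lapply(1:6, function(k) extract_expansion(sc$t0, sc$t1, k))
  expect_equal(Reduce(`+`, grids) == 1, sc$t0$values != sc$t1$values)
})

test_that("LEAS random forest finds the driving factor and stays bounded", {
  set.seed(10)
  r <- toy_raster(matrix(1L, 120, 120), K = 2)
  # expansion fully explained by a threshold on driver 1
  drv <- list(driver_1 = matrix(runif(120 * 120), 120, 120),
              driver_2 = matrix(runif(120 * 120), 120, 120),
              driver_3 = matrix(runif(120 * 120), 120, 120))
  exp_grid <- (drv$driver_1 > 0.8) * 1
  fit <- train_leas_rf(list("2" = exp_grid), drv, trees = 100, seed = 3)
  expect_gt(fit$contributions["2", "driver_1"], 0.8)
  expect_true(all(fit$prob[["2"]] >= 0 & fit$prob[["2"]] <= 1, na.rm = TRUE))
  expect_equal(sum(fit$contributions["2", ]), 1, tolerance = 1e-9)

  # pure-noise expansion: contributions near symmetric
  exp_noise <- matrix(rbinom(120 * 120, 1, 0.1), 120, 120)
  fit_n <- train_leas_rf(list("2" = exp_noise), drv, trees = 100, seed = 4)
  expect_true(all(abs(fit_n$contributions["2", ] - 1 / 3) < 0.1))

  # no change at all -> error pointing to the ANN mode
  expect_error(train_leas_rf(list("2" = exp_grid * 0), drv), "ANN")
  # too few positives -> flat surface with warning
  sparse <- matrix(0, 120, 120); sparse[1, 1:3] <- 1
  expect_warning(flat <- train_leas_rf(list("2" = sparse, "1" = exp_grid),
                                       drv, seed = 5),
                 "flat probability")
  expect_true(all(flat$prob[["2"]] == 0.5))
})
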