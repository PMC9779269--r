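test_that("neighborhood effect counts window occupancy, centre excluded", {
  # interior of a uniform map saturates at w_k
  uni <- toy_raster(matrix(1L, 5, 5), K = 2)
  om <- neighborhood_effect(uni, 1, ca_config(window = 3))
  expect_equal(om[3, 3], 1)
  expect_equal(om[1, 1], 1)   # shrunken corner window, matching denominator
  expect_true(all(neighborhood_effect(uni, 2, ca_config(window = 3)) == 0))

  # centre cell with 4 of 8 neighbors of class k -> 0.5
  m <- matrix(1L, 3, 3)
  m[c(1, 3, 5, 7)] <- 2L   # 4 cells around centre... positions 1,3,7,9 corners
  m2 <- matrix(c(2L, 1L, 2L, 1L, 1L, 1L, 2L, 1L, 2L), 3, 3)
  om2 <- neighborhood_effect(toy_raster(m2, K = 2), 2, ca_config(window = 3))
  expect_equal(om2[2, 2], 0.5)

  # class weight scales the effect
  om_w <- neighborhood_effect(toy_raster(m2, K = 2), 2,
                              ca_config(window = 3, weights = c(1, 2)))
  expect_equal(om_w[2, 2], 1)
})

test_that("adaptive inertia follows the three-branch gap rule", {
  expect_equal(update_inertia(1, 5, 5), 1)            # |D1| <= |D2|
  expect_equal(update_inertia(1, -4, -2), 0.5)        # 0 > D2 > D1
  expect_equal(update_inertia(1, 4, 2), 2)            # D1 > D2 > 0
  expect_equal(update_inertia(c(1, 1, 1), c(5, -4, 4), c(5, -2, 2)),
               c(1, 0.5, 2))
  expect_true(update_inertia(2, -8, -2) > 0)
  expect_equal(update_inertia(1, 0, 0), 1)            # guarded degenerate case
})

test_that("combined probability multiplies factors and respects restriction", {
  P <- list(a = matrix(0.4, 2, 2), b = matrix(0.6, 2, 2))
  om <- list(a = matrix(1, 2, 2), b = matrix(0.5, 2, 2))
  R <- matrix(c(1, 0, 1, 1), 2, 2)
  op <- combined_probability(P, c(1, 1), om, R)
  expect_equal(op$a[1, 1], 0.4)
  expect_equal(op$b[1, 1], 0.3)
  expect_equal(op$a[2, 1] + op$b[2, 1], 0)   # R = 0 kills every class
  op2 <- combined_probability(P, c(2, 1), om, R)
  expect_equal(op2$a, 2 * op$a)              # linear in inertia
})

test_that("flus allocation meets demand, respects restriction, reproducible", {
  sc <- small_scene()
  samp <- sample_cells(sc$t1, sc$drivers, 0.05, "stratified", seed = 1)
  P <- predict_ann(train_ann(samp, seed = 1), sc$drivers)
  counts <- as.numeric(table(factor(sc$t1$values, levels = 1:6)))

  same <- flus_allocate(sc$t1, P, counts, ca_config(seed = 1))
  expect_identical(same$values, sc$t1$values)   # nothing to allocate

  tmhat <- estimate_transition_matrix(crosstab(sc$t0, sc$t1))
  dem <- demand_from_markov(sc$t1, tmhat, 2)
  R <- build_restriction("S4", sc$masks$eprl, sc$masks$cf, sc$t1)
  out <- flus_allocate(sc$t1, P, dem, ca_config(seed = 2, restriction = R))
  cv <- attr(out, "convergence")
  expect_true(cv$converged)
  got <- as.integer(table(factor(out$values, levels = 1:6)))
  expect_true(all(abs(got - dem) <= 0))
  expect_identical(out$values[R == 0], sc$t1$values[R == 0])

  out2 <- flus_allocate(sc$t1, P, dem, ca_config(seed = 2, restriction = R))
  expect_identical(out$values, out2$values)
})

test_that("flus growth concentrates where occurrence probability is high", {
  base <- toy_raster(matrix(1L, 20, 20), K = 2)
  P2 <- matrix(0.05, 20, 20)
  P2[1:6, 1:6] <- 0.95                      # known high-probability corner
  P <- list("1" = 1 - P2, "2" = P2)
  out <- flus_allocate(base, P, c(390, 10),
                       ca_config(seed = 3, batch_fraction = 1))
  changed <- which(out$values == 2L)
  expect_equal(length(changed), 10)
  top_quartile <- which(P2 >= quantile(P2, 0.75))
  expect_gte(sum(changed %in% top_quartile), 8)
})

test_that("plus allocation honours TM, threshold decay and patch seeding", {
  expect_equal(decreasing_threshold(3, 0.5, 1), 0.125)
  expect_error(plus_config(delta = 1.5), "in \\(0, 1\\)")
  tm_bad <- diag(6); tm_bad[1, 1] <- 0
  expect_error(plus_config(tm = tm_bad), "diagonal")

  sc <- small_scene()
  expg <- lapply(stats::setNames(nm = 1:6),
                 function(k) extract_expansion(sc$t0, sc$t1, as.integer(k)))
  leas <- suppressWarnings(train_leas_rf(expg, sc$drivers, trees = 40,
                                         seed = 2))
  tmhat <- estimate_transition_matrix(crosstab(sc$t0, sc$t1))
  dem <- demand_from_markov(sc$t1, tmhat, 2)

  out <- plus_allocate(sc$t1, leas$prob, dem, ca_config(seed = 4),
                       plus_config())
  expect_true(attr(out, "convergence")$converged)
  got <- as.integer(table(factor(out$values, levels = 1:6)))
  expect_true(all(got == dem))
  out_b <- plus_allocate(sc$t1, leas$prob, dem, ca_config(seed = 4),
                         plus_config())
  expect_identical(out$values, out_b$values)

  # forbidding transitions out of grassland (class 3) keeps every grassland
  # cell in place
  TM <- matrix(1, 6, 6); TM[3, -3] <- 0
  dem_tm <- dem
  # make the blocked run feasible: grassland cannot shrink below its count
  dem_tm[3] <- max(dem[3], sum(sc$t1$values == 3L))
  excess <- sum(dem_tm) - sum(dem)
  dem_tm[6] <- dem_tm[6] - excess
  out_tm <- plus_allocate(sc$t1, leas$prob, dem_tm,
                          ca_config(seed = 5), plus_config(tm = TM))
  was3 <- sc$t1$values == 3L
  expect_true(all(out_tm$values[was3] == 3L))

  # all-off-diagonal-zero TM with demand change is rejected
  expect_error(plus_allocate(sc$t1, leas$prob, dem, ca_config(seed = 5),
                             plus_config(tm = diag(6))),
               "forbids every transition")
})

test_that("cells with higher overall growth probability change more often", {
  # scattered class-2 presence so the neighborhood effect is informative
  set.seed(99)
  v <- matrix(1L, 30, 30)
  v[sample(900, 135)] <- 2L
  base <- toy_raster(v, K = 2)
  P2 <- matrix(runif(900), 30, 30)
  P <- list("1" = 1 - P2, "2" = P2)
  op0 <- P2 * neighborhood_effect(base, 2, ca_config(window = 3))
  n1 <- sum(v == 1L)
  freq <- matrix(0, 30, 30)
  for (s in 1:50) {
    out <- flus_allocate(base, P, c(n1 - 90, 135 + 90),
                         ca_config(seed = s, batch_fraction = 0.3))
    freq <- freq + (out$values == 2L & v == 1L)
  }
  chg <- v == 1L
  expect_gt(cor(op0[chg], freq[chg], method = "spearman"), 0.8)
})
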