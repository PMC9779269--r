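#' Synthetic landscape generation
#'
#' The generators in this file produce fully synthetic test scenes with the
#' statistical structure the simulation engines expect from real data: a
#' spatially autocorrelated categorical landscape, driver surfaces whose
#' association with class membership is controllable, a second-date map
#' evolved by a known Markov law, and contiguous policy masks. Everything is
#' deterministic under a fixed seed.
#'
#' @name synthetic_landscape
NULL

# --- smoothed-field machinery -----------------------------------------------

# separable box sum over a (2h+1)-cell window; edges use shrunken windows
box_sum <- function(M, h) {
  if (h < 1L) return(M)
  one_dim <- function(X) {
    n <- nrow(X)
    cs <- rbind(0, apply(X, 2L, cumsum))
    hi <- pmin(seq_len(n) + h, n) + 1L
    lo <- pmax(seq_len(n) - h - 1L, 0L) + 1L
    cs[hi, , drop = FALSE] - cs[lo, , drop = FALSE]
  }
  t(one_dim(t(one_dim(M))))
}

# matching per-cell window cell counts (edge-aware denominator)
box_count <- function(rows, cols, h) {
  box_sum(matrix(1, rows, cols), h)
}

# zero-mean unit-variance Gaussian field smoothed over ~`range` cells
smooth_field <- function(rows, cols, range) {
  h <- max(1L, as.integer(round(range / 2)))
  f <- matrix(stats::rnorm(rows * cols), rows, cols)
  f <- box_sum(f, h) / box_count(rows, cols, h)
  f <- box_sum(f, h) / box_count(rows, cols, h)   # second pass: smoother bumps
  (f - mean(f)) / stats::sd(f)
}

# --- specs ------------------------------------------------------------------

#' Landscape specification
#'
#' @param rows,cols grid dimensions.
#' @param n_classes number of LULC classes (>= 2 unless a single-class map is
#'   requested explicitly with `n_classes = 1`).
#' @param proportions simplex vector of target class proportions; defaults to
#'   shares resembling a semi-arid agro-pastoral region (grassland-dominated,
#'   farmland second).
#' @param autocorr_range spatial autocorrelation range in cells.
#' @param legend optional named character legend; defaults to the 6-class
#'   farmland/forest/grassland/water/built-up/unused legend when
#'   `n_classes == 6`, generic names otherwise.
#' @param seed integer seed.
#' @return object of class `landscape_spec`.
#' @export
landscape_spec <- function(rows, cols, n_classes = 6,
                           proportions = NULL, autocorr_range = 8,
                           legend = NULL, seed = 1L) {
  if (autocorr_range < 0) stop("`autocorr_range` must be nonnegative")
  if (n_classes < 1) stop("`n_classes` must be at least 1")
  if (is.null(proportions)) {
    proportions <- if (n_classes == 6)
      c(0.30, 0.08, 0.43, 0.02, 0.03, 0.14)
    else rep(1 / n_classes, n_classes)
  }
  if (length(proportions) != n_classes)
    stop("`proportions` length must equal `n_classes`")
  if (abs(sum(proportions) - 1) > 1e-9)
    stop("`proportions` must sum to 1")
  if (any(proportions < 0)) stop("`proportions` must be nonnegative")
  if (is.null(legend)) legend <- default_legend(n_classes)
  structure(list(rows = rows, cols = cols, n_classes = n_classes,
                 proportions = proportions, autocorr_range = autocorr_range,
                 legend = legend, seed = as.integer(seed)),
            class = "landscape_spec")
}

default_legend <- function(n_classes) {
  if (n_classes == 6) {
    stats::setNames(c("farmland", "forest", "grassland", "water",
                      "built-up", "unused"), 1:6)
  } else {
    stats::setNames(paste0("class_", seq_len(n_classes)), seq_len(n_classes))
  }
}

#' Ground-truth landscape dynamics
#'
#' Bundles the known Markov transition law (and optional driver tilt and
#' restriction fraction) used by [evolve_landscape()], so parameter-recovery
#' tests can compare estimates against it.
#'
#' @param transition_matrix K x K row-stochastic matrix.
#' @param driver_effects optional K x n_drivers coefficient matrix tilting
#'   per-cell target-class odds by `exp(drivers %*% t(effects))`.
#' @param restriction_fraction share of the map frozen during evolution.
#' @return object of class `true_dynamics`.
#' @export
true_dynamics <- function(transition_matrix, driver_effects = NULL,
                          restriction_fraction = 0) {
  tm <- as.matrix(transition_matrix)
  if (nrow(tm) != ncol(tm)) stop("transition matrix must be square")
  if (any(tm < 0) || any(abs(rowSums(tm) - 1) > 1e-9))
    stop("transition matrix rows must be nonnegative and sum to 1")
  if (any(diag(tm) < 0.5))
    warning("transition matrix has diagonal entries < 0.5; ",
            "dynamics are faster than the slow-change regime the defaults emulate")
  if (restriction_fraction < 0 || restriction_fraction > 1)
    stop("`restriction_fraction` must be in [0, 1]")
  structure(list(transition_matrix = tm, driver_effects = driver_effects,
                 restriction_fraction = restriction_fraction),
            class = "true_dynamics")
}

# --- generators -------------------------------------------------------------

#' Generate a spatially autocorrelated categorical landscape
#'
#' A smoothed Gaussian random field is thresholded at the cumulative
#' proportion quantiles, so realized class proportions match the spec closely
#' and class indicator surfaces are spatially autocorrelated.
#'
#' @param spec a [landscape_spec].
#' @return a [lulc_raster] with the spec's legend and no nodata cells.
#' @export
generate_landscape <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  set.seed(spec$seed)
  if (spec$n_classes == 1L) {
    v <- matrix(1L, spec$rows, spec$cols)
    return(lulc_raster(v, legend = spec$legend))
  }
  f <- smooth_field(spec$rows, spec$cols, spec$autocorr_range)
  # rank -> class via cumulative proportion breakpoints (exact quantiles)
  q <- stats::quantile(f, probs = cumsum(spec$proportions)[-spec$n_classes])
  v <- matrix(1L + findInterval(f, q, left.open = TRUE),
              spec$rows, spec$cols)
  lulc_raster(v, legend = spec$legend)
}

#' Generate driver surfaces associated with class membership
#'
#' Each driver is a convex mix `signal * class-mean surface +
#' (1 - signal) * smooth noise`, both standardized, so `signal = 0` gives
#' drivers independent of class and `signal = 1` gives drivers that determine
#' the class exactly (distinct per-class means).
#'
#' @param lulc a [lulc_raster].
#' @param n_drivers number of driver layers (>= 1).
#' @param signal association strength in \[0, 1\].
#' @param seed integer seed.
#' @param names_ optional layer names.
#' @return named list of numeric matrices (`NA` at nodata cells), with
#'   attribute `cell_size` copied from `lulc`; the package's DriverStack.
#' @export
generate_drivers <- function(lulc, n_drivers = 5, signal = 0.7, seed = 1L,
                             names_ = NULL) {
  if (n_drivers < 1) stop("`n_drivers` must be at least 1")
  if (signal < 0 || signal > 1) stop("`signal` must be in [0, 1]")
  set.seed(seed)
  K <- length(lulc$legend)
  codes <- class_codes(lulc)
  rows <- nrow(lulc$values); cols <- ncol(lulc$values)
  nd <- !valid_mask(lulc)
  out <- vector("list", n_drivers)
  for (d in seq_len(n_drivers)) {
    mu <- sample(seq(-2, 2, length.out = K))     # distinct per-class means
    surf <- matrix(mu[match(lulc$values, codes)], rows, cols)
    if (stats::sd(surf, na.rm = TRUE) > 0)
      surf <- (surf - mean(surf, na.rm = TRUE)) / stats::sd(surf, na.rm = TRUE)
    noise <- smooth_field(rows, cols, 4)
    layer <- signal * surf + (1 - signal) * noise
    layer[nd] <- NA_real_
    out[[d]] <- layer
  }
  names(out) <- names_ %||% paste0("driver_", seq_len(n_drivers))
  check_driver_stack(out, lulc)
  attr(out, "cell_size") <- lulc$cell_size
  out
}

# driver stacks are plain named lists of matrices; validate shape/constancy
check_driver_stack <- function(drivers, ref) {
  for (nm in names(drivers)) {
    if (!all(dim(drivers[[nm]]) == dim(ref$values)))
      stop("driver layer '", nm, "' shape differs from the reference raster")
    v <- drivers[[nm]][valid_mask(ref)]
    if (stats::sd(v, na.rm = TRUE) == 0)
      warning("driver layer '", nm, "' is constant over the valid mask")
  }
  invisible(TRUE)
}

#' Evolve a landscape by a known Markov law
#'
#' Each cell's new class is drawn from the row of the ground-truth transition
#' matrix indexed by its current class, optionally tilted by driver effects.
#' Restricted cells keep their class (both cells where a supplied restriction
#' grid is 0 and a seeded random fraction `dyn$restriction_fraction`).
#'
#' @param lulc a [lulc_raster].
#' @param dyn a [true_dynamics].
#' @param seed integer seed.
#' @param drivers optional driver stack for the tilt.
#' @param restriction optional binary grid, 0 = frozen.
#' @return a [lulc_raster] at the next date.
#' @export
evolve_landscape <- function(lulc, dyn, seed = 1L, drivers = NULL,
                             restriction = NULL) {
  stopifnot(inherits(dyn, "true_dynamics"))
  codes <- class_codes(lulc)
  K <- length(codes)
  if (nrow(dyn$transition_matrix) != K)
    stop("dynamics dimension does not match the legend")
  set.seed(seed)
  v <- lulc$values
  out <- v
  ok <- valid_mask(lulc)
  frozen <- matrix(FALSE, nrow(v), ncol(v))
  if (!is.null(restriction)) frozen <- frozen | (restriction == 0)
  if (dyn$restriction_fraction > 0) {
    idx <- which(ok & !frozen)
    nfr <- round(dyn$restriction_fraction * length(idx))
    frozen[sample(idx, nfr)] <- TRUE
  }
  act <- which(ok & !frozen)
  if (length(act) == 0L) return(lulc)
  if (is.null(dyn$driver_effects) || is.null(drivers)) {
    cur <- match(v[act], codes)
    for (a in seq_len(K)) {
      cells <- act[cur == a]
      if (length(cells))
        out[cells] <- codes[sample.int(K, length(cells), replace = TRUE,
                                       prob = dyn$transition_matrix[a, ])]
    }
  } else {
    X <- sapply(drivers, function(m) m[act])           # n_act x D
    tilt <- exp(X %*% t(dyn$driver_effects))           # n_act x K
    W <- dyn$transition_matrix[match(v[act], codes), , drop = FALSE] * tilt
    cw <- W / rowSums(W)
    cum <- t(apply(cw, 1L, cumsum))
    u <- stats::runif(length(act))
    pick <- rowSums(cum < u) + 1L
    out[act] <- codes[pick]
  }
  r <- lulc
  r$values <- out
  r
}

#' Generate contiguous policy masks
#'
#' Builds an ecological-protection (EPRL) mask that preferentially overlaps
#' grassland/forest cells and a capital-farmland (CF) mask that preferentially
#' overlaps farmland cells. Masks are contiguous blobs obtained by
#' thresholding a smooth field plus a class-affinity bonus at the exact
#' fraction quantile, so realized fractions match the request.
#'
#' @param lulc a [lulc_raster] with the default 6-class legend (or any legend;
#'   affinities fall back to the first classes).
#' @param eprl_fraction,cf_fraction target mask fractions of the valid area.
#' @param seed integer seed.
#' @return list with binary matrices `eprl` and `cf` (1 = inside the zone).
#' @export
generate_masks <- function(lulc, eprl_fraction = 0.15, cf_fraction = 0.15,
                           seed = 1L) {
  if (any(c(eprl_fraction, cf_fraction) < 0) ||
      any(c(eprl_fraction, cf_fraction) > 1))
    stop("mask fractions must be in [0, 1]")
  set.seed(seed)
  nm <- tolower(unname(lulc$legend))
  codes <- class_codes(lulc)
  pick_codes <- function(patterns, fallback) {
    hit <- codes[grepl(paste(patterns, collapse = "|"), nm)]
    if (length(hit)) hit else fallback
  }
  eprl_pref <- pick_codes(c("grass", "forest", "wood"), codes[1])
  cf_pref <- pick_codes(c("farm", "arable", "crop"), codes[1])
  one_mask <- function(fraction, pref) {
    if (fraction == 0) return(matrix(0L, nrow(lulc$values), ncol(lulc$values)))
    f <- smooth_field(nrow(lulc$values), ncol(lulc$values), 10)
    f <- f + 0.8 * (lulc$values %in% pref)
    ok <- valid_mask(lulc)
    thr <- stats::quantile(f[ok], probs = 1 - fraction)
    m <- matrix(0L, nrow(lulc$values), ncol(lulc$values))
    m[ok & f > thr] <- 1L
    m
  }
  list(eprl = one_mask(eprl_fraction, eprl_pref),
       cf = one_mask(cf_fraction, cf_pref))
}

#' Moran's I of a class indicator
#'
#' Rook-adjacency Moran's I used to verify that generated landscapes are
#' spatially autocorrelated.
#'
#' @param ind numeric/logical matrix (NA ignored).
#' @return scalar Moran's I.
#' @export
morans_i <- function(ind) {
  z <- ind - mean(ind, na.rm = TRUE)
  zv <- !is.na(z)
  z0 <- ifelse(zv, z, 0)
  num_h <- sum(z0[, -1] * z0[, -ncol(z0)] *
                 (zv[, -1] & zv[, -ncol(zv)]))
  num_v <- sum(z0[-1, ] * z0[-nrow(z0), ] *
                 (zv[-1, ] & zv[-nrow(zv), ]))
  n_pairs <- sum(zv[, -1] & zv[, -ncol(zv)]) + sum(zv[-1, ] & zv[-nrow(zv), ])
  n <- sum(zv)
  s0 <- 2 * n_pairs
  (n / s0) * (2 * (num_h + num_v)) / sum(z[zv]^2)
}

#' Standard synthetic test scene
#'
#' Generates the complete scene used throughout the package's examples and
#' tests: a 6-class landscape, two later dates evolved by a slow ground-truth
#' Markov law (mirroring a region whose class totals change little between
#' dates), a 5-layer driver stack, and EPRL/CF policy masks.
#'
#' @param rows,cols grid dimensions.
#' @param seed integer seed.
#' @param signal driver association strength.
#' @return list with elements `t0`, `t1`, `t2` ([lulc_raster]s), `drivers`,
#'   `masks`, and `dynamics` (the ground truth, a [true_dynamics]).
#' @export
make_scene <- function(rows = 300, cols = 300, seed = 1L, signal = 0.8) {
  spec <- landscape_spec(rows, cols, seed = seed)
  t0 <- generate_landscape(spec)
  dyn <- true_dynamics(default_transition_matrix())
  t1 <- evolve_landscape(t0, dyn, seed = seed + 1L)
  t2 <- evolve_landscape(t1, dyn, seed = seed + 2L)
  drivers <- generate_drivers(t0, n_drivers = 5, signal = signal,
                              seed = seed + 3L)
  masks <- generate_masks(t0, seed = seed + 4L)
  list(t0 = t0, t1 = t1, t2 = t2, drivers = drivers, masks = masks,
       dynamics = dyn)
}

#' Default slow-change ground-truth transition matrix
#'
#' Six-class, strongly diagonal matrix emulating a landscape whose per-class
#' totals shift by only a few percent per step, with the main exchanges
#' between farmland, grassland and unused land and steady built-up growth.
#'
#' @return 6 x 6 row-stochastic matrix.
#' @export
default_transition_matrix <- function() {
  tm <- matrix(0, 6, 6)
  diag(tm) <- c(0.950, 0.960, 0.945, 0.960, 0.995, 0.940)
  tm[1, 3] <- 0.030; tm[1, 5] <- 0.010; tm[1, 6] <- 0.010   # farmland ->
  tm[2, 3] <- 0.030; tm[2, 1] <- 0.010                      # forest ->
  tm[3, 1] <- 0.030; tm[3, 6] <- 0.020; tm[3, 2] <- 0.005   # grassland ->
  tm[4, 3] <- 0.020; tm[4, 6] <- 0.020                      # water ->
  tm[5, 1] <- 0.005                                         # built-up ->
  tm[6, 3] <- 0.035; tm[6, 1] <- 0.020; tm[6, 4] <- 0.005   # unused ->
  stopifnot(all(abs(rowSums(tm) - 1) < 1e-12))
  tm
}

#' Write a complete fixture scene to disk
#'
#' Writes the two-date LULC pair, driver stack, and policy masks of
#' [make_scene()] as ESRI ASCII grids with a legend sidecar, so external
#' tools can consume the same fixture.
#'
#' @param dir output directory (created if needed).
#' @param scene optional scene from [make_scene()]; generated if missing.
#' @param ... passed to [make_scene()].
#' @return the directory, invisibly.
#' @export
write_fixture_scene <- function(dir, scene = NULL, ...) {
  if (is.null(scene)) scene <- make_scene(...)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_asc(scene$t0, file.path(dir, "lulc_t0.asc"))
  write_asc(scene$t1, file.path(dir, "lulc_t1.asc"))
  write_asc(scene$t2, file.path(dir, "lulc_t2.asc"))
  for (nm in names(scene$drivers))
    write_asc(scene$drivers[[nm]], file.path(dir, paste0(nm, ".asc")))
  write_asc(scene$masks$eprl + 0, file.path(dir, "mask_eprl.asc"))
  write_asc(scene$masks$cf + 0, file.path(dir, "mask_cf.asc"))
  invisible(dir)
}
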