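#' Point set for interpolation
#'
#' @param x,y coordinates (grid/map units).
#' @param value observed values.
#' @return data.frame of class `point_set`; exact duplicate coordinates are
#'   merged by their mean with a warning (they would make the kriging system
#'   singular).
#' @export
point_set <- function(x, y, value) {
  d <- data.frame(x = x, y = y, value = value)
  if (nrow(d) < 3) stop("need at least 3 points")
  key <- paste(d$x, d$y)
  if (anyDuplicated(key)) {
    warning("duplicate coordinates merged by mean")
    d <- stats::aggregate(value ~ x + y, data = d, FUN = mean)
  }
  class(d) <- c("point_set", class(d))
  d
}

#' Variogram model
#'
#' @param model `"spherical"`, `"exponential"` or `"gaussian"`.
#' @param nugget nonnegative nugget variance.
#' @param sill total sill (>= nugget).
#' @param range positive range parameter.
#' @return object of class `variogram_model`.
#' @export
variogram_model <- function(model = c("spherical", "exponential", "gaussian"),
                            nugget = 0, sill = 1, range = 1) {
  model <- match.arg(model)
  if (nugget < 0) stop("`nugget` must be nonnegative")
  if (sill < nugget) stop("`sill` must be at least the nugget")
  if (range <= 0) stop("`range` must be positive")
  structure(list(model = model, nugget = nugget, sill = sill, range = range),
            class = "variogram_model")
}

# semivariance at distance h (vectorised)
semivariance <- function(vg, h) {
  ps <- vg$sill - vg$nugget
  g <- switch(vg$model,
    spherical = ifelse(h >= vg$range, ps,
                       ps * (1.5 * h / vg$range - 0.5 * (h / vg$range)^3)),
    exponential = ps * (1 - exp(-3 * h / vg$range)),
    gaussian = ps * (1 - exp(-3 * (h / vg$range)^2)))
  out <- vg$nugget + g
  out[h == 0] <- 0
  out
}

#' Empirical semivariogram
#'
#' Bins squared value differences by point-pair distance:
#' `gamma(h) = mean((z_i - z_j)^2) / 2` per distance bin.
#'
#' @param pts a [point_set].
#' @param n_bins number of distance bins.
#' @param max_lag maximum pair distance used (default: half the maximum).
#' @return data.frame with `dist` (bin centre), `gamma`, `n` (pairs).
#' @export
empirical_variogram <- function(pts, n_bins = 12, max_lag = NULL) {
  dx <- outer(pts$x, pts$x, "-")
  dy <- outer(pts$y, pts$y, "-")
  h <- sqrt(dx^2 + dy^2)[lower.tri(dx)]
  g <- (outer(pts$value, pts$value, "-")^2 / 2)[lower.tri(dx)]
  if (is.null(max_lag)) max_lag <- max(h) / 2
  keep <- h <= max_lag & h > 0
  h <- h[keep]; g <- g[keep]
  br <- seq(0, max_lag, length.out = n_bins + 1)
  bin <- cut(h, br, include.lowest = TRUE)
  data.frame(dist = (br[-1] + br[-length(br)]) / 2,
             gamma = as.numeric(tapply(g, bin, mean)),
             n = as.numeric(table(bin)))
}

#' Fit a variogram model to the empirical semivariogram
#'
#' Weighted least squares (weights = pair counts) over nugget, partial sill
#' and range via box-constrained optimisation.
#'
#' @param pts a [point_set].
#' @param model model kind.
#' @param n_bins,max_lag passed to [empirical_variogram()].
#' @return a [variogram_model].
#' @export
fit_variogram <- function(pts, model = "spherical", n_bins = 12,
                          max_lag = NULL) {
  ev <- empirical_variogram(pts, n_bins, max_lag)
  ev <- ev[!is.na(ev$gamma) & ev$n > 0, ]
  if (nrow(ev) < 3) stop("too few variogram bins to fit a model")
  obj <- function(par) {
    vg <- variogram_model(model, nugget = par[1],
                          sill = par[1] + par[2], range = par[3])
    sum(ev$n * (semivariance(vg, ev$dist) - ev$gamma)^2)
  }
  s0 <- max(ev$gamma, na.rm = TRUE)
  r0 <- max(ev$dist) * 0.6
  fit <- stats::optim(c(0.01 * s0, s0, r0), obj, method = "L-BFGS-B",
                      lower = c(0, 1e-9 * s0, 1e-6),
                      upper = c(s0, 10 * s0, 10 * max(ev$dist)))
  variogram_model(model, nugget = fit$par[1],
                  sill = fit$par[1] + fit$par[2], range = fit$par[3])
}

# ordinary-kriging weights for prediction locations; returns weights matrix
# (n_pts x n_pred) solving the constrained system (weights sum to 1)
krige_weights <- function(pts, vg, px, py) {
  n <- nrow(pts)
  dmat <- sqrt(outer(pts$x, pts$x, "-")^2 + outer(pts$y, pts$y, "-")^2)
  A <- rbind(cbind(semivariance(vg, dmat), 1), c(rep(1, n), 0))
  d0 <- sqrt(outer(pts$x, px, "-")^2 + outer(pts$y, py, "-")^2)
  B <- rbind(semivariance(vg, d0), 1)
  sol <- solve(A, B)
  sol[seq_len(n), , drop = FALSE]
}

#' Ordinary kriging to a grid
#'
#' Predicts a continuous surface from point observations with
#' ordinary-kriging weights (which sum to 1 at every node); with a zero
#' nugget the surface interpolates the observations exactly.
#'
#' @param pts a [point_set].
#' @param vg a [variogram_model] (e.g. from [fit_variogram()]).
#' @param rows,cols output grid dimensions.
#' @param cell_size cell size; node (r, c) is predicted at the cell centre
#'   with row 1 the top row, matching the raster convention.
#' @param xll,yll grid origin.
#' @return numeric matrix with `cell_size`, `xll`, `yll` attributes (a
#'   driver-stack layer).
#' @export
krige_surface <- function(pts, vg, rows, cols, cell_size = 1,
                          xll = 0, yll = 0) {
  cx <- xll + (seq_len(cols) - 0.5) * cell_size
  cy <- yll + (rows - seq_len(rows) + 0.5) * cell_size
  px <- rep(cx, each = rows)
  py <- rep(cy, times = cols)
  W <- krige_weights(pts, vg, px, py)
  pred <- as.numeric(crossprod(W, pts$value))
  m <- matrix(pred, rows, cols)
  attr(m, "cell_size") <- cell_size
  attr(m, "xll") <- xll
  attr(m, "yll") <- yll
  m
}

#' Leave-one-out cross-validation of a kriging model
#'
#' Predicts each point from all others and reports the mean error and root
#' mean square error of the predictions.
#'
#' @param pts a [point_set] (>= 4 points).
#' @param vg a [variogram_model].
#' @return named vector `c(me = ..., rmse = ...)`.
#' @export
cross_validate <- function(pts, vg) {
  n <- nrow(pts)
  if (n < 4) stop("leave-one-out cross-validation needs at least 4 points")
  err <- vapply(seq_len(n), function(i) {
    w <- krige_weights(pts[-i, ], vg, pts$x[i], pts$y[i])
    sum(w * pts$value[-i]) - pts$value[i]
  }, numeric(1))
  c(me = mean(err), rmse = sqrt(mean(err^2)))
}
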