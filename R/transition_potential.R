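#' Sample training cells from a map and driver stack
#'
#' Draws cells for training occurrence-probability models. Uniform sampling
#' draws `rate` of all valid cells; stratified sampling draws `rate` of each
#' class separately so rare classes keep their share. Cells that are nodata
#' or have a missing driver value are never sampled.
#'
#' @param lulc a [lulc_raster].
#' @param drivers driver stack (named list of matrices).
#' @param rate sampling rate in (0, 1].
#' @param strategy `"uniform"` or `"stratified"`.
#' @param seed integer seed.
#' @return data.frame with columns `cell` (grid index), `label` (class code,
#'   factor over the legend) and one column per driver.
#' @export
sample_cells <- function(lulc, drivers, rate = 0.1,
                         strategy = c("uniform", "stratified"), seed = 1L) {
  strategy <- match.arg(strategy)
  if (rate <= 0 || rate > 1) stop("`rate` must be in (0, 1]")
  set.seed(seed)
  ok <- valid_mask(lulc)
  for (d in drivers) ok <- ok & !is.na(d)
  idx <- which(ok)
  if (strategy == "uniform") {
    n <- max(1L, round(rate * length(idx)))
    pick <- if (rate == 1) idx else sort(sample(idx, n))
  } else {
    codes <- class_codes(lulc)
    pick <- integer(0)
    for (k in codes) {
      cells <- idx[lulc$values[idx] == k]
      if (!length(cells)) {
        warning("class ", k, " has no valid cells; skipped in stratified sampling")
        next
      }
      n <- max(1L, round(rate * length(cells)))
      pick <- c(pick, if (rate == 1) cells else sample(cells, n))
    }
    pick <- sort(pick)
  }
  X <- sapply(drivers, function(m) m[pick])
  if (is.null(dim(X))) X <- matrix(X, nrow = length(pick),
                                   dimnames = list(NULL, names(drivers)))
  out <- data.frame(cell = pick,
                    label = factor(lulc$values[pick],
                                   levels = names(lulc$legend)))
  cbind(out, as.data.frame(X))
}

#' Train an ANN occurrence-probability model
#'
#' Fits a single-hidden-layer neural network (sigmoid hidden units, softmax
#' output) mapping standardized driver values to class membership
#' probabilities — the classifier behind the FLUS-style engine's
#' probability-of-occurrence surfaces. Training is deterministic under the
#' seed.
#'
#' @param samples data.frame from [sample_cells()].
#' @param hidden_units hidden layer size (default 12, matched to a ~dozen
#'   drivers).
#' @param epochs maximum training iterations.
#' @param seed integer seed.
#' @return object of class `ann_potential`.
#' @export
train_ann <- function(samples, hidden_units = 12, epochs = 300, seed = 1L) {
  drv <- setdiff(names(samples), c("cell", "label"))
  y <- droplevels(samples$label)
  if (nlevels(y) < 2) stop("ANN training needs at least 2 classes in the sample")
  X <- as.matrix(samples[drv])
  ctr <- colMeans(X); scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- scale(X, ctr, scl)
  set.seed(seed)
  fit <- nnet::nnet(Xs, nnet::class.ind(y), size = hidden_units,
                    softmax = TRUE, maxit = epochs, trace = FALSE,
                    MaxNWts = 100000)
  acc <- mean(max.col(fit$fitted.values) == as.integer(y))
  if (acc < 1 / nlevels(y))
    warning("ANN training accuracy below chance; model may not have converged")
  structure(list(net = fit, center = ctr, scale = scl,
                 levels = levels(samples$label), drivers = drv),
            class = "ann_potential")
}

#' Predict an ANN probability-of-occurrence stack
#'
#' Applies a trained [train_ann()] model to every valid cell. The per-cell
#' class probabilities form a simplex (sum to 1), so they are directly
#' comparable across classes during roulette competition.
#'
#' @param model an `ann_potential`.
#' @param drivers driver stack aligned to the prediction grid.
#' @return named list of probability matrices (one per legend class, `NA`
#'   where any driver is missing).
#' @export
predict_ann <- function(model, drivers) {
  ok <- !Reduce(`|`, lapply(drivers, is.na))
  idx <- which(ok)
  X <- sapply(drivers[model$drivers], function(m) m[idx])
  Xs <- scale(X, model$center, model$scale)
  P <- stats::predict(model$net, Xs)              # rows on the simplex
  P <- P / rowSums(P)
  trained <- colnames(P)
  out <- lapply(model$levels, function(k) {
    m <- matrix(NA_real_, nrow(drivers[[1]]), ncol(drivers[[1]]))
    m[idx] <- if (k %in% trained) P[, k] else 0
    m
  })
  names(out) <- model$levels
  out
}

#' Extract per-class expansion grids between two dates
#'
#' A cell is an expansion cell for class k when it was not k at the first
#' date and is k at the second — the land expansion analysis strategy's
#' training target.
#'
#' @param date1,date2 aligned [lulc_raster]s.
#' @param k class code (must be in the legend).
#' @return binary matrix (1 = newly expanded into k, `NA` at nodata).
#' @export
extract_expansion <- function(date1, date2, k) {
  check_aligned(date1, date2, "expansion inputs")
  if (!as.character(k) %in% names(date1$legend))
    stop("class ", k, " is not in the legend")
  ok <- valid_mask(date1) & valid_mask(date2)
  m <- matrix(NA_real_, nrow(date1$values), ncol(date1$values))
  m[ok] <- as.numeric(date1$values[ok] != k & date2$values[ok] == k)
  m
}

#' Train random-forest expansion-probability models (LEAS)
#'
#' For each class, fits a binary random forest separating its expansion cells
#' from sampled non-expansion cells (1:1 class balance, capped per class) on
#' the driver values, and predicts an expansion-probability surface over the
#' whole grid. Driver contributions are the normalised impurity importances.
#' Surfaces are per-class probabilities in \[0, 1\] and are deliberately not
#' normalised across classes.
#'
#' @param expansion named list of binary grids from [extract_expansion()],
#'   one per class code.
#' @param drivers driver stack.
#' @param sample_cap maximum positives (and negatives) per class.
#' @param trees number of trees.
#' @param min_pos classes with fewer expansion cells get a flat 0.5 surface
#'   with a warning.
#' @param seed integer seed.
#' @return object of class `leas_potential`: list with `prob` (stack) and
#'   `contributions` (class x driver matrix, rows summing to 1).
#' @export
train_leas_rf <- function(expansion, drivers, sample_cap = 3000, trees = 100,
                          min_pos = 10, seed = 1L) {
  drv <- names(drivers)
  nvalid <- sapply(expansion, function(e) sum(e == 1, na.rm = TRUE))
  if (all(nvalid == 0))
    stop("no expansion cells for any class; LEAS needs change between the ",
         "dates (consider the ANN potential instead)")
  ok <- !Reduce(`|`, lapply(drivers, is.na))
  idx_all <- which(ok)
  Xall <- sapply(drivers, function(m) m[idx_all])
  prob <- list(); contrib <- list()
  set.seed(seed)
  for (k in names(expansion)) {
    e <- expansion[[k]]
    pos <- which(e == 1 & ok)
    if (length(pos) < min_pos) {
      warning("class ", k, " has ", length(pos),
              " expansion cells (< ", min_pos, "); flat probability used")
      m <- matrix(NA_real_, nrow(e), ncol(e))
      m[idx_all] <- 0.5
      prob[[k]] <- m
      contrib[[k]] <- stats::setNames(rep(1 / length(drv), length(drv)), drv)
      next
    }
    if (length(pos) > sample_cap) pos <- sample(pos, sample_cap)
    neg_pool <- setdiff(which(e == 0 & ok), pos)
    neg <- sample(neg_pool, min(length(neg_pool), length(pos)))
    cells <- c(pos, neg)
    dat <- data.frame(y = factor(rep(c(1, 0), c(length(pos), length(neg)))),
                      sapply(drivers, function(m) m[cells]))
    fit <- ranger::ranger(y ~ ., data = dat, num.trees = trees,
                          probability = TRUE, importance = "impurity",
                          mtry = max(1L, floor(sqrt(length(drv)))),
                          seed = seed, num.threads = 1)
    pr <- stats::predict(fit, data.frame(Xall),
                         num.threads = 1)$predictions[, "1"]
    m <- matrix(NA_real_, nrow(e), ncol(e))
    m[idx_all] <- pr
    prob[[k]] <- m
    imp <- fit$variable.importance
    contrib[[k]] <- imp / sum(imp)
  }
  structure(list(prob = prob,
                 contributions = do.call(rbind, contrib)),
            class = "leas_potential")
}
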