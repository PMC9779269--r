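#' Estimate a Markov transition matrix from two-date counts
#'
#' Row-normalises the transition count matrix from [crosstab()]. Classes
#' absent at the first date get an identity row (they cannot be observed to
#' transition), with a warning.
#'
#' @param counts a `transition_counts` object.
#' @param period_years years between the two dates (metadata; projections
#'   step in whole matrix applications).
#' @return object of class `transition_matrix` with elements `probs`
#'   (row-stochastic K x K), `counts`, and `period_years`.
#' @export
estimate_transition_matrix <- function(counts, period_years = 5) {
  stopifnot(inherits(counts, "transition_counts"))
  cm <- counts$counts
  if (sum(cm) == 0L) stop("cannot estimate a transition matrix from empty counts")
  rs <- rowSums(cm)
  probs <- cm / ifelse(rs == 0, 1, rs)
  if (any(rs == 0)) {
    warning("class(es) absent at date 1 get identity rows: ",
            paste(rownames(cm)[rs == 0], collapse = ", "))
    for (i in which(rs == 0)) probs[i, ] <- as.numeric(seq_len(ncol(cm)) == i)
  }
  structure(list(probs = probs, counts = counts, period_years = period_years),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix> %d classes, %g-year step\n",
              nrow(x$probs), x$period_years))
  print(round(x$probs, 4))
  invisible(x)
}

mat_power <- function(m, n) {
  out <- diag(nrow(m))
  for (i in seq_len(n)) out <- out %*% m
  out
}

#' Project class demand with a Markov chain
#'
#' Multiplies current class amounts by the n-step transition matrix
#' (`areas %*% probs^n`). Works in any units (km2 or cell counts); the total
#' is conserved because the matrix is row-stochastic. Fractional steps are
#' not supported: a 5-year matrix projected 15 years means `n_steps = 3`.
#'
#' @param areas_now named nonnegative vector in legend order.
#' @param tm a [estimate_transition_matrix()] result (or row-stochastic matrix).
#' @param n_steps whole number of matrix applications (>= 1).
#' @return named numeric demand vector, same units as `areas_now`.
#' @export
project_demand <- function(areas_now, tm, n_steps = 1L) {
  probs <- if (inherits(tm, "transition_matrix")) tm$probs else as.matrix(tm)
  if (n_steps < 1 || n_steps != round(n_steps))
    stop("`n_steps` must be a whole number >= 1")
  if (any(areas_now < 0)) stop("areas must be nonnegative")
  out <- as.numeric(areas_now %*% mat_power(probs, as.integer(n_steps)))
  stats::setNames(out, names(areas_now) %||% rownames(probs))
}

#' Largest-remainder rounding to a fixed total
#'
#' Rounds a nonnegative vector to integers whose sum equals `total`, giving
#' the extra units to the largest fractional remainders; used so projected
#' demand in cells conserves the valid-cell total exactly.
#'
#' @param x nonnegative numeric vector.
#' @param total target integer total (defaults to `round(sum(x))`).
#' @return integer vector summing to `total`.
#' @export
round_largest_remainder <- function(x, total = round(sum(x))) {
  fl <- floor(x)
  need <- round(as.numeric(total) - sum(fl))
  if (need > 0) {
    ord <- order(x - fl, decreasing = TRUE)
    fl[ord[seq_len(need)]] <- fl[ord[seq_len(need)]] + 1
  }
  as.integer(fl)
}

# neighborhood share of class `code` in an n x n window, centre excluded,
# edge cells use shrunken windows with matching denominators
neigh_share <- function(values, code, window) {
  h <- (window - 1L) %/% 2L
  ind <- (values == code) * 1
  cnt <- box_count(nrow(values), ncol(values), h)
  (box_sum(ind, h) - ind) / (cnt - 1)
}

#' Default transition-suitability stack for the Markov CA
#'
#' Builds one suitability surface per class from two calibration dates: the
#' class-occurrence indicator at the later date smoothed by the CA window's
#' mean filter (default 5 x 5), so cells inside and adjacent to existing
#' class patches score high. A transparent stand-in for suitability mapping
#' done by desktop GIS workflows; user-supplied stacks are accepted
#' everywhere.
#'
#' @param date1,date2 aligned [lulc_raster]s (the calibration pair).
#' @param window odd filter width in cells.
#' @return named list of matrices in \[0, 1\], one per legend class.
#' @export
transition_suitability <- function(date1, date2, window = 5) {
  check_aligned(date1, date2, "suitability inputs")
  h <- (window - 1L) %/% 2L
  cnt <- box_count(nrow(date2$values), ncol(date2$values), h)
  out <- lapply(class_codes(date2), function(k) {
    ind <- (date2$values == k) * 1
    box_sum(ind, h) / cnt
  })
  names(out) <- names(date2$legend)
  out
}

#' Markov-chain cellular-automata allocation
#'
#' Allocates projected class demand onto the map: over `cycles` rounds, cells
#' of over-supplied classes are reassigned to under-supplied classes at the
#' locations with the highest `suitability x neighborhood share` score, ties
#' broken by a seeded jitter. Restricted cells (restriction grid = 0) never
#' change.
#'
#' @param base starting [lulc_raster].
#' @param suit suitability stack (named list of \[0,1\] matrices, legend
#'   order), e.g. from [transition_suitability()].
#' @param demand target per-class amounts (cells, or any units summing to the
#'   valid-cell total after largest-remainder rounding), legend order.
#' @param cycles number of CA rounds the reallocation is spread over.
#' @param window odd neighborhood width (the classic default is 5).
#' @param seed integer seed (jitter tie-breaks).
#' @param restriction optional binary grid, 0 = frozen.
#' @return a [lulc_raster] whose composition matches `demand`.
#' @export
ca_markov_allocate <- function(base, suit, demand, cycles = 3, window = 5,
                               seed = 1L, restriction = NULL) {
  if (window < 3 || window %% 2 == 0) stop("`window` must be odd and >= 3")
  if (cycles < 1) stop("`cycles` must be >= 1")
  codes <- class_codes(base)
  K <- length(codes)
  total <- sum(class_counts(base))
  target <- round_largest_remainder(as.numeric(demand), total)
  if (any(target < 0) || sum(target) > total)
    stop("demand is infeasible for the valid area")
  set.seed(seed)
  cur <- base$values
  ok <- valid_mask(base)
  free <- ok
  if (!is.null(restriction)) free <- free & (restriction != 0)
  counts0 <- class_counts(base)
  for (cyc in seq_len(cycles)) {
    counts <- as.integer(table(factor(cur[ok], levels = codes)))
    step_target <- round_largest_remainder(
      counts0 + (target - counts0) * cyc / cycles, total)
    D <- step_target - counts
    if (all(D == 0)) next
    growth <- which(D > 0)
    release <- stats::setNames(pmax(counts - step_target, 0L), codes)
    cand_cells <- which(free & matrix(match(cur, codes), nrow(cur)) %in%
                          which(release > 0))
    if (!length(cand_cells)) break
    pairs <- list()
    for (g in growth) {
      score <- suit[[g]] * (neigh_share(cur, codes[g], window) + 0.01)
      sc <- score[cand_cells] + stats::runif(length(cand_cells), 0, 1e-9)
      keep <- order(sc, decreasing = TRUE)[seq_len(min(length(sc), 4L * D[g]))]
      pairs[[length(pairs) + 1L]] <-
        data.frame(cell = cand_cells[keep], g = g, score = sc[keep])
    }
    pairs <- do.call(rbind, pairs)
    pairs <- pairs[order(pairs$score, decreasing = TRUE), ]
    need <- D
    taken <- logical(length(cur))
    for (i in seq_len(nrow(pairs))) {
      cell <- pairs$cell[i]; g <- pairs$g[i]
      if (need[g] <= 0L) next
      if (taken[cell]) next
      src <- as.character(cur[cell])
      if (release[src] <= 0L) next
      cur[cell] <- codes[g]
      need[g] <- need[g] - 1L
      release[src] <- release[src] - 1L
      taken[cell] <- TRUE
      if (all(need <= 0L)) break
    }
    # completion sweep: the trimmed candidate lists can run dry for a class
    # whose high-score cells all sit in an exhausted source class; finish the
    # cycle by ranking the full remaining pool per unmet class
    for (g in which(need > 0L)) {
      pool <- which(free & !taken &
                      matrix(match(cur, codes), nrow(cur)) %in%
                        which(release > 0))
      if (!length(pool)) break
      score <- suit[[g]] * (neigh_share(cur, codes[g], window) + 0.01)
      pool <- pool[order(score[pool] + stats::runif(length(pool), 0, 1e-9),
                         decreasing = TRUE)]
      for (cell in pool) {
        if (need[g] <= 0L) break
        src <- as.character(cur[cell])
        if (release[src] <= 0L) next
        cur[cell] <- codes[g]
        need[g] <- need[g] - 1L
        release[src] <- release[src] - 1L
        taken[cell] <- TRUE
      }
    }
  }
  out <- base
  out$values <- cur
  out
}

#' Read / write transition matrices as delimited text
#'
#' @param tm a `transition_matrix` (or plain matrix) / file path.
#' @param path file path.
#' @return `read_transition_matrix` returns a row-stochastic matrix with
#'   class-code dimnames.
#' @export
write_transition_matrix <- function(tm, path) {
  probs <- if (inherits(tm, "transition_matrix")) tm$probs else as.matrix(tm)
  utils::write.csv(probs, path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_transition_matrix
#' @export
read_transition_matrix <- function(path) {
  d <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(d)
}
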