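#' CA engine configuration
#'
#' Shared settings for the roulette-competition allocation engines.
#'
#' @param window odd neighborhood width (>= 3).
#' @param weights per-class neighborhood weights w_k (recycled; default 1).
#' @param inertia_start starting per-class inertia coefficients.
#' @param restriction optional binary grid; 0 = no transition allowed.
#' @param tolerance allowed per-class cell-count deviation from demand at
#'   convergence (0 = exact).
#' @param max_iter iteration cap.
#' @param batch_fraction fraction of eligible source cells updated per
#'   iteration.
#' @param stall_limit consecutive no-change iterations before the engine
#'   falls back to deterministic ranked assignment to guarantee convergence.
#' @param seed integer seed.
#' @return object of class `ca_config`.
#' @export
ca_config <- function(window = 3, weights = 1, inertia_start = 1,
                      restriction = NULL, tolerance = 0, max_iter = 200,
                      batch_fraction = 0.5, stall_limit = 5, seed = 1L) {
  if (window < 3 || window %% 2 == 0) stop("`window` must be odd and >= 3")
  if (any(weights <= 0)) stop("neighborhood weights must be positive")
  if (tolerance < 0) stop("`tolerance` must be nonnegative")
  structure(list(window = window, weights = weights,
                 inertia_start = inertia_start, restriction = restriction,
                 tolerance = tolerance, max_iter = max_iter,
                 batch_fraction = batch_fraction, stall_limit = stall_limit,
                 seed = as.integer(seed)),
            class = "ca_config")
}

#' PLUS-engine configuration
#'
#' Settings of the patch-seeding allocation: the decreasing threshold
#' `tau = delta^l * r1` (r1 a truncated half-normal draw in (0, 1]), the
#' demand-gap stride `Step` controlling when the decay counter l increments,
#' the binary allowed-transition matrix TM, and the random patch-seed
#' probability.
#'
#' @param step demand-gap stride; when an iteration improves the total
#'   absolute gap by less than `step`, l increments and tau decays. `NULL`
#'   sets 1% of the initial total gap.
#' @param delta decay factor in (0, 1).
#' @param r1_mean,r1_sd parameters of the half-normal r1 draw.
#' @param tm K x K binary allowed-transition matrix (diagonal must be 1);
#'   `NULL` allows everything.
#' @param seed_prob probability a candidate cell is treated as a fresh patch
#'   seed (neighborhood term waived).
#' @return object of class `plus_config`.
#' @export
plus_config <- function(step = NULL, delta = 0.9, r1_mean = 0, r1_sd = 1,
                        tm = NULL, seed_prob = 0.02) {
  if (delta <= 0 || delta >= 1) stop("`delta` must be in (0, 1)")
  if (!is.null(tm)) {
    tm <- as.matrix(tm)
    if (any(diag(tm) != 1)) stop("TM diagonal must be 1 (a class may keep itself)")
    if (!all(tm %in% c(0, 1))) stop("TM must be binary")
  }
  if (!is.null(step) && step <= 0) stop("`step` must be positive")
  structure(list(step = step, delta = delta, r1_mean = r1_mean, r1_sd = r1_sd,
                 tm = tm, seed_prob = seed_prob),
            class = "plus_config")
}

#' Neighborhood effect of a class
#'
#' Share of the n x n window (centre excluded) occupied by class k at the
#' current state, scaled by the class weight: `Omega in [0, w_k]`. Edge cells
#' use shrunken windows with matching denominators.
#'
#' @param map a [lulc_raster] (or integer matrix of codes).
#' @param k class code.
#' @param cfg a [ca_config] (its `window` and `weights` are used).
#' @return numeric matrix.
#' @export
neighborhood_effect <- function(map, k, cfg = ca_config()) {
  values <- if (inherits(map, "lulc_raster")) map$values else map
  codes <- if (inherits(map, "lulc_raster")) class_codes(map) else
    sort(unique(as.vector(values)))
  w <- rep_len(cfg$weights, length(codes))[match(k, codes)]
  neigh_share(values, k, cfg$window) * w
}

#' Adaptive inertia update
#'
#' Adjusts a class's inertia coefficient from its demand gaps at the last two
#' iterations (gap = demand - current amount). The coefficient is unchanged
#' while the absolute gap is not growing; it is scaled by `D2/D1` when a
#' negative gap (overshoot) worsens and by `D1/D2` when a positive gap
#' (shortfall) worsens. Vectorised over classes.
#'
#' @param prev positive inertia value(s).
#' @param d_t1 gap at the more recent iteration.
#' @param d_t2 gap one iteration earlier.
#' @return updated inertia, always positive.
#' @export
update_inertia <- function(prev, d_t1, d_t2) {
  stopifnot(all(prev > 0))
  out <- prev
  worse_neg <- (d_t2 < 0) & (d_t1 < d_t2)            # 0 > D2 > D1
  worse_pos <- (d_t1 > d_t2) & (d_t2 > 0)            # D1 > D2 > 0
  safe <- function(a, b) ifelse(b == 0, 1, a / b)
  out[worse_neg] <- prev[worse_neg] * safe(d_t2[worse_neg], d_t1[worse_neg])
  out[worse_pos] <- prev[worse_pos] * safe(d_t1[worse_pos], d_t2[worse_pos])
  out
}

#' Combined (overall) growth probability
#'
#' `OP_{i,k} = P_{i,k} * Inertia_k * Omega_{i,k} * R_i`, with R binary
#' (0 = no transition allowed).
#'
#' @param P probability stack (named list of matrices).
#' @param inertia per-class inertia vector (legend order).
#' @param omega neighborhood-effect stack (named list, same order).
#' @param R binary restriction grid (or `NULL` for all-permitted).
#' @return named list of OP matrices.
#' @export
combined_probability <- function(P, inertia, omega, R = NULL) {
  K <- length(P)
  if (is.null(R)) R <- matrix(1, nrow(P[[1]]), ncol(P[[1]]))
  out <- lapply(seq_len(K), function(k) P[[k]] * inertia[k] * omega[[k]] * R)
  names(out) <- names(P)
  out
}

# half-normal draw truncated to (0, 1]
draw_r1 <- function(n, mean = 0, sd = 1) {
  x <- abs(stats::rnorm(n, mean, sd))
  pmin(pmax(x, 1e-6), 1)
}

# Shared roulette-competition allocation loop. `mode` selects the FLUS-style
# behaviour (no patch seeds, no threshold) or the PLUS-style behaviour
# (patch seeds, decreasing threshold tau, TM gate). The demand-gap
# bookkeeping interprets the per-class gap G as demand minus current count.
ca_engine <- function(base, P, demand, cfg, pcfg = NULL,
                      mode = c("flus", "plus")) {
  mode <- match.arg(mode)
  codes <- class_codes(base)
  K <- length(codes)
  ok <- valid_mask(base)
  total <- sum(ok)
  target <- round_largest_remainder(as.numeric(demand), total)
  if (any(target < 0) || sum(target) != total)
    stop("demand is infeasible: per-class targets must be nonnegative and ",
         "sum to the valid-cell total")
  w <- rep_len(cfg$weights, K)
  R <- cfg$restriction
  free <- ok
  if (!is.null(R)) free <- free & (R != 0)
  frozen_counts <- tabulate(match(base$values[ok & !free], codes), K)
  if (any(target < frozen_counts))
    warning("demand below the restricted (frozen) cell count for class(es) ",
            paste(codes[target < frozen_counts], collapse = ", "),
            "; demand cannot be met exactly")
  TM <- if (!is.null(pcfg) && !is.null(pcfg$tm)) pcfg$tm else
    matrix(1, K, K)
  set.seed(cfg$seed)
  cur <- base$values
  cur_idx <- matrix(match(cur, codes), nrow(cur))
  Pmat <- vapply(P, as.vector, numeric(length(cur)))   # cells x K, fixed
  Pmat[is.na(Pmat)] <- 0
  inertia <- rep_len(cfg$inertia_start, K)
  counts <- tabulate(cur_idx[ok], K)
  D1 <- D2 <- target - counts
  l <- 0L
  step <- if (!is.null(pcfg)) pcfg$step %||% max(1, round(0.01 * sum(abs(D1))))
  gap_prev <- sum(abs(D1))
  stall <- 0L
  log <- list()
  for (it in seq_len(cfg$max_iter)) {
    counts <- tabulate(cur_idx[ok], K)
    D <- target - counts
    if (it > 2) inertia <- update_inertia(inertia, D1, D2)
    D2 <- D1; D1 <- D
    log[[it]] <- c(iter = it, gap = sum(abs(D)), l = l, counts)
    if (max(abs(D)) <= cfg$tolerance) break
    eff_inertia <- ifelse(D > 0, inertia, 1)   # inertia boosts growth classes
    release <- pmax(-D, 0L)
    need <- pmax(D, 0L)
    src_classes <- which(release > 0)
    src_cells <- which(free & (cur_idx %in% src_classes))
    if (!length(src_cells)) break
    nb <- max(1L, ceiling(cfg$batch_fraction * length(src_cells)))
    batch <- if (nb >= length(src_cells)) src_cells else
      sample(src_cells, nb)
    omega <- vapply(seq_len(K), function(k)
      as.vector(neigh_share(cur, codes[k], cfg$window)) * w[k],
      numeric(length(cur)))
    OP <- Pmat[batch, , drop = FALSE] * omega[batch, , drop = FALSE] *
      rep(eff_inertia, each = length(batch))
    if (mode == "plus") {
      seeds <- stats::runif(length(batch)) < pcfg$seed_prob
      if (any(seeds))
        OP[seeds, ] <- Pmat[batch[seeds], , drop = FALSE] *
          rep(eff_inertia, each = sum(seeds))
      OP <- OP * TM[cur_idx[batch], , drop = FALSE]
    }
    # competition is restricted to classes still short of demand; cells whose
    # draw fails simply keep their class this round
    OP[, need <= 0L] <- 0
    # roulette draw of the candidate class per batch cell
    rs <- rowSums(OP)
    live <- which(rs > 0)
    pick <- integer(length(batch))
    if (length(live)) {
      u <- stats::runif(length(live)) * rs[live]
      cum <- OP[live, , drop = FALSE]
      for (k in 2:K) cum[, k] <- cum[, k] + cum[, k - 1]
      pick[live] <- rowSums(cum < u) + 1L
    }
    src <- cur_idx[batch]
    cand <- which(pick > 0L)
    cand <- cand[pick[cand] != src[cand] & need[pick[cand]] > 0 &
                   release[src[cand]] > 0]
    if (mode == "plus" && length(cand)) {
      tau <- pcfg$delta^l * draw_r1(length(cand), pcfg$r1_mean, pcfg$r1_sd)
      pk <- Pmat[cbind(batch[cand], pick[cand])]
      cand <- cand[pk > tau]
    }
    accepted <- 0L
    if (length(cand)) {
      sc <- OP[cbind(cand, pick[cand])]
      cand <- cand[order(sc, decreasing = TRUE)]
      for (ci in cand) {
        g <- pick[ci]; s <- src[ci]
        if (need[g] <= 0L || release[s] <= 0L) next
        cell <- batch[ci]
        cur[cell] <- codes[g]
        cur_idx[cell] <- g
        need[g] <- need[g] - 1L
        release[s] <- release[s] - 1L
        accepted <- accepted + 1L
      }
    }
    gap_now <- sum(abs(target - tabulate(cur_idx[ok], K)))
    if (mode == "plus" && (gap_prev - gap_now) < step) l <- l + 1L
    gap_prev <- gap_now
    stall <- if (accepted == 0L) stall + 1L else 0L
    if (stall >= cfg$stall_limit) {
      # deterministic fallback: rank remaining moves by raw potential so a
      # feasible demand always completes
      for (g in which(need > 0)) {
        pool <- which(free & (cur_idx %in% which(release > 0)) &
                        TM[cbind(as.vector(cur_idx), g)] == 1)
        if (!length(pool)) next
        pool <- pool[order(Pmat[pool, g], decreasing = TRUE)]
        for (cell in pool) {
          if (need[g] <= 0L) break
          s <- cur_idx[cell]
          if (release[s] <= 0L) next
          cur[cell] <- codes[g]
          cur_idx[cell] <- g
          need[g] <- need[g] - 1L
          release[s] <- release[s] - 1L
        }
      }
      stall <- 0L
    }
  }
  counts <- tabulate(cur_idx[ok], K)
  converged <- max(abs(target - counts)) <= cfg$tolerance
  if (!converged)
    warning("allocation stopped at max_iter with residual demand gap ",
            sum(abs(target - counts)))
  out <- base
  out$values <- cur
  log <- as.data.frame(do.call(rbind, log))
  names(log) <- c("iter", "gap", "l", paste0("count_", codes))
  attr(out, "convergence") <- list(converged = converged, log = log,
                                   target = stats::setNames(target, codes),
                                   inertia = inertia)
  out
}

#' FLUS-style allocation
#'
#' Iterative roulette competition: each round recomputes neighborhood
#' effects, adapts per-class inertia toward the demand gap, combines them
#' with the ANN occurrence probabilities into overall growth probabilities,
#' and lets sampled cells of over-supplied classes convert to the class a
#' roulette draw selects, until every class count matches demand within the
#' configured tolerance. Restricted cells never change.
#'
#' @param base starting [lulc_raster].
#' @param P probability stack (e.g. from [predict_ann()]), legend order.
#' @param demand per-class target (cells; rounded by largest remainder).
#' @param cfg a [ca_config].
#' @return a [lulc_raster] with a `convergence` attribute (flag, per-iteration
#'   log, final inertia).
#' @export
flus_allocate <- function(base, P, demand, cfg = ca_config()) {
  ca_engine(base, P, demand, cfg, mode = "flus")
}

#' PLUS-style allocation (patch-seeding CA)
#'
#' Extends the roulette engine with the patch-seeding mechanism: candidate
#' cells may ignore the neighborhood term with a small probability (seeding
#' new patches away from existing ones), a candidate conversion to class c is
#' accepted only when its expansion probability exceeds the decreasing
#' threshold `tau = delta^l * r1` and the transition matrix allows it, and l
#' increments whenever an iteration narrows the total demand gap by less than
#' `Step`, so acceptance progressively loosens and feasible demand always
#' completes.
#'
#' @param base starting [lulc_raster].
#' @param P_leas expansion-probability stack (e.g. from [train_leas_rf()]).
#' @param demand per-class target (cells).
#' @param cfg a [ca_config].
#' @param pcfg a [plus_config].
#' @return a [lulc_raster] with a `convergence` attribute.
#' @export
plus_allocate <- function(base, P_leas, demand, cfg = ca_config(),
                          pcfg = plus_config()) {
  if (!is.null(pcfg$tm)) {
    K <- length(base$legend)
    if (!all(dim(pcfg$tm) == K)) stop("TM dimension does not match the legend")
    off <- pcfg$tm; diag(off) <- 0
    counts <- class_counts(base)
    target <- round_largest_remainder(as.numeric(demand), sum(counts))
    if (all(off == 0) && any(target != counts))
      stop("TM forbids every transition but demand requires change")
  }
  ca_engine(base, P_leas, demand, cfg, pcfg = pcfg, mode = "plus")
}

#' Decreasing threshold sequence
#'
#' `tau = delta^l * r1`; exposed for auditing the threshold decay.
#'
#' @param l decay step counter (nonnegative integer).
#' @param delta decay factor in (0, 1).
#' @param r1 random component (fixed value or draw).
#' @return numeric threshold.
#' @export
decreasing_threshold <- function(l, delta, r1 = 1) delta^l * r1
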