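#' Shannon diversity and evenness of a landscape
#'
#' `SHDI = -sum p_k ln p_k` over the classes present (proportions over valid
#' cells, natural log); `SHEI = SHDI / ln(K)` with K the legend size, so a
#' landscape with all legend classes equally abundant scores 1.
#'
#' @param map a [lulc_raster].
#' @return scalar metric value.
#' @export
shdi <- function(map) {
  p <- class_proportions(map)
  p <- p[p > 0]
  if (!length(p)) stop("empty map: no valid cells")
  -sum(p * log(p))
}

#' @rdname shdi
#' @export
shei <- function(map) {
  K <- length(map$legend)
  if (K < 2) stop("SHEI needs a legend with at least 2 classes")
  shdi(map) / log(K)
}

class_proportions <- function(map) {
  counts <- class_counts(map)
  if (sum(counts) == 0) stop("empty map: no valid cells")
  counts / sum(counts)
}

#' Contagion index
#'
#' Landscape-level contagion (percent) from the 4-neighbour cell adjacency
#' matrix with like-adjacencies double-counted:
#' `CONTAG = 100 * (1 + sum_ik q_ik ln q_ik / (2 ln m))` where
#' `q_ik = p_i * g_ik / sum_k g_ik` and m is the number of classes present.
#' High values mean large aggregated patches; low values a fine-grained
#' interspersed mosaic.
#'
#' @param map a [lulc_raster].
#' @return contagion in (0, 100].
#' @export
contag <- function(map) {
  v <- map$values
  nodata <- map$nodata
  codes <- class_codes(map)
  present <- codes[codes %in% unique(v[v != nodata])]
  m <- length(present)
  if (m < 2)
    stop("contagion is undefined for a single-class landscape")
  idx <- matrix(match(v, present), nrow(v))     # NA for nodata
  K <- m
  tally <- function(a, b) {
    okp <- !is.na(a) & !is.na(b)
    t1 <- table(factor(a[okp], levels = seq_len(K)),
                factor(b[okp], levels = seq_len(K)))
    matrix(as.numeric(t1), K, K)
  }
  h <- tally(idx[, -ncol(idx)], idx[, -1])
  vv <- tally(idx[-nrow(idx), ], idx[-1, ])
  g <- h + t(h) + vv + t(vv)                    # double-count both directions
  p <- tabulate(idx[!is.na(idx)], K)
  p <- p / sum(p)
  q <- p * g / rowSums(g)
  ql <- q[q > 0]
  100 * (1 + sum(ql * log(ql)) / (2 * log(m)))
}

#' Landscape metrics report
#'
#' @param maps named list of [lulc_raster]s (e.g. one per scenario).
#' @return data.frame with columns `shdi`, `shei`, `contag`, one row per map.
#' @export
landscape_metrics <- function(maps) {
  if (inherits(maps, "lulc_raster")) maps <- list(map = maps)
  data.frame(shdi = sapply(maps, shdi),
             shei = sapply(maps, shei),
             contag = sapply(maps, contag))
}
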