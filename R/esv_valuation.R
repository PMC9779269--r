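#' Load an ecosystem-service coefficient table
#'
#' Reads a delimited coefficient table (rows = services, columns = LULC
#' types, values in yuan per hectare per year, plus `category` and `service`
#' columns). The packaged default is the regional table for a
#' grassland-dominated semi-arid prefecture in which the built-up column is
#' all zero: converting land to built-up is valued as a loss of ecosystem
#' services.
#'
#' @param path delimited file; defaults to the packaged table.
#' @return object of class `coefficient_table`: numeric matrix
#'   (service x type) with a `categories` attribute.
#' @export
load_coefficients <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "esv_coefficients_tongliao.csv",
                        package = "lucsim", mustWork = TRUE)
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("category", "service") %in% names(d)))
    stop("coefficient table needs `category` and `service` columns")
  types <- setdiff(names(d), c("category", "service"))
  if (!length(types)) stop("coefficient table has no LULC type columns")
  m <- as.matrix(d[types])
  if (any(is.na(m)) || any(m < 0))
    stop("coefficients must be nonnegative numbers")
  rownames(m) <- d$service
  attr(m, "categories") <- stats::setNames(d$category, d$service)
  class(m) <- c("coefficient_table", class(m))
  m
}

#' Benefit-transfer valuation of class areas
#'
#' Converts per-class areas (km2) to per-service ecosystem service values:
#' `value_s = sum_j area_j * 100 [ha/km2] * V[s, j] / 1e6`, reported in
#' 10^6 yuan per year.
#'
#' @param areas named areas in km2; names must all have coefficient columns.
#' @param coeff a [load_coefficients()] table.
#' @return object of class `esv_snapshot`: named numeric vector (one entry
#'   per service) in 10^6 yuan/yr, with a `total` attribute.
#' @export
esv_from_areas <- function(areas, coeff = load_coefficients()) {
  if (any(areas < 0)) stop("areas must be nonnegative")
  if (is.null(names(areas))) stop("`areas` must be named by LULC type")
  missing_ <- setdiff(names(areas), colnames(coeff))
  if (length(missing_))
    stop("no coefficient column for type(s): ", paste(missing_, collapse = ", "))
  v <- as.numeric(coeff[, names(areas), drop = FALSE] %*%
                    (areas * KM2_TO_HA)) / 1e6
  out <- stats::setNames(v, rownames(coeff))
  attr(out, "total") <- sum(v)
  class(out) <- "esv_snapshot"
  out
}

KM2_TO_HA <- 100  # hectares per square kilometre; the one unit conversion

#' @export
print.esv_snapshot <- function(x, ...) {
  cat("<esv_snapshot> 10^6 yuan/yr\n")
  print(round(unclass(x), 2))
  cat(sprintf("Total: %.2f\n", attr(x, "total")))
  invisible(x)
}

#' Total of an ESV snapshot
#' @param x an `esv_snapshot`.
#' @return scalar total in 10^6 yuan/yr.
#' @export
esv_total <- function(x) attr(x, "total")

#' Per-cell ESV surface
#'
#' Values every cell at `cell area (ha) x` the sum of its class's service
#' coefficients, in yuan per year. The grid total equals the aggregate
#' [esv_from_areas()] total (conservation between the per-cell and aggregate
#' pathways).
#'
#' @param lulc a [lulc_raster].
#' @param coeff a [load_coefficients()] table.
#' @return numeric matrix (yuan/yr per cell; `NA` at nodata).
#' @export
esv_per_cell <- function(lulc, coeff = load_coefficients()) {
  types <- unname(lulc$legend)
  missing_ <- setdiff(types, colnames(coeff))
  if (length(missing_))
    stop("no coefficient column for type(s): ", paste(missing_, collapse = ", "))
  per_ha <- colSums(coeff[, types, drop = FALSE])
  cell_ha <- lulc$cell_size^2 / 1e4
  idx <- match(lulc$values, class_codes(lulc))
  m <- matrix(per_ha[idx] * cell_ha, nrow(lulc$values), ncol(lulc$values))
  m[!valid_mask(lulc)] <- NA_real_
  m
}

#' Change between two ESV snapshots
#'
#' @param a,b `esv_snapshot`s over the same services.
#' @return named vector of per-service changes (b - a) with a `total`
#'   attribute, class `esv_change`.
#' @export
esv_change <- function(a, b) {
  if (!identical(names(a), names(b)))
    stop("snapshots cover different services")
  out <- stats::setNames(as.numeric(b) - as.numeric(a), names(a))
  attr(out, "total") <- attr(b, "total") - attr(a, "total")
  class(out) <- "esv_change"
  out
}

#' @export
print.esv_change <- function(x, ...) {
  cat("<esv_change> 10^6 yuan/yr\n")
  print(round(unclass(x), 2))
  cat(sprintf("Total change: %.2f\n", attr(x, "total")))
  invisible(x)
}

#' Assemble an ESV table across snapshots
#'
#' Builds the service x snapshot table (with a Total row and optional
#' consecutive-change columns) in which valuation results are reported.
#'
#' @param snapshots named list of `esv_snapshot`s (names = years/scenarios).
#' @param changes add change columns between consecutive snapshots.
#' @return data.frame, services + Total row.
#' @export
esv_table <- function(snapshots, changes = FALSE) {
  stopifnot(length(snapshots) >= 1)
  d <- data.frame(lapply(snapshots, as.numeric), check.names = FALSE,
                  row.names = names(snapshots[[1]]))
  d <- rbind(d, Total = sapply(snapshots, function(s) attr(s, "total")))
  if (changes && length(snapshots) > 1) {
    for (i in 2:length(snapshots)) {
      nm <- paste0("change_", names(snapshots)[i - 1], "_",
                   names(snapshots)[i])
      d[[nm]] <- d[[i]] - d[[i - 1]]
    }
  }
  d
}

#' Packaged regional area table
#'
#' Per-class LULC areas (km2) of the study region at the five observed dates
#' and the simulated horizon year, as packaged delimited text.
#'
#' @return numeric matrix, classes x years (columns `y2000` ... `y2035`).
#' @export
tongliao_areas <- function() {
  path <- system.file("extdata", "lulc_areas_tongliao.csv",
                      package = "lucsim", mustWork = TRUE)
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[-1])
  rownames(m) <- d$class
  m
}
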