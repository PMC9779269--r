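#' Categorical LULC raster
#'
#' Construct the grid container used throughout the package: an integer matrix
#' of land use / land cover (LULC) class codes with a nodata code, a cell size
#' in metres, a class legend, and a lower-left georeference. Row 1 is the
#' northernmost (top) row; indexing is row-major from the upper-left corner.
#'
#' @param values integer matrix of class codes (rows x cols).
#' @param legend named character vector mapping class code (name) to class
#'   name, e.g. `c("1" = "farmland", ...)`.
#' @param nodata integer nodata code; cells equal to it are ignored by every
#'   operation.
#' @param cell_size cell edge length in metres (> 0).
#' @param xll,yll x/y coordinate of the lower-left corner (map units).
#' @return an object of class `lulc_raster`.
#' @export
lulc_raster <- function(values, legend, nodata = -9999L, cell_size = 100,
                        xll = 0, yll = 0) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (any(values[!is.na(values)] != round(values[!is.na(values)])))
    stop("categorical raster values must be integer class codes")
  storage.mode(values) <- "integer"
  values[is.na(values)] <- as.integer(nodata)
  if (nrow(values) < 1L || ncol(values) < 1L) stop("grid must be at least 1x1")
  if (cell_size <= 0) stop("`cell_size` must be positive")
  if (is.null(names(legend))) stop("`legend` must be named by class code")
  codes <- as.integer(names(legend))
  present <- unique(values[values != nodata])
  if (length(setdiff(present, codes)) > 0L)
    stop("raster contains codes absent from the legend: ",
         paste(setdiff(present, codes), collapse = ", "))
  structure(list(values = values, nodata = as.integer(nodata),
                 cell_size = cell_size, legend = legend,
                 xll = xll, yll = yll),
            class = "lulc_raster")
}

#' @export
print.lulc_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<lulc_raster> %d x %d cells, %g m resolution\n",
              nrow(v), ncol(v), x$cell_size))
  valid <- v != x$nodata
  cat(sprintf("  valid cells: %d (%.1f%%)\n", sum(valid),
              100 * mean(valid)))
  tab <- table(factor(v[valid], levels = names(x$legend)))
  cat("  classes:",
      paste(sprintf("%s=%d", x$legend, tab), collapse = ", "), "\n")
  invisible(x)
}

class_codes <- function(r) as.integer(names(r$legend))

valid_mask <- function(r) r$values != r$nodata

#' @export
dim.lulc_raster <- function(x) dim(x$values)

# Georeference agreement to within 1e-6 of a cell; mismatch is an error, never
# an implicit resample.
check_aligned <- function(a, b, what = "rasters") {
  tol <- 1e-6 * a$cell_size
  if (!all(dim(a$values) == dim(b$values)))
    stop(what, " are not aligned: shapes differ")
  if (abs(a$cell_size - b$cell_size) > tol ||
      abs(a$xll - b$xll) > tol || abs(a$yll - b$yll) > tol)
    stop(what, " are not aligned: georeference differs beyond tolerance")
  invisible(TRUE)
}

#' Read an ESRI ASCII grid
#'
#' Reads a raster from the ESRI ASCII grid format (`ncols/nrows/xllcorner/
#' yllcorner/cellsize/NODATA_value` header followed by whitespace-separated
#' values, north row first). Categorical reads reject non-integer pixel
#' values and attach a legend, either supplied or from a `<path>.legend.csv`
#' sidecar (columns `code,name`).
#'
#' @param path file path.
#' @param kind `"categorical"` or `"continuous"`.
#' @param legend optional named character legend for categorical reads;
#'   when `NULL`, a sidecar file is used if present, otherwise the codes in
#'   the file name themselves.
#' @return a [lulc_raster] for categorical reads; a numeric matrix with `NA`
#'   nodata and attributes `cell_size`, `xll`, `yll` for continuous reads.
#' @export
read_asc <- function(path, kind = c("categorical", "continuous"),
                     legend = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("cannot read raster: ", path)
  lines <- readLines(path, n = 6L)
  hdr <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr))) stop("malformed ASCII grid header: ", path)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(path, skip = 6L, quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("ASCII grid body size does not match header: ", path)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else 0
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else 0
  if (kind == "continuous") {
    m[m == nodata] <- NA_real_
    attr(m, "cell_size") <- hdr$cellsize
    attr(m, "xll") <- xll
    attr(m, "yll") <- yll
    return(m)
  }
  body <- m[m != nodata]
  if (any(body != round(body)))
    stop("categorical raster contains non-integer values: ", path)
  if (is.null(legend)) {
    side <- paste0(path, ".legend.csv")
    if (file.exists(side)) {
      legend <- read_legend(side)
    } else {
      codes <- sort(unique(as.integer(body)))
      legend <- stats::setNames(paste0("class_", codes), codes)
    }
  }
  lulc_raster(matrix(as.integer(m), nrow(m), ncol(m)), legend = legend,
              nodata = as.integer(nodata), cell_size = hdr$cellsize,
              xll = xll, yll = yll)
}

#' Write an ESRI ASCII grid
#'
#' @param x a [lulc_raster] or a numeric matrix (optionally with `cell_size`,
#'   `xll`, `yll` attributes).
#' @param path output file path.
#' @param nodata nodata code written for `NA` / nodata cells.
#' @param legend_sidecar for categorical rasters, also write the legend to
#'   `<path>.legend.csv`.
#' @return `path`, invisibly.
#' @export
write_asc <- function(x, path, nodata = -9999, legend_sidecar = TRUE) {
  if (inherits(x, "lulc_raster")) {
    m <- x$values
    m[m == x$nodata] <- as.integer(nodata)
    cs <- x$cell_size; xll <- x$xll; yll <- x$yll
    if (legend_sidecar) write_legend(x$legend, paste0(path, ".legend.csv"))
  } else {
    m <- x
    cs <- attr(x, "cell_size") %||% 100
    xll <- attr(x, "xll") %||% 0
    yll <- attr(x, "yll") %||% 0
    m[is.na(m)] <- nodata
  }
  hdr <- c(paste("ncols", ncol(m)), paste("nrows", nrow(m)),
           paste("xllcorner", format(xll, scientific = FALSE)),
           paste("yllcorner", format(yll, scientific = FALSE)),
           paste("cellsize", format(cs, scientific = FALSE)),
           paste("NODATA_value", format(nodata, scientific = FALSE)))
  body <- apply(m, 1L, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write a class legend sidecar
#'
#' Legends are stored as two-column delimited text (`code,name`).
#'
#' @param path file path.
#' @return named character vector (names are codes).
#' @export
read_legend <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(as.character(d$name), d$code)
}

#' @rdname read_legend
#' @param legend named character vector.
#' @export
write_legend <- function(legend, path) {
  utils::write.csv(data.frame(code = names(legend), name = unname(legend)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cross-tabulate two dated LULC maps
#'
#' Counts, for every ordered pair of classes (a, b), the cells that are class
#' a at the first date and class b at the second. Cells that are nodata in
#' either map are excluded. The result is the transition (transfer) count
#' matrix from which a Markov transition matrix is estimated.
#'
#' @param date1,date2 aligned [lulc_raster]s sharing a legend.
#' @return object of class `transition_counts`: a K x K integer matrix
#'   (`$counts`, dimnames = class codes) plus the class order.
#' @export
crosstab <- function(date1, date2) {
  check_aligned(date1, date2, "crosstab inputs")
  if (!identical(names(date1$legend), names(date2$legend)))
    stop("crosstab inputs must share a legend")
  codes <- names(date1$legend)
  keep <- valid_mask(date1) & valid_mask(date2)
  f1 <- factor(date1$values[keep], levels = codes)
  f2 <- factor(date2$values[keep], levels = codes)
  counts <- table(f1, f2, dnn = NULL)
  counts <- matrix(as.integer(counts), length(codes), length(codes),
                   dimnames = list(codes, codes))
  structure(list(counts = counts, class_order = codes),
            class = "transition_counts")
}

#' @export
print.transition_counts <- function(x, ...) {
  cat("<transition_counts>", sum(x$counts), "jointly valid cells\n")
  print(x$counts)
  invisible(x)
}

#' Per-class area table
#'
#' Converts cell counts to areas in km2 (`count * cell_size^2 / 1e6`). Every
#' legend class appears in the table, empty classes with area 0.
#'
#' @param r a [lulc_raster].
#' @return named numeric vector of areas in km2, one entry per legend class.
#' @export
area_table <- function(r) {
  counts <- table(factor(r$values[valid_mask(r)], levels = names(r$legend)))
  areas <- as.numeric(counts) * r$cell_size^2 / 1e6
  stats::setNames(areas, unname(r$legend))
}

# cell counts per class over the valid mask, in legend order
class_counts <- function(r) {
  as.integer(table(factor(r$values[valid_mask(r)], levels = names(r$legend))))
}
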