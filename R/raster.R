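#' Axis-aligned raster layer in a local projected frame
#'
#' Minimal raster container used throughout the package. All geometry in
#' this package lives in a local projected Cartesian frame with meter
#' units; a layer is a numeric matrix plus the coordinates of its
#' lower-left corner and a square pixel size. Row 1 of the matrix is the
#' southernmost row (smallest y); column 1 is the westernmost column.
#' \code{NA} entries are masked (nodata) pixels.
#'
#' @param values numeric matrix of pixel values; \code{NA} marks masked
#'   pixels.
#' @param origin numeric length-2, (x, y) of the lower-left corner of the
#'   raster extent, meters.
#' @param pixel_size pixel edge length in meters.
#' @param band band semantics, one of \code{"index"}, \code{"reflectance"}
#'   (values in [0,1] where unmasked), \code{"rgb"} ([0,1]),
#'   \code{"elevation"} (meters), \code{"cover"} (0/1).
#' @return An object of class \code{field_raster}.
#' @examples
#' r <- field_raster(matrix(1:12, 3, 4), origin = c(0, 0), pixel_size = 0.5)
#' raster_extent(r)
#' @export
field_raster <- function(values, origin = c(0, 0), pixel_size,
                         band = c("index", "reflectance", "rgb",
                                  "elevation", "cover")) {
  band <- match.arg(band)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix", call. = FALSE)
  }
  stop_if_not_scalar_pos(pixel_size, "pixel_size")
  if (length(origin) != 2L || !is.numeric(origin)) {
    stop("'origin' must be numeric length 2 (x, y)", call. = FALSE)
  }
  ok <- values[!is.na(values)]
  if (band %in% c("reflectance", "rgb") && length(ok) &&
      (min(ok) < -1e-9 || max(ok) > 1 + 1e-9)) {
    stop(sprintf("'%s' band values must lie in [0, 1]", band), call. = FALSE)
  }
  if (band == "cover" && length(ok) && !all(ok %in% c(0, 1))) {
    stop("'cover' band values must be 0/1", call. = FALSE)
  }
  structure(list(values = values, origin = as.numeric(origin),
                 pixel_size = as.numeric(pixel_size), band = band),
            class = "field_raster")
}

#' @export
print.field_raster <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<field_raster> %d x %d pixels @ %g m (%s band)\n",
              nrow(x$values), ncol(x$values), x$pixel_size, x$band))
  cat(sprintf("  extent: x [%g, %g], y [%g, %g] m\n",
              x$origin[1], x$origin[1] + ncol(x$values) * x$pixel_size,
              x$origin[2], x$origin[2] + nrow(x$values) * x$pixel_size))
  if (length(v)) {
    cat(sprintf("  values: [%g, %g], %d masked\n", min(v), max(v),
                sum(is.na(x$values))))
  } else {
    cat("  values: fully masked\n")
  }
  invisible(x)
}

#' Raster extent
#' @param r a \code{field_raster}.
#' @return Named numeric vector \code{(xmin, ymin, xmax, ymax)} in meters.
#' @export
raster_extent <- function(r) {
  stopifnot(inherits(r, "field_raster"))
  c(xmin = r$origin[1], ymin = r$origin[2],
    xmax = r$origin[1] + ncol(r$values) * r$pixel_size,
    ymax = r$origin[2] + nrow(r$values) * r$pixel_size)
}

#' Pixel center coordinates
#'
#' @param r a \code{field_raster}.
#' @return \code{pixel_centers_x}: x coordinate of each column center;
#'   \code{pixel_centers_y}: y coordinate of each row center.
#' @export
pixel_centers_x <- function(r) {
  r$origin[1] + (seq_len(ncol(r$values)) - 0.5) * r$pixel_size
}

#' @rdname pixel_centers_x
#' @export
pixel_centers_y <- function(r) {
  r$origin[2] + (seq_len(nrow(r$values)) - 0.5) * r$pixel_size
}

# two layers share pixel grid and georeferencing
same_grid <- function(a, b, tol = 1e-9) {
  inherits(a, "field_raster") && inherits(b, "field_raster") &&
    all(dim(a$values) == dim(b$values)) &&
    all(abs(a$origin - b$origin) < tol) &&
    abs(a$pixel_size - b$pixel_size) < tol
}

check_coregistered <- function(a, b, what = "layers") {
  if (!same_grid(a, b)) {
    stop(sprintf("co-registration error: %s differ in shape, origin or pixel size",
                 what), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read and write rasters as ESRI ASCII grids
#'
#' Plain-text raster interchange. The on-disk format stores rows from
#' north to south; in memory row 1 is the southernmost row, so rows are
#' flipped on read and write. Masked pixels are written as the nodata
#' value.
#'
#' @param r a \code{field_raster}.
#' @param path file path (conventionally \code{.asc}).
#' @param nodata nodata sentinel written for masked pixels.
#' @param band band semantics to attach on read (the format itself does
#'   not record them).
#' @return \code{read_ascii_grid} returns a \code{field_raster};
#'   \code{write_ascii_grid} returns \code{path} invisibly.
#' @export
write_ascii_grid <- function(r, path, nodata = -9999) {
  stopifnot(inherits(r, "field_raster"))
  v <- r$values
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %s", fmt_num(r$origin[1], 12)),
    sprintf("yllcorner %s", fmt_num(r$origin[2], 12)),
    sprintf("cellsize %s", fmt_num(r$pixel_size, 12)),
    sprintf("NODATA_value %s", fmt_num(nodata, 12))
  ), con)
  for (i in rev(seq_len(nrow(v)))) {
    writeLines(paste(fmt_num(v[i, ], 12), collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path, band = "index") {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("malformed ASCII grid header in ", path, call. = FALSE)
  }
  body <- lines[seq(i, length.out = hdr$nrows)]
  vals <- vapply(body, function(l) as.numeric(strsplit(trimws(l), "[[:space:]]+")[[1]]),
                 numeric(hdr$ncols), USE.NAMES = FALSE)
  # vapply gives ncols x nrows; transpose and flip to south-up order
  m <- t(vals)[rev(seq_len(hdr$nrows)), , drop = FALSE]
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  field_raster(m,
               origin = c(hdr$xllcorner %||% 0, hdr$yllcorner %||% 0),
               pixel_size = hdr$cellsize, band = band)
}

#' Export a raster as TIFF with a world file
#'
#' Writes the pixel matrix as a 32-bit float TIFF (via the \pkg{tiff}
#' package) plus a standard six-line \code{.tfw} world file carrying the
#' georeferencing. Masked pixels are written as \code{NaN}.
#'
#' @inheritParams write_ascii_grid
#' @return \code{path}, invisibly.
#' @export
write_raster_tiff <- function(r, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("package 'tiff' is required for TIFF export", call. = FALSE)
  }
  stopifnot(inherits(r, "field_raster"))
  v <- r$values[rev(seq_len(nrow(r$values))), , drop = FALSE]  # north-up
  v[is.na(v)] <- NaN
  tiff::writeTIFF(v, path, bits.per.sample = 32L, reduce = FALSE)
  tfw <- sub("\\.tiff?$", ".tfw", path)
  if (identical(tfw, path)) tfw <- paste0(path, ".tfw")
  ymax <- r$origin[2] + nrow(r$values) * r$pixel_size
  writeLines(fmt_num(c(r$pixel_size, 0, 0, -r$pixel_size,
                       r$origin[1] + r$pixel_size / 2,
                       ymax - r$pixel_size / 2), 12), tfw)
  invisible(path)
}
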