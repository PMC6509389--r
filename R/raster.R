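#' Gridded landscape rasters
#'
#' Minimal raster container used for land-cover and resistance surfaces: a
#' numeric matrix (row 1 = northern-most row, as displayed) with cell size,
#' lower-left origin, and a nodata value.
#'
#' @param values numeric matrix.
#' @param cellsize cell edge length (map units, e.g. metres).
#' @param xll,yll coordinates of the lower-left corner.
#' @param nodata value coding missing cells.
#' @return an object of class `landscape_raster`.
#' @export
landscape_raster <- function(values, cellsize = 1, xll = 0, yll = 0,
                             nodata = -9999) {
  values <- as.matrix(values)
  structure(
    list(values = values, cellsize = cellsize, xll = xll, yll = yll,
         nodata = nodata),
    class = "landscape_raster"
  )
}

#' @export
print.landscape_raster <- function(x, ...) {
  cat(sprintf("<landscape_raster> %d x %d cells, cellsize %g\n",
              nrow(x$values), ncol(x$values), x$cellsize))
  invisible(x)
}

#' Read an ESRI ASCII grid
#'
#' @param path path to an `.asc` file (6 header lines then the cell matrix,
#'   north row first).
#' @return a [landscape_raster()].
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^[a-zA-Z]", trimws(lines[i]))) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows")
  if (!all(need %in% names(hdr))) stop("missing ncols/nrows header in ", path)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$nrows * hdr$ncols) {
    stop(sprintf("expected %d cells, found %d in %s",
                 hdr$nrows * hdr$ncols, length(vals), path))
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  m[m == nodata] <- NA
  landscape_raster(
    m,
    cellsize = if (!is.null(hdr$cellsize)) hdr$cellsize else 1,
    xll = if (!is.null(hdr$xllcorner)) hdr$xllcorner else 0,
    yll = if (!is.null(hdr$yllcorner)) hdr$yllcorner else 0,
    nodata = nodata
  )
}

#' Write an ESRI ASCII grid
#'
#' @param x a [landscape_raster()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(x, path) {
  m <- x$values
  m[is.na(m)] <- x$nodata
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %g", x$xll),
    sprintf("yllcorner %g", x$yll),
    sprintf("cellsize %g", x$cellsize),
    sprintf("NODATA_value %g", x$nodata)
  ), con)
  for (i in seq_len(nrow(m))) {
    writeLines(paste(format(m[i, ], trim = TRUE, digits = 10),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Build a single-variable resistance surface
#'
#' Three parameterizations are supported, mirroring common resistance-surface
#' practice: `binary_cover` recodes a classed land-cover raster to resistance
#' 2 in the named class and 1 elsewhere; `raw` uses a continuous surface
#' directly, shifted by `offset` minus its minimum if any cell is
#' non-positive (resistances must be strictly positive); `uniform` sets every
#' cell to 1 (the isolation-by-distance layer).
#'
#' @param raster a [landscape_raster()] (classed cover for `binary_cover`,
#'   continuous for `raw`; any raster supplies the shape for `uniform`).
#' @param mode `"binary_cover"`, `"raw"`, or `"uniform"`.
#' @param class_value cover class value for `binary_cover`.
#' @param offset positive shift applied when a raw surface contains
#'   non-positive cells.
#' @return a [landscape_raster()] of strictly positive resistances (NA cells
#'   preserved as nodata).
#' @export
parameterize <- function(raster, mode = c("binary_cover", "raw", "uniform"),
                         class_value = NULL, offset = 1) {
  mode <- match.arg(mode)
  m <- raster$values
  out <- switch(mode,
    uniform = {
      r <- m; r[] <- 1; r[is.na(m)] <- NA; r
    },
    binary_cover = {
      if (is.null(class_value)) stop("binary_cover needs a class_value")
      if (!any(m == class_value, na.rm = TRUE)) {
        stop("class ", class_value, " absent from raster")
      }
      r <- ifelse(m == class_value, 2, 1)
      r[is.na(m)] <- NA
      r
    },
    raw = {
      r <- m
      mn <- min(r, na.rm = TRUE)
      if (mn <= 0) r <- r - mn + offset
      r
    }
  )
  landscape_raster(out, raster$cellsize, raster$xll, raster$yll,
                   raster$nodata)
}
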