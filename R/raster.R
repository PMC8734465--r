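#' Gridded covariate raster
#'
#' A regular grid of covariate values aligned to the plot, as produced by
#' rasterising historical land-use polygons or by the focal-abundance
#' analysis. Values are stored as a matrix with row 1 the northernmost row
#' (the ESRI ASCII on-disk order); missing cells are `NA`.
#'
#' @param values Numeric matrix, `[nrows, ncols]`, row 1 = top (north).
#' @param cell_size Cell side in metres.
#' @param xll,yll Coordinates of the lower-left corner of the grid.
#' @param kind `"categorical"` or `"continuous"`.
#' @param classes For categorical rasters, the declared class codes (integer
#'   values the cells may take).
#' @param nodata Sentinel used on disk for missing cells (default -9999).
#' @return An object of class `"covariate_raster"`.
#' @export
covariate_raster <- function(values, cell_size, xll = 0, yll = 0,
                             kind = c("continuous", "categorical"),
                             classes = NULL, nodata = -9999) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (kind == "categorical" && !is.null(classes)) {
    bad <- !is.na(values) & !(values %in% classes)
    if (any(bad))
      stop("categorical raster holds values outside the declared class list")
  }
  structure(list(values = values, cell_size = cell_size, xll = xll, yll = yll,
                 kind = kind, classes = classes, nodata = nodata,
                 ncols = ncol(values), nrows = nrow(values)),
            class = "covariate_raster")
}

#' @export
print.covariate_raster <- function(x, ...) {
  cat(sprintf("%s raster: %d cols x %d rows @ %g m, origin (%g, %g), %d NA cell(s)\n",
              x$kind, x$ncols, x$nrows, x$cell_size, x$xll, x$yll,
              sum(is.na(x$values))))
  invisible(x)
}

#' Read an ESRI ASCII grid
#'
#' Parses the standard six-line header (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, `NODATA_value`) followed by `nrows` rows of
#' whitespace-separated values, northernmost row first. Cells equal to the
#' nodata marker are returned as `NA`.
#'
#' @param path Path to the `.asc` file.
#' @param kind,classes Passed to [covariate_raster()].
#' @return A [covariate_raster()].
#' @export
read_ascii_raster <- function(path, kind = "continuous", classes = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 7) stop("format error: truncated ASCII grid")
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2) stop("format error: malformed header line: ", lines[i])
    hdr[[tolower(parts[1])]] <- suppressWarnings(as.numeric(parts[2]))
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  if (!all(need %in% names(hdr)) || anyNA(unlist(hdr[need])))
    stop("format error: header must declare ", paste(need, collapse = ", "))
  ncols <- as.integer(hdr$ncols); nrows <- as.integer(hdr$nrows)
  body <- lines[-(1:6)]
  if (length(body) != nrows)
    stop("format error: expected ", nrows, " data rows, found ", length(body))
  vals <- lapply(body, function(l) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
    if (length(v) != ncols || anyNA(v))
      stop("format error: data row with ", length(v),
           " values, header declares ncols = ", ncols)
    v
  })
  m <- do.call(rbind, vals)
  m[m == hdr$nodata_value] <- NA
  covariate_raster(m, cell_size = hdr$cellsize, xll = hdr$xllcorner,
                   yll = hdr$yllcorner, kind = kind, classes = classes,
                   nodata = hdr$nodata_value)
}

#' Write an ESRI ASCII grid
#'
#' Inverse of [read_ascii_raster()]; `NA` cells are written as the raster's
#' nodata marker. Write-then-read is the identity.
#'
#' @param raster A [covariate_raster()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ascii_raster <- function(raster, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", raster$ncols),
    paste("nrows", raster$nrows),
    paste("xllcorner", format(raster$xll, digits = 15)),
    paste("yllcorner", format(raster$yll, digits = 15)),
    paste("cellsize", format(raster$cell_size, digits = 15)),
    paste("NODATA_value", format(raster$nodata, digits = 15))
  ), con)
  m <- raster$values
  m[is.na(m)] <- raster$nodata
  writeLines(apply(m, 1, function(r) paste(format(r, digits = 15, trim = TRUE),
                                           collapse = " ")), con)
  invisible(path)
}

#' Sample a raster at point locations
#'
#' Returns the value of the cell containing each point (nearest-cell lookup,
#' no interpolation), under the same half-open cell convention as
#' [assign_quadrats()]: points on shared cell edges belong to the
#' higher-index cell, and the grid's outer maximal edges are closed.
#'
#' @param raster A [covariate_raster()].
#' @param x,y Point coordinates (metres); must fall inside the raster extent.
#' @return Numeric vector of cell values; points landing in nodata cells give
#'   `NA` with a warning.
#' @export
sample_raster_at_points <- function(raster, x, y) {
  w <- raster$ncols * raster$cell_size
  h <- raster$nrows * raster$cell_size
  out <- x < raster$xll | x > raster$xll + w | y < raster$yll | y > raster$yll + h
  if (any(out))
    stop("point(s) outside raster extent: index ",
         paste(which(out), collapse = ", "))
  col <- .cell_index(x, raster$xll, raster$cell_size, raster$ncols) + 1L
  row_bottom <- .cell_index(y, raster$yll, raster$cell_size, raster$nrows)
  row <- raster$nrows - row_bottom            # matrix row 1 = north
  v <- raster$values[cbind(row, col)]
  if (anyNA(v)) warning(sum(is.na(v)), " point(s) fall in nodata cells")
  v
}
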