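#' Georeferenced raster grid
#'
#' Light container for the elevation and height surfaces the pipeline
#' manipulates: digital surface models (DSM), digital terrain models (DTM) and
#' canopy height models (CHM). Values are stored as a numeric matrix whose
#' rows run north-to-south, i.e. row 1 is the top (maximum y) edge of the
#' grid, matching the usual raster convention.
#'
#' @param values Numeric matrix of cell values in metres. `NA` is accepted and
#'   converted to `nodata` on write.
#' @param origin Length-2 numeric, the (x, y) coordinate of the *top-left
#'   corner* of the grid in metres.
#' @param cell Cell size in metres (square cells). Must be positive.
#' @param nodata Sentinel used on disk for missing cells. In memory missing
#'   cells are `NA`.
#' @return A `raster_grid` object.
#' @export
raster_grid <- function(values, origin = c(0, 0), cell = 0.05, nodata = -9999) {
  if (!is.matrix(values)) values <- as.matrix(values)
  stopifnot(is.numeric(cell), length(cell) == 1L, is.finite(cell))
  if (cell <= 0) stop("cell size must be positive", call. = FALSE)
  stopifnot(length(origin) == 2L, all(is.finite(origin)))
  storage.mode(values) <- "double"
  values[!is.na(values) & values == nodata] <- NA_real_
  structure(
    list(values = values, origin = as.numeric(origin), cell = cell,
         nodata = nodata),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf(
    "<raster_grid> %d x %d cells @ %.3g m (extent %.2f x %.2f m)\n",
    nrow(v), ncol(v), x$cell, ncol(v) * x$cell, nrow(v) * x$cell))
  fin <- v[is.finite(v)]
  if (length(fin)) {
    cat(sprintf("  values: [%.3f, %.3f] m, %d nodata cells\n",
                min(fin), max(fin), sum(is.na(v))))
  } else {
    cat("  all cells nodata\n")
  }
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

#' Coordinates of cell centres
#'
#' @param x A [raster_grid()].
#' @return A tibble with one row per cell: `row`, `col`, `x`, `y`, `value`.
#' @export
raster_cells <- function(x) {
  stopifnot(inherits(x, "raster_grid"))
  nr <- nrow(x$values); nc <- ncol(x$values)
  rows <- rep(seq_len(nr), times = nc)
  cols <- rep(seq_len(nc), each = nr)
  cx <- x$origin[1] + (cols - 0.5) * x$cell
  cy <- x$origin[2] - (rows - 0.5) * x$cell
  vals <- as.vector(x$values)
  tibble::tibble(row = rows, col = cols, x = cx, y = cy, value = vals)
}

# TRUE when two grids share origin, cell size and shape (to tolerance).
same_grid <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$cell - b$cell) < tol &&
    all(abs(a$origin - b$origin) < tol)
}

#' Canopy height model from DSM and DTM
#'
#' Elementwise `CHM = DSM - DTM`, the canopy height model. Negative heights
#' (surface below terrain, a physically meaningless artefact of noise) are
#' clamped to zero. A cell that is nodata in either operand is nodata in the
#' result.
#'
#' @param dsm,dtm [raster_grid()] objects on the same grid (origin, cell,
#'   shape).
#' @return A `raster_grid` of canopy heights in metres, all values `>= 0`.
#' @export
compute_chm <- function(dsm, dtm) {
  stopifnot(inherits(dsm, "raster_grid"), inherits(dtm, "raster_grid"))
  if (!same_grid(dsm, dtm)) {
    stop("DSM and DTM grids do not match (origin, cell size or shape)",
         call. = FALSE)
  }
  v <- dsm$values - dtm$values
  v[!is.na(v) & v < 0] <- 0
  raster_grid(v, origin = dsm$origin, cell = dsm$cell, nodata = dsm$nodata)
}

#' Read and write rasters as ESRI ASCII grid
#'
#' Plain-text raster interchange: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `nodata_value`) followed by rows of
#' values from the north edge southwards.
#'
#' @param x A [raster_grid()].
#' @param path File path (`.asc`).
#' @return `write_asc` returns `path` invisibly; `read_asc` returns a
#'   `raster_grid`.
#' @export
write_asc <- function(x, path) {
  stopifnot(inherits(x, "raster_grid"))
  v <- x$values
  nr <- nrow(v); nc <- ncol(v)
  yll <- x$origin[2] - nr * x$cell
  hdr <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.10g", x$origin[1]),
    sprintf("yllcorner %.10g", yll),
    sprintf("cellsize %.10g", x$cell),
    sprintf("nodata_value %.10g", x$nodata)
  )
  v[is.na(v)] <- x$nodata
  body <- apply(v, 1L, function(r) paste(format(r, digits = 10, trim = TRUE),
                                         collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_asc
#' @export
read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(key) {
    ln <- hdr[grepl(paste0("^", key, "\\b"), hdr, ignore.case = TRUE)]
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2])
  }
  nc <- val("ncols"); nr <- val("nrows")
  xll <- val("xllcorner"); yll <- val("yllcorner")
  cell <- val("cellsize"); nodata <- val("nodata_value")
  body <- lines[-(1:6)]
  v <- do.call(rbind, lapply(body, function(ln) {
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
  }))
  stopifnot(nrow(v) == nr, ncol(v) == nc)
  v[v == nodata] <- NA_real_
  raster_grid(v, origin = c(xll, yll + nr * cell), cell = cell,
              nodata = nodata)
}
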