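#' Build per-plot demarcation masks
#'
#' One rectangular mask per plot, inset from the plot footprint by `shrink`
#' of each dimension on every side. Demarcation is repeated per time point in
#' real campaigns because the canopy area changes as plants grow; the
#' `time_point` is recorded with each mask and the inset may differ between
#' demarcations.
#'
#' @param design A [field_design()].
#' @param shrink Fraction (< 0.5) of each plot dimension removed from each
#'   side; 0 keeps the full footprint.
#' @param time_point Index of the acquisition this demarcation belongs to.
#' @return A tibble with `plot_id`, `time_point`, the mask bounding box, and
#'   a `polygon` list-column of 4 x 2 vertex matrices (counter-clockwise).
#' @export
build_plot_masks <- function(design, shrink = 0, time_point = 1L) {
  if (shrink >= 0.5) stop("shrink must be < 0.5", call. = FALSE)
  if (shrink < 0) stop("shrink must be >= 0", call. = FALSE)
  fp <- plot_footprints(design)
  dx <- (fp$x_max - fp$x_min) * shrink
  dy <- (fp$y_max - fp$y_min) * shrink
  out <- tibble::tibble(
    plot_id = fp$plot_id,
    time_point = as.integer(time_point),
    x_min = fp$x_min + dx, x_max = fp$x_max - dx,
    y_min = fp$y_min + dy, y_max = fp$y_max - dy
  )
  out$polygon <- purrr::pmap(out[, c("x_min", "x_max", "y_min", "y_max")],
    function(x_min, x_max, y_min, y_max) {
      cbind(x = c(x_min, x_max, x_max, x_min),
            y = c(y_min, y_min, y_max, y_max))
    })
  out
}

# polygon matrix from a mask (one-row tibble slice or bare matrix)
mask_polygon <- function(mask) {
  if (is.matrix(mask)) return(mask)
  if (is.data.frame(mask)) {
    if (nrow(mask) != 1) stop("expected a single mask row", call. = FALSE)
    return(mask$polygon[[1]])
  }
  if (is.list(mask) && !is.null(mask$polygon)) return(mask$polygon)
  stop("cannot interpret mask", call. = FALSE)
}

#' Raster values inside a plot mask
#'
#' All non-nodata cell values whose cell centre falls inside the mask
#' polygon (point-in-polygon on cell centres; boundary cells are resolved by
#' the polygon test, and the grids used here never place centres exactly on
#' mask edges).
#'
#' @param raster A [raster_grid()].
#' @param mask One row of [build_plot_masks()] output, or a vertex matrix.
#' @return Numeric vector of in-mask cell values.
#' @export
zonal_values <- function(raster, mask) {
  stopifnot(inherits(raster, "raster_grid"))
  poly <- mask_polygon(mask)
  cells <- raster_cells(raster)
  # cheap bbox prefilter before the polygon test
  inbb <- cells$x >= min(poly[, 1]) & cells$x <= max(poly[, 1]) &
    cells$y >= min(poly[, 2]) & cells$y <= max(poly[, 2])
  cand <- cells[inbb, ]
  if (nrow(cand) == 0) stop("mask does not intersect the raster", call. = FALSE)
  inside <- mgcv::in.out(rbind(poly, poly[1, , drop = FALSE]),
                         cbind(cand$x, cand$y))
  vals <- cand$value[inside]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) {
    stop("mask does not intersect the raster", call. = FALSE)
  }
  vals
}

#' Percentile plant height from an RGB surface model
#'
#' Plant height as the difference between high and low percentiles of the
#' in-mask surface elevations: the minimum over the low interval (default
#' 1-2 %) stands in for the ground elevation, the maximum over the high
#' interval (default 95-98 %) for the top of the stems. Because only
#' within-mask percentile differences are used, the result does not depend on
#' the absolute elevation datum, which is the point of the method when no
#' bare-ground flight exists. Percentiles use linear interpolation between
#' order statistics (type 7); by monotonicity the result equals
#' `p_high[max] - p_low[min]`.
#'
#' @param dsm A surface [raster_grid()].
#' @param mask One row of [build_plot_masks()] output.
#' @param p_low,p_high Percent intervals evaluated on an integer grid.
#' @param min_cells Minimum number of in-mask cells required.
#' @return Plant height in metres (never negative).
#' @export
extract_rgb_ph <- function(dsm, mask, p_low = c(1, 2), p_high = c(95, 98),
                           min_cells = 20L) {
  vals <- zonal_values(dsm, mask)
  if (length(vals) < min_cells) {
    stop(sprintf("only %d in-mask cells (need >= %d)", length(vals),
                 min_cells), call. = FALSE)
  }
  qlo <- stats::quantile(vals, seq(p_low[1], p_low[2]) / 100,
                         type = 7, names = FALSE)
  qhi <- stats::quantile(vals, seq(p_high[1], p_high[2]) / 100,
                         type = 7, names = FALSE)
  max(0, max(qhi) - min(qlo))
}

#' Zonal plant height from a canopy height model
#'
#' Aggregates in-mask CHM values; the default 95th percentile is robust to
#' residual high outliers while still tracking the canopy top.
#'
#' @param chm A canopy-height [raster_grid()] (see [compute_chm()]).
#' @param mask One row of [build_plot_masks()] output.
#' @param aggregator One of `"p95"`, `"p99"`, `"max"`, `"mean_top_decile"`.
#' @param min_cells Minimum number of in-mask cells required.
#' @return Plant height in metres.
#' @export
extract_lidar_ph <- function(chm, mask,
                             aggregator = c("p95", "p99", "max",
                                            "mean_top_decile"),
                             min_cells = 20L) {
  aggregator <- match.arg(aggregator)
  vals <- zonal_values(chm, mask)
  if (length(vals) < min_cells) {
    stop(sprintf("only %d in-mask cells (need >= %d)", length(vals),
                 min_cells), call. = FALSE)
  }
  switch(aggregator,
    p95 = stats::quantile(vals, 0.95, type = 7, names = FALSE),
    p99 = stats::quantile(vals, 0.99, type = 7, names = FALSE),
    max = max(vals),
    mean_top_decile = mean(sort(vals, decreasing = TRUE)[
      seq_len(max(1L, floor(length(vals) / 10)))])
  )
}

#' Assemble per-plot heights into a height series
#'
#' Collects per-plot, per-time extraction results into the long series table
#' used by calibration and clustering. A failed extraction is recorded as
#' `NA`, never zero.
#'
#' @param values Tibble with `plot_id`, `time_point` and `extracted_m`
#'   (optionally `measured_m`, `predicted_m`).
#' @param sensor `"rgb"` or `"lidar"`.
#' @return A `plot_height_series` tibble (long format).
#' @export
assemble_series <- function(values, sensor = c("lidar", "rgb")) {
  sensor <- match.arg(sensor)
  stopifnot(all(c("plot_id", "time_point", "extracted_m") %in% names(values)))
  if (anyDuplicated(values[, c("plot_id", "time_point")])) {
    stop("duplicate (plot, time) entries", call. = FALSE)
  }
  out <- tibble::as_tibble(values)
  out$sensor <- sensor
  class(out) <- c("plot_height_series", class(out))
  out
}

#' Wide accession-by-time matrix from a height series
#'
#' @param series A `plot_height_series` (long) tibble.
#' @param column Which value column to spread.
#' @return A numeric matrix, rows = plots, columns = time points.
#' @export
series_matrix <- function(series, column = "extracted_m") {
  w <- tidyr::pivot_wider(series[, c("plot_id", "time_point", column)],
                          names_from = "time_point",
                          values_from = dplyr::all_of(column),
                          names_prefix = "t", names_sort = TRUE)
  m <- as.matrix(w[, -1])
  rownames(m) <- w$plot_id
  m
}

#' Height-series CSV I/O
#'
#' Long-format CSV with columns `plot_id`, `time_point`, `sensor` and the
#' value columns present.
#'
#' @param series A `plot_height_series` tibble.
#' @param path CSV path.
#' @return `write_series_csv` returns `path` invisibly; `read_series_csv`
#'   returns the series tibble.
#' @export
write_series_csv <- function(series, path) {
  readr::write_csv(series, path)
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  class(out) <- c("plot_height_series", class(out))
  out
}

#' Plot-mask GeoJSON I/O
#'
#' Masks are exchanged as a GeoJSON FeatureCollection of polygons with
#' `plot_id` and `time_point` properties.
#'
#' @param masks Output of [build_plot_masks()].
#' @param path GeoJSON path.
#' @return `write_geojson` returns `path` invisibly; `read_geojson` returns
#'   a mask tibble equivalent to [build_plot_masks()] output.
#' @export
write_geojson <- function(masks, path) {
  feats <- purrr::pmap(list(masks$plot_id, masks$time_point, masks$polygon),
    function(id, tp, poly) {
      ring <- rbind(poly, poly[1, , drop = FALSE])
      list(
        type = "Feature",
        properties = list(plot_id = id, time_point = tp),
        geometry = list(
          type = "Polygon",
          coordinates = list(lapply(seq_len(nrow(ring)), function(i) {
            c(ring[i, 1], ring[i, 2])
          }))
        )
      )
    })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_geojson
#' @export
read_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  rows <- purrr::map(fc$features, function(f) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(p) unlist(p)))
    poly <- ring[-nrow(ring), , drop = FALSE]
    colnames(poly) <- c("x", "y")
    tibble::tibble(
      plot_id = f$properties$plot_id,
      time_point = as.integer(f$properties$time_point),
      x_min = min(poly[, 1]), x_max = max(poly[, 1]),
      y_min = min(poly[, 2]), y_max = max(poly[, 2]),
      polygon = list(poly)
    )
  })
  dplyr::bind_rows(rows)
}
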