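#' Voxel-grid resampling of a point cloud
#'
#' Thins a point cloud to at most one return per 3-D voxel, keeping the
#' return closest to the voxel centroid. The output is a subset of the input
#' rows, so all auxiliary columns survive.
#'
#' @param cloud Point-cloud tibble with numeric `x`, `y`, `z`.
#' @param cell Voxel edge length, metres.
#' @return The thinned point-cloud tibble.
#' @export
voxel_resample <- function(cloud, cell = 0.03) {
  if (cell <= 0) stop("voxel size must be positive", call. = FALSE)
  if (nrow(cloud) == 0) stop("empty point cloud", call. = FALSE)
  x0 <- min(cloud$x); y0 <- min(cloud$y); z0 <- min(cloud$z)
  kx <- floor((cloud$x - x0) / cell)
  ky <- floor((cloud$y - y0) / cell)
  kz <- floor((cloud$z - z0) / cell)
  d2 <- (cloud$x - (x0 + (kx + 0.5) * cell))^2 +
    (cloud$y - (y0 + (ky + 0.5) * cell))^2 +
    (cloud$z - (z0 + (kz + 0.5) * cell))^2
  key <- paste(kx, ky, kz)
  keep <- vapply(split(seq_len(nrow(cloud)), key),
                 function(ix) ix[which.min(d2[ix])], integer(1))
  cloud[sort(unname(keep)), ]
}

#' Statistical outlier removal
#'
#' Classic statistical-outlier-removal denoising: a point whose mean distance
#' to its `k_neighbors` nearest neighbours exceeds the global mean of that
#' statistic by more than `n_sigma` standard deviations is treated as noise
#' and dropped.
#'
#' @param cloud Point-cloud tibble with `x`, `y`, `z`.
#' @param k_neighbors Neighbourhood size; must be smaller than the number of
#'   points.
#' @param n_sigma Rejection threshold in standard deviations.
#' @return The denoised point-cloud tibble.
#' @export
denoise_points <- function(cloud, k_neighbors = 8L, n_sigma = 3) {
  n <- nrow(cloud)
  if (k_neighbors >= n) {
    stop("k_neighbors must be smaller than the number of points",
         call. = FALSE)
  }
  d <- FNN::knn.dist(as.matrix(cloud[, c("x", "y", "z")]), k = k_neighbors)
  md <- rowMeans(d)
  thr <- mean(md) + n_sigma * stats::sd(md)
  cloud[md <= thr, ]
}

# Per-cell index of points on a grid defined by extent/cell.
# Returns list(row, col, nr, nc, x0, y_top).
grid_index <- function(cloud, cell, extent = NULL) {
  if (is.null(extent)) {
    extent <- c(min(cloud$x), max(cloud$x), min(cloud$y), max(cloud$y))
  }
  nc <- max(1L, ceiling((extent[2] - extent[1]) / cell - 1e-9))
  nr <- max(1L, ceiling((extent[4] - extent[3]) / cell - 1e-9))
  col <- pmin(pmax(floor((cloud$x - extent[1]) / cell) + 1L, 1L), nc)
  row <- pmin(pmax(nr - floor((cloud$y - extent[3]) / cell), 1L), nr)
  list(row = row, col = col, nr = nr, nc = nc,
       x0 = extent[1], y_top = extent[3] + nr * cell)
}

#' Ground / non-ground classification
#'
#' Minimum-elevation seeding with a local planar consistency test, in the
#' spirit of progressive morphological filters. The cloud is binned on a
#' coarse grid; per-cell minima seed the ground surface; cells whose minimum
#' sits more than `veg_thresh` above the lowest minimum in the surrounding
#' window are treated as vegetated and excluded; a plane is fitted to the
#' remaining minima in each window and a point is labelled `ground` when its
#' elevation is within `slope_tol` of the plane at its cell. Run on a
#' denoised cloud (see [denoise_points()]): gross low outliers corrupt the
#' per-cell minima.
#'
#' @param cloud Denoised point-cloud tibble.
#' @param cell Analysis grid cell, metres. Coarser than the raster cell;
#'   each cell should hold tens of returns.
#' @param slope_tol Tolerance above the local ground plane, metres.
#' @param veg_thresh Minimum canopy height detectable above the local ground
#'   minimum, metres.
#' @param window Window radius in cells for the local ground neighbourhood;
#'   the window must out-span half a canopy patch.
#' @return The cloud with `class` set to `"ground"` / `"non_ground"`.
#' @export
classify_ground <- function(cloud, cell = 0.5, slope_tol = 0.08,
                            veg_thresh = 0.2, window = 3L) {
  if (nrow(cloud) == 0) stop("empty point cloud", call. = FALSE)
  g <- grid_index(cloud, cell)
  cellid <- (g$col - 1L) * g$nr + g$row
  zmin <- rep(NA_real_, g$nr * g$nc)
  agg <- tapply(cloud$z, cellid, min)
  zmin[as.integer(names(agg))] <- agg
  zmin_m <- matrix(zmin, g$nr, g$nc)

  w <- as.integer(window)
  # windowed minimum of cell minima
  win_min <- matrix(NA_real_, g$nr, g$nc)
  for (i in seq_len(g$nr)) {
    ri <- max(1, i - w):min(g$nr, i + w)
    for (j in seq_len(g$nc)) {
      cj <- max(1, j - w):min(g$nc, j + w)
      blk <- zmin_m[ri, cj]
      if (any(!is.na(blk))) win_min[i, j] <- min(blk, na.rm = TRUE)
    }
  }
  veg <- !is.na(zmin_m) & (zmin_m > win_min + veg_thresh)
  seed <- zmin_m
  seed[veg] <- NA_real_

  # local plane fit to non-vegetated minima; fall back to windowed minimum
  ground_at <- matrix(NA_real_, g$nr, g$nc)
  xs <- g$x0 + (seq_len(g$nc) - 0.5) * cell
  ys <- g$y_top - (seq_len(g$nr) - 0.5) * cell
  for (i in seq_len(g$nr)) {
    ri <- max(1, i - w):min(g$nr, i + w)
    for (j in seq_len(g$nc)) {
      cj <- max(1, j - w):min(g$nc, j + w)
      blk <- seed[ri, cj]
      ok <- which(!is.na(blk))
      if (length(ok) >= 4) {
        bx <- rep(xs[cj], each = length(ri))[ok]
        by <- rep(ys[ri], times = length(cj))[ok]
        bz <- blk[ok]
        X <- cbind(1, bx - xs[j], by - ys[i])
        fit <- tryCatch(solve(crossprod(X), crossprod(X, bz)),
                        error = function(e) NULL)
        ground_at[i, j] <- if (is.null(fit)) win_min[i, j] else fit[1]
      } else {
        ground_at[i, j] <- win_min[i, j]
      }
    }
  }
  if (all(is.na(ground_at))) {
    stop("no ground surface could be seeded", call. = FALSE)
  }
  ref <- ground_at[cbind(g$row, g$col)]
  cloud$class <- ifelse(cloud$z <= ref + slope_tol, "ground", "non_ground")
  cloud
}

#' Rasterize a point cloud to a digital surface model
#'
#' Per-cell maximum elevation of all points; cells without points are nodata.
#'
#' @param cloud Point-cloud tibble (noise already removed).
#' @param cell Raster cell size, metres.
#' @param extent Optional `c(xmin, xmax, ymin, ymax)`; defaults to the cloud
#'   bounding box.
#' @return A [raster_grid()] DSM.
#' @export
rasterize_dsm <- function(cloud, cell = 0.05, extent = NULL) {
  if (nrow(cloud) == 0) stop("empty point cloud", call. = FALSE)
  if (cell <= 0) stop("cell size must be positive", call. = FALSE)
  g <- grid_index(cloud, cell, extent)
  cellid <- (g$col - 1L) * g$nr + g$row
  v <- rep(NA_real_, g$nr * g$nc)
  agg <- tapply(cloud$z, cellid, max)
  v[as.integer(names(agg))] <- agg
  raster_grid(matrix(v, g$nr, g$nc), origin = c(g$x0, g$y_top), cell = cell)
}

#' Interpolate a digital terrain model from ground points
#'
#' Linear (Delaunay/TIN) interpolation of ground-classified points onto the
#' raster grid; cells outside the convex hull of the ground points take the
#' elevation of the nearest ground point.
#'
#' @param cloud Point-cloud tibble with `class` set (see [classify_ground()]).
#' @param cell Raster cell size, metres.
#' @param extent Optional `c(xmin, xmax, ymin, ymax)`; defaults to the cloud
#'   bounding box (of the whole cloud, so DSM and DTM grids align).
#' @param max_ground_points Triangulating every ground return of a dense
#'   cloud buys no accuracy on smooth terrain and is memory-hungry; above
#'   this count the ground points are thinned to the per-cell minimum on a
#'   2-D grid just fine enough to stay under it (deterministic).
#' @return A [raster_grid()] DTM.
#' @export
interpolate_dtm <- function(cloud, cell = 0.05, extent = NULL,
                            max_ground_points = 20000L) {
  if (cell <= 0) stop("cell size must be positive", call. = FALSE)
  gpt <- cloud[cloud$class == "ground", ]
  if (nrow(gpt) < 3) stop("need at least 3 ground points", call. = FALSE)
  if (nrow(gpt) > max_ground_points) {
    span <- max(max(gpt$x) - min(gpt$x), max(gpt$y) - min(gpt$y))
    tc <- span / floor(sqrt(max_ground_points))
    kx <- floor((gpt$x - min(gpt$x)) / tc)
    ky <- floor((gpt$y - min(gpt$y)) / tc)
    key <- paste(kx, ky)
    keep <- vapply(split(seq_len(nrow(gpt)), key),
                   function(ix) ix[which.min(gpt$z[ix])], integer(1))
    gpt <- gpt[sort(unname(keep)), ]
  }
  xy <- cbind(gpt$x, gpt$y)
  if (qr(sweep(xy, 2, colMeans(xy)))$rank < 2) {
    stop("ground points are collinear", call. = FALSE)
  }
  g <- grid_index(cloud, cell, extent)
  xs <- g$x0 + (seq_len(g$nc) - 0.5) * cell
  ys_asc <- g$y_top - (rev(seq_len(g$nr)) - 0.5) * cell  # ascending y
  res <- interp::interp(x = gpt$x, y = gpt$y, z = gpt$z,
                        xo = xs, yo = ys_asc,
                        method = "linear", duplicate = "mean")
  # res$z is [x, y] with y ascending; convert to rows = y descending
  v <- t(res$z)[rev(seq_len(g$nr)), , drop = FALSE]
  if (anyNA(v)) {
    na_idx <- which(is.na(v), arr.ind = TRUE)
    qx <- xs[na_idx[, 2]]
    qy <- (g$y_top - (na_idx[, 1] - 0.5) * cell)
    nn <- FNN::get.knnx(xy, cbind(qx, qy), k = 1)$nn.index[, 1]
    v[na_idx] <- gpt$z[nn]
  }
  raster_grid(v, origin = c(g$x0, g$y_top), cell = cell)
}

#' Point-cloud text I/O
#'
#' Reads and writes point clouds as whitespace/tab-separated XYZ+class text
#' (gzip transparently supported via a `.gz` suffix).
#'
#' @param cloud Point-cloud tibble.
#' @param path Output path.
#' @return `write_xyz` returns `path` invisibly; `read_xyz` returns the
#'   point-cloud tibble.
#' @export
write_xyz <- function(cloud, path) {
  readr::write_tsv(cloud, path)
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
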