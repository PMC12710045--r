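test_that("voxel resampling keeps one point per voxel, closest to the centroid", {
  cl <- tibble::tibble(x = c(0.01, 0.02, 0.015), y = c(0.01, 0.02, 0.016),
                       z = c(0.01, 0.005, 0.02), class = "unclassified")
  expect_equal(nrow(voxel_resample(cl, cell = 1)), 1)

  set.seed(2)
  cl2 <- tibble::tibble(x = runif(40, 0, 5), y = runif(40, 0, 5),
                        z = runif(40, 0, 1), class = "unclassified")
  expect_equal(voxel_resample(cl2, cell = 1e-6), cl2)

  # dictionary-of-voxels oracle
  out <- voxel_resample(cl2, cell = 0.5)
  key <- paste(floor((cl2$x - min(cl2$x)) / 0.5),
               floor((cl2$y - min(cl2$y)) / 0.5),
               floor((cl2$z - min(cl2$z)) / 0.5))
  cent <- function(v, v0) v0 + (floor((v - v0) / 0.5) + 0.5) * 0.5
  d2 <- (cl2$x - cent(cl2$x, min(cl2$x)))^2 +
    (cl2$y - cent(cl2$y, min(cl2$y)))^2 +
    (cl2$z - cent(cl2$z, min(cl2$z)))^2
  expected <- sort(vapply(split(seq_len(40), key),
                          function(ix) ix[which.min(d2[ix])], integer(1)))
  expect_equal(out, cl2[unname(expected), ])
  expect_error(voxel_resample(cl2[0, ], 0.5), "empty")
})

test_that("statistical outlier removal drops isolated points and nothing else", {
  g <- expand.grid(x = seq(0, 2, 0.2), y = seq(0, 2, 0.2))
  cl <- tibble::tibble(x = g$x, y = g$y, z = 0, class = "unclassified")
  spike <- tibble::tibble(x = 1.05, y = 1.05, z = 5, class = "unclassified")
  both <- dplyr::bind_rows(cl, spike)
  out <- denoise_points(both, k_neighbors = 8, n_sigma = 3)
  expect_false(any(out$z == 5))             # the spike is gone
  expect_gte(nrow(out), 0.95 * nrow(cl))    # the lattice survives

  # fully symmetric configuration: every mean k-NN distance is identical,
  # so nothing can be flagged at any finite threshold
  theta <- seq(0, 2 * pi, length.out = 41)[-41]
  ring <- tibble::tibble(x = cos(theta), y = sin(theta), z = 0,
                         class = "unclassified")
  expect_equal(nrow(denoise_points(ring, 8, 3)), nrow(ring))
  # infinite threshold keeps everything including the spike
  expect_equal(nrow(denoise_points(both, 8, Inf)), nrow(both))
  expect_error(denoise_points(cl[1:5, ], k_neighbors = 5), "k_neighbors")
})

test_that("ground classification separates soil from a canopy plateau", {
  sc <- tiny_scene(noise_sd = 0.01, canopy_cover = 0.3, seed = 31)
  cloud <- generate_point_cloud(sc$terrain, sc$design, sc$truth, 5,
                                sc$sensor)
  out <- classify_ground(cloud)
  tab <- table(truth = out$truth, class = out$class)
  recall <- tab["ground", "ground"] / sum(tab["ground", ])
  precision <- tab["ground", "ground"] / sum(tab[, "ground"])
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)

  # plateau at +1 m over 30 % of cells: no canopy point labelled ground
  g <- expand.grid(x = seq(0, 10, 0.1), y = seq(0, 10, 0.1))
  plateau <- g$x > 3.5 & g$x < 6.5 & g$y > 3.5 & g$y < 6.5
  cl <- tibble::tibble(x = g$x, y = g$y, z = ifelse(plateau, 1, 0),
                       class = "unclassified")
  out2 <- classify_ground(cl)
  expect_true(all(out2$class[out2$z == 1] == "non_ground"))
  expect_true(all(out2$class[out2$z == 0] == "ground"))

  # ground-only cloud: everything labelled ground
  out3 <- classify_ground(cl[!plateau, ])
  expect_true(all(out3$class == "ground"))
})

test_that("DSM rasterisation takes the per-cell maximum and marks empty cells", {
  cl <- tibble::tibble(x = c(0.5, 1.5, 0.5), y = c(0.5, 0.5, 0.51),
                       z = c(1, 2, 5), class = "ground")
  dsm <- rasterize_dsm(cl, cell = 1, extent = c(0, 2, 0, 1))
  expect_equal(dsm$values[1, 1], 5)
  expect_equal(dsm$values[1, 2], 2)

  set.seed(6)
  cl2 <- tibble::tibble(x = runif(300, 0, 4), y = runif(300, 0, 3),
                        z = rnorm(300), class = "ground")
  dsm2 <- rasterize_dsm(cl2, cell = 0.5, extent = c(0, 4, 0, 3))
  # per-cell scan oracle
  for (i in seq_len(nrow(dsm2$values))) {
    for (j in seq_len(ncol(dsm2$values))) {
      sel <- cl2$x >= (j - 1) * 0.5 & cl2$x < j * 0.5 &
        cl2$y >= 3 - i * 0.5 & cl2$y < 3 - (i - 1) * 0.5
      expected <- if (any(sel)) max(cl2$z[sel]) else NA_real_
      expect_equal(dsm2$values[i, j], expected)
    }
  }
  # permutation invariance
  perm <- sample(nrow(cl2))
  dsm3 <- rasterize_dsm(cl2[perm, ], cell = 0.5, extent = c(0, 4, 0, 3))
  expect_identical(dsm2$values, dsm3$values)
  expect_error(rasterize_dsm(cl2[0, ]), "empty")
})

test_that("DTM interpolation reproduces a plane and refuses degenerate input", {
  set.seed(3)
  x <- runif(150, 0, 8); y <- runif(150, 0, 8)
  cl <- tibble::tibble(x = x, y = y, z = 1 + 0.2 * x - 0.1 * y,
                       class = "ground")
  dtm <- interpolate_dtm(cl, cell = 0.4, extent = c(0, 8, 0, 8))
  cells <- raster_cells(dtm)
  inhull <- cells$x > 1 & cells$x < 7 & cells$y > 1 & cells$y < 7
  expect_lt(max(abs(cells$value - (1 + 0.2 * cells$x - 0.1 * cells$y))
                [inhull]), 1e-9)
  expect_false(anyNA(dtm$values))  # outside hull filled by nearest neighbour

  const <- tibble::tibble(x = x, y = y, z = 7, class = "ground")
  dtm2 <- interpolate_dtm(const, cell = 0.4, extent = c(0, 8, 0, 8))
  expect_equal(max(abs(dtm2$values - 7)), 0, tolerance = 1e-12)

  none <- tibble::tibble(x = x, y = y, z = 1, class = "non_ground")
  expect_error(interpolate_dtm(none, 0.4), "ground points")
  coll <- tibble::tibble(x = 1:5, y = 2 * (1:5), z = 1, class = "ground")
  expect_error(interpolate_dtm(coll, 0.4), "collinear")
})

test_that("noiseless cloud pipeline recovers true height within quantisation", {
  sc <- tiny_scene(noise_sd = 0, outlier_rate = 0, seed = 17)
  cloud <- generate_point_cloud(sc$terrain, sc$design, sc$truth, 4,
                                sc$sensor)
  cloud <- classify_ground(denoise_points(voxel_resample(cloud, 0.03), 8, 3))
  ext <- phenoheight:::field_extent(sc$design)
  chm <- compute_chm(rasterize_dsm(cloud, 0.05, ext),
                     interpolate_dtm(cloud, 0.05, ext))
  masks <- build_plot_masks(sc$design, 0.05, 4)
  got <- extract_plot_heights(chm, masks, "lidar", "max")$extracted_m
  expect_equal(got, unname(sc$truth$heights[1:6, 4]), tolerance = 0.02)
})

test_that("XYZ text I/O round-trips a classified cloud", {
  sc <- tiny_scene(noise_sd = 0.01, seed = 23)
  cloud <- generate_point_cloud(sc$terrain, sc$design, sc$truth, 1,
                                sc$sensor)[1:200, ]
  path <- withr::local_tempfile(fileext = ".xyz.gz")
  write_xyz(cloud, path)
  back <- read_xyz(path)
  expect_equal(as.data.frame(back), as.data.frame(cloud), tolerance = 1e-12)
})
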