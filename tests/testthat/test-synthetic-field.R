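test_that("terrain generator is flat at zero relief and bounded by the amplitude", {
  d <- tiny_field()
  flat <- generate_terrain(d, relief_amplitude = 0, seed = 1)
  expect_true(all(flat$values == 0))

  t1 <- generate_terrain(d, 0.5, seed = 9)
  t2 <- generate_terrain(d, 0.5, seed = 9)
  expect_identical(t1$values, t2$values)
  expect_lte(max(t1$values) - min(t1$values), 2 * 0.5)

  t3 <- generate_terrain(d, 0.5, seed = 10)
  expect_false(identical(t1$values, t3$values))
  expect_error(generate_terrain(d, 0.5, cell = 0), "positive")
})

test_that("growth truth: monotone logistic curves with ordered cluster rates", {
  tr <- generate_growth_truth(419, 5, 5, separation = 4, seed = 3)
  expect_equal(dim(tr$heights), c(419, 5))
  expect_true(all(tr$heights >= 0))
  expect_true(all(apply(tr$heights, 1, function(r) all(diff(r) >= 0))))
  rate_means <- tapply(tr$curve_params$rate_per_day, tr$cluster_id, mean)
  expect_true(all(diff(rate_means) > 0))
  expect_equal(sort(unique(tr$cluster_id)), 1:5)

  one <- generate_growth_truth(30, 5, 1, seed = 2)
  expect_true(all(one$cluster_id == 1))
  expect_error(generate_growth_truth(10, 5, 0), "n_clusters")
  # same seed reproduces bit-identically
  expect_identical(generate_growth_truth(50, 5, 3, 4, seed = 11)$heights,
                   generate_growth_truth(50, 5, 3, 4, seed = 11)$heights)
})

test_that("zero separation leaves clusters unrecoverable beyond chance", {
  tr <- generate_growth_truth(300, 5, 5, separation = 0, seed = 5)
  cl <- cluster_growth(tr$heights, 5, seed = 6)
  expect_lt(abs(adjusted_rand_index(cl$assignments$cluster, tr$cluster_id)),
            0.05)
})

test_that("point cloud geometry matches the sensor model", {
  sc <- tiny_scene(noise_sd = 0.01, canopy_cover = 0)
  cloud <- generate_point_cloud(sc$terrain, sc$design, sc$truth, 3, sc$sensor)
  ter_z <- phenoheight:::raster_value_at(sc$terrain, cloud$x, cloud$y)
  dev <- abs(cloud$z - ter_z)
  expect_gt(mean(dev <= 3 * 0.01), 0.99)   # Gaussian tail, no canopy shift
  expect_lt(max(dev), 5.5 * 0.01)

  # expected count ~ density x plot area, Poisson tolerance
  sc2 <- tiny_scene(seed = 21)
  cloud2 <- generate_point_cloud(sc2$terrain, sc2$design, sc2$truth, 3,
                                 sc2$sensor)
  per_plot <- table(cloud2$plot_id)
  expected <- 80 * 4.5 * 5
  expect_true(all(abs(per_plot - expected) < 5 * sqrt(expected)))

  # noiseless limit: canopy top minus ground equals true height exactly
  sc3 <- tiny_scene(noise_sd = 0, outlier_rate = 0)
  cloud3 <- generate_point_cloud(sc3$terrain, sc3$design, sc3$truth, 2,
                                 sc3$sensor)
  p1 <- cloud3[cloud3$plot_id == "P001" & !is.na(cloud3$plot_id), ]
  expect_equal(max(p1$z) - min(p1$z), sc3$truth$heights[1, 2],
               tolerance = 1e-12)

  expect_error(generate_point_cloud(sc3$terrain, sc3$design, sc3$truth, 9,
                                    sc3$sensor), "time_point")
})

test_that("RGB surface raster mixes soil and canopy cells", {
  sc <- tiny_scene(noise_sd = 0, canopy_cover = 0.2)
  dsm <- generate_dsm(sc$terrain, sc$design, sc$truth, 4, sc$sensor, 0.05)
  masks <- build_plot_masks(sc$design, 0, 4)
  v <- zonal_values(dsm, masks[1, ])
  # soil cells sit at terrain elevation (0 on a flat field)
  expect_gte(mean(abs(v) < 1e-9), 0.70)
  expect_equal(max(v) - min(v), sc$truth$heights[1, 4], tolerance = 1e-9)

  d1 <- generate_dsm(sc$terrain, sc$design, sc$truth, 4,
                     sensor_config(seed = 3), 0.05)
  d2 <- generate_dsm(sc$terrain, sc$design, sc$truth, 4,
                     sensor_config(seed = 3), 0.05)
  expect_identical(d1$values, d2$values)
  expect_error(generate_dsm(sc$terrain, sc$design, sc$truth, 4, sc$sensor,
                            cell = 10), "plot width")
})

test_that("genotype panel has the requested shape, MAF spectrum and missingness", {
  G <- generate_genotypes(419, 500, missing_rate = 0.05, seed = 13)
  expect_equal(dim(G$dosages), c(419, 500))
  expect_true(all(G$dosages %in% c(0L, 1L, 2L) | is.na(G$dosages)))
  expect_lt(abs(mean(is.na(G$dosages)) - 0.05), 0.005)
  # positions sorted within chromosome
  for (ch in unique(G$map$chrom)) {
    expect_true(!is.unsorted(G$map$pos[G$map$chrom == ch]))
  }
  # realized allele frequencies track the sampled spectrum
  p <- colMeans(G$dosages, na.rm = TRUE) / 2
  expect_true(mean(p > 0.02 & p < 0.6) > 0.95)

  G0 <- generate_genotypes(50, 100, missing_rate = 0, seed = 1)
  expect_false(anyNA(G0$dosages))
  expect_error(generate_genotypes(10, 20, maf_range = c(0, 0.6)),
               "maf_range")
})

test_that("population structure is visible in PCA only when fst > 0", {
  gt_str <- genotype_truth(h2 = 0.5, n_subpop = 2, fst_like = 0.15)
  Gs <- generate_genotypes(150, 400, missing_rate = 0, truth = gt_str,
                           seed = 4)
  pc <- prcomp(Gs$dosages, rank. = 1)$x[, 1]
  p_str <- t.test(pc ~ Gs$subpop)$p.value
  expect_lt(p_str, 1e-6)

  gt_null <- genotype_truth(h2 = 0.5, n_subpop = 2, fst_like = 0)
  Gn <- generate_genotypes(150, 400, missing_rate = 0, truth = gt_null,
                           seed = 4)
  pcn <- prcomp(Gn$dosages, rank. = 1)$x[, 1]
  expect_gt(t.test(pcn ~ Gn$subpop)$p.value, 0.01)
})

test_that("phenotypes realise the target heritability and replicate layout", {
  gt <- genotype_truth(causal_indices = c(50, 200), effect_sizes = 0.05,
                       h2 = 0.6, polygenic_share = 0.5)
  G <- generate_genotypes(419, 400, missing_rate = 0.02, truth = gt,
                          seed = 8)
  ph <- generate_phenotypes(G, n_reps = 3, seed = 9)
  expect_equal(nrow(ph$records), 3 * 419)
  expect_equal(ph$h2_realized, 0.6, tolerance = 0.05)

  # near-noiseless limit: phenotype linear in causal dosages
  gt1 <- genotype_truth(causal_indices = 10, effect_sizes = 0.1,
                        h2 = 0.999, polygenic_share = 0)
  G1 <- generate_genotypes(200, 50, missing_rate = 0, truth = gt1, seed = 2)
  ph1 <- generate_phenotypes(G1, n_reps = 1, seed = 3)
  expect_gt(cor(ph1$accession$value_m, G1$dosages[, 10]), 0.99)

  bad <- genotype_truth(causal_indices = 999, effect_sizes = 0.1)
  expect_error(generate_phenotypes(G1, truth = bad), "causal index")
})

test_that("calibration pair simulator applies the polynomial distortion", {
  pairs <- simulate_calibration_pairs(500, c(0, 1.05, 0.9), noise_sd = 0,
                                      seed = 4)
  expect_equal(pairs$measured_m,
               1.05 * pairs$extracted_m + 0.9 * pairs$extracted_m^2,
               tolerance = 1e-12)
  expect_identical(simulate_calibration_pairs(50, seed = 5),
                   simulate_calibration_pairs(50, seed = 5))
})
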