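# Shared fixture builders; everything is generated in code at test time.

tiny_field <- function() field_design(2, 3)

# small flat-terrain scene with known heights, for extraction checks
tiny_scene <- function(noise_sd = 0, outlier_rate = 0, canopy_cover = 0.3,
                       seed = 7L, relief = 0) {
  d <- tiny_field()
  ter <- generate_terrain(d, relief, 0.05, seed = seed)
  tr <- generate_growth_truth(6, 5, 3, separation = 4, seed = seed)
  sc <- sensor_config(point_density = 80, noise_sd = noise_sd,
                      outlier_rate = outlier_rate,
                      canopy_cover = canopy_cover, seed = seed)
  list(design = d, terrain = ter, truth = tr, sensor = sc)
}

random_raster <- function(nr = 15, nc = 20, seed = 1, na_frac = 0) {
  set.seed(seed)
  v <- matrix(rnorm(nr * nc, 50, 0.3), nr, nc)
  if (na_frac > 0) v[runif(nr * nc) < na_frac] <- NA
  raster_grid(v, origin = c(0, nr * 0.1), cell = 0.1)
}

# brute-force metric suite, written directly from the scoring formulas
brute_metrics <- function(zm, zp) {
  n <- length(zm)
  r2 <- 1 - sum((zm - zp)^2) / sum((zm - mean(zm))^2)
  mae <- sum(abs(zm - zp)) / n
  mse <- sum((zm - zp)^2) / n
  c(r2 = r2, mae = mae, mse = mse, rmse = sqrt(mse),
    rmsle = sqrt(sum((log(1 + zp) - log(1 + zm))^2) / n),
    mape = sum(abs(zm - zp) / abs(zm)) / n)
}

# point-in-polygon by ray casting (independent of mgcv)
pip_oracle <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}
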