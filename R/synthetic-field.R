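#' Field trial layout
#'
#' Describes a rectangular grid of plots of identical footprint separated by
#' bare-soil alleys, the layout of a typical variety trial. The default plot
#' footprint is 4.5 m x 5.0 m. A half-alley margin of bare ground surrounds
#' the plot grid so that every plot has soil returns nearby.
#'
#' @param n_rows,n_cols Number of plot rows/columns; their product is the
#'   number of plots.
#' @param plot_length_m Plot extent along y in metres.
#' @param plot_width_m Plot extent along x in metres.
#' @param alley_m Bare-soil alley width between adjacent plots, metres.
#' @param origin (x, y) of the bottom-left corner of the field, metres.
#' @return A `field_design` object.
#' @export
field_design <- function(n_rows, n_cols, plot_length_m = 4.5,
                         plot_width_m = 5.0, alley_m = 0.5,
                         origin = c(0, 0)) {
  stopifnot(n_rows >= 1, n_cols >= 1, plot_length_m > 0, plot_width_m > 0,
            alley_m >= 0)
  d <- list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
            plot_length_m = plot_length_m, plot_width_m = plot_width_m,
            alley_m = alley_m, origin = as.numeric(origin))
  class(d) <- "field_design"
  d
}

#' @export
print.field_design <- function(x, ...) {
  cat(sprintf("<field_design> %d x %d plots of %.1f x %.1f m (alley %.1f m)\n",
              x$n_rows, x$n_cols, x$plot_width_m, x$plot_length_m, x$alley_m))
  invisible(x)
}

# Full field extent including the half-alley margin: c(xmin, xmax, ymin, ymax)
field_extent <- function(design) {
  m <- design$alley_m / 2
  w <- design$n_cols * design$plot_width_m +
    (design$n_cols - 1) * design$alley_m
  h <- design$n_rows * design$plot_length_m +
    (design$n_rows - 1) * design$alley_m
  c(design$origin[1] - m, design$origin[1] + w + m,
    design$origin[2] - m, design$origin[2] + h + m)
}

#' Plot footprints of a field design
#'
#' @param design A [field_design()].
#' @return A tibble with `plot_id`, `row`, `col` and the plot's bounding
#'   box (`x_min`, `x_max`, `y_min`, `y_max`) in metres. Plots are numbered
#'   row-major from the bottom-left of the field.
#' @export
plot_footprints <- function(design) {
  px <- design$plot_width_m + design$alley_m
  py <- design$plot_length_m + design$alley_m
  g <- expand.grid(col = seq_len(design$n_cols), row = seq_len(design$n_rows))
  idx <- (g$row - 1L) * design$n_cols + g$col
  tibble::tibble(
    plot_id = sprintf("P%03d", idx),
    row = g$row, col = g$col,
    x_min = design$origin[1] + (g$col - 1) * px,
    x_max = design$origin[1] + (g$col - 1) * px + design$plot_width_m,
    y_min = design$origin[2] + (g$row - 1) * py,
    y_max = design$origin[2] + (g$row - 1) * py + design$plot_length_m
  )[order(idx), ]
}

#' Sensor acquisition model
#'
#' Parameters of the simulated LiDAR/RGB acquisition: return density, vertical
#' noise, gross-outlier contamination and the fraction of each plot actually
#' covered by canopy.
#'
#' @param point_density Returns per square metre.
#' @param noise_sd Vertical Gaussian noise, metres.
#' @param outlier_rate Fraction of returns displaced by +/- 5 m (gross
#'   outliers to exercise denoising).
#' @param canopy_cover Fraction of each plot's area covered by canopy.
#' @param seed RNG seed used by generators that take this config.
#' @return A `sensor_config` object.
#' @export
sensor_config <- function(point_density = 100, noise_sd = 0.02,
                          outlier_rate = 0.01, canopy_cover = 0.3,
                          seed = 1L) {
  stopifnot(point_density > 0, noise_sd >= 0,
            outlier_rate >= 0, outlier_rate <= 1,
            canopy_cover >= 0, canopy_cover <= 1)
  structure(list(point_density = point_density, noise_sd = noise_sd,
                 outlier_rate = outlier_rate, canopy_cover = canopy_cover,
                 seed = as.integer(seed)),
            class = "sensor_config")
}

#' Generate a smooth terrain surface
#'
#' Band-limited relief built from a small number of random-phase sinusoids
#' whose wavelengths are of the order of the field size, normalised so that
#' the surface stays within `+/- relief_amplitude` of zero. With
#' `relief_amplitude = 0` the field is perfectly flat.
#'
#' @param design A [field_design()].
#' @param relief_amplitude Half-range of the relief, metres.
#' @param cell Raster cell size, metres.
#' @param seed RNG seed; the same seed always yields the same surface.
#' @param n_waves Number of sinusoidal components.
#' @return A [raster_grid()] DTM-like elevation surface covering the field.
#' @export
generate_terrain <- function(design, relief_amplitude = 0.2, cell = 0.05,
                             seed = 1L, n_waves = 6L) {
  stopifnot(inherits(design, "field_design"), relief_amplitude >= 0)
  if (cell <= 0) stop("cell size must be positive", call. = FALSE)
  ext <- field_extent(design)
  nc <- max(1L, ceiling((ext[2] - ext[1]) / cell))
  nr <- max(1L, ceiling((ext[4] - ext[3]) / cell))
  xs <- ext[1] + (seq_len(nc) - 0.5) * cell
  ys <- ext[4] - (seq_len(nr) - 0.5) * cell
  L <- max(ext[2] - ext[1], ext[4] - ext[3])
  v <- with_seed(seed, {
    amp <- stats::runif(n_waves, 0.3, 1)
    lambda <- stats::runif(n_waves, 0.8 * L, 2.5 * L)
    theta <- stats::runif(n_waves, 0, pi)
    phase <- stats::runif(n_waves, 0, 2 * pi)
    xg <- matrix(xs, nr, nc, byrow = TRUE)
    yg <- matrix(ys, nr, nc)
    z <- matrix(0, nr, nc)
    for (k in seq_len(n_waves)) {
      z <- z + amp[k] * sin(2 * pi * (xg * cos(theta[k]) +
                                        yg * sin(theta[k])) / lambda[k] +
                              phase[k])
    }
    z / sum(amp)   # |z| <= 1
  })
  raster_grid(relief_amplitude * v, origin = c(ext[1], ext[4]), cell = cell)
}

#' Generate true growth trajectories for a panel of accessions
#'
#' Each accession follows a 3-parameter logistic growth curve
#' `h(t) = A / (1 + exp(-r (t - t_mid)))` sampled at the acquisition days.
#' Accessions fall into `n_clusters` groups whose mean growth rate (and,
#' matching the ordered maximum heights seen in real panels, mean asymptote)
#' increase with cluster index. `separation` is the gap between adjacent
#' cluster means expressed in units of the within-cluster standard deviation:
#' `separation = 0` makes all clusters exchangeable, `separation >= 4` makes
#' them well separated. Clusters are relabelled so realised mean rates are
#' strictly increasing.
#'
#' @param n_accessions Number of accessions (one plot each).
#' @param n_times Number of acquisition time points (>= 2).
#' @param n_clusters Number of growth-habit clusters.
#' @param separation Between-cluster mean gap in within-cluster sd units.
#' @param seed RNG seed.
#' @param times Acquisition days; default five flights across a 27-day window
#'   of rapid growth.
#' @param genetic Optional per-accession additive offset (metres) applied to
#'   the asymptote, used to couple height to genotype.
#' @param fluct_sd Per-time-point biological fluctuation around the smooth
#'   curve, metres; a running maximum keeps each trajectory non-decreasing.
#' @return A `growth_truth` object: `heights` (accessions x times, metres),
#'   `times`, `cluster_id`, `curve_params` tibble, `accession` ids.
#' @export
generate_growth_truth <- function(n_accessions, n_times = 5L,
                                  n_clusters = 5L, separation = 4,
                                  seed = 1L, times = NULL, genetic = NULL,
                                  fluct_sd = 0.025) {
  if (n_clusters < 1) stop("n_clusters must be >= 1", call. = FALSE)
  stopifnot(n_clusters <= n_accessions, n_times >= 2)
  if (is.null(times)) {
    times <- if (n_times == 5L) c(0, 7, 14, 20, 27)
             else seq(0, 27, length.out = n_times)
  }
  stopifnot(length(times) == n_times)
  if (!is.null(genetic)) stopifnot(length(genetic) == n_accessions)

  sd_rate <- 0.012   # within-cluster sd of logistic rate, d^-1
  sd_asym <- 0.02    # within-cluster sd of asymptote, m
  res <- with_seed(seed, {
    cl <- sort(rep_len(seq_len(n_clusters), n_accessions))
    cl <- sample(cl)
    rate_mean <- 0.10 + (seq_len(n_clusters) - 1) * separation * sd_rate
    asym_mean <- 0.65 + (seq_len(n_clusters) - 1) * separation * 0.05
    rate <- pmax(stats::rnorm(n_accessions, rate_mean[cl], sd_rate), 0.02)
    asym <- pmax(stats::rnorm(n_accessions, asym_mean[cl], sd_asym), 0.2)
    tmid <- stats::rnorm(n_accessions, 13, 0.4)
    fluct <- matrix(stats::rnorm(n_accessions * n_times, 0, fluct_sd),
                    n_accessions, n_times)
    list(cl = cl, rate = rate, asym = asym, tmid = tmid, fluct = fluct)
  })
  if (!is.null(genetic)) res$asym <- pmax(res$asym + genetic, 0.1)

  # relabel clusters so realised mean rates are strictly increasing
  ord <- order(tapply(res$rate, res$cl, mean))
  relab <- integer(n_clusters); relab[ord] <- seq_len(n_clusters)
  cl <- relab[res$cl]

  h <- outer(seq_len(n_accessions), seq_len(n_times), function(i, j) {
    res$asym[i] / (1 + exp(-res$rate[i] * (times[j] - res$tmid[i])))
  })
  h <- pmax(h + res$fluct, 0)
  # running maximum preserves the pre-topping monotone growth invariant
  h <- t(apply(h, 1, cummax))
  acc <- sprintf("ACC%03d", seq_len(n_accessions))
  dimnames(h) <- list(acc, paste0("t", seq_len(n_times)))
  structure(list(
    heights = h, times = times, cluster_id = cl,
    curve_params = tibble::tibble(accession = acc, cluster = cl,
                                  asymptote_m = res$asym,
                                  rate_per_day = res$rate,
                                  midpoint_day = res$tmid),
    accession = acc
  ), class = "growth_truth")
}

#' @export
print.growth_truth <- function(x, ...) {
  cat(sprintf("<growth_truth> %d accessions x %d times, %d clusters\n",
              nrow(x$heights), ncol(x$heights), max(x$cluster_id)))
  invisible(x)
}

# canopy patch (centred rectangle of area canopy_cover * plot area) of one plot
canopy_patch <- function(fp_row, canopy_cover) {
  s <- sqrt(canopy_cover)
  cx <- (fp_row$x_min + fp_row$x_max) / 2
  cy <- (fp_row$y_min + fp_row$y_max) / 2
  w <- (fp_row$x_max - fp_row$x_min) * s
  h <- (fp_row$y_max - fp_row$y_min) * s
  c(cx - w / 2, cx + w / 2, cy - h / 2, cy + h / 2)
}

#' Simulate a LiDAR point cloud over the field
#'
#' Returns are placed uniformly over the field extent at the configured
#' density. A return over a plot's canopy patch (a centred rectangle covering
#' `canopy_cover` of the plot) sits at terrain + true plant height; all other
#' returns are ground. Vertical Gaussian noise is added everywhere and a
#' fraction `outlier_rate` of returns is displaced by +/- 5 m. True origin
#' labels are retained in the `truth` column for evaluation only; the `class`
#' column starts `"unclassified"`.
#'
#' @param terrain Terrain [raster_grid()] from [generate_terrain()].
#' @param design A [field_design()].
#' @param truth A [generate_growth_truth()] result; accession i occupies
#'   plot i.
#' @param time_point Index into `truth$times`.
#' @param sensor A [sensor_config()].
#' @return A tibble point cloud: `x`, `y`, `z`, `class`, `truth`, `plot_id`.
#' @export
generate_point_cloud <- function(terrain, design, truth, time_point,
                                 sensor = sensor_config()) {
  stopifnot(inherits(terrain, "raster_grid"), inherits(design, "field_design"),
            inherits(truth, "growth_truth"))
  if (time_point < 1 || time_point > ncol(truth$heights)) {
    stop("time_point outside the range of the growth truth", call. = FALSE)
  }
  ext <- field_extent(design)
  area <- (ext[2] - ext[1]) * (ext[4] - ext[3])
  if (area <= 0) stop("empty field extent", call. = FALSE)
  fp <- plot_footprints(design)
  n_plots <- nrow(fp)
  heights <- truth$heights[, time_point]
  if (length(heights) < n_plots) {
    stop("growth truth has fewer accessions than the design has plots",
         call. = FALSE)
  }

  with_seed(derive_seed(sensor$seed, 7L + time_point), {
    n <- stats::rpois(1, sensor$point_density * area)
    x <- stats::runif(n, ext[1], ext[2])
    y <- stats::runif(n, ext[3], ext[4])
    z <- raster_value_at(terrain, x, y)
    lab <- rep("ground", n)
    plot_id <- rep(NA_character_, n)
    for (i in seq_len(n_plots)) {
      p <- canopy_patch(fp[i, ], sensor$canopy_cover)
      inplot <- x >= fp$x_min[i] & x <= fp$x_max[i] &
        y >= fp$y_min[i] & y <= fp$y_max[i]
      plot_id[inplot] <- fp$plot_id[i]
      incan <- x >= p[1] & x <= p[2] & y >= p[3] & y <= p[4]
      z[incan] <- z[incan] + heights[i]
      lab[incan] <- "canopy"
    }
    if (sensor$noise_sd > 0) z <- z + stats::rnorm(n, 0, sensor$noise_sd)
    if (sensor$outlier_rate > 0) {
      out <- stats::runif(n) < sensor$outlier_rate
      z[out] <- z[out] + sample(c(-5, 5), sum(out), replace = TRUE)
      lab[out] <- "outlier"
    }
    tibble::tibble(x = x, y = y, z = z, class = "unclassified",
                   truth = lab, plot_id = plot_id)
  })
}

#' Simulate an RGB-photogrammetry surface raster
#'
#' The RGB branch produces a single surface model (no separate ground
#' flight): soil cells at terrain elevation, canopy cells at terrain plus the
#' plot's true height, plus vertical noise.
#'
#' @inheritParams generate_point_cloud
#' @param cell Output cell size, metres; must not exceed the plot width.
#' @return A [raster_grid()] surface.
#' @export
generate_dsm <- function(terrain, design, truth, time_point,
                         sensor = sensor_config(), cell = 0.05) {
  stopifnot(inherits(design, "field_design"), inherits(truth, "growth_truth"))
  if (cell > design$plot_width_m) {
    stop("cell size exceeds the plot width", call. = FALSE)
  }
  if (time_point < 1 || time_point > ncol(truth$heights)) {
    stop("time_point outside the range of the growth truth", call. = FALSE)
  }
  ext <- field_extent(design)
  nc <- max(1L, ceiling((ext[2] - ext[1]) / cell))
  nr <- max(1L, ceiling((ext[4] - ext[3]) / cell))
  xs <- ext[1] + (seq_len(nc) - 0.5) * cell
  ys <- ext[4] - (seq_len(nr) - 0.5) * cell
  xg <- matrix(rep(xs, each = nr), nr, nc)
  yg <- matrix(rep(ys, times = nc), nr, nc)
  z <- matrix(raster_value_at(terrain, as.vector(xg), as.vector(yg)), nr, nc)
  fp <- plot_footprints(design)
  heights <- truth$heights[, time_point]
  for (i in seq_len(nrow(fp))) {
    p <- canopy_patch(fp[i, ], sensor$canopy_cover)
    incan <- xg >= p[1] & xg <= p[2] & yg >= p[3] & yg <= p[4]
    z[incan] <- z[incan] + heights[i]
  }
  if (sensor$noise_sd > 0) {
    z <- z + with_seed(derive_seed(sensor$seed, 37L + time_point),
                       matrix(stats::rnorm(nr * nc, 0, sensor$noise_sd),
                              nr, nc))
  }
  raster_grid(z, origin = c(ext[1], ext[4]), cell = cell)
}

#' Genetic architecture of the simulated panel
#'
#' @param causal_indices Integer indices (into the SNP set) of causal loci.
#' @param effect_sizes Additive allele effects, metres per dose; recycled to
#'   the length of `causal_indices`.
#' @param h2 Narrow-sense heritability of the accession-level phenotype.
#' @param n_subpop Number of subpopulations.
#' @param fst_like Differentiation between subpopulation allele frequencies
#'   (Balding-Nichols F); 0 disables structure.
#' @param polygenic_share Fraction of the genetic variance contributed by the
#'   polygenic (infinitesimal) background rather than the planted causal loci.
#' @param structure_share With population structure (`n_subpop > 1`), the
#'   fraction of the polygenic variance aligned with subpopulation membership
#'   — the confounding component that inflates a naive scan and that the
#'   kinship correction must absorb.
#' @return A `genotype_truth` object.
#' @export
genotype_truth <- function(causal_indices = integer(), effect_sizes = 0.1,
                           h2 = 0.5, n_subpop = 1L, fst_like = 0,
                           polygenic_share = 0.5, structure_share = 0.5) {
  stopifnot(h2 > 0, h2 < 1, n_subpop >= 1, fst_like >= 0, fst_like < 1,
            polygenic_share >= 0, polygenic_share <= 1,
            structure_share >= 0, structure_share <= 1)
  structure(list(
    causal_indices = as.integer(causal_indices),
    effect_sizes = rep_len(effect_sizes, length(causal_indices)),
    h2 = h2, n_subpop = as.integer(n_subpop), fst_like = fst_like,
    polygenic_share = polygenic_share, structure_share = structure_share
  ), class = "genotype_truth")
}

#' Simulate a genotype panel
#'
#' Biallelic dosages in \{0, 1, 2\} with missingness, a minor-allele-frequency
#' spectrum drawn from `maf_range`, and optional population structure:
#' subpopulation allele frequencies are drifted from the ancestral frequency
#' by a Balding-Nichols Beta draw with parameter `truth$fst_like`. SNPs are
#' placed on five chromosomes with sorted positions.
#'
#' @param n_samples,n_snps Panel dimensions.
#' @param maf_range Interval in (0, 0.5] for ancestral minor-allele
#'   frequencies.
#' @param missing_rate Fraction of calls set missing at random.
#' @param truth A [genotype_truth()].
#' @param seed RNG seed.
#' @return A `genotype_matrix`: `dosages` (samples x SNPs, `NA` = missing),
#'   `map` tibble (`snp_id`, `chrom`, `pos`), `sample_ids`, `subpop`, `truth`.
#' @export
generate_genotypes <- function(n_samples, n_snps, maf_range = c(0.05, 0.5),
                               missing_rate = 0.02,
                               truth = genotype_truth(), seed = 1L) {
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    stop("maf_range must lie inside (0, 0.5]", call. = FALSE)
  }
  stopifnot(missing_rate >= 0, missing_rate < 1)
  if (length(truth$causal_indices) &&
      any(truth$causal_indices < 1 | truth$causal_indices > n_snps)) {
    stop("causal index out of range", call. = FALSE)
  }
  chroms <- c("A01", "A02", "A07", "A10", "D11")
  with_seed(derive_seed(seed, 211L), {
    p_anc <- stats::runif(n_snps, maf_range[1], maf_range[2])
    sub <- rep_len(seq_len(truth$n_subpop), n_samples)
    if (truth$n_subpop > 1 && truth$fst_like > 0) {
      f <- truth$fst_like
      pf <- matrix(0, truth$n_subpop, n_snps)
      for (k in seq_len(truth$n_subpop)) {
        pf[k, ] <- stats::rbeta(n_snps, p_anc * (1 - f) / f,
                                (1 - p_anc) * (1 - f) / f)
      }
      pf <- pmin(pmax(pf, 1e-4), 1 - 1e-4)
      dos <- matrix(stats::rbinom(n_samples * n_snps, 2,
                                  pf[sub, , drop = FALSE]),
                    n_samples, n_snps)
    } else {
      dos <- matrix(stats::rbinom(n_samples * n_snps, 2,
                                  rep(p_anc, each = n_samples)),
                    n_samples, n_snps)
    }
    if (missing_rate > 0) {
      dos[stats::runif(length(dos)) < missing_rate] <- NA_integer_
    }
    chrom <- sort(rep_len(chroms, n_snps))
    pos <- unlist(lapply(split(seq_len(n_snps), chrom), function(ix) {
      sort(sample.int(120e6, length(ix)))
    }), use.names = FALSE)
    ordc <- order(match(chrom, chroms))
    map <- tibble::tibble(
      snp_id = sprintf("%s_%d", chrom[ordc], pos),
      chrom = chrom[ordc], pos = as.integer(pos)
    )
    sample_ids <- sprintf("ACC%03d", seq_len(n_samples))
    dimnames(dos) <- list(sample_ids, map$snp_id)
    structure(list(dosages = dos, map = map, sample_ids = sample_ids,
                   subpop = sub, truth = truth),
              class = "genotype_matrix")
  })
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d SNPs on %d chromosome(s)\n",
              nrow(x$dosages), ncol(x$dosages),
              length(unique(x$map$chrom))))
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Simulate replicated plant-height phenotypes from genotypes
#'
#' The accession-level phenotype is `base + causal + polygenic + residual`:
#' the causal component is the dosage-weighted sum of the planted effects,
#' the polygenic component follows the infinitesimal model (standardised
#' genome-wide dosages times i.i.d. effects), and both are scaled so that the
#' realised accession-level heritability equals `truth$h2` and the polygenic
#' fraction of genetic variance equals `truth$polygenic_share`. Each of the
#' `n_reps` replicate records adds a replicate effect and plot-level noise.
#'
#' @param G A `genotype_matrix` from [generate_genotypes()].
#' @param truth A [genotype_truth()]; defaults to the one stored in `G`.
#' @param n_reps Replicate plots per accession.
#' @param seed RNG seed.
#' @param base_height_m Panel mean height, metres.
#' @param total_sd_m Accession-level phenotypic standard deviation, metres.
#' @param rep_noise_sd Plot-level measurement noise per replicate, metres.
#' @return A `phenotypes` object: `records` tibble (`accession`, `replicate`,
#'   `value_m`), `accession` tibble (`accession`, `genetic_m`, `value_m`),
#'   and `h2_realized`.
#' @export
generate_phenotypes <- function(G, truth = NULL, n_reps = 3L, seed = 1L,
                                base_height_m = 1.0, total_sd_m = 0.1,
                                rep_noise_sd = 0.02) {
  stopifnot(inherits(G, "genotype_matrix"), n_reps >= 1)
  truth <- truth %||% G$truth
  n <- nrow(G$dosages); m <- ncol(G$dosages)
  if (length(truth$causal_indices) &&
      any(truth$causal_indices < 1 | truth$causal_indices > m)) {
    stop("causal index out of range", call. = FALSE)
  }
  dos <- G$dosages
  cm <- colMeans(dos, na.rm = TRUE)
  for (j in seq_len(m)) dos[is.na(dos[, j]), j] <- cm[j]

  with_seed(derive_seed(seed, 401L), {
    causal <- if (length(truth$causal_indices)) {
      as.vector(dos[, truth$causal_indices, drop = FALSE] %*%
                  truth$effect_sizes)
    } else rep(0, n)
    Z <- scale(dos)
    Z[, attr(Z, "scaled:scale") == 0 | !is.finite(colSums(Z))] <- 0
    Z[is.na(Z)] <- 0
    poly <- as.vector(Z %*% stats::rnorm(m)) / sqrt(m)
    # with population structure, part of the polygenic background is
    # aligned with subpopulation membership (the classic confounder a
    # kinship-corrected scan has to absorb)
    if (!is.null(G$subpop) && length(unique(G$subpop)) > 1 &&
        truth$structure_share > 0) {
      sub_eff <- stats::rnorm(length(unique(G$subpop)))
      # fixed-magnitude, random-sign subpopulation contrasts
      sub_eff <- sign(sub_eff) * (0.5 + 0.5 * abs(sub_eff))
      struct <- sub_eff[G$subpop]
      s_str <- stats::sd(struct)
      if (s_str > 1e-12) {
        struct <- (struct - mean(struct)) / s_str
        p_unstr <- (poly - mean(poly)) / max(stats::sd(poly), 1e-12)
        poly <- sqrt(truth$structure_share) * struct +
          sqrt(1 - truth$structure_share) * p_unstr
      }
    }

    unit_var <- function(v) {
      s <- stats::sd(v)
      if (s < 1e-12) rep(0, length(v)) else (v - mean(v)) / s
    }
    var_g <- truth$h2 * total_sd_m^2
    v_causal <- var_g * (1 - truth$polygenic_share)
    v_poly <- var_g * truth$polygenic_share
    g <- if (stats::sd(causal) > 1e-12) {
      unit_var(causal) * sqrt(v_causal) + unit_var(poly) * sqrt(v_poly)
    } else {
      unit_var(poly) * sqrt(var_g)
    }
    e <- unit_var(stats::rnorm(n)) * sqrt((1 - truth$h2) * total_sd_m^2)
    y <- base_height_m + g + e

    rep_eff <- stats::rnorm(n_reps, 0, 0.01)
    rec <- tidyr::expand_grid(accession = G$sample_ids,
                              replicate = seq_len(n_reps))
    rec$value_m <- y[match(rec$accession, G$sample_ids)] +
      rep_eff[rec$replicate] +
      stats::rnorm(nrow(rec), 0, rep_noise_sd)

    structure(list(
      records = rec,
      accession = tibble::tibble(accession = G$sample_ids, genetic_m = g,
                                 value_m = y),
      h2_realized = stats::var(g) / stats::var(y)
    ), class = "phenotypes")
  })
}

#' @export
print.phenotypes <- function(x, ...) {
  cat(sprintf("<phenotypes> %d accessions x %d replicates, realised h2 = %.3f\n",
              nrow(x$accession), max(x$records$replicate), x$h2_realized))
  invisible(x)
}

#' Simulate calibration pairs with a polynomial sensor distortion
#'
#' Draws UAV-extracted heights uniformly over `x_range` and produces the
#' corresponding manually measured heights through a polynomial response
#' `y = c0 + c1 x + c2 x^2 + ...` plus Gaussian noise — the test bed for the
#' regression-calibration stage.
#'
#' @param n Number of plot-time pairs.
#' @param coefs Polynomial coefficients, lowest order first.
#' @param noise_sd Measurement noise on y, metres.
#' @param x_range Range of extracted heights, metres.
#' @param seed RNG seed.
#' @return A tibble with `plot_id`, `extracted_m`, `measured_m`.
#' @export
simulate_calibration_pairs <- function(n, coefs = c(0, 1.05, 0.9),
                                       noise_sd = 0.03,
                                       x_range = c(0.2, 1.2), seed = 1L) {
  stopifnot(n >= 1, length(coefs) >= 1)
  with_seed(derive_seed(seed, 601L), {
    x <- stats::runif(n, x_range[1], x_range[2])
    y <- as.vector(outer(x, seq_along(coefs) - 1, `^`) %*% coefs) +
      stats::rnorm(n, 0, noise_sd)
    tibble::tibble(plot_id = sprintf("P%03d", seq_len(n)),
                   extracted_m = x, measured_m = y)
  })
}
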