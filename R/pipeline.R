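#' Per-plot heights from a raster and a set of masks
#'
#' Vectorised extraction over all plots of one acquisition: computes the
#' raster cell table once, then applies the RGB percentile rule or the CHM
#' zonal aggregator per mask.
#'
#' @param raster A [raster_grid()] (surface model for `mode = "rgb"`, canopy
#'   height model for `mode = "lidar"`).
#' @param masks Mask tibble from [build_plot_masks()].
#' @param mode `"rgb"` (percentile difference) or `"lidar"` (zonal
#'   aggregation).
#' @param aggregator Aggregator for lidar mode (see [extract_lidar_ph()]).
#' @param min_cells Minimum in-mask cells; plots below it yield `NA`.
#' @return A tibble `plot_id`, `time_point`, `extracted_m`.
#' @export
extract_plot_heights <- function(raster, masks, mode = c("lidar", "rgb"),
                                 aggregator = "p95", min_cells = 20L) {
  mode <- match.arg(mode)
  cells <- raster_cells(raster)
  cells <- cells[!is.na(cells$value), ]
  vals <- purrr::pmap_dbl(
    masks[, c("x_min", "x_max", "y_min", "y_max")],
    function(x_min, x_max, y_min, y_max) {
      v <- cells$value[cells$x > x_min & cells$x < x_max &
                         cells$y > y_min & cells$y < y_max]
      if (length(v) < min_cells) return(NA_real_)
      if (mode == "rgb") {
        qlo <- stats::quantile(v, 1:2 / 100, type = 7, names = FALSE)
        qhi <- stats::quantile(v, 95:98 / 100, type = 7, names = FALSE)
        max(0, max(qhi) - min(qlo))
      } else {
        switch(aggregator,
          p95 = stats::quantile(v, 0.95, type = 7, names = FALSE),
          p99 = stats::quantile(v, 0.99, type = 7, names = FALSE),
          max = max(v),
          mean_top_decile = mean(sort(v, decreasing = TRUE)[
            seq_len(max(1L, floor(length(v) / 10)))]))
      }
    })
  tibble::tibble(plot_id = masks$plot_id,
                 time_point = masks$time_point[1],
                 extracted_m = vals)
}

#' Default pipeline configuration
#'
#' Desk-scale defaults for the end-to-end synthetic run: a 60-plot field
#' observed at five time points, LiDAR and RGB branches, polynomial + Huber
#' calibration, gap-statistic cluster selection and a kinship-corrected
#' scan on the calibrated heights. Every stage draws its randomness from a
#' sub-seed derived from the global seed.
#'
#' @param seed Global seed.
#' @return A nested configuration list (YAML-serialisable).
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    stages = list(simulate = TRUE, surfaces = TRUE, extract = TRUE,
                  calibrate = TRUE, cluster = TRUE, gwas = TRUE),
    field = list(n_rows = 6L, n_cols = 10L, plot_length_m = 4.5,
                 plot_width_m = 5.0, alley_m = 0.5),
    terrain = list(relief_amplitude = 0.15, cell = 0.05),
    growth = list(n_times = 5L, n_clusters = 5L, separation = 4),
    sensor = list(point_density = 100, noise_sd = 0.02, outlier_rate = 0.01,
                  canopy_cover = 0.3),
    genotypes = list(n_snps = 1500L, maf_range = c(0.05, 0.5),
                     missing_rate = 0.02, n_subpop = 2L, fst_like = 0.1,
                     n_causal = 1L, h2 = 0.8, polygenic_share = 0.1,
                     effect_size = 0.1, genetic_sd_m = 0.25),
    surfaces = list(voxel = 0.03, knn = 8L, n_sigma = 3, raster_cell = 0.05,
                    ground_cell = 0.5, slope_tol = 0.08, veg_thresh = 0.2),
    extract = list(shrink = 0.05, aggregator = "p95"),
    calibrate = list(families = c("poly1", "poly2", "poly3", "huber", "lar"),
                     n_train_plots = 24L, test_times = c(4L, 5L),
                     measure_noise_sd = 0.02),
    cluster = list(k_max = 8L, B = 50L),
    gwas = list(maf_min = 0.05, missing_max = 0.10, threshold = 5,
                merge_window = 5e5, n_genes = 200L)
  )
}

#' Read/write a pipeline configuration as YAML
#'
#' @param config Configuration list (see [default_config()]).
#' @param path YAML path.
#' @return `write_config` returns `path` invisibly; `read_config` the list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

#' Run the full synthetic phenotyping and association pipeline
#'
#' Executes the enabled stages in order — simulate, surfaces, extract,
#' calibrate, cluster, gwas — writing CSV/TSV artefacts and a JSON manifest
#' (parameters, outputs, checksums, sub-seeds) to `out_dir`. Reruns with the
#' same configuration and seed produce byte-identical outputs.
#'
#' @param config Configuration list from [default_config()] /
#'   [read_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Optional override of `config$seed`.
#' @return A `pipeline_run` object holding the stage results and the
#'   manifest (invisibly written to `manifest.json`).
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("phrun"),
                         seed = NULL) {
  cfg <- config
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (is.null(cfg$seed)) stop("config must carry a seed", call. = FALSE)
  st <- cfg$stages
  if (isTRUE(st$gwas) && !(isTRUE(st$simulate) && isTRUE(st$calibrate))) {
    stop("gwas stage requires the simulate and calibrate stages", call. = FALSE)
  }
  if (isTRUE(st$calibrate) && !isTRUE(st$extract)) {
    stop("calibrate stage requires the extract stage", call. = FALSE)
  }
  if (isTRUE(st$cluster) && !isTRUE(st$calibrate)) {
    stop("cluster stage requires the calibrate stage", call. = FALSE)
  }
  if (isTRUE(st$extract) && !isTRUE(st$surfaces)) {
    stop("extract stage requires the surfaces stage", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = cfg$seed, config = cfg, stages = list())
  res <- list(config = cfg, out_dir = out_dir)
  log_msg <- function(...) message(sprintf(...))
  add_stage <- function(name, params, files) {
    manifest$stages[[name]] <<- list(
      params = params, outputs = basename(files),
      md5 = unname(tools::md5sum(files)))
  }

  # ---- simulate -----------------------------------------------------------
  design <- field_design(cfg$field$n_rows, cfg$field$n_cols,
                         cfg$field$plot_length_m, cfg$field$plot_width_m,
                         cfg$field$alley_m)
  n_acc <- design$n_rows * design$n_cols
  if (isTRUE(st$simulate)) {
    log_msg("[simulate] %d plots, %d SNPs", n_acc, cfg$genotypes$n_snps)
    gcfg <- cfg$genotypes
    G <- generate_genotypes(n_acc, gcfg$n_snps, gcfg$maf_range,
                            gcfg$missing_rate,
                            genotype_truth(h2 = gcfg$h2,
                                           n_subpop = gcfg$n_subpop,
                                           fst_like = gcfg$fst_like,
                                           polygenic_share =
                                             gcfg$polygenic_share),
                            seed = derive_seed(cfg$seed, 1L))
    if (gcfg$n_causal > 0) {
      # plant causal loci at common variants spread across the panel,
      # so they survive the MAF filter downstream
      st_tbl <- snp_stats(G)
      common <- which(st_tbl$maf > 0.2)
      causal <- common[as.integer(round(
        seq(1, length(common), length.out = gcfg$n_causal)))]
      G$truth <- genotype_truth(causal_indices = causal,
                                effect_sizes = gcfg$effect_size,
                                h2 = gcfg$h2, n_subpop = gcfg$n_subpop,
                                fst_like = gcfg$fst_like,
                                polygenic_share = gcfg$polygenic_share)
    }
    ph <- generate_phenotypes(G, n_reps = 1L,
                              seed = derive_seed(cfg$seed, 2L),
                              total_sd_m = gcfg$genetic_sd_m %||% 0.1)
    genetic <- ph$accession$genetic_m
    truth <- generate_growth_truth(n_acc, cfg$growth$n_times,
                                   cfg$growth$n_clusters,
                                   cfg$growth$separation,
                                   seed = derive_seed(cfg$seed, 3L),
                                   genetic = genetic)
    terrain <- generate_terrain(design, cfg$terrain$relief_amplitude,
                                cfg$terrain$cell,
                                seed = derive_seed(cfg$seed, 4L))
    sensor <- sensor_config(cfg$sensor$point_density, cfg$sensor$noise_sd,
                            cfg$sensor$outlier_rate, cfg$sensor$canopy_cover,
                            seed = derive_seed(cfg$seed, 5L))
    f_truth <- file.path(out_dir, "truth_heights.csv")
    readr::write_csv(dplyr::bind_cols(
      tibble::tibble(accession = truth$accession,
                     cluster = truth$cluster_id),
      tibble::as_tibble(truth$heights)), f_truth)
    f_vcf <- file.path(out_dir, "genotypes.vcf")
    write_vcf(G, f_vcf)
    f_asc <- file.path(out_dir, "terrain.asc")
    write_asc(terrain, f_asc)
    add_stage("simulate", cfg[c("field", "growth", "sensor", "genotypes")],
              c(f_truth, f_vcf, f_asc))
    res$design <- design; res$truth <- truth; res$terrain <- terrain
    res$sensor <- sensor; res$G <- G; res$genetic <- genetic
  }

  # ---- surfaces + extract -------------------------------------------------
  if (isTRUE(st$surfaces)) {
    sc <- cfg$surfaces
    n_times <- cfg$growth$n_times
    series_rows <- list()
    for (tp in seq_len(n_times)) {
      log_msg("[surfaces] time point %d", tp)
      cloud <- generate_point_cloud(res$terrain, design, res$truth, tp,
                                    res$sensor)
      cloud <- voxel_resample(cloud, sc$voxel)
      cloud <- denoise_points(cloud, sc$knn, sc$n_sigma)
      cloud <- classify_ground(cloud, sc$ground_cell, sc$slope_tol,
                               sc$veg_thresh)
      ext <- field_extent(design)
      dsm <- rasterize_dsm(cloud, sc$raster_cell,
                           extent = c(ext[1], ext[2], ext[3], ext[4]))
      dtm <- interpolate_dtm(cloud, sc$raster_cell,
                             extent = c(ext[1], ext[2], ext[3], ext[4]))
      chm <- compute_chm(dsm, dtm)
      rgb_dsm <- generate_dsm(res$terrain, design, res$truth, tp,
                              res$sensor, sc$raster_cell)
      if (tp == n_times) {
        f_chm <- file.path(out_dir, sprintf("chm_t%d.asc", tp))
        write_asc(chm, f_chm)
        add_stage("surfaces", cfg["surfaces"], f_chm)
        res$chm <- chm; res$dtm <- dtm
      }
      if (isTRUE(st$extract)) {
        masks <- build_plot_masks(design, cfg$extract$shrink, tp)
        lid <- extract_plot_heights(chm, masks, "lidar",
                                    cfg$extract$aggregator)
        rgb <- extract_plot_heights(rgb_dsm, masks, "rgb")
        lid$sensor <- "lidar"; rgb$sensor <- "rgb"
        series_rows[[tp]] <- dplyr::bind_rows(lid, rgb)
      }
    }
    if (isTRUE(st$extract)) {
      series <- dplyr::bind_rows(series_rows)
      # attach manual measurements (truth + measurement noise) where the
      # field protocol provides them: training plots at all times, the
      # whole panel at the test times
      cc <- cfg$calibrate
      train_plots <- with_seed(derive_seed(cfg$seed, 6L),
        sort(sample(plot_footprints(design)$plot_id, cc$n_train_plots)))
      meas_noise <- with_seed(derive_seed(cfg$seed, 8L),
        stats::rnorm(nrow(series), 0, cc$measure_noise_sd))
      truth_h <- res$truth$heights[
        cbind(match(series$plot_id,
                    plot_footprints(design)$plot_id),
              series$time_point)]
      series$measured_m <- ifelse(
        series$plot_id %in% train_plots |
          series$time_point %in% cc$test_times,
        truth_h + meas_noise, NA_real_)
      series$truth_m <- truth_h
      f_series <- file.path(out_dir, "height_series.csv")
      readr::write_csv(series, f_series)
      add_stage("extract", cfg[c("surfaces", "extract")], f_series)
      res$series <- series; res$train_plots <- train_plots
    }
  }

  # ---- calibrate ----------------------------------------------------------
  if (isTRUE(st$calibrate)) {
    log_msg("[calibrate] families: %s",
            paste(cfg$calibrate$families, collapse = ", "))
    lid_series <- dplyr::filter(res$series, .data$sensor == "lidar")
    report <- train_test_protocol(lid_series, res$train_plots,
                                  cfg$calibrate$test_times,
                                  cfg$calibrate$families,
                                  seed = derive_seed(cfg$seed, 9L))
    best <- report$models[[report$best_family]]
    lid_series$predicted_m <- stats::predict(best, lid_series)
    f_metrics <- file.path(out_dir, "calibration_metrics.csv")
    readr::write_csv(report$metrics, f_metrics)
    f_pred <- file.path(out_dir, "predicted_heights.csv")
    readr::write_csv(lid_series, f_pred)
    add_stage("calibrate",
              c(cfg["calibrate"], list(best_family = report$best_family)),
              c(f_metrics, f_pred))
    res$calibration <- report; res$predicted <- lid_series
  }

  # ---- cluster ------------------------------------------------------------
  if (isTRUE(st$cluster)) {
    log_msg("[cluster] gap statistic over k = 1..%d", cfg$cluster$k_max)
    m <- series_matrix(res$predicted, "predicted_m")
    gap <- gap_statistic(m, seq_len(cfg$cluster$k_max), cfg$cluster$B,
                         seed = derive_seed(cfg$seed, 10L))
    cl <- cluster_growth(m, gap$chosen_k,
                         seed = derive_seed(cfg$seed, 11L))
    dyn <- cluster_dynamics(cl, m, times = res$truth$times)
    f_asg <- file.path(out_dir, "cluster_assignments.csv")
    readr::write_csv(cl$assignments, f_asg)
    f_sum <- file.path(out_dir, "cluster_summary.csv")
    readr::write_csv(dyn[, setdiff(names(dyn), "mean_curve")], f_sum)
    add_stage("cluster", c(cfg["cluster"], list(chosen_k = gap$chosen_k)),
              c(f_asg, f_sum))
    res$gap <- gap; res$clusters <- cl; res$dynamics <- dyn
  }

  # ---- gwas ---------------------------------------------------------------
  if (isTRUE(st$gwas)) {
    gw <- cfg$gwas
    log_msg("[gwas] scan at %d time points", cfg$growth$n_times)
    Gf <- filter_snps(res$G, gw$maf_min, gw$missing_max)
    K <- kinship_ibs(Gf)
    scans <- list()
    pf <- plot_footprints(design)
    scan_files <- character()
    for (tp in seq_len(cfg$growth$n_times)) {
      ph_tp <- res$predicted[res$predicted$time_point == tp, ]
      y <- tibble::tibble(
        accession = res$truth$accession[match(ph_tp$plot_id, pf$plot_id)],
        blue_m = ph_tp$predicted_m)
      y <- compute_blue(tibble::tibble(accession = y$accession,
                                       replicate = 1L, value_m = y$blue_m))
      scans[[as.character(tp)]] <- mixed_scan(y, Gf, K, time_point = tp)
      f <- file.path(out_dir, sprintf("scan_t%d.csv", tp))
      readr::write_csv(scans[[as.character(tp)]]$table, f)
      scan_files <- c(scan_files, f)
    }
    peaks <- significant_peaks(scans, gw$threshold, gw$merge_window)
    genes <- simulate_annotation(Gf$map, gw$n_genes,
                                 seed = derive_seed(cfg$seed, 12L))
    f_gff <- file.path(out_dir, "annotation.gff3")
    write_gff3(genes, f_gff)
    hits <- if (nrow(peaks)) genes_in_interval(genes, peaks) else genes[0, ]
    f_peaks <- file.path(out_dir, "peaks.tsv")
    pk_out <- peaks
    if (nrow(pk_out)) {
      pk_out$supporting <- vapply(pk_out$supporting, paste,
                                  character(1), collapse = ",")
      # BED-style 0-based half-open interval columns alongside 1-based
      pk_out$bed_start <- pk_out$start - 1L
      pk_out$bed_end <- pk_out$end
    }
    readr::write_tsv(pk_out, f_peaks)
    f_genes <- file.path(out_dir, "peak_genes.csv")
    readr::write_csv(hits, f_genes)
    qq <- export_scan(scans[[1]])
    f_man <- file.path(out_dir, "manhattan_t1.csv")
    readr::write_csv(qq$manhattan, f_man)
    f_qq <- file.path(out_dir, "qq_t1.csv")
    readr::write_csv(qq$qq, f_qq)
    add_stage("gwas", cfg["gwas"],
              c(scan_files, f_gff, f_peaks, f_genes, f_man, f_qq))
    res$scans <- scans; res$peaks <- peaks; res$genes <- genes
    res$peak_genes <- hits; res$G_filtered <- Gf; res$K <- K
  }

  f_manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, f_manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  res$manifest <- manifest
  class(res) <- "pipeline_run"
  res
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> seed %d, %d stages -> %s\n",
              x$config$seed, length(x$manifest$stages), x$out_dir))
  invisible(x)
}

#' Score a pipeline run against its generator truth
#'
#' The recovery dashboard: height-extraction RMSE per sensor, adjusted Rand
#' index of the growth clustering against the true cluster labels, and the
#' detection status of every planted causal SNP (top association score,
#' significance at the run's threshold, replicated-peak membership).
#'
#' @param run A `pipeline_run` from [run_pipeline()].
#' @return A list with `heights` (per-sensor RMSE tibble), `cluster_ari`,
#'   and `causal` (per-causal-SNP detection tibble).
#' @export
validate_against_truth <- function(run) {
  stopifnot(inherits(run, "pipeline_run"))
  if (is.null(run$truth)) stop("run carries no truth tables", call. = FALSE)
  out <- list()
  if (!is.null(run$series)) {
    out$heights <- run$series |>
      dplyr::group_by(.data$sensor) |>
      dplyr::summarise(
        n = sum(is.finite(.data$extracted_m)),
        rmse_m = sqrt(mean((.data$extracted_m - .data$truth_m)^2,
                           na.rm = TRUE)),
        bias_m = mean(.data$extracted_m - .data$truth_m, na.rm = TRUE),
        .groups = "drop")
  }
  if (!is.null(run$clusters)) {
    out$cluster_ari <- adjusted_rand_index(run$clusters$assignments$cluster,
                                           run$truth$cluster_id)
    out$chosen_k <- run$gap$chosen_k
  }
  if (!is.null(run$scans)) {
    tr <- run$G_filtered$truth
    thr <- run$config$gwas$threshold
    out$causal <- tibble::tibble(snp_id = character(),
                                 best_neg_log10_p = numeric(),
                                 n_times_significant = integer(),
                                 in_replicated_peak = logical())
    if (length(tr$causal_indices)) {
      causal_ids <- run$G_filtered$map$snp_id[tr$causal_indices]
      rows <- purrr::map_dfr(causal_ids, function(id) {
        best <- purrr::map_dbl(run$scans, function(s) {
          s$table$neg_log10_p[s$table$snp_id == id]
        })
        pos <- run$G_filtered$map$pos[run$G_filtered$map$snp_id == id]
        ch <- run$G_filtered$map$chrom[run$G_filtered$map$snp_id == id]
        in_rep_peak <- nrow(run$peaks) > 0 && any(
          run$peaks$replicated & run$peaks$chrom == ch &
            run$peaks$start <= pos & run$peaks$end >= pos)
        tibble::tibble(snp_id = id,
                       best_neg_log10_p = max(best),
                       n_times_significant = sum(best >= thr),
                       in_replicated_peak = in_rep_peak)
      })
      out$causal <- rows
    }
  }
  out
}
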