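#' Best linear unbiased estimates from replicated plots
#'
#' Accession phenotype estimates from a two-way fixed-effects model
#' (accession + replicate) fitted by least squares. The accession estimate
#' is the model prediction averaged over all replicate levels, so with a
#' balanced design and no replicate effect it equals the accession mean, a
#' constant replicate shift leaves relative values unchanged, and an
#' accession observed in a single record passes its value through (adjusted
#' only for the replicate effect estimated from the rest of the panel).
#'
#' @param records Tibble with columns `accession`, `replicate`, `value_m`
#'   (one row per replicate plot record).
#' @return A tibble `accession`, `blue_m`.
#' @export
compute_blue <- function(records) {
  stopifnot(all(c("accession", "replicate", "value_m") %in% names(records)))
  records <- records[is.finite(records$value_m), ]
  if (nrow(records) == 0) stop("empty phenotype table", call. = FALSE)
  acc <- factor(records$accession)
  rep_f <- factor(records$replicate)
  if (nlevels(rep_f) == 1L) {
    mu <- tapply(records$value_m, acc, mean)
    return(tibble::tibble(accession = names(mu), blue_m = as.numeric(mu)))
  }
  fit <- stats::lm(value_m ~ 0 + acc + rep_f,
                   data = data.frame(value_m = records$value_m,
                                     acc = acc, rep_f = rep_f))
  co <- stats::coef(fit)
  acc_co <- co[paste0("acc", levels(acc))]
  rep_co <- c(0, co[paste0("rep_f", levels(rep_f)[-1])])
  rep_co[is.na(rep_co)] <- 0
  tibble::tibble(accession = levels(acc),
                 blue_m = as.numeric(acc_co) + mean(rep_co))
}

#' Filter SNPs on minor allele frequency and missingness
#'
#' Keeps SNPs with minor allele frequency strictly greater than `maf_min`
#' and missing-call fraction strictly below `missing_max` (the PLINK-style
#' "MAF > 0.05, missing rate < 10 %" rule). MAF is computed from non-missing
#' calls. Planted causal indices stored with the matrix are remapped to the
#' filtered coordinates.
#'
#' @param G A `genotype_matrix`.
#' @param maf_min MAF threshold (exclusive).
#' @param missing_max Missing-fraction threshold (exclusive).
#' @return The filtered `genotype_matrix`.
#' @export
filter_snps <- function(G, maf_min = 0.05, missing_max = 0.10) {
  stopifnot(inherits(G, "genotype_matrix"))
  stats_tbl <- snp_stats(G)
  keep <- which(stats_tbl$maf > maf_min & stats_tbl$missing < missing_max)
  out <- G
  out$dosages <- G$dosages[, keep, drop = FALSE]
  out$map <- G$map[keep, ]
  if (!is.null(G$truth) && length(G$truth$causal_indices)) {
    remap <- match(G$truth$causal_indices, keep)
    out$truth$causal_indices <- remap[!is.na(remap)]
    out$truth$effect_sizes <- G$truth$effect_sizes[!is.na(remap)]
  }
  out
}

#' Per-SNP allele frequency and missingness
#'
#' @param G A `genotype_matrix`.
#' @return A tibble `snp_id`, `chrom`, `pos`, `maf`, `missing`.
#' @export
snp_stats <- function(G) {
  dos <- G$dosages
  n <- nrow(dos)
  miss <- colMeans(is.na(dos))
  p <- colMeans(dos, na.rm = TRUE) / 2
  p[is.nan(p)] <- 0
  tibble::tibble(snp_id = G$map$snp_id, chrom = G$map$chrom,
                 pos = G$map$pos, maf = pmin(p, 1 - p), missing = miss)
}

# mean-impute missing dosages per SNP
impute_dosages <- function(dos) {
  cm <- colMeans(dos, na.rm = TRUE)
  cm[is.nan(cm)] <- 0
  na_ix <- which(is.na(dos), arr.ind = TRUE)
  if (nrow(na_ix)) dos[na_ix] <- cm[na_ix[, 2]]
  dos
}

#' Identity-by-state kinship matrix
#'
#' Pairwise IBS similarity between samples:
#' `K[i, j] = 1 - mean(|g_i - g_j|) / 2` over SNPs, after per-SNP mean
#' imputation of missing calls. Values lie in `[0, 1]`, the matrix is
#' symmetric and its diagonal is 1; duplicated samples get off-diagonal 1.
#'
#' @param G A `genotype_matrix` (ideally already passed through
#'   [filter_snps()]).
#' @return An n x n numeric matrix with sample ids as dimnames.
#' @export
kinship_ibs <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  dos <- impute_dosages(G$dosages)
  m <- ncol(dos)
  if (m == 0) stop("no SNPs in genotype matrix", call. = FALSE)
  D <- as.matrix(stats::dist(dos, method = "manhattan"))
  K <- 1 - D / (2 * m)
  dimnames(K) <- list(G$sample_ids, G$sample_ids)
  K
}

# EMMA-style REML fit of the variance ratio delta = sigma_e^2 / sigma_g^2
# on the eigenbasis of S K S, S the projection off the null fixed effects.
reml_null <- function(y, K, X0, tol = 1e-8) {
  n <- length(y)
  p <- ncol(X0)
  S <- diag(n) - X0 %*% solve(crossprod(X0), t(X0))
  M <- S %*% K %*% S
  M <- (M + t(M)) / 2
  eg <- eigen(M, symmetric = TRUE)
  q <- n - p
  th <- eg$values[seq_len(q)]
  th[th < 1e-10] <- 1e-10
  U <- eg$vectors[, seq_len(q), drop = FALSE]
  eta <- drop(crossprod(U, y))
  ll <- function(ldelta) {
    d <- 10^ldelta
    h <- th + d
    0.5 * (q * log(q / (2 * pi)) - q - q * log(sum(eta^2 / h)) -
             sum(log(h)))
  }
  grid <- seq(-6, 6, length.out = 61)
  vals <- vapply(grid, ll, numeric(1))
  i <- which.max(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(ll, c(lo, hi), maximum = TRUE, tol = tol)
  delta <- 10^opt$maximum
  sigma_g2 <- sum(eta^2 / (th + delta)) / q
  list(delta = delta, sigma_g2 = sigma_g2, sigma_e2 = delta * sigma_g2)
}

#' Kinship-corrected genome-wide association scan
#'
#' The EMMAX approximation to the single-marker mixed model
#' `y = X0 b + g beta + u + e`, `u ~ N(0, sigma_g^2 K)`: the variance
#' components are estimated once under the null model by REML on the
#' eigenbasis of the kinship matrix, the phenotype and designs are rotated
#' into that basis, and each SNP is tested by generalized least squares with
#' a Wald t-test on the allele-dosage effect. With `K = I` the scan reduces
#' exactly to per-SNP ordinary least squares.
#'
#' @param y Per-accession phenotype: a named numeric vector or a tibble with
#'   `accession` and a value column (`blue_m` or `value_m`).
#' @param G A `genotype_matrix`; missing dosages are mean-imputed.
#' @param K Kinship matrix from [kinship_ibs()] (or any PSD relatedness
#'   matrix aligned to the samples).
#' @param covariates Optional numeric matrix of covariates (e.g. principal
#'   components), rows aligned to samples.
#' @param time_point Optional label recorded in the result.
#' @return A `scan_result`: per-SNP tibble (`snp_id`, `chrom`, `pos`,
#'   `effect`, `se`, `p_value`, `neg_log10_p`) plus variance components.
#' @export
mixed_scan <- function(y, G, K, covariates = NULL, time_point = NA) {
  stopifnot(inherits(G, "genotype_matrix"))
  ids <- G$sample_ids
  if (is.data.frame(y)) {
    vcol <- intersect(c("blue_m", "value_m", "value"), names(y))[1]
    if (is.na(vcol)) stop("no phenotype value column found", call. = FALSE)
    yv <- y[[vcol]][match(ids, y$accession)]
  } else {
    yv <- if (!is.null(names(y))) y[ids] else y
  }
  if (anyNA(yv)) stop("phenotype and genotype samples do not align",
                      call. = FALSE)
  yv <- as.numeric(yv)
  n <- length(yv)
  if (!all(dim(K) == n)) stop("kinship dimension mismatch", call. = FALSE)
  K <- (K + t(K)) / 2
  if (min(eigen(K, symmetric = TRUE, only.values = TRUE)$values) < -1e-6) {
    stop("kinship matrix is not positive semi-definite", call. = FALSE)
  }
  X0 <- cbind(`(Intercept)` = rep(1, n), covariates)
  vc <- reml_null(yv, K, X0)

  eg <- eigen(K, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  w <- 1 / (d + vc$delta)
  Ut <- t(eg$vectors)
  sw <- sqrt(w)
  yt <- sw * drop(Ut %*% yv)
  X0t <- sw * (Ut %*% X0)
  Gt <- sw * (Ut %*% impute_dosages(G$dosages))

  # residualise phenotype and dosages on the null design under GLS weights
  P <- solve(crossprod(X0t), t(X0t))
  ey <- yt - X0t %*% (P %*% yt)
  EG <- Gt - X0t %*% (P %*% Gt)
  gg <- colSums(EG^2)
  gy <- drop(crossprod(EG, ey))
  dfree <- n - ncol(X0t) - 1L
  beta <- ifelse(gg > 1e-12, gy / gg, NA_real_)
  rss <- sum(ey^2) - ifelse(is.na(beta), 0, beta^2 * gg)
  se <- sqrt(pmax(rss, 0) / dfree / gg)
  tstat <- beta / se
  pval <- 2 * stats::pt(-abs(tstat), dfree)
  pval[!is.na(pval) & pval < .Machine$double.xmin] <- .Machine$double.xmin

  structure(list(
    table = tibble::tibble(
      snp_id = G$map$snp_id, chrom = G$map$chrom, pos = G$map$pos,
      effect = unname(beta), se = unname(se), p_value = unname(pval),
      neg_log10_p = unname(-log10(pval))),
    sigma_g2 = vc$sigma_g2, sigma_e2 = vc$sigma_e2, delta = vc$delta,
    n = n, time_point = time_point
  ), class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf(
    "<scan_result> %d SNPs, n = %d, sigma_g2 = %.4g, sigma_e2 = %.4g\n",
    nrow(x$table), x$n, x$sigma_g2, x$sigma_e2))
  top <- x$table[order(x$table$p_value), ][1:min(3, nrow(x$table)), ]
  print(top)
  invisible(x)
}

#' @method tidy scan_result
#' @export
tidy.scan_result <- function(x, ...) x$table

#' @method glance scan_result
#' @export
glance.scan_result <- function(x, ...) {
  tibble::tibble(n = x$n, n_snps = nrow(x$table), sigma_g2 = x$sigma_g2,
                 sigma_e2 = x$sigma_e2, delta = x$delta,
                 lambda_gc = genomic_lambda(x))
}

#' Genomic-control lambda of a scan
#'
#' Median association chi-square statistic divided by its null median; ~1
#' indicates calibrated p-values, values well above 1 indicate residual
#' confounding (e.g. uncorrected population structure).
#'
#' @param scan A `scan_result` or a numeric vector of p-values.
#' @return Lambda (numeric).
#' @export
genomic_lambda <- function(scan) {
  p <- if (inherits(scan, "scan_result")) scan$table$p_value else scan
  p <- p[is.finite(p)]
  chi <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  stats::median(chi) / stats::qchisq(0.5, df = 1, lower.tail = FALSE)
}

#' Merge significant SNPs into association peaks
#'
#' SNPs reaching `threshold` (in -log10 p, inclusive) are grouped into peaks
#' per chromosome and time point whenever the gap to the next significant
#' SNP is below `merge_window`. A peak is flagged replicated when its
#' interval intersects a peak from at least one other time point on the same
#' chromosome.
#'
#' @param scans A `scan_result` or a list of them (one per time point).
#' @param threshold Significance threshold on -log10 p (default 5).
#' @param merge_window Maximum gap (bp) between significant SNPs in one
#'   peak.
#' @return A tibble of peaks: `time_point`, `chrom`, `start`, `end`,
#'   `n_snps`, `top_snp`, `top_neg_log10_p`, `replicated`, `supporting`.
#' @export
significant_peaks <- function(scans, threshold = 5, merge_window = 5e5) {
  if (inherits(scans, "scan_result")) scans <- list(scans)
  if (is.null(names(scans))) {
    names(scans) <- vapply(seq_along(scans), function(i) {
      tp <- scans[[i]]$time_point
      if (is.na(tp)) as.character(i) else as.character(tp)
    }, character(1))
  }
  peak_rows <- purrr::imap(scans, function(s, nm) {
    tab <- s$table[!is.na(s$table$neg_log10_p) &
                     s$table$neg_log10_p >= threshold, ]
    if (nrow(tab) == 0) return(NULL)
    tab <- tab[order(tab$chrom, tab$pos), ]
    purrr::map_dfr(split(tab, tab$chrom), function(ch) {
      brk <- c(0, cumsum(diff(ch$pos) >= merge_window))
      purrr::map_dfr(split(ch, brk), function(pk) {
        top <- which.max(pk$neg_log10_p)
        tibble::tibble(
          time_point = nm, chrom = pk$chrom[1],
          start = min(pk$pos), end = max(pk$pos), n_snps = nrow(pk),
          top_snp = pk$snp_id[top], top_neg_log10_p = pk$neg_log10_p[top])
      })
    })
  })
  peaks <- dplyr::bind_rows(peak_rows)
  if (nrow(peaks) == 0) {
    return(tibble::tibble(time_point = character(), chrom = character(),
                          start = integer(), end = integer(),
                          n_snps = integer(), top_snp = character(),
                          top_neg_log10_p = numeric(),
                          replicated = logical(), supporting = list()))
  }
  peaks$supporting <- purrr::pmap(
    peaks[, c("time_point", "chrom", "start", "end")],
    function(time_point, chrom, start, end) {
      hit <- peaks$chrom == chrom & peaks$start <= end & peaks$end >= start
      sort(unique(peaks$time_point[hit]))
    })
  peaks$replicated <- vapply(peaks$supporting, function(s) length(s) > 1,
                             logical(1))
  peaks
}

#' Genes overlapping a peak interval
#'
#' Returns annotation records whose `[start, end]` overlaps the query
#' interval by at least 1 bp, with 1-based inclusive coordinates as in GFF3;
#' a gene exactly abutting the interval end is included.
#'
#' @param genes Gene table with `gene_id`, `chrom`, `start`, `end` (see
#'   [read_gff3()]).
#' @param peaks A peak tibble (see [significant_peaks()]) or a one-row
#'   data frame / list with `chrom`, `start`, `end`.
#' @return The overlapping gene rows, with `peak_chrom`, `peak_start`,
#'   `peak_end` columns identifying the query.
#' @export
genes_in_interval <- function(genes, peaks) {
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(genes)))
  if (any(!is.finite(genes$start) | !is.finite(genes$end) |
            genes$start > genes$end)) {
    stop("malformed annotation record", call. = FALSE)
  }
  if (!is.data.frame(peaks)) peaks <- tibble::as_tibble(peaks[c("chrom",
                                                                "start",
                                                                "end")])
  gr_genes <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start, genes$end))
  gr_peaks <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(peaks$start, peaks$end))
  hits <- GenomicRanges::findOverlaps(gr_genes, gr_peaks)
  out <- genes[S4Vectors::queryHits(hits), ]
  pk <- peaks[S4Vectors::subjectHits(hits), ]
  out$peak_chrom <- pk$chrom
  out$peak_start <- pk$start
  out$peak_end <- pk$end
  dplyr::distinct(out)
}

#' Compare phenotypes between two-SNP haplotype groups
#'
#' Partitions accessions by their joint homozygous genotype at two SNPs
#' (heterozygous or missing calls at either SNP are excluded), takes the two
#' most frequent joint genotypes as the haplotype groups, and tests the
#' group mean difference per time point with Welch's t-test.
#'
#' @param G A `genotype_matrix` containing both SNPs.
#' @param snp_ids Character vector of exactly two SNP ids.
#' @param pheno Long phenotype tibble: `accession`, `time_point`, `value_m`.
#' @return A `haplotype_comparison`: `groups` tibble (`accession`,
#'   `haplotype`) and `tests` tibble (`time_point`, group means, `diff_m`,
#'   `p_value`).
#' @export
haplotype_compare <- function(G, snp_ids, pheno) {
  stopifnot(length(snp_ids) == 2)
  miss <- setdiff(snp_ids, G$map$snp_id)
  if (length(miss)) {
    stop("SNP(s) not present: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  d <- G$dosages[, snp_ids, drop = FALSE]
  hom <- !is.na(d[, 1]) & !is.na(d[, 2]) & d[, 1] %in% c(0, 2) &
    d[, 2] %in% c(0, 2)
  joint <- paste(d[hom, 1], d[hom, 2], sep = "|")
  if (length(unique(joint)) < 2) {
    stop("all accessions carry a single haplotype", call. = FALSE)
  }
  tab <- sort(table(joint), decreasing = TRUE)
  hap_names <- names(tab)[1:2]
  if (any(tab[1:2] < 3)) stop("haplotype group with fewer than 3 accessions",
                              call. = FALSE)
  groups <- tibble::tibble(
    accession = G$sample_ids[hom][joint %in% hap_names],
    haplotype = ifelse(joint[joint %in% hap_names] == hap_names[1],
                       "Hap1", "Hap2"))
  ph <- dplyr::inner_join(pheno, groups, by = "accession")
  tests <- ph |>
    dplyr::group_by(.data$time_point) |>
    dplyr::summarise(
      n_hap1 = sum(.data$haplotype == "Hap1"),
      n_hap2 = sum(.data$haplotype == "Hap2"),
      mean_hap1 = mean(.data$value_m[.data$haplotype == "Hap1"]),
      mean_hap2 = mean(.data$value_m[.data$haplotype == "Hap2"]),
      diff_m = .data$mean_hap1 - .data$mean_hap2,
      p_value = stats::t.test(
        .data$value_m[.data$haplotype == "Hap1"],
        .data$value_m[.data$haplotype == "Hap2"])$p.value,
      .groups = "drop")
  structure(list(groups = groups, tests = tests,
                 haplotypes = stats::setNames(hap_names, c("Hap1", "Hap2"))),
            class = "haplotype_comparison")
}

#' @export
print.haplotype_comparison <- function(x, ...) {
  cat(sprintf("<haplotype_comparison> Hap1 = %s (n=%d), Hap2 = %s (n=%d)\n",
              x$haplotypes[1], sum(x$groups$haplotype == "Hap1"),
              x$haplotypes[2], sum(x$groups$haplotype == "Hap2")))
  print(x$tests)
  invisible(x)
}

#' Manhattan and QQ export tables
#'
#' Per-SNP table with a cumulative genome coordinate for Manhattan plotting
#' and a QQ table of observed vs expected -log10 p under the uniform null
#' (expected quantiles `-log10((i - 0.5) / n)`).
#'
#' @param scan A `scan_result`.
#' @param chrom_gap Cosmetic gap (bp) between chromosomes on the cumulative
#'   axis.
#' @return A list with `manhattan` and `qq` tibbles.
#' @export
export_scan <- function(scan, chrom_gap = 5e6) {
  tab <- scan$table
  chroms <- unique(tab$chrom)
  offs <- stats::setNames(numeric(length(chroms)), chroms)
  run <- 0
  for (ch in chroms) {
    offs[ch] <- run
    run <- run + max(tab$pos[tab$chrom == ch]) + chrom_gap
  }
  man <- tab
  man$cum_pos <- man$pos + offs[man$chrom]
  man <- man[order(man$cum_pos), ]
  p <- sort(tab$p_value[is.finite(tab$p_value)])
  n <- length(p)
  qq <- tibble::tibble(
    expected = -log10((seq_len(n) - 0.5) / n),
    observed = -log10(p))
  list(manhattan = man, qq = qq)
}

#' @method autoplot scan_result
#' @export
autoplot.scan_result <- function(object, threshold = 5, ...) {
  man <- export_scan(object)$manhattan
  ggplot2::ggplot(man, ggplot2::aes(x = .data$cum_pos / 1e6,
                                    y = .data$neg_log10_p,
                                    colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2) +
    ggplot2::labs(x = "cumulative position (Mb)",
                  y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}

#' QQ plot of a scan
#'
#' @param scan A `scan_result`.
#' @return A ggplot object.
#' @export
plot_qq <- function(scan) {
  qq <- export_scan(scan)$qq
  ggplot2::ggplot(qq, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = expression(Expected ~ -log[10](p)),
                  y = expression(Observed ~ -log[10](p))) +
    ggplot2::theme_minimal()
}
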