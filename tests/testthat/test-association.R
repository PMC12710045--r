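test_that("BLUE equals accession means on balanced designs and absorbs replicate shifts", {
  base <- tibble::tibble(
    accession = rep(c("A", "B", "C"), each = 3),
    replicate = rep(1:3, 3),
    value_m = c(1.0, 1.1, 0.9, 1.4, 1.5, 1.3, 0.8, 0.9, 0.7))
  b <- compute_blue(base)
  expect_equal(b$blue_m, as.numeric(tapply(base$value_m, base$accession,
                                           mean)))

  # +0.1 m on every replicate-2 plot: relative BLUEs unchanged
  shifted <- base
  shifted$value_m[shifted$replicate == 2] <-
    shifted$value_m[shifted$replicate == 2] + 0.1
  b2 <- compute_blue(shifted)
  expect_equal(diff(b2$blue_m), diff(b$blue_m), tolerance = 1e-12)

  single <- tibble::tibble(accession = "X", replicate = 1, value_m = 0.77)
  expect_equal(compute_blue(single)$blue_m, 0.77)
  expect_error(compute_blue(single[0, ]), "empty")
})

test_that("SNP filter applies strict MAF and missingness rules", {
  dos <- rbind(
    c(0, 0, 2, 0, 1),
    c(0, 1, 2, NA, 1),
    c(0, 0, 2, NA, 1),
    c(1, 0, 2, 0, 1),
    c(0, 0, 2, 0, 1),
    c(0, 0, 2, 0, 1),
    c(0, 1, 2, 0, 1),
    c(0, 0, 2, 0, 1),
    c(0, 0, 2, 0, 1),
    c(0, 0, 2, 0, 1))
  G <- structure(list(
    dosages = dos,
    map = tibble::tibble(snp_id = paste0("s", 1:5), chrom = "A01",
                         pos = as.integer(1:5 * 1000)),
    sample_ids = sprintf("S%02d", 1:10), subpop = NULL, truth = NULL),
    class = "genotype_matrix")
  # s1: 1/20 alleles = 0.05, not > 0.05 -> dropped
  # s2: 2/20 = 0.10 -> kept; s3: monomorphic (MAF 0) -> dropped
  # s4: 2/10 samples missing (20 %) -> dropped; s5: MAF 0.5 -> kept
  Gf <- filter_snps(G)
  expect_equal(Gf$map$snp_id, c("s2", "s5"))

  # 4-sample toy: dosages (0,0,0,1) -> MAF 0.125 > 0.05, kept
  G4 <- structure(list(
    dosages = matrix(c(0, 0, 0, 1), 4, 1),
    map = tibble::tibble(snp_id = "t1", chrom = "A01", pos = 1L),
    sample_ids = paste0("S", 1:4), subpop = NULL, truth = NULL),
    class = "genotype_matrix")
  expect_equal(snp_stats(G4)$maf, 0.125)
  expect_equal(ncol(filter_snps(G4)$dosages), 1)

  # idempotent, and output is always a column subset of input
  expect_identical(filter_snps(Gf)$map, Gf$map)
  expect_true(all(Gf$map$snp_id %in% G$map$snp_id))
})

test_that("IBS kinship matches the brute-force pairwise loop", {
  G <- generate_genotypes(25, 60, missing_rate = 0.05, seed = 3)
  K <- kinship_ibs(G)
  dos <- phenoheight:::impute_dosages(G$dosages)
  oracle <- matrix(0, 25, 25)
  for (i in 1:25) {
    for (j in 1:25) {
      oracle[i, j] <- 1 - mean(abs(dos[i, ] - dos[j, ])) / 2
    }
  }
  expect_equal(unname(K), oracle, tolerance = 1e-12)
  expect_equal(unname(diag(K)), rep(1, 25))
  expect_equal(K, t(K))
  expect_true(all(K >= 0 & K <= 1))

  # duplicated sample: off-diagonal 1
  G$dosages[2, ] <- G$dosages[1, ]
  K2 <- kinship_ibs(G)
  expect_equal(unname(K2[1, 2]), 1)
})

test_that("mixed scan with identity kinship reproduces OLS per-SNP tests", {
  G <- generate_genotypes(120, 150, missing_rate = 0.02, seed = 6)
  set.seed(7)
  y <- stats::setNames(rnorm(120, 1, 0.1) + 0.05 * ifelse(
    is.na(G$dosages[, 10]), 1, G$dosages[, 10]), G$sample_ids)
  s <- mixed_scan(y, G, diag(120))
  dos <- phenoheight:::impute_dosages(G$dosages)
  for (j in c(1, 10, 50, 150)) {
    pv <- summary(lm(y ~ dos[, j]))$coefficients[2, 4]
    expect_lt(abs(log10(pv) - log10(s$table$p_value[j])), 0.01)
  }
  expect_true(all(s$table$p_value > 0 & s$table$p_value <= 1))
  expect_equal(s$table$neg_log10_p, -log10(s$table$p_value))

  expect_error(mixed_scan(y, G, diag(10)), "dimension")
  badK <- diag(120); badK[1, 1] <- -2
  expect_error(mixed_scan(y, G, badK), "positive semi-definite")
  expect_error(mixed_scan(y[-1], G, diag(119)), "align|dimension")
})

test_that("kinship correction calibrates a structured null that OLS inflates", {
  gt <- genotype_truth(h2 = 0.5, n_subpop = 2, fst_like = 0.1,
                       polygenic_share = 1)
  G <- generate_genotypes(200, 800, missing_rate = 0.02, truth = gt,
                          seed = 21)
  ph <- generate_phenotypes(G, n_reps = 1, seed = 22)
  y <- stats::setNames(ph$accession$value_m, ph$accession$accession)
  Gf <- filter_snps(G)
  s_mixed <- mixed_scan(y, Gf, kinship_ibs(Gf))
  s_naive <- mixed_scan(y, Gf, diag(200))
  expect_lt(genomic_lambda(s_mixed), 1.25)
  expect_gt(genomic_lambda(s_naive), 1.2)
  expect_gt(genomic_lambda(s_naive), genomic_lambda(s_mixed))
})

test_that("significant SNPs merge into peaks and replicate across time points", {
  mk_scan <- function(pos, nlp, chrom = "A01") {
    structure(list(table = tibble::tibble(
      snp_id = sprintf("%s_%d", chrom, pos), chrom = chrom,
      pos = as.integer(pos), effect = 0.1, se = 0.01,
      p_value = 10^(-nlp), neg_log10_p = nlp),
      sigma_g2 = 1, sigma_e2 = 1, delta = 1, n = 100, time_point = NA),
      class = "scan_result")
  }
  s1 <- mk_scan(c(3750000, 3800000, 3880000, 10000000, 20000000),
                c(6, 7, 5.5, 6, 2))
  pk <- significant_peaks(list(t1 = s1), threshold = 5)
  expect_equal(nrow(pk), 2)
  expect_equal(pk$start[1], 3750000)
  expect_equal(pk$end[1], 3880000)
  expect_equal(pk$n_snps, c(3L, 1L))
  expect_equal(pk$top_snp[1], "A01_3800000")
  expect_false(any(pk$replicated))
  # non-overlap of merged peaks within a time point
  expect_true(all(pk$end[-nrow(pk)] < pk$start[-1]))

  pk2 <- significant_peaks(list(t1 = s1, t2 = s1), threshold = 5)
  expect_true(all(pk2$replicated))
  expect_equal(pk2$supporting[[1]], c("t1", "t2"))

  none <- mk_scan(1e6, 2)
  expect_equal(nrow(significant_peaks(none, threshold = 5)), 0)
})

test_that("gene lookup uses 1-based inclusive overlap", {
  genes <- tibble::tibble(
    gene_id = c("g1", "g2", "g3"),
    chrom = "A01",
    start = c(100L, 900L, 5000L),
    end = c(500L, 1500L, 6000L))
  peak <- tibble::tibble(chrom = "A01", start = 400L, end = 1000L)
  hit <- genes_in_interval(genes, peak)
  expect_setequal(hit$gene_id, c("g1", "g2"))

  desert <- tibble::tibble(chrom = "A01", start = 2000L, end = 3000L)
  expect_equal(nrow(genes_in_interval(genes, desert)), 0)

  # gene starting exactly at the peak end is included (inclusive coords)
  abut <- tibble::tibble(chrom = "A01", start = 4000L, end = 5000L)
  expect_equal(genes_in_interval(genes, abut)$gene_id, "g3")

  bad <- genes; bad$end[1] <- 50L
  expect_error(genes_in_interval(bad, peak), "malformed")
})

test_that("haplotype groups separate phenotypes with a planted effect", {
  G <- generate_genotypes(400, 40, missing_rate = 0, seed = 31)
  G$dosages[, 2] <- G$dosages[, 1]   # two SNPs in perfect LD
  d <- G$dosages[, 1]
  set.seed(32)
  ph <- tidyr::expand_grid(accession = G$sample_ids, time_point = 1:3)
  ph$value_m <- 1 + 0.05 * d[match(ph$accession, G$sample_ids)] +
    rnorm(nrow(ph), 0, 0.03)
  hc <- haplotype_compare(G, G$map$snp_id[1:2], ph)
  expect_equal(nrow(hc$tests), 3)
  expect_equal(abs(hc$tests$diff_m), rep(0.1, 3), tolerance = 0.05)
  expect_true(all(hc$tests$p_value < 0.01))
  # heterozygous accessions excluded from both groups
  het <- G$sample_ids[d == 1]
  expect_false(any(het %in% hc$groups$accession))

  Gmono <- G; Gmono$dosages[, 1:2] <- 0
  expect_error(haplotype_compare(Gmono, G$map$snp_id[1:2], ph), "single")
  expect_error(haplotype_compare(G, c("nope_1", G$map$snp_id[2]), ph),
               "not present")
})

test_that("null haplotype comparison shows no systematic difference", {
  G <- generate_genotypes(400, 40, missing_rate = 0, seed = 41)
  G$dosages[, 2] <- G$dosages[, 1]
  pvals <- vapply(1:10, function(r) {
    set.seed(100 + r)
    ph <- tibble::tibble(accession = G$sample_ids, time_point = 1L,
                         value_m = rnorm(400, 1, 0.1))
    haplotype_compare(G, G$map$snp_id[1:2], ph)$tests$p_value
  }, numeric(1))
  expect_gt(min(pvals), 1e-4)
  expect_gt(mean(pvals > 0.05), 0.5)
})

test_that("scan export produces QQ quantiles and monotone genome coordinates", {
  G <- generate_genotypes(80, 120, missing_rate = 0, seed = 51)
  set.seed(52)
  y <- stats::setNames(rnorm(80, 1, 0.1), G$sample_ids)
  s <- mixed_scan(y, G, kinship_ibs(G))
  ex <- export_scan(s)
  n <- nrow(s$table)
  expect_equal(ex$qq$expected, -log10((seq_len(n) - 0.5) / n))
  expect_true(all(diff(ex$qq$observed) <= 1e-12))
  expect_true(all(diff(ex$manhattan$cum_pos) > 0))

  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(ex$manhattan, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(back$neg_log10_p, ex$manhattan$neg_log10_p, tolerance = 1e-12)
})

test_that("VCF and GFF3 round-trips preserve genotype and annotation content", {
  G <- generate_genotypes(15, 40, missing_rate = 0.1, seed = 61)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(G, vcf)
  G2 <- read_vcf(vcf)
  expect_equal(unname(G2$dosages), unname(G$dosages))
  expect_equal(G2$map$pos, G$map$pos)
  expect_equal(G2$sample_ids, G$sample_ids)

  genes <- simulate_annotation(G$map, 25, seed = 62)
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(genes, gff)
  back <- read_gff3(gff)
  expect_equal(back$gene_id, genes$gene_id)
  expect_equal(back$start, genes$start)
  expect_equal(back$end, genes$end)
  expect_equal(is.na(back$annotation), is.na(genes$annotation))
})
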