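#' Genotype matrix VCF I/O
#'
#' Writes a `genotype_matrix` as VCF 4.2 with unphased GT calls (dosage 0 =
#' `0/0`, 1 = `0/1`, 2 = `1/1`, missing = `./.`) and reads one back through
#' `vcfR`. Round-tripping preserves dosages, sample ids and the SNP map.
#'
#' @param G A `genotype_matrix`.
#' @param path VCF path (plain text; a `.gz` suffix gzips transparently).
#' @return `write_vcf` returns `path` invisibly; `read_vcf` returns a
#'   `genotype_matrix` (with no simulation truth attached).
#' @export
write_vcf <- function(G, path) {
  stopifnot(inherits(G, "genotype_matrix"))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  dos <- G$dosages
  m <- ncol(dos)
  body <- vapply(seq_len(m), function(j) {
    gt <- gt_code[as.character(dos[, j])]
    gt[is.na(gt)] <- "./."
    paste(c(G$map$chrom[j], G$map$pos[j], G$map$snp_id[j], "A", "G",
            ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=phenoheight",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", G$sample_ids), collapse = "\t"),
    body), con)
  invisible(path)
}

#' @rdname write_vcf
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_integer_, nrow = ncol(gt), ncol = nrow(gt))
  gt_num <- matrix(NA_integer_, nrow(gt), ncol(gt))
  gt_num[gt %in% c("0/0", "0|0")] <- 0L
  gt_num[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  gt_num[gt %in% c("1/1", "1|1")] <- 2L
  dos <- t(gt_num)
  fix <- vcfR::getFIX(v)
  map <- tibble::tibble(snp_id = fix[, "ID"], chrom = fix[, "CHROM"],
                        pos = as.integer(fix[, "POS"]))
  sample_ids <- colnames(gt)
  dimnames(dos) <- list(sample_ids, map$snp_id)
  structure(list(dosages = dos, map = map, sample_ids = sample_ids,
                 subpop = NULL, truth = NULL),
            class = "genotype_matrix")
}

#' Toy gene annotation and GFF3 I/O
#'
#' `write_gff3` writes a gene table as GFF3; `read_gff3` imports gene
#' records from any GFF3 via `rtracklayer` and returns the tibble consumed
#' by [genes_in_interval()]. `simulate_annotation` scatters genes of
#' realistic size uniformly along each chromosome of a SNP map, with a
#' fraction carrying a functional annotation.
#'
#' @param genes Gene tibble: `gene_id`, `chrom`, `start`, `end`, optional
#'   `annotation`.
#' @param path GFF3 path.
#' @return `write_gff3` returns `path` invisibly; `read_gff3` returns a
#'   gene tibble.
#' @export
write_gff3 <- function(genes, path) {
  attr_col <- if ("annotation" %in% names(genes)) {
    ifelse(is.na(genes$annotation) | genes$annotation == "",
           sprintf("ID=%s", genes$gene_id),
           sprintf("ID=%s;Note=%s", genes$gene_id, genes$annotation))
  } else sprintf("ID=%s", genes$gene_id)
  lines <- sprintf("%s\tphenoheight\tgene\t%d\t%d\t.\t+\t.\t%s",
                   genes$chrom, genes$start, genes$end, attr_col)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' @rdname write_gff3
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
  md <- S4Vectors::mcols(gr)
  note <- if ("Note" %in% names(md)) {
    vapply(md$Note, function(x) if (length(x)) as.character(x[[1]])
           else NA_character_, character(1))
  } else rep(NA_character_, length(gr))
  tibble::tibble(
    gene_id = as.character(md$ID),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    annotation = note)
}

#' @rdname write_gff3
#' @param map SNP map tibble (`chrom`, `pos`) whose chromosome extents the
#'   genes should cover.
#' @param n_genes Number of genes to place.
#' @param annotated_frac Fraction of genes given a functional annotation.
#' @param seed RNG seed.
#' @export
simulate_annotation <- function(map, n_genes = 200, annotated_frac = 0.4,
                                seed = 1L) {
  chroms <- unique(map$chrom)
  with_seed(derive_seed(seed, 811L), {
    ch <- sample(chroms, n_genes, replace = TRUE)
    max_pos <- vapply(chroms, function(c) max(map$pos[map$chrom == c]),
                      numeric(1))
    start <- floor(stats::runif(n_genes, 1, max_pos[ch]))
    len <- pmax(500L, stats::rnbinom(n_genes, mu = 3000, size = 2))
    ann <- ifelse(stats::runif(n_genes) < annotated_frac,
                  sprintf("putative growth regulator %d",
                          seq_len(n_genes)), NA_character_)
    out <- tibble::tibble(
      gene_id = sprintf("GENE%04d", seq_len(n_genes)),
      chrom = ch, start = as.integer(start),
      end = as.integer(start + len), annotation = ann)
    out[order(out$chrom, out$start), ]
  })
}
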