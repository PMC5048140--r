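#' Watterson's estimator of nucleotide diversity per site
#'
#' `theta = S / (H_{n-1} * L)` where `S` is the number of segregating sites
#' observed among `n` sequences over `L` base pairs and `H_{n-1}` is the
#' harmonic number `sum(1/i, i = 1..n-1)`. A monomorphic gene (`S = 0`) has
#' theta 0. All arguments recycle.
#'
#' @param S Integer count(s) of segregating sites.
#' @param n Number of sequences sampled (2 per diploid individual); must be
#'   at least 2.
#' @param L Sequence length in bp; must be positive.
#' @return Per-site theta estimate(s).
#' @export
#' @examples
#' watterson_theta(S = 5, n = 2, L = 1000)  # 0.005
watterson_theta <- function(S, n, L) {
  if (any(L <= 0)) abort("sequence length must be positive")
  if (any(n < 2)) abort("need at least 2 sequences")
  if (any(S < 0)) abort("segregating-site counts must be non-negative")
  S / (harmonic_number(n - 1) * L)
}

harmonic_number <- function(k) {
  vapply(k, function(ki) sum(1 / seq_len(ki)), numeric(1))
}

#' Read a BED table of gene spans
#'
#' BED is 0-based half-open: a gene covering reference bases 1..L (1-based)
#' has `start = 0`, `end = L`. One interval per gene.
#'
#' @param path BED file (3 columns plus a 4th gene-id column; no header).
#' @return Tibble with `chrom`, `start`, `end`, `gene_id`, and derived
#'   `length_bp`.
#' @export
read_gene_bed <- function(path) {
  x <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "gene_id"),
                       show_col_types = FALSE, progress = FALSE)
  if (anyDuplicated(x$gene_id)) abort("duplicate gene entries in BED")
  if (any(x$end <= x$start)) abort("BED intervals must have end > start")
  dplyr::mutate(x, length_bp = .data$end - .data$start)
}

#' @rdname read_gene_bed
#' @param bed Tibble as returned by `read_gene_bed()`.
#' @export
write_gene_bed <- function(bed, path) {
  readr::write_tsv(bed[c("chrom", "start", "end", "gene_id")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(bed)
}

#' Per-gene segregating-site summary from a VCF
#'
#' Reads genotypes with `vcfR`, intersects site positions with the gene
#' spans, and counts per gene the sites at which at least two distinct
#' alleles are called among the genotyped individuals. Multi-allelic sites
#' count once. The number of sequences `n` is twice the number of individuals
#' in the panel (diploids resolved to two sequences each), applied gene-wide
#' rather than per site.
#'
#' @param vcf Path to a VCF (plain or bgzipped), or a `vcfR` object.
#' @param bed Gene spans from [read_gene_bed()] (or a path to a BED file).
#' @return Tibble with `gene_id`, `n`, `S`, `L`.
#' @export
gene_snp_summary <- function(vcf, bed) {
  if (is.character(bed)) bed <- read_gene_bed(bed)
  if (is.character(vcf)) vcf <- vcfR::read.vcfR(vcf, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  chrom <- vcfR::getCHROM(vcf)
  pos <- as.numeric(vcfR::getPOS(vcf))  # 1-based
  n_ind <- ncol(gt)
  if (is.null(n_ind) || n_ind < 1) abort("VCF has no genotyped individuals")
  seg <- apply(gt, 1, site_is_segregating)

  per_gene <- purrr::pmap_int(
    bed[c("chrom", "start", "end")],
    function(chrom_g, start, end) {
      # VCF positions are 1-based; BED half-open [start, end) in 0-based
      in_gene <- chrom == chrom_g & pos > start & pos <= end
      sum(seg & in_gene)
    })
  tibble::tibble(gene_id = bed$gene_id, n = 2L * n_ind,
                 S = per_gene, L = bed$length_bp)
}

# >= 2 distinct called alleles at the site
site_is_segregating <- function(gt_row) {
  alleles <- unlist(strsplit(gt_row[!is.na(gt_row)], "[/|]"))
  alleles <- alleles[alleles != "."]
  length(unique(alleles)) >= 2
}

#' Attach per-gene theta to a gene table
#'
#' Joins a segregating-site summary onto the gene table and computes
#' Watterson's theta per site. Genes without SNP coverage (absent from the
#' summary) receive `theta = 0` and flag `"no_snp_data"`; duplicate summary
#' rows are an error.
#'
#' @param genes Gene table (`gene_id`, `cds_length`, ...).
#' @param snp_summary Tibble from [gene_snp_summary()], or any tibble with
#'   `gene_id`, `n`, `S`, `L`.
#' @return `genes` with columns `theta` and `theta_flag` added (and `n`, `S`,
#'   `L` carried along).
#' @export
theta_table <- function(genes, snp_summary) {
  validate_gene_table(genes, need = character())
  if (anyDuplicated(snp_summary$gene_id))
    abort("duplicate gene entries in SNP summary")
  out <- dplyr::left_join(genes, snp_summary[c("gene_id", "n", "S", "L")],
                          by = "gene_id")
  covered <- !is.na(out$S)
  theta <- rep(0, nrow(out))
  theta[covered] <- watterson_theta(out$S[covered], out$n[covered], out$L[covered])
  out$theta <- theta
  out$theta_flag <- ifelse(covered, "ok", "no_snp_data")
  out
}

#' Write the per-gene theta summary as TSV
#' @param theta_tbl Output of [theta_table()].
#' @param path Output path.
#' @export
write_theta_table <- function(theta_tbl, path) {
  cols <- intersect(c("gene_id", "n", "S", "L", "theta", "theta_flag"),
                    names(theta_tbl))
  readr::write_tsv(theta_tbl[cols], path, progress = FALSE)
  invisible(theta_tbl)
}
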