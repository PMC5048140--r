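#' Tiny deterministic fixture with pen-and-paper index values
#'
#' Six genes, five stages, three resequenced individuals — small enough that
#' every derived quantity can be checked by hand. The returned `manifest`
#' records those hand-computed values (length-weighted TAI and TPI per
#' stage, per-gene Watterson theta) as exact fractions; they are authored
#' arithmetic, not output of the package's own functions, so they can serve
#' as an oracle.
#'
#' @return A list with `genes`, `counts` (raw-count `expr_tbl`), `hits`,
#'   `lineage`, `snps` (per-site genotypes), `bed`, `manifest`.
#' @export
fixture_small <- function() {
  gene_id <- paste0("g", 1:6)
  genes <- tibble::tibble(
    gene_id = gene_id,
    cds_length = c(1000L, 500L, 2000L, 1000L, 400L, 800L),
    phylostratum = c(1L, 3L, 5L, 8L, 11L, 11L))
  counts <- matrix(
    c(100, 200, 300, 200, 100,
      50,  50,  50,  50,  50,
      200, 200, 400, 200, 200,
      0,   100, 100, 100, 0,
      40,  80,  400, 80,  40,
      0,   0,   80,  0,   0),
    nrow = 6, byrow = TRUE,
    dimnames = list(gene_id, paste0("s", 1:5)))

  lineage <- lineage_map(c(paste0("sp_r", 1:10), "focal"), 1:11, "focal")
  hits <- tibble::tibble(
    query_gene      = c("g1",    "g2",    "g2",    "g3",   "g4",    "g4",   "g6"),
    subject_species = c("sp_r1", "sp_r3", "sp_r7", "sp_r5","sp_r8", "sp_r2","focal"),
    evalue          = c(1e-30,   1e-10,   1e-8,    1e-6,   1e-12,   0.5,    0))

  # genes laid end to end on chr1 (0-based starts), no strand
  start0 <- c(0L, 1000L, 1500L, 3500L, 4500L, 4900L)
  bed <- tibble::tibble(chrom = "chr1", start = start0,
                        end = start0 + genes$cds_length,
                        gene_id = gene_id, length_bp = genes$cds_length)

  # segregating sites per gene: g1 5, g2 0, g3 10, g4 2, g5 4, g6 1
  site <- function(gene, pos_in, g1, g2, g3) {
    offset <- start0[match(gene, gene_id)]
    tibble::tibble(gene_id = gene, chrom = "chr1", pos = offset + pos_in,
                   ref = "A", alt = "G", ind1 = g1, ind2 = g2, ind3 = g3)
  }
  snps <- dplyr::bind_rows(
    site("g1", c(11L, 101L, 333L, 657L, 950L),
         c("0/1", "0/0", "0/1", "1/1", "0/0"),
         c("0/0", "0/1", "0/0", "0/1", "0/1"),
         c("0/0", "0/0", "1/1", "0/0", "0/0")),
    site("g3", c(5L, 100L, 200L, 400L, 700L, 900L, 1200L, 1500L, 1800L, 1999L),
         rep("0/1", 10), rep("0/0", 10), rep("1/1", 10)),
    site("g4", c(250L, 750L), c("0/0", "0/1"), c("0/1", "0/0"), c("0/0", "0/0")),
    site("g5", c(40L, 120L, 280L, 390L),
         c("0/1", "0/1", "0/0", "1/1"), c("0/0", "0/0", "0/1", "0/0"),
         c("0/1", "0/0", "0/0", "0/1")),
    site("g6", 400L, "0/1", "0/0", "0/0"))

  # hand-computed expectations -----------------------------------------
  # length-weighted e (counts / bp):
  #   g1 .1 .2 .3 .2 .1 | g2 .1 x5 | g3 .1 .1 .2 .1 .1
  #   g4 0 .1 .1 .1 0   | g5 .1 .2 1.0 .2 .1 | g6 0 0 .1 0 0
  # TAI_s = sum(ps * e) / sum(e)
  h5 <- 1 + 1/2 + 1/3 + 1/4 + 1/5   # harmonic number for n = 6 sequences
  theta <- c(g1 = 5 / (h5 * 1000), g2 = 0, g3 = 10 / (h5 * 2000),
             g4 = 2 / (h5 * 1000), g5 = 4 / (h5 * 400), g6 = 1 / (h5 * 800))
  e <- rbind(c(.1, .2, .3, .2, .1), rep(.1, 5), c(.1, .1, .2, .1, .1),
             c(0, .1, .1, .1, 0), c(.1, .2, 1, .2, .1), c(0, 0, .1, 0, 0))
  manifest <- list(
    tai = c(s1 = 2.0 / 0.4, s2 = 4.0 / 0.7, s3 = 14.5 / 1.8,
            s4 = 4.0 / 0.7, s5 = 2.0 / 0.4),
    theta = theta,
    tpi = 1000 * as.numeric(theta %*% e) / colSums(e),
    n_sequences = 6L,
    S = c(g1 = 5L, g2 = 0L, g3 = 10L, g4 = 2L, g5 = 4L, g6 = 1L))
  names(manifest$tpi) <- paste0("s", 1:5)

  list(genes = genes,
       counts = expr_table(counts, kind = "raw_counts"),
       hits = hits, lineage = lineage, snps = snps, bed = bed,
       manifest = manifest)
}
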