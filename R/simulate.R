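#' Configuration for the synthetic phylotranscriptomic dataset
#'
#' The generator emulates the structure of a stage-resolved developmental
#' RNA-seq study with phylostratigraphic ages and population resequencing:
#' gene ages over `n_strata` phylostrata, an ordered series of `n_stages`
#' stages, overdispersed counts with an age-dependent stage signal, per-gene
#' nucleotide diversity with known truth, a homology hit table from which
#' [assign_phylostrata()] recovers the generating ages exactly, and a second
#' "species" with known orthology whose transcriptome is maximally similar
#' at the phylotypic stage.
#'
#' The hourglass signal works in two opposing waves, mirroring the two
#' phylostratum groups seen in real trochozoan ontogeny: genes from the old
#' strata (`old_ranks`) have their expected expression multiplied by up to
#' `delta` in a window around `stage_of_phylotype`, while genes from the
#' youngest strata ramp up toward the terminal stages. `delta = 1` is the
#' null: age and expression are independent.
#'
#' @param n_genes Number of genes (default 2000).
#' @param n_strata Number of phylostrata (default 11).
#' @param n_stages Number of ordered stages (default 11).
#' @param stage_of_phylotype Index of the phylotypic stage (default 6).
#' @param delta Hourglass effect size, a multiplier at least 1 (default 1 =
#'   null).
#' @param age_distribution Probability vector over strata; the default is
#'   peaked at ps1 with a secondary bump at the youngest strata, the shape
#'   phylostratigraphic censuses typically show.
#' @param old_ranks,young_ranks Strata forming the two opposing expression
#'   waves (defaults: ranks 1-4; the two youngest ranks).
#' @param length_meanlog,length_sdlog,min_length CDS length model:
#'   lognormal, floored (defaults log(1200), 0.6, 150 bp).
#' @param expr_meanlog,expr_sdlog Per-bp baseline expression rate,
#'   lognormal (defaults log(0.15), 1.2) — median read depth around 180
#'   counts for a 1.2 kb gene, with the heavy right tail real libraries
#'   have.
#' @param noise `"nb"` (negative binomial, default) or `"poisson"`.
#' @param dispersion NB dispersion (default 0.1).
#' @param n_individuals Resequenced individuals (default 10, so 20
#'   sequences).
#' @param theta_range Range of the per-gene theta baseline, log-uniform
#'   (default 0.002-0.02 per site, the high polymorphism of marine
#'   broadcast spawners).
#' @param theta_age_slope Log-scale increase of theta per phylostratum rank
#'   (default 0.08: young genes are more polymorphic).
#' @param ortholog_fraction Fraction of genes with a species-B ortholog
#'   (default 0.6).
#' @param swap_rate Controls species-B rank perturbation: fraction of
#'   adjacent rank swaps per unit of stage distance from the phylotypic
#'   stage (default 0.5).
#' @param seed Integer seed recorded in the config and used by
#'   [simulate_dataset()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000, n_strata = 11, n_stages = 11,
                       stage_of_phylotype = 6, delta = 1,
                       age_distribution = NULL,
                       old_ranks = 1:4, young_ranks = NULL,
                       length_meanlog = log(1200), length_sdlog = 0.6,
                       min_length = 150,
                       expr_meanlog = log(0.15), expr_sdlog = 1.2,
                       noise = c("nb", "poisson"), dispersion = 0.1,
                       n_individuals = 10,
                       theta_range = c(0.002, 0.02), theta_age_slope = 0.08,
                       ortholog_fraction = 0.6, swap_rate = 0.5,
                       seed = 1L) {
  noise <- match.arg(noise)
  if (is.null(young_ranks)) young_ranks <- (n_strata - 1):n_strata
  if (is.null(age_distribution)) {
    w <- rep(1, n_strata)
    w[1] <- 5
    w[n_strata] <- 3
    if (n_strata >= 2) w[n_strata - 1] <- 2
    age_distribution <- w / sum(w)
  }
  if (length(age_distribution) != n_strata)
    abort("age_distribution length must equal n_strata")
  if (abs(sum(age_distribution) - 1) > 1e-8)
    abort("age_distribution must sum to 1")
  if (stage_of_phylotype < 1 || stage_of_phylotype > n_stages)
    abort("stage_of_phylotype out of range")
  if (delta < 1) abort("delta must be at least 1")
  if (n_genes < 2 || n_stages < 2 || n_strata < 2)
    abort("need at least 2 genes, stages and strata")
  structure(list(
    n_genes = n_genes, n_strata = n_strata, n_stages = n_stages,
    stage_of_phylotype = stage_of_phylotype, delta = delta,
    age_distribution = age_distribution,
    old_ranks = old_ranks, young_ranks = young_ranks,
    length_meanlog = length_meanlog, length_sdlog = length_sdlog,
    min_length = min_length,
    expr_meanlog = expr_meanlog, expr_sdlog = expr_sdlog,
    noise = noise, dispersion = dispersion,
    n_individuals = n_individuals,
    theta_range = theta_range, theta_age_slope = theta_age_slope,
    ortholog_fraction = ortholog_fraction, swap_rate = swap_rate,
    seed = as.integer(seed)), class = "sim_config")
}

# expected expression multiplier for stratum a at each stage
stage_modulation <- function(cfg, rank) {
  s <- seq_len(cfg$n_stages)
  if (rank %in% cfg$old_ranks) {
    kern <- pmax(0, 1 - abs(s - cfg$stage_of_phylotype) / 3)
    1 + (cfg$delta - 1) * kern
  } else if (rank %in% cfg$young_ranks) {
    1 + (cfg$delta - 1) * (s - 1) / (cfg$n_stages - 1)
  } else {
    rep(1, cfg$n_stages)
  }
}

#' Analytic expectation of the TAI profile under a simulation config
#'
#' The population value the plug-in TAI estimator targets:
#' `sum_a P(a) * a * m(a, s) / sum_a P(a) * m(a, s)` where `m(a, s)` is the
#' configured age-by-stage expression modulation (the per-gene baseline is
#' age-independent and cancels).
#'
#' @param cfg A [sim_config()].
#' @return Numeric vector, one expected TAI per stage.
#' @export
true_tai <- function(cfg) {
  mods <- vapply(seq_len(cfg$n_strata), function(a) stage_modulation(cfg, a),
                 numeric(cfg$n_stages))
  num <- as.numeric(mods %*% (cfg$age_distribution * seq_len(cfg$n_strata)))
  den <- as.numeric(mods %*% cfg$age_distribution)
  num / den
}

#' Generate a complete synthetic dataset with known ground truth
#'
#' Draws gene ages, CDS lengths, baseline expression and stage-modulated
#' counts, per-gene theta with matching SNP genotypes
#' (`E[S] = theta * H_{2N-1} * L`), a homology hit table consistent with the
#' drawn ages, and a second species' expression plus ortholog truth and
#' reciprocal hit tables. All randomness flows from `cfg$seed`; the same
#' config yields byte-identical output.
#'
#' @param cfg A [sim_config()].
#' @param components Which expensive components to generate, any of
#'   `"snps"`, `"hits"`, `"species_b"`; expression and the gene table are
#'   always produced.
#' @return A list with elements `genes` (gene table with `phylostratum` and
#'   `theta_true`), `counts` (`expr_tbl` of raw counts, stages `s1..`),
#'   `lineage`, `hits`, `snps` (per-site genotype tibble), `bed`,
#'   `expr_b`, `orthologs`, `hits_ab`, `hits_ba`, `config`.
#' @export
simulate_dataset <- function(cfg,
                             components = c("snps", "hits", "species_b")) {
  stopifnot(inherits(cfg, "sim_config"))
  if (length(components) > 0)
    components <- match.arg(components, several.ok = TRUE,
                            choices = c("snps", "hits", "species_b"))
  with_seed_if(cfg$seed, simulate_dataset_impl(cfg, components))
}

simulate_dataset_impl <- function(cfg, components) {
  n <- cfg$n_genes
  gene_id <- sprintf("g%04d", seq_len(n))
  age <- sample.int(cfg$n_strata, n, replace = TRUE,
                    prob = cfg$age_distribution)
  len <- pmax(cfg$min_length,
              round(rlnorm(n, cfg$length_meanlog, cfg$length_sdlog)))
  q <- rlnorm(n, cfg$expr_meanlog, cfg$expr_sdlog)  # per-bp rate
  mods <- vapply(seq_len(cfg$n_strata), function(a) stage_modulation(cfg, a),
                 numeric(cfg$n_stages))              # stages x strata
  mu <- (q * len) * t(mods[, age, drop = FALSE])     # genes x stages
  counts <- if (cfg$noise == "nb") {
    matrix(rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion), n)
  } else {
    matrix(rpois(length(mu), mu), n)
  }
  dimnames(counts) <- list(gene_id, paste0("s", seq_len(cfg$n_stages)))

  log_th <- runif(n, log(cfg$theta_range[1]), log(cfg$theta_range[2]))
  theta_true <- exp(log_th + cfg$theta_age_slope *
                      (age - (cfg$n_strata + 1) / 2))

  genes <- tibble::tibble(gene_id = gene_id, cds_length = as.integer(len),
                          phylostratum = as.integer(age),
                          theta_true = theta_true)
  offset <- cumsum(c(0, len[-n] + 100))  # genes laid end to end, 100 bp gaps
  bed <- tibble::tibble(chrom = "chr1", start = offset, end = offset + len,
                        gene_id = gene_id, length_bp = as.integer(len))

  out <- list(genes = genes,
              counts = expr_table(counts, kind = "raw_counts"),
              bed = bed, config = cfg)
  if ("hits" %in% components) {
    lin <- sim_lineage(cfg)
    out$lineage <- lin
    out$hits <- sim_age_hits(genes, lin)
  }
  if ("snps" %in% components) out$snps <- sim_snps(genes, bed, cfg)
  if ("species_b" %in% components) {
    sb <- sim_species_b(out$counts, genes, cfg)
    out$expr_b <- sb$expr_b
    out$orthologs <- sb$orthologs
    out$hits_ab <- sb$hits_ab
    out$hits_ba <- sb$hits_ba
  }
  out
}

sim_lineage <- function(cfg) {
  species <- c(paste0("sp_r", seq_len(cfg$n_strata - 1)), "focal")
  lineage_map(species, seq_len(cfg$n_strata), "focal")
}

# hit table from which assign_phylostrata recovers the true ages exactly:
# one strong hit at the gene's own stratum, extra strong hits at younger
# strata, and above-cutoff decoys at older strata
sim_age_hits <- function(genes, lineage) {
  nmax <- n_strata(lineage)
  rows <- purrr::map2_dfr(genes$gene_id, genes$phylostratum, function(g, a) {
    hit <- NULL
    if (a < nmax) {
      pool <- if (a + 1 <= nmax - 1) (a + 1):(nmax - 1) else integer()
      extra_ranks <- if (length(pool) > 0 && runif(1) < 0.5)
        pool[sample.int(length(pool), 1)] else integer()
      ranks <- c(a, extra_ranks)
      hit <- tibble::tibble(query_gene = g,
                            subject_species = paste0("sp_r", ranks),
                            evalue = 10^runif(length(ranks), -50, -5))
    } else {
      hit <- tibble::tibble(query_gene = g, subject_species = "focal",
                            evalue = 0)
    }
    if (a > 1 && runif(1) < 0.3) {  # decoy above the cutoff at an older node
      hit <- dplyr::bind_rows(hit, tibble::tibble(
        query_gene = g,
        subject_species = paste0("sp_r", sample.int(a - 1, 1)),
        evalue = 10^runif(1, -2, 1)))
    }
    hit
  })
  rows$bitscore <- 50 - log10(rows$evalue + 1e-300)
  rows
}

# per-site diploid genotypes with E[S] = theta * H_{2N-1} * L per gene
sim_snps <- function(genes, bed, cfg) {
  n_ind <- cfg$n_individuals
  n_chrom <- 2L * n_ind
  h <- harmonic_number(n_chrom - 1)
  S <- rpois(nrow(genes), genes$theta_true * h * genes$cds_length)
  S <- pmin(S, genes$cds_length)
  ind_cols <- paste0("ind", seq_len(n_ind))
  sfs_prob <- (1 / seq_len(n_chrom - 1))
  rows <- purrr::pmap_dfr(
    list(genes$gene_id, genes$cds_length, bed$start, S),
    function(g, L, start0, s_g) {
      if (s_g == 0) return(NULL)
      pos_in <- sort(sample.int(L, s_g))
      k <- sample.int(n_chrom - 1, s_g, replace = TRUE, prob = sfs_prob)
      gt <- vapply(k, function(ki) {
        alleles <- integer(n_chrom)
        alleles[sample.int(n_chrom, ki)] <- 1L
        paste0(alleles[seq(1, n_chrom, 2)], "/", alleles[seq(2, n_chrom, 2)])
      }, character(n_ind))
      gt <- matrix(gt, nrow = s_g, byrow = TRUE,
                   dimnames = list(NULL, ind_cols))
      dplyr::bind_cols(
        tibble::tibble(gene_id = g, chrom = "chr1", pos = start0 + pos_in,
                       ref = "A", alt = "G"),
        tibble::as_tibble(gt))
    })
  if (nrow(rows) == 0)
    rows <- tibble::tibble(gene_id = character(), chrom = character(),
                           pos = integer(), ref = character(),
                           alt = character())
  rows
}

# species B: rank-preserving perturbation of the ortholog expression,
# maximally correlated at the phylotypic stage
sim_species_b <- function(counts, genes, cfg) {
  n <- nrow(genes)
  idx <- sort(sample.int(n, round(cfg$ortholog_fraction * n)))
  m <- expr_values(counts)[idx, , drop = FALSE]
  k <- nrow(m)
  b <- matrix(0, k, cfg$n_stages)
  for (s in seq_len(cfg$n_stages)) {
    x <- m[, s]
    n_swaps <- round(cfg$swap_rate * k *
                       abs(s - cfg$stage_of_phylotype) /
                       max(1, cfg$n_stages - 1))
    ord <- order(x)
    perm <- seq_len(k)
    if (n_swaps > 0) {
      at <- sample.int(k - 1, n_swaps, replace = TRUE)
      for (j in at) perm[c(j, j + 1)] <- perm[c(j + 1, j)]
    }
    # gene holding sorted-rank r in A gets the value at perturbed rank perm[r]
    b[ord, s] <- sort(x)[perm]
  }
  gene_b <- sub("^g", "b", genes$gene_id[idx])
  dimnames(b) <- list(gene_b, paste0("t", seq_len(cfg$n_stages)))
  orthologs <- tibble::tibble(gene_a = genes$gene_id[idx], gene_b = gene_b)
  ev <- 10^runif(k, -60, -10)
  hits_ab <- tibble::tibble(query_gene = orthologs$gene_a,
                            subject_id = orthologs$gene_b,
                            evalue = ev, bitscore = 60 - log10(ev))
  hits_ba <- tibble::tibble(query_gene = orthologs$gene_b,
                            subject_id = orthologs$gene_a,
                            evalue = ev, bitscore = 60 - log10(ev))
  # off-target weaker hits exercise the best-hit selection
  n_decoy <- max(1, round(0.1 * k))
  di <- sample.int(k, n_decoy)
  decoy_ev <- pmax(hits_ab$evalue[di] * 10^runif(n_decoy, 2, 6), 1e-300)
  hits_ab <- dplyr::bind_rows(hits_ab, tibble::tibble(
    query_gene = orthologs$gene_a[di],
    subject_id = sample(orthologs$gene_b, n_decoy),
    evalue = decoy_ev, bitscore = 60 - log10(decoy_ev)))
  list(expr_b = expr_table(b, kind = "raw_counts"),
       orthologs = orthologs, hits_ab = hits_ab, hits_ba = hits_ba)
}

#' Write a simulated dataset to a directory in the pipeline's file formats
#'
#' Produces `counts.tsv`, `genes.tsv`, `lineage.tsv`, `hits.tsv`,
#' `snps.vcf`, `genes.bed`, `counts_b.tsv`, `orthologs.tsv` and a
#' `manifest.yaml` recording the generating parameters (including the seed).
#'
#' @param sim Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expr_table(sim$counts, file.path(dir, "counts.tsv"))
  write_gene_table(sim$genes, file.path(dir, "genes.tsv"))
  write_gene_bed(sim$bed, file.path(dir, "genes.bed"))
  if (!is.null(sim$lineage))
    readr::write_tsv(sim$lineage, file.path(dir, "lineage.tsv"),
                     progress = FALSE)
  if (!is.null(sim$hits))
    readr::write_tsv(sim$hits, file.path(dir, "hits.tsv"), progress = FALSE)
  if (!is.null(sim$snps))
    write_snp_vcf(sim$snps, file.path(dir, "snps.vcf"))
  if (!is.null(sim$expr_b)) {
    write_expr_table(sim$expr_b, file.path(dir, "counts_b.tsv"))
    write_ortholog_map(sim$orthologs, file.path(dir, "orthologs.tsv"))
  }
  cfg <- sim$config
  yaml::write_yaml(cfg[setdiff(names(cfg), "class")],
                   file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Write per-site genotypes as a minimal VCFv4.2 file
#'
#' @param snps Site tibble as produced by [simulate_dataset()] (`chrom`,
#'   `pos` 1-based, `ref`, `alt`, one `GT` column per individual).
#' @param path Output path (plain text).
#' @export
write_snp_vcf <- function(snps, path) {
  ind_cols <- grep("^ind", names(snps), value = TRUE)
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", ind_cols), collapse = "\t"))
  body <- if (nrow(snps) == 0) character() else {
    gts <- do.call(paste, c(unname(as.list(snps[ind_cols])), sep = "\t"))
    paste(snps$chrom, snps$pos, ".", snps$ref, snps$alt, ".", "PASS", ".",
          "GT", gts, sep = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}
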