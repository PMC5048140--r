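#' Assemble and validate a pipeline run configuration
#'
#' A run configuration names the input files, the developmental stage order,
#' every threshold of the pipeline, and the seed. It round-trips through
#' YAML ([read_run_config()] / [write_run_config()]) without loss, so a run
#' report always carries enough metadata to reproduce itself.
#'
#' Stage order is explicit configuration (`stages`), never silently inferred
#' beyond the column order of the count matrix: developmental ordering is
#' semantically load-bearing for every profile.
#'
#' @param counts Path to the raw count TSV (gene x stage).
#' @param genes Path to the gene table TSV (`gene_id`, `cds_length`, and
#'   optionally precomputed `phylostratum` / `theta`).
#' @param out_dir Output directory.
#' @param hits,lineage Paths to the homology hit table and lineage map for
#'   age assignment (optional if `genes` already carries `phylostratum`).
#' @param focal_species Focal species id in the lineage map.
#' @param vcf,bed Paths to the SNP VCF and gene-span BED for theta
#'   (optional; without them TPI is skipped unless `genes` carries `theta`).
#' @param counts_b,orthologs Paths to a second species' count TSV and an
#'   ortholog map for stage similarity (optional).
#' @param stages Explicit stage order for the focal species (optional).
#' @param evalue_cutoff_age,evalue_cutoff_rbh E-value cutoffs.
#' @param logratio_trim,abs_trim TMM trim fractions.
#' @param r_threshold,max_length_bp,min_peak_expression Correlation-filter
#'   settings (peak threshold in RPKM units).
#' @param n_boot,n_perm,level Inference settings.
#' @param alternative,combine Permutation-test tail and p-value combiner.
#' @param seed Integer seed governing all randomness of the run.
#' @return A list of class `run_config`.
#' @export
run_config <- function(counts, genes, out_dir,
                       hits = NULL, lineage = NULL, focal_species = "focal",
                       vcf = NULL, bed = NULL,
                       counts_b = NULL, orthologs = NULL,
                       stages = NULL,
                       evalue_cutoff_age = 1e-3, evalue_cutoff_rbh = 1e-5,
                       logratio_trim = 0.30, abs_trim = 0.05,
                       r_threshold = 0.99, max_length_bp = 500,
                       min_peak_expression = 10000,
                       n_boot = 1000, n_perm = 1000, level = 0.95,
                       alternative = "two.sided", combine = "fisher",
                       seed = 1L) {
  cfg <- list(counts = counts, genes = genes, out_dir = out_dir,
              hits = hits, lineage = lineage, focal_species = focal_species,
              vcf = vcf, bed = bed,
              counts_b = counts_b, orthologs = orthologs, stages = stages,
              evalue_cutoff_age = evalue_cutoff_age,
              evalue_cutoff_rbh = evalue_cutoff_rbh,
              logratio_trim = logratio_trim, abs_trim = abs_trim,
              r_threshold = r_threshold, max_length_bp = max_length_bp,
              min_peak_expression = min_peak_expression,
              n_boot = n_boot, n_perm = n_perm, level = level,
              alternative = alternative, combine = combine,
              seed = as.integer(seed))
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  if (is.null(cfg$counts) || is.null(cfg$genes) || is.null(cfg$out_dir))
    abort("run config needs `counts`, `genes` and `out_dir`")
  if (cfg$n_perm < 100) abort("n_perm must be at least 100")
  if (cfg$n_boot < 100) abort("n_boot must be at least 100")
  if (cfg$level <= 0 || cfg$level >= 1) abort("level must be in (0, 1)")
  if (cfg$evalue_cutoff_age <= 0 || cfg$evalue_cutoff_rbh <= 0)
    abort("e-value cutoffs must be positive")
  if (cfg$r_threshold <= 0 || cfg$r_threshold > 1)
    abort("r_threshold must be in (0, 1]")
  if (cfg$logratio_trim < 0 || cfg$logratio_trim >= 0.5 ||
      cfg$abs_trim < 0 || cfg$abs_trim >= 0.5)
    abort("trim fractions must be in [0, 0.5)")
  invisible(cfg)
}

#' @rdname run_config
#' @param path YAML path.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

#' @rdname run_config
#' @param cfg A `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg)[!vapply(unclass(cfg), is.null, logical(1))],
                   path)
  invisible(cfg)
}

#' Run the full phylotranscriptomic pipeline on files
#'
#' Executes, as configured: age assignment from homology hits; per-gene
#' theta from VCF + BED; length-weighting, TMM scaling and the
#' correlated-duplicate filter; TAI (and TPI when theta is available) with
#' bootstrap confidence bands and the per-stage permutation test; and
#' cross-species stage similarity when a second species is supplied. Every
#' output table, the null-model report and the echoed configuration are
#' written under `cfg$out_dir`.
#'
#' @param cfg A [run_config()] (validated before any computation).
#' @return Invisibly, a list with the in-memory results: `genes`, `expr`
#'   (the weighted matrix), per-index `profile` tibbles and `null` objects,
#'   and `similarity` when computed.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  validate_run_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  counts <- read_expr_table(cfg$counts, stages = cfg$stages)
  genes <- read_gene_table(cfg$genes)

  # ages ---------------------------------------------------------------
  if (!is.null(cfg$hits) && !is.null(cfg$lineage)) {
    lineage <- read_lineage_map(cfg$lineage, cfg$focal_species)
    hits <- read_hit_table(cfg$hits)
    ages <- assign_phylostrata(hits, lineage, gene_ids = genes$gene_id,
                               evalue_cutoff = cfg$evalue_cutoff_age)
    genes$phylostratum <- ages$phylostratum[match(genes$gene_id, ages$gene_id)]
    write_gene_ages(ages, file.path(cfg$out_dir, "gene_ages.tsv"))
  }
  if (!"phylostratum" %in% names(genes))
    abort("no phylostratum available: supply `hits` + `lineage` or a gene table with a phylostratum column")

  # theta --------------------------------------------------------------
  if (!is.null(cfg$vcf) && !is.null(cfg$bed)) {
    summ <- gene_snp_summary(cfg$vcf, cfg$bed)
    genes <- theta_table(genes, summ)
    write_theta_table(genes, file.path(cfg$out_dir, "theta.tsv"))
  }

  # preprocessing ------------------------------------------------------
  rpkm_tbl <- rpkm(counts, genes)
  filt <- filter_correlated_duplicates(
    rpkm_tbl, genes, r_threshold = cfg$r_threshold,
    max_length_bp = cfg$max_length_bp,
    min_peak_expression = cfg$min_peak_expression)
  if (nrow(filt$removed) > 0)
    readr::write_tsv(filt$removed,
                     file.path(cfg$out_dir, "removed_duplicates.tsv"),
                     progress = FALSE)
  inform(sprintf("correlated-duplicate filter removed %d gene(s)",
                 nrow(filt$removed)))
  counts <- counts[counts$gene_id %in% filt$expr$gene_id, , drop = FALSE]
  counts <- new_expr_tbl(counts, "raw_counts")
  expr <- tmm_normalize(length_weight(counts, genes),
                        logratio_trim = cfg$logratio_trim,
                        abs_trim = cfg$abs_trim)

  # indices + inference ------------------------------------------------
  results <- list(genes = genes, expr = expr, config = cfg)
  run_index <- function(kind) {
    prof <- bootstrap_ci(expr, genes, index = kind, n_boot = cfg$n_boot,
                         level = cfg$level, seed = cfg$seed)
    null <- permutation_null(expr, genes, index = kind, n_perm = cfg$n_perm,
                             seed = cfg$seed, alternative = cfg$alternative,
                             combine = cfg$combine)
    prof$p <- null$p_stage
    write_profile(prof, file.path(cfg$out_dir, paste0(tolower(kind), "_profile.tsv")))
    write_null_report(null, file.path(cfg$out_dir, paste0(tolower(kind), "_null.txt")))
    list(profile = prof, null = null)
  }
  results$tai <- run_index("TAI")
  if ("theta" %in% names(genes)) results$tpi <- run_index("TPI")

  # similarity ---------------------------------------------------------
  if (!is.null(cfg$counts_b) && !is.null(cfg$orthologs)) {
    expr_b <- read_expr_table(cfg$counts_b)
    orth <- read_ortholog_map(cfg$orthologs)
    grid <- stage_similarity(rpkm_tbl, expr_b, orth)
    write_similarity_grid(grid, file.path(cfg$out_dir, "similarity.tsv"))
    results$similarity <- grid
  }

  write_run_config(cfg, file.path(cfg$out_dir, "run_config.yaml"))
  inform(paste0("pipeline outputs written to ", cfg$out_dir))
  invisible(results)
}

#' Write a permutation-null model as a structured text report
#'
#' One line per stage (observed value, gamma shape and scale, p), followed
#' by the combined p, combiner, tail convention, permutation count and seed.
#'
#' @param null An `index_null` from [permutation_null()].
#' @param path Output path.
#' @export
write_null_report <- function(null, path) {
  per_stage <- tidy.index_null(null)
  lines <- c(
    sprintf("index\t%s", null$index_kind),
    sprintf("n_perm\t%d", null$n_perm),
    sprintf("seed\t%s", if (is.null(null$seed)) "NA" else null$seed),
    sprintf("alternative\t%s", null$alternative),
    sprintf("combine\t%s", null$combine),
    sprintf("p_combined\t%.6g", null$p_combined),
    "stage\tobserved\tshape\tscale\tp",
    sprintf("%s\t%.6g\t%.6g\t%.6g\t%.6g", as.character(per_stage$stage),
            per_stage$observed, per_stage$shape, per_stage$scale,
            per_stage$p))
  writeLines(lines, path)
  invisible(null)
}
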