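#' Length-weight a count matrix
#'
#' Divides each gene's read counts by its CDS length so the value is
#' proportional to the number of transcript molecules rather than to the
#' number of sequenceable positions. This is the per-gene weighting underlying
#' every expression-weighted index in the package.
#'
#' @param counts An [expr_table()] of kind `raw_counts`.
#' @param genes Gene table with `gene_id`, `cds_length` (bp) for every matrix
#'   gene; a missing length is an error naming the gene.
#' @return An `expr_tbl` of kind `length_weighted`.
#' @export
length_weight <- function(counts, genes) {
  g <- align_genes(counts, genes, need = "cds_length")
  if (anyNA(g$cds_length))
    abort(paste0("no CDS length for gene(s): ",
                 paste(head(g$gene_id[is.na(g$cds_length)], 5), collapse = ", ")))
  m <- expr_values(counts) / g$cds_length
  expr_replace(counts, m, kind = "length_weighted")
}

#' Reads per kilobase per million (RPKM)
#'
#' `value = count * 1e9 / (cds_length * library_size)`, with the library size
#' of a stage taken as its raw-count column sum.
#'
#' @inheritParams length_weight
#' @return An `expr_tbl` of kind `rpkm`.
#' @export
rpkm <- function(counts, genes) {
  g <- align_genes(counts, genes, need = "cds_length")
  m <- expr_values(counts)
  lib <- colSums(m)
  if (any(lib <= 0)) abort(paste0("zero library size in stage(s): ",
                                  paste(colnames(m)[lib <= 0], collapse = ", ")))
  out <- sweep(m / g$cds_length, 2, lib, "/") * 1e9
  expr_replace(counts, out, kind = "rpkm")
}

#' Trimmed mean of M-values (TMM) scaling factors
#'
#' Between-stage scaling factors correcting the RNA composition effect: for
#' each stage versus a reference stage, log-ratios of library-size-normalized
#' proportions (M-values) are doubly trimmed — by `logratio_trim` on M and
#' `abs_trim` on average log abundance A — and averaged with inverse
#' delta-method (binomial) variance weights; the factor is `2^` that weighted
#' mean. Genes with zero value in either compared library are excluded.
#'
#' @param expr An `expr_tbl` (raw counts or length-weighted values) with at
#'   least two stages, none all-zero.
#' @param logratio_trim Two-sided trim fraction on M-values (default 0.30).
#' @param abs_trim Two-sided trim fraction on A-values (default 0.05).
#' @param reference Reference stage id, or `NULL` to pick the stage whose
#'   upper-quartile proportion is closest to the mean upper quartile.
#' @param scale `"geometric"` (default) rescales factors to geometric mean 1,
#'   the convention of the published algorithm's reference implementation;
#'   `"reference"` leaves the reference stage at exactly 1.
#' @return A named numeric vector of per-stage factors. Dividing the
#'   library-size-normalized columns by these factors yields composition-
#'   corrected values (see [tmm_normalize()]).
#' @export
tmm_factors <- function(expr, logratio_trim = 0.30, abs_trim = 0.05,
                        reference = NULL, scale = c("geometric", "reference")) {
  scale <- match.arg(scale)
  m <- expr_values(expr)
  if (ncol(m) < 2) abort("TMM needs at least two stages")
  lib <- colSums(m)
  if (any(lib <= 0)) abort(paste0("stage with all-zero values: ",
                                  paste(colnames(m)[lib <= 0], collapse = ", ")))
  if (is.null(reference)) {
    uq <- apply(sweep(m, 2, lib, "/"), 2, quantile, probs = 0.75)
    ref_idx <- which.min(abs(uq - mean(uq)))
  } else {
    ref_idx <- match(reference, colnames(m))
    if (is.na(ref_idx)) abort(paste0("unknown reference stage: ", reference))
  }
  f <- vapply(seq_len(ncol(m)), function(k) {
    tmm_pair(m[, k], m[, ref_idx], lib[k], lib[ref_idx],
             logratio_trim, abs_trim)
  }, numeric(1))
  names(f) <- colnames(m)
  if (scale == "geometric") f <- f / exp(mean(log(f))) else f <- f / f[ref_idx]
  attr(f, "reference") <- colnames(m)[ref_idx]
  f
}

# one library against the reference; mirrors the published double-trimmed,
# precision-weighted mean of M-values
tmm_pair <- function(obs, ref, n_obs, n_ref, logratio_trim, abs_trim) {
  keep0 <- obs > 0 & ref > 0
  obs <- obs[keep0]; ref <- ref[keep0]
  m_val <- log2((obs / n_obs) / (ref / n_ref))
  a_val <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(m_val) & is.finite(a_val)
  m_val <- m_val[fin]; a_val <- a_val[fin]; w <- w[fin]
  if (length(m_val) == 0 || max(abs(m_val)) < 1e-6) return(1)
  n <- length(m_val)
  lo_m <- floor(n * logratio_trim) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * abs_trim) + 1;     hi_a <- n + 1 - lo_a
  r_m <- rank(m_val); r_a <- rank(a_val)
  keep <- r_m >= lo_m & r_m <= hi_m & r_a >= lo_a & r_a <= hi_a
  f <- sum(m_val[keep] / w[keep], na.rm = TRUE) / sum(1 / w[keep], na.rm = TRUE)
  if (is.na(f)) f <- 0
  2^f
}

#' Apply TMM scaling to an expression table
#'
#' Divides each stage column by `library_size * factor` (times the mean
#' library size, to keep values on a readable scale). The result is the
#' composition-corrected matrix used as `e_is` by the indices.
#'
#' @inheritParams tmm_factors
#' @param factors Optional precomputed factors from [tmm_factors()].
#' @param ... Passed to [tmm_factors()].
#' @return An `expr_tbl` of kind `tmm_scaled`.
#' @export
tmm_normalize <- function(expr, factors = NULL, ...) {
  if (is.null(factors)) factors <- tmm_factors(expr, ...)
  m <- expr_values(expr)
  lib <- colSums(m)
  eff <- lib * factors[colnames(m)]
  out <- sweep(m, 2, eff / mean(lib), "/")
  expr_replace(expr, out, kind = "tmm_scaled")
}

#' Collapse clusters of near-identical expression profiles
#'
#' Short, extremely highly expressed genes whose stage profiles are almost
#' perfectly correlated (Pearson r above `r_threshold`) typically reflect a
#' single repeated genomic element (e.g. a retrotransposon family) counted
#' under several gene ids; as a group they can dominate the weighted
#' transcriptome. Candidates (short and highly expressed) are clustered by
#' correlation, and one representative per connected component is retained —
#' the longest CDS, ties broken by lexicographically smallest id.
#'
#' @param expr An `expr_tbl` with at least 3 stages.
#' @param genes Gene table with `cds_length`.
#' @param r_threshold Pearson correlation above which two candidates are
#'   linked (default 0.99).
#' @param max_length_bp Candidacy: CDS length at most this (default 500 bp).
#' @param min_peak_expression Candidacy: peak expression at least this, in the
#'   units of `expr` (default 10000, intended for RPKM-scale input).
#' @return A list with `expr` (filtered table) and `removed` (tibble of
#'   removed genes with their component id and the kept representative).
#' @export
filter_correlated_duplicates <- function(expr, genes, r_threshold = 0.99,
                                         max_length_bp = 500,
                                         min_peak_expression = 10000) {
  if (length(stage_ids(expr)) < 3)
    abort("correlation filtering needs at least 3 stages")
  g <- align_genes(expr, genes, need = "cds_length")
  m <- expr_values(expr)
  cand <- g$cds_length <= max_length_bp & apply(m, 1, max) >= min_peak_expression
  constant <- apply(m, 1, function(x) sd(x) == 0)
  if (any(cand & constant)) {
    inform(sprintf("%d constant-expression gene(s) excluded from duplicate candidacy",
                   sum(cand & constant)))
    cand <- cand & !constant
  }
  removed <- tibble::tibble(gene_id = character(), component = integer(),
                            representative = character())
  if (sum(cand) >= 2) {
    cm <- cor(t(m[cand, , drop = FALSE]))
    adj <- cm > r_threshold
    diag(adj) <- FALSE
    comp <- redundancy_components(rownames(cm), adj)
    removed <- pick_representatives(comp, g)
  }
  keep <- !(expr$gene_id %in% removed$gene_id)
  list(expr = new_expr_tbl(expr[keep, , drop = FALSE], expr_kind(expr)),
       removed = removed)
}

#' Collapse sequence-redundant gene clusters
#'
#' Duplicated gene models are detected from a self-vs-self alignment table:
#' two genes are linked when their proteins share at least
#' `prot_identity_min`% identity over the aligned region, their DNA at least
#' `dna_identity_min`%, and the protein alignment has no gaps. Connected
#' components are collapsed to one representative (longest CDS, then smallest
#' id); self-alignments are ignored.
#'
#' @param alignments Tibble with columns `query_gene`, `subject_id`,
#'   `pct_identity_protein`, `pct_identity_dna`, `aligned_gaps_protein`.
#' @param genes Gene table with `cds_length`; an alignment row referencing a
#'   gene absent from it is an error.
#' @param prot_identity_min,dna_identity_min Identity thresholds in percent
#'   (defaults 97 and 95).
#' @return A list with `kept` (character vector of retained gene ids over all
#'   of `genes`) and `removed` (tibble as in
#'   [filter_correlated_duplicates()]).
#' @export
filter_sequence_redundant <- function(alignments, genes,
                                      prot_identity_min = 97,
                                      dna_identity_min = 95) {
  validate_gene_table(genes)
  need <- c("query_gene", "subject_id", "pct_identity_protein",
            "pct_identity_dna", "aligned_gaps_protein")
  missing <- setdiff(need, names(alignments))
  if (length(missing) > 0)
    abort(paste0("alignment table lacks column(s): ",
                 paste(missing, collapse = ", ")))
  ids <- unique(c(alignments$query_gene, alignments$subject_id))
  unknown <- setdiff(ids, genes$gene_id)
  if (length(unknown) > 0)
    abort(paste0("alignment references unknown gene(s): ",
                 paste(head(unknown, 5), collapse = ", ")))
  edges <- alignments |>
    dplyr::filter(.data$query_gene != .data$subject_id,
                  .data$pct_identity_protein >= prot_identity_min,
                  .data$pct_identity_dna >= dna_identity_min,
                  .data$aligned_gaps_protein == 0)
  removed <- tibble::tibble(gene_id = character(), component = integer(),
                            representative = character())
  if (nrow(edges) > 0) {
    gr <- igraph::graph_from_data_frame(
      edges[c("query_gene", "subject_id")], directed = FALSE)
    memb <- igraph::components(gr)$membership
    comp <- split(names(memb), memb)
    removed <- pick_representatives(comp, genes)
  }
  list(kept = setdiff(genes$gene_id, removed$gene_id), removed = removed)
}

# components of an adjacency matrix over named nodes
redundancy_components <- function(ids, adj) {
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  memb <- igraph::components(gr)$membership
  comp <- split(ids, memb)
  comp[lengths(comp) >= 2]
}

# one representative per component: longest CDS, tie -> smallest id
pick_representatives <- function(components, genes) {
  components <- components[lengths(components) >= 2]
  if (length(components) == 0)
    return(tibble::tibble(gene_id = character(), component = integer(),
                          representative = character()))
  purrr::imap_dfr(components, function(ids, comp_id) {
    len <- genes$cds_length[match(ids, genes$gene_id)]
    ord <- order(-len, ids)
    rep <- ids[ord[1]]
    tibble::tibble(gene_id = setdiff(ids, rep),
                   component = as.integer(comp_id),
                   representative = rep)
  })
}
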