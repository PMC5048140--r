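#' Reciprocal-best-hit ortholog map between two species
#'
#' A pair `(a, b)` is called orthologous when `b` is `a`'s best qualifying
#' hit searching A against B, and `a` is `b`'s best searching B against A.
#' "Best" means lowest e-value, ties broken by highest bit score, then by
#' lexicographically smallest subject id; hits with e-value above
#' `evalue_cutoff` never qualify. The result is one-to-one by construction.
#'
#' @param hits_ab,hits_ba Hit tables (columns `query_gene`, `subject_id`,
#'   `evalue`, and optionally `bitscore`) for the two search directions.
#' @param evalue_cutoff Qualifying-hit threshold (default `1e-5`).
#' @return A tibble with `gene_a`, `gene_b` and the supporting scores in both
#'   directions (`evalue_ab`, `bitscore_ab`, `evalue_ba`, `bitscore_ba`).
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba, evalue_cutoff = 1e-5) {
  if (nrow(hits_ab) == 0 || nrow(hits_ba) == 0)
    abort("both hit tables must be non-empty")
  best_ab <- best_hits(hits_ab, evalue_cutoff)
  best_ba <- best_hits(hits_ba, evalue_cutoff)
  dplyr::inner_join(
    dplyr::rename(best_ab, gene_a = "query_gene", gene_b = "subject_id",
                  evalue_ab = "evalue", bitscore_ab = "bitscore"),
    dplyr::rename(best_ba, gene_b = "query_gene", gene_a = "subject_id",
                  evalue_ba = "evalue", bitscore_ba = "bitscore"),
    by = c("gene_a", "gene_b")) |>
    dplyr::arrange(.data$gene_a)
}

best_hits <- function(hits, evalue_cutoff) {
  if (!"bitscore" %in% names(hits)) hits$bitscore <- 0
  hits |>
    dplyr::filter(.data$evalue <= evalue_cutoff) |>
    dplyr::arrange(.data$evalue, dplyr::desc(.data$bitscore), .data$subject_id) |>
    dplyr::distinct(.data$query_gene, .keep_all = TRUE) |>
    dplyr::select("query_gene", "subject_id", "evalue", "bitscore")
}

#' Read / write an ortholog map as two-column TSV
#' @param path File path.
#' @export
read_ortholog_map <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(x)[1:2] <- c("gene_a", "gene_b")
  x
}

#' @rdname read_ortholog_map
#' @param orthologs Tibble with `gene_a`, `gene_b`.
#' @export
write_ortholog_map <- function(orthologs, path) {
  readr::write_tsv(orthologs[c("gene_a", "gene_b")], path, progress = FALSE)
  invisible(orthologs)
}

#' All-stages-by-all-stages Spearman similarity between two species
#'
#' For each pair of stages (one per species) the Spearman rank correlation is
#' computed across ortholog pairs between the two expression vectors. Ranks
#' use the average-tie convention (Pearson on mid-ranks), which is exact in
#' the presence of ties. Ortholog pairs silent at every stage in either
#' species are dropped first (all-tie vectors distort ranks); the number of
#' pairs actually used is recorded. A stage column constant across orthologs
#' yields `NaN` cells and a warning.
#'
#' @param expr_a,expr_b [expr_table()]s for the two species; RPKM-like
#'   (length- and library-normalized) units are recommended so cross-species
#'   magnitudes are comparable in rank space.
#' @param orthologs One-to-one map from [reciprocal_best_hits()] (columns
#'   `gene_a`, `gene_b`).
#' @return A tibble of class `similarity_grid` with `stage_a`, `stage_b`
#'   (factors in developmental order), `rho`; attribute `n_orthologs`.
#' @export
stage_similarity <- function(expr_a, expr_b, orthologs) {
  keep <- orthologs$gene_a %in% expr_a$gene_id &
    orthologs$gene_b %in% expr_b$gene_id
  orthologs <- orthologs[keep, , drop = FALSE]
  ma <- expr_values(expr_a)[orthologs$gene_a, , drop = FALSE]
  mb <- expr_values(expr_b)[orthologs$gene_b, , drop = FALSE]
  expressed <- rowSums(ma) > 0 & rowSums(mb) > 0
  if (sum(expressed) < nrow(ma))
    inform(sprintf("dropped %d ortholog pair(s) silent in one species",
                   sum(!expressed)))
  ma <- ma[expressed, , drop = FALSE]
  mb <- mb[expressed, , drop = FALSE]
  if (nrow(ma) < 3) abort("need at least 3 expressed ortholog pairs")
  rho <- suppressWarnings(cor(ma, mb, method = "spearman"))
  if (anyNA(rho)) warn("constant stage column across orthologs: NaN cells")
  out <- tibble::as_tibble(rho, rownames = "stage_a") |>
    tidyr::pivot_longer(-"stage_a", names_to = "stage_b", values_to = "rho") |>
    dplyr::mutate(
      stage_a = factor(.data$stage_a, levels = colnames(ma)),
      stage_b = factor(.data$stage_b, levels = colnames(mb)))
  class(out) <- c("similarity_grid", class(out))
  attr(out, "n_orthologs") <- nrow(ma)
  out
}

#' Best-matching partner stage per focal stage
#'
#' For every stage of species A, the species-B stage with maximal Spearman
#' rho. Ties resolve to the earliest developmental stage (with a message);
#' an all-NaN row is flagged.
#'
#' @param grid A `similarity_grid` from [stage_similarity()].
#' @return Tibble with `stage_a`, `best_stage_b`, `rho`, `flag`.
#' @export
best_matching_stage <- function(grid) {
  if (nrow(grid) == 0) abort("empty similarity grid")
  res <- grid |>
    dplyr::group_by(.data$stage_a) |>
    dplyr::group_modify(function(d, key) {
      ok <- is.finite(d$rho)
      if (!any(ok))
        return(tibble::tibble(best_stage_b = factor(NA, levels(d$stage_b)),
                              rho = NA_real_, flag = "all_nan"))
      top <- which(d$rho == max(d$rho[ok]))
      if (length(top) > 1)
        inform(sprintf("tie at stage %s resolved to earliest partner stage",
                       as.character(key$stage_a)))
      i <- top[which.min(as.integer(d$stage_b[top]))]
      tibble::tibble(best_stage_b = d$stage_b[i], rho = d$rho[i], flag = "ok")
    }) |>
    dplyr::ungroup()
  res
}

#' Write a similarity grid as a wide TSV (stages of A as rows)
#' @param grid A `similarity_grid`.
#' @param path Output path.
#' @export
write_similarity_grid <- function(grid, path) {
  wide <- tidyr::pivot_wider(grid, names_from = "stage_b", values_from = "rho")
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(grid)
}
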