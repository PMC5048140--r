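#' Transcriptome age index (TAI) per developmental stage
#'
#' `TAI_s = sum_i ps_i * e_is / sum_i e_is`: the expression-weighted mean
#' phylostratum rank of the stage's transcriptome. Lower values mean an
#' evolutionarily older transcriptome. Genes silent at every stage are
#' dropped first (with a message); a stage with zero total expression is an
#' error naming the stage.
#'
#' @param expr An [expr_table()]; length-weighted, TMM-scaled values are the
#'   intended input, but any non-negative expression units work (the index
#'   depends only on within-stage composition).
#' @param genes Gene table with a `phylostratum` column covering every matrix
#'   gene.
#' @return A stage-index profile: tibble with `stage` (factor in
#'   developmental order) and `value`, class `stage_profile`, attribute
#'   `index_kind = "TAI"`.
#' @export
#' @examples
#' ex <- expr_table(matrix(c(3, 1), 1, 2, dimnames = list("g", c("s1", "s2"))))
tai <- function(expr, genes) {
  weighted_stage_index(expr, genes, covariate = "phylostratum", kind = "TAI")
}

#' TAI excluding given phylostrata
#'
#' Recomputes [tai()] on the subset of genes whose rank is not in
#' `excluded_ranks` — e.g. dropping the species-specific "new gene" strata to
#' ask whether they drive a stage's index. An exclusion that empties a stage
#' is an error.
#'
#' @inheritParams tai
#' @param excluded_ranks Integer vector of phylostratum ranks to drop.
#' @return A `stage_profile` as in [tai()].
#' @export
tai_excluding <- function(expr, genes, excluded_ranks) {
  g <- align_genes(expr, genes, need = "phylostratum")
  keep <- !(g$phylostratum %in% excluded_ranks)
  if (!any(keep)) abort("exclusion removes every gene")
  sub <- new_expr_tbl(expr[keep, , drop = FALSE], expr_kind(expr))
  tai(sub, genes)
}

#' Transcriptome polymorphism index (TPI) per developmental stage
#'
#' `TPI_s = (sum_i theta_i * e_is / sum_i e_is) * 1000` (when
#' `kilo_scale`): the expression-weighted mean per-gene nucleotide diversity,
#' reported per kilobase. Lower values mean the stage's transcriptome is
#' dominated by genes that are more conserved within the population.
#'
#' @inheritParams tai
#' @param genes Gene table with a non-negative `theta` column.
#' @param kilo_scale Multiply by 1e3 so the units are theta per kilo
#'   nucleotide sites (default `TRUE`).
#' @return A `stage_profile` with `index_kind = "TPI"`.
#' @export
tpi <- function(expr, genes, kilo_scale = TRUE) {
  g <- align_genes(expr, genes, need = "theta")
  if (any(g$theta < 0)) abort("negative theta")
  p <- weighted_stage_index(expr, genes, covariate = "theta", kind = "TPI")
  if (kilo_scale) p$value <- p$value * 1e3
  p
}

# shared engine: expression-weighted mean of a per-gene covariate, per stage
weighted_stage_index <- function(expr, genes, covariate, kind) {
  g <- align_genes(expr, genes, need = covariate)
  if (anyNA(g[[covariate]]))
    abort(paste0("missing `", covariate, "` for some genes"))
  expr <- drop_silent_genes(expr, quiet = FALSE)
  g <- g[match(expr$gene_id, g$gene_id), , drop = FALSE]
  m <- expr_values(expr)
  tot <- colSums(m)
  if (any(tot <= 0))
    abort(paste0("zero total expression at stage(s): ",
                 paste(colnames(m)[tot <= 0], collapse = ", ")))
  vals <- as.numeric(crossprod(m, g[[covariate]])) / tot
  stage_profile(colnames(m), vals, kind)
}

stage_profile <- function(stages, values, kind) {
  out <- tibble::tibble(stage = factor(stages, levels = stages),
                        value = unname(values))
  class(out) <- c("stage_profile", class(out))
  attr(out, "index_kind") <- kind
  out
}

#' @export
print.stage_profile <- function(x, ...) {
  cat("# ", attr(x, "index_kind") %||% "index", " profile over ",
      nrow(x), " stages\n", sep = "")
  NextMethod()
}

#' Relative expression level (REL) per phylostratum and stage
#'
#' For each stage, every gene's partial concentration
#' `f_is = e_is / sum_i e_is` is computed (they sum to 1 within a stage);
#' genes are then averaged within their phylostratum, and each
#' phylostratum's mean-concentration trajectory is min-max normalized across
#' stages to `[0, 1]`. A phylostratum whose mean concentration is constant
#' across stages has no dynamics to normalize: its row is `NaN` with a
#' warning, deliberately distinct from a row at its minimum.
#'
#' @inheritParams tai
#' @return A tibble of class `rel_matrix` with columns `phylostratum`,
#'   `stage` (ordered factor), `f_bar` (mean partial concentration), `rel`.
#' @export
rel_matrix <- function(expr, genes) {
  g <- align_genes(expr, genes, need = "phylostratum")
  expr <- drop_silent_genes(expr, quiet = FALSE)
  g <- g[match(expr$gene_id, g$gene_id), , drop = FALSE]
  m <- expr_values(expr)
  f <- sweep(m, 2, colSums(m), "/")
  stages <- colnames(m)
  out <- tibble::as_tibble(f) |>
    dplyr::mutate(phylostratum = g$phylostratum) |>
    tidyr::pivot_longer(-"phylostratum", names_to = "stage",
                        values_to = "f") |>
    dplyr::summarise(f_bar = mean(.data$f),
                     .by = c("phylostratum", "stage")) |>
    dplyr::mutate(rel = minmax01(.data$f_bar), .by = "phylostratum") |>
    dplyr::mutate(stage = factor(.data$stage, levels = stages)) |>
    dplyr::arrange(.data$phylostratum, .data$stage)
  if (anyNA(out$rel))
    warn("phylostratum with constant mean concentration: REL row is NaN")
  class(out) <- c("rel_matrix", class(out))
  out
}

minmax01 <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) return(rep(NaN, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

#' Per-gene min-max normalization across stages
#'
#' Rescales each selected gene's profile to `[0, 1]`: 0 at its lowest stage,
#' 1 where it is maximally expressed — the scaling used to compare expression
#' timing across a gene panel (e.g. the Hox family). Constant genes cannot be
#' scaled: they come back as `NaN` with `flag = "constant"`.
#'
#' @param expr An `expr_tbl` with at least two stages.
#' @param gene_subset Genes to include (default: all); an unknown id is an
#'   error.
#' @return A long tibble with `gene_id`, `stage` (ordered factor), `scaled`,
#'   `flag`.
#' @export
minmax_per_gene <- function(expr, gene_subset = NULL) {
  if (length(stage_ids(expr)) < 2) abort("need at least two stages")
  if (is.null(gene_subset)) gene_subset <- expr$gene_id
  unknown <- setdiff(gene_subset, expr$gene_id)
  if (length(unknown) > 0)
    abort(paste0("unknown gene(s): ", paste(head(unknown, 5), collapse = ", ")))
  m <- expr_values(expr)[gene_subset, , drop = FALSE]
  scaled <- t(apply(m, 1, minmax01))
  colnames(scaled) <- colnames(m)
  tibble::as_tibble(scaled) |>
    dplyr::mutate(gene_id = gene_subset) |>
    tidyr::pivot_longer(-"gene_id", names_to = "stage", values_to = "scaled") |>
    dplyr::mutate(stage = factor(.data$stage, levels = colnames(m)),
                  flag = ifelse(is.nan(.data$scaled), "constant", "ok"))
}

#' Write a stage-index profile as TSV
#' @param profile A `stage_profile` (optionally carrying CI / p columns).
#' @param path Output path.
#' @export
write_profile <- function(profile, path) {
  readr::write_tsv(profile, path, progress = FALSE)
  invisible(profile)
}
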