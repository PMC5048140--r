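#' Build a lineage map
#'
#' A lineage map assigns every species in the homology database to a
#' phylostratum rank on the focal species' lineage: rank 1 is the oldest node
#' (cellular organisms), rank `n_strata` the focal-species-specific node.
#' Genes whose homologs reach no deeper than the youngest node are the
#' "new genes" of phylostratigraphy.
#'
#' @param species Character vector of species identifiers.
#' @param rank Integer phylostratum rank per species (1 = oldest).
#' @param focal_species Identifier of the focal species; must map to the
#'   maximum rank.
#' @return A tibble of class `lineage_map` with columns `species_id`, `rank`
#'   and attributes `n_strata`, `focal_species`.
#' @export
#' @examples
#' lineage_map(c("E. coli", "H. sapiens", "C. gigas"), c(1, 2, 3), "C. gigas")
lineage_map <- function(species, rank, focal_species) {
  rank <- as.integer(rank)
  if (length(species) != length(rank)) abort("species and rank lengths differ")
  if (anyDuplicated(species)) abort("each species must map to exactly one rank")
  if (any(rank < 1L)) abort("ranks must be >= 1")
  n_strata <- max(rank)
  if (!setequal(unique(rank), seq_len(n_strata)))
    abort("ranks must form a contiguous 1..n_strata range")
  if (!focal_species %in% species)
    abort("focal species absent from lineage map")
  if (rank[match(focal_species, species)] != n_strata)
    abort("focal species must map to the youngest rank (n_strata)")
  out <- tibble::tibble(species_id = as.character(species), rank = rank)
  class(out) <- c("lineage_map", class(out))
  attr(out, "n_strata") <- n_strata
  attr(out, "focal_species") <- focal_species
  out
}

#' @rdname lineage_map
#' @param lineage A `lineage_map`.
#' @export
n_strata <- function(lineage) attr(lineage, "n_strata")

#' Read a lineage map from a two-column TSV
#'
#' @param path TSV with columns `species_id`, `rank` (header optional if the
#'   columns are in that order).
#' @inheritParams lineage_map
#' @return A `lineage_map`.
#' @export
read_lineage_map <- function(path, focal_species) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(x)[1:2] <- c("species_id", "rank")
  lineage_map(x$species_id, x$rank, focal_species)
}

#' Read a homology hit table
#'
#' Accepts either the minimal 3-column layout (`query_gene`,
#' `subject_species`, `evalue`) or a BLAST tabular ("outfmt 6"-style) TSV with
#' named columns; any of `subject_id`, `bitscore`, `pct_identity_protein`,
#' `pct_identity_dna`, `aligned_gaps_protein` are carried through when
#' present.
#'
#' @param path File path.
#' @return A tibble with at least `query_gene`, `subject_species`, `evalue`.
#' @export
read_hit_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(x) == 3 && !all(c("query_gene", "subject_species", "evalue") %in% names(x)))
    names(x) <- c("query_gene", "subject_species", "evalue")
  validate_hit_table(x)
  x
}

validate_hit_table <- function(hits,
                               need = c("query_gene", "subject_species", "evalue")) {
  missing <- setdiff(need, names(hits))
  if (length(missing) > 0)
    abort(paste0("hit table lacks column(s): ", paste(missing, collapse = ", ")))
  if (any(!is.finite(hits$evalue)) || any(hits$evalue < 0))
    abort("e-values must be finite and non-negative")
  invisible(hits)
}

#' Assign phylostratum ranks to genes from homology hits
#'
#' Each gene receives the minimum phylostratum rank among subject species
#' with a hit passing the e-value cutoff — the oldest lineage node at which a
#' homolog is detectable. Genes with no qualifying hit outside the focal
#' species (including genes absent from the hit table altogether) are
#' species-specific "new genes" and receive rank `n_strata`. Self-hits
#' (subject species equal to the focal species) never inform the age.
#'
#' @param hits Hit table (see [read_hit_table()]).
#' @param lineage A [lineage_map()].
#' @param gene_ids Character vector of all genes to age; genes absent from
#'   `hits` are assigned rank `n_strata`. Defaults to the genes present in
#'   `hits`.
#' @param evalue_cutoff Hits with `evalue` above this are ignored. Default
#'   `1e-3`, the classic phylostratigraphy setting; configurable.
#' @param unknown_species `"skip"` (default) drops hit rows whose species is
#'   absent from the lineage map with one warning; `"error"` aborts.
#' @return A tibble with columns `gene_id`, `phylostratum`.
#' @export
#' @examples
#' lin <- lineage_map(c("sp1", "sp2", "focal"), 1:3, "focal")
#' hits <- tibble::tibble(query_gene = c("g1", "g1"),
#'                        subject_species = c("sp2", "sp1"),
#'                        evalue = c(1e-20, 1e-4))
#' assign_phylostrata(hits, lin, gene_ids = c("g1", "g2"))
assign_phylostrata <- function(hits, lineage, gene_ids = NULL,
                               evalue_cutoff = 1e-3,
                               unknown_species = c("skip", "error")) {
  unknown_species <- match.arg(unknown_species)
  validate_hit_table(hits)
  stopifnot(inherits(lineage, "lineage_map"), evalue_cutoff > 0)
  if (is.null(gene_ids)) gene_ids <- unique(hits$query_gene)
  gene_ids <- as.character(gene_ids)

  unknown <- !(hits$subject_species %in% lineage$species_id)
  if (any(unknown)) {
    if (unknown_species == "error")
      abort(paste0("hit rows reference species absent from the lineage map: ",
                   paste(unique(hits$subject_species[unknown])[1:min(3, sum(unknown))],
                         collapse = ", ")))
    warn(sprintf("skipping %d hit row(s) with species absent from the lineage map",
                 sum(unknown)))
    hits <- hits[!unknown, , drop = FALSE]
  }

  focal <- attr(lineage, "focal_species")
  nmax <- n_strata(lineage)
  qualifying <- hits |>
    dplyr::filter(.data$evalue <= evalue_cutoff,
                  .data$subject_species != focal) |>
    dplyr::mutate(rank = lineage$rank[match(.data$subject_species,
                                            lineage$species_id)])
  qualifying <- if (nrow(qualifying) == 0) {
    tibble::tibble(query_gene = character(), phylostratum = integer())
  } else {
    dplyr::summarise(qualifying, phylostratum = min(.data$rank),
                     .by = "query_gene")
  }

  tibble::tibble(gene_id = gene_ids) |>
    dplyr::left_join(qualifying, by = c(gene_id = "query_gene")) |>
    dplyr::mutate(phylostratum = as.integer(
      dplyr::coalesce(.data$phylostratum, nmax)))
}

#' Write gene ages as a two-column TSV
#' @param ages Tibble with `gene_id`, `phylostratum`.
#' @param path Output path.
#' @export
write_gene_ages <- function(ages, path) {
  readr::write_tsv(ages[c("gene_id", "phylostratum")], path, progress = FALSE)
  invisible(ages)
}
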