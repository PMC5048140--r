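#' Build a stage-resolved expression table
#'
#' The central container of the package is an ordinary tibble whose first
#' column is `gene_id` and whose remaining columns are developmental stages in
#' developmental order. Column order is semantically load-bearing: every index
#' profile inherits it. A `kind` attribute records the processing state of the
#' values (`"raw_counts"`, `"length_weighted"`, `"tmm_scaled"`, `"rpkm"`).
#'
#' @param x A data frame with a `gene_id` column and one numeric column per
#'   stage, or a numeric matrix with gene row names.
#' @param stages Optional character vector giving the developmental stage
#'   order. Defaults to the column order of `x`.
#' @param kind Processing state of the values.
#' @return A tibble of class `expr_tbl` (genes x stages) with attribute
#'   `kind`.
#' @export
#' @examples
#' m <- matrix(1:6, 2, dimnames = list(c("g1", "g2"), c("egg", "larva", "adult")))
#' expr_table(m)
expr_table <- function(x, stages = NULL,
                       kind = c("raw_counts", "length_weighted",
                                "tmm_scaled", "rpkm")) {
  kind <- match.arg(kind)
  if (is.matrix(x)) {
    if (is.null(rownames(x))) abort("matrix input needs gene row names")
    if (is.null(colnames(x))) colnames(x) <- paste0("s", seq_len(ncol(x)))
    x <- tibble::as_tibble(x, rownames = "gene_id")
  }
  x <- tibble::as_tibble(x)
  if (!"gene_id" %in% names(x)) abort("expression table needs a `gene_id` column")
  x <- dplyr::relocate(x, "gene_id")
  if (!is.null(stages)) {
    missing <- setdiff(stages, names(x))
    if (length(missing) > 0)
      abort(paste0("stages absent from table: ", paste(missing, collapse = ", ")))
    x <- dplyr::select(x, "gene_id", dplyr::all_of(stages))
  }
  vals <- as.matrix(x[-1])
  if (ncol(vals) < 1) abort("expression table needs at least one stage column")
  if (!is.numeric(vals)) abort("stage columns must be numeric")
  if (anyNA(vals)) abort("expression values must not be missing")
  if (any(vals < 0)) abort("expression values must be non-negative")
  if (anyDuplicated(x$gene_id)) abort("gene ids must be unique")
  new_expr_tbl(x, kind)
}

new_expr_tbl <- function(x, kind) {
  x <- tibble::as_tibble(x)
  class(x) <- c("expr_tbl", class(x))
  attr(x, "kind") <- kind
  x
}

#' @export
print.expr_tbl <- function(x, ...) {
  cat("# Expression table (", expr_kind(x), "): ",
      nrow(x), " genes x ", length(stage_ids(x)), " stages\n", sep = "")
  NextMethod()
}

#' Stage identifiers of an expression table, in developmental order
#' @param expr An `expr_tbl`.
#' @return Character vector of stage ids.
#' @export
stage_ids <- function(expr) setdiff(names(expr), "gene_id")

#' Processing state of an expression table
#' @param expr An `expr_tbl`.
#' @return One of `"raw_counts"`, `"length_weighted"`, `"tmm_scaled"`, `"rpkm"`.
#' @export
expr_kind <- function(expr) attr(expr, "kind") %||% "raw_counts"

# numeric matrix view (genes x stages), gene ids as row names
expr_values <- function(expr) {
  m <- as.matrix(expr[setdiff(names(expr), "gene_id")])
  rownames(m) <- expr$gene_id
  storage.mode(m) <- "double"
  m
}

# rebuild an expr_tbl from a values matrix, keeping stage order
expr_replace <- function(expr, values, kind = expr_kind(expr)) {
  out <- tibble::as_tibble(values)
  out <- dplyr::bind_cols(tibble::tibble(gene_id = rownames(values)), out)
  new_expr_tbl(out, kind)
}

#' Read / write expression tables as TSV
#'
#' TSV layout: first column `gene_id`, header row of stage ids in
#' developmental order.
#'
#' @param path File path.
#' @param stages Optional explicit stage order (subset/reorder of columns).
#' @inheritParams expr_table
#' @return `read_expr_table()` a tibble of class `expr_tbl`;
#'   `write_expr_table()` the input, invisibly.
#' @export
read_expr_table <- function(path, stages = NULL, kind = "raw_counts") {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(x)[1] <- "gene_id"
  expr_table(x, stages = stages, kind = kind)
}

#' @rdname read_expr_table
#' @param expr An `expr_tbl`.
#' @export
write_expr_table <- function(expr, path) {
  readr::write_tsv(expr, path, progress = FALSE)
  invisible(expr)
}

#' Read / write per-gene metadata tables
#'
#' A gene table carries `gene_id`, `cds_length` (bp) and, once computed,
#' `phylostratum` (integer rank) and `theta` (per-site nucleotide diversity).
#'
#' @param path File path to a TSV with at least columns `gene_id` and
#'   `cds_length`.
#' @return A tibble.
#' @export
read_gene_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_gene_table(x)
  x
}

#' @rdname read_gene_table
#' @param genes A gene table.
#' @export
write_gene_table <- function(genes, path) {
  readr::write_tsv(genes, path, progress = FALSE)
  invisible(genes)
}

validate_gene_table <- function(genes, need = "cds_length") {
  if (!"gene_id" %in% names(genes)) abort("gene table needs a `gene_id` column")
  if (anyDuplicated(genes$gene_id)) abort("duplicate gene ids in gene table")
  for (col in need) {
    if (!col %in% names(genes))
      abort(paste0("gene table needs a `", col, "` column"))
  }
  if ("cds_length" %in% names(genes) && any(genes$cds_length <= 0, na.rm = TRUE))
    abort("CDS lengths must be positive")
  invisible(genes)
}

# align a gene table to the rows of an expr_tbl, erroring on absentees
align_genes <- function(expr, genes, need) {
  validate_gene_table(genes, need = need)
  missing <- setdiff(expr$gene_id, genes$gene_id)
  if (length(missing) > 0)
    abort(paste0("genes missing from gene table: ",
                 paste(head(missing, 5), collapse = ", "),
                 if (length(missing) > 5) sprintf(" (and %d more)", length(missing) - 5)))
  genes[match(expr$gene_id, genes$gene_id), , drop = FALSE]
}

#' Drop genes with zero expression at every stage
#'
#' Genes that are silent across the whole series contribute nothing to any
#' expression-weighted index and break per-phylostratum means, so they are
#' removed before index computation. The number removed is reported once.
#'
#' @param expr An `expr_tbl`.
#' @param quiet Suppress the message.
#' @return The filtered `expr_tbl`.
#' @export
drop_silent_genes <- function(expr, quiet = FALSE) {
  m <- expr_values(expr)
  keep <- rowSums(m) > 0
  if (!all(keep) && !quiet)
    inform(sprintf("dropped %d gene(s) with zero expression at every stage",
                   sum(!keep)))
  new_expr_tbl(expr[keep, , drop = FALSE], expr_kind(expr))
}
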