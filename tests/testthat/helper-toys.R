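# small builders shared across test files

toy_expr <- function(m, kind = "raw_counts") {
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  expr_table(m, kind = kind)
}

toy_genes <- function(expr, cds_length = 1000L, phylostratum = NULL,
                      theta = NULL) {
  g <- tibble::tibble(gene_id = expr$gene_id,
                      cds_length = rep_len(cds_length, nrow(expr)))
  if (!is.null(phylostratum)) g$phylostratum <- phylostratum
  if (!is.null(theta)) g$theta <- theta
  g
}

# two-library count matrix with a fraction of genes inflated in library B;
# deterministic given seed
tmm_fixture <- function(n_genes = 200, inflated_frac = 0.05, fold = 8,
                        seed = 42) {
  withr::with_seed(seed, {
    base <- rnbinom(n_genes, mu = 200, size = 10) + 1
    b <- base
    hot <- seq_len(round(inflated_frac * n_genes))
    b[hot] <- b[hot] * fold
    m <- cbind(A = base, B = b)
    rownames(m) <- sprintf("g%03d", seq_len(n_genes))
    m
  })
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))
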