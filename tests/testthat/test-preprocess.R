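test_that("length weighting divides by CDS length and preserves zeros", {
  ex <- toy_expr(matrix(c(100, 0, 100, 100), 2, byrow = TRUE))
  genes <- toy_genes(ex, cds_length = c(1000L, 500L))
  lw <- length_weight(ex, genes)
  expect_equal(unname(as.matrix(lw[-1])),
               matrix(c(0.1, 0, 0.2, 0.2), 2, byrow = TRUE))
  expect_equal(expr_kind(lw), "length_weighted")

  # counts (100, 100) with lengths (500, 2000) -> weighted 0.2 and 0.05, 4:1
  ex2 <- toy_expr(matrix(c(100, 100), 2, 1))
  lw2 <- length_weight(ex2, toy_genes(ex2, c(500L, 2000L)))
  expect_equal(lw2$s1, c(0.2, 0.05))

  bad <- toy_genes(ex, cds_length = c(1000L, NA))
  expect_error(length_weight(ex, bad), "g2")
})

test_that("rpkm follows the per-kilobase per-million convention", {
  ex <- toy_expr(matrix(c(10, 1e6 - 10), 2, 1))
  out <- rpkm(ex, toy_genes(ex, cds_length = c(1000L, 1000L)))
  expect_equal(out$s1[1], 10)

  ex2 <- toy_expr(matrix(c(5, 2e6 - 5), 2, 1))
  out2 <- rpkm(ex2, toy_genes(ex2, cds_length = c(500L, 1000L)))
  expect_equal(out2$s1[1], 5)

  # doubling every count in a stage leaves RPKM unchanged
  m <- matrix(c(10, 90, 20, 180), 2)
  ex3 <- toy_expr(m); ex4 <- toy_expr(m * 2)
  g <- toy_genes(ex3, c(300L, 700L))
  expect_equal(rpkm(ex3, g)$s1, rpkm(ex4, g)$s1)

  ex5 <- toy_expr(matrix(c(0, 0, 1, 1), 2))
  expect_error(rpkm(ex5, toy_genes(ex5)), "library size")
})

test_that("TMM factors are 1 for identical and proportional libraries", {
  m <- tmm_fixture()
  same <- toy_expr(cbind(A = m[, 1], B = m[, 1]))
  expect_equal(as.numeric(tmm_factors(same)), c(1, 1))
  prop <- toy_expr(cbind(A = m[, 1], B = 2 * m[, 1]))
  expect_equal(as.numeric(tmm_factors(prop)), c(1, 1))
})

test_that("TMM factors match the independent reference implementation", {
  skip_if_not_installed("edgeR")
  m <- tmm_fixture(n_genes = 200, inflated_frac = 0.05, fold = 8)
  ours <- as.numeric(tmm_factors(toy_expr(m)))
  theirs <- edgeR::calcNormFactors(m, method = "TMM")
  expect_lt(max(abs(ours - theirs)), 1e-6)

  # and on a wider matrix with several stages
  withr::with_seed(7, {
    m5 <- matrix(rnbinom(200 * 5, mu = 150, size = 5) + 1, 200)
    rownames(m5) <- sprintf("g%03d", 1:200)
    colnames(m5) <- paste0("s", 1:5)
  })
  expect_lt(max(abs(tmm_factors(toy_expr(m5)) -
                      edgeR::calcNormFactors(m5, method = "TMM"))), 1e-6)
})

test_that("TMM factors are invariant to per-stage library scaling", {
  m <- tmm_fixture(n_genes = 150)
  scaled <- sweep(m, 2, c(3.7, 0.21), "*")
  expect_equal(tmm_factors(toy_expr(m)), tmm_factors(toy_expr(scaled)),
               tolerance = 1e-12)
  ex0 <- toy_expr(cbind(A = c(0, 0), B = c(1, 1)))
  expect_error(tmm_factors(ex0), "all-zero")
})

test_that("correlated near-duplicates collapse to one representative", {
  # g1-g2-g3 one component (r ~ 1), g4-g5 another, g6 uncorrelated
  base <- c(1, 5, 20, 5, 1) * 1000
  dip <- c(10, 2, 1, 3, 12) * 1000
  m <- rbind(g1 = base, g2 = base * 2.001, g3 = base * c(1.99, 2, 2, 2, 2),
             g4 = dip, g5 = dip * 3,
             g6 = c(5, 5, 200, 5, 300) * 100)
  ex <- toy_expr(m)
  genes <- toy_genes(ex, cds_length = c(300L, 400L, 400L, 250L, 260L, 200L))
  # brute-force oracle: pairwise Pearson + connected components
  cm <- cor(t(m))
  expect_true(all(cm[1:3, 1:3] > 0.99))
  expect_true(cm[4, 5] > 0.99)
  expect_true(max(cm[6, -6]) < 0.99)

  res <- filter_correlated_duplicates(ex, genes, min_peak_expression = 1e4,
                                      max_length_bp = 500)
  expect_equal(nrow(res$removed), 3)
  expect_setequal(res$expr$gene_id, c("g2", "g5", "g6"))
  # representative = longest CDS, tie -> smallest id
  expect_true("g2" %in% res$expr$gene_id)   # 400 bp ties g3, id g2 wins
  expect_false(any(c("g1", "g3") %in% res$expr$gene_id))
  expect_true("g5" %in% res$expr$gene_id && !"g4" %in% res$expr$gene_id)
})

test_that("correlation filter leaves non-candidates and weak pairs alone", {
  m <- rbind(g1 = c(1, 2, 3) * 1e5, g2 = c(3, 1, 2) * 1e5)
  ex <- toy_expr(m)
  res <- filter_correlated_duplicates(ex, toy_genes(ex, 300L),
                                      min_peak_expression = 1e4,
                                      max_length_bp = 500)
  expect_equal(nrow(res$removed), 0)
  expect_equal(nrow(res$expr), 2)

  # constant-expression candidate is excluded from candidacy with a note
  m2 <- rbind(g1 = rep(2e4, 3), g2 = rep(2e4, 3), g3 = c(1, 5, 9) * 1e4)
  ex2 <- toy_expr(m2)
  expect_message(
    res2 <- filter_correlated_duplicates(ex2, toy_genes(ex2, 300L),
                                         min_peak_expression = 1e4,
                                         max_length_bp = 500),
    "constant")
  expect_equal(nrow(res2$removed), 0)
})

test_that("sequence-redundancy clustering follows the identity and gap rules", {
  genes <- tibble::tibble(gene_id = c("A", "B", "C", "D", "E"),
                          cds_length = c(900L, 1200L, 800L, 500L, 500L))
  aln <- tibble::tibble(
    query_gene = c("A", "B", "A", "D"),
    subject_id = c("B", "C", "C", "E"),
    pct_identity_protein = c(98, 97.5, 99, 98),
    pct_identity_dna = c(96, 95.5, 96, 96),
    aligned_gaps_protein = c(0L, 0L, 0L, 1L))
  # chain A-B, B-C pass; A-C irrelevant; D-E blocked by the gap
  res <- filter_sequence_redundant(aln, genes)
  expect_setequal(res$kept, c("B", "D", "E"))  # B longest in {A,B,C}
  expect_equal(sort(res$removed$gene_id), c("A", "C"))
  expect_equal(unique(res$removed$representative), "B")

  # below-threshold identity never clusters
  aln2 <- aln; aln2$pct_identity_dna <- c(94, 94, 94, 96)
  expect_equal(nrow(filter_sequence_redundant(aln2, genes)$removed), 0)

  aln3 <- aln; aln3$subject_id[1] <- "ghost"
  expect_error(filter_sequence_redundant(aln3, genes), "unknown gene")
})

test_that("length-weighting then column normalization is proportional to RPKM", {
  withr::with_seed(3, m <- matrix(rpois(40, 60) + 1, 8, 5))
  ex <- toy_expr(m)
  genes <- toy_genes(ex, cds_length = sample(300:3000, 8))
  lw <- as.matrix(length_weight(ex, genes)[-1])
  lw_norm <- sweep(lw, 2, colSums(lw), "/")
  rp <- as.matrix(rpkm(ex, genes)[-1])
  for (s in 1:5) {
    ratio <- rp[, s] / lw_norm[, s]
    expect_lt(diff(range(ratio)) / mean(ratio), 1e-12)
  }
})

test_that("redundancy filters are idempotent and order-stable", {
  base <- c(2, 8, 30, 8, 2) * 1e4
  m <- rbind(g1 = base, g2 = base * 1.5, g3 = c(9, 1, 4, 1, 8) * 1e4,
             g4 = c(1, 2, 30, 2, 1))
  ex <- toy_expr(m)
  genes <- toy_genes(ex, cds_length = c(400L, 300L, 350L, 450L))
  r1 <- filter_correlated_duplicates(ex, genes, min_peak_expression = 1e4,
                                     max_length_bp = 500)
  r2 <- filter_correlated_duplicates(r1$expr, genes,
                                     min_peak_expression = 1e4,
                                     max_length_bp = 500)
  expect_equal(nrow(r2$removed), 0)
  expect_identical(r1$expr$gene_id, r2$expr$gene_id)
})
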