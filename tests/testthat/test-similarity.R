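test_that("reciprocal best hits require mutual best status", {
  ab <- tibble::tibble(query_gene = c("a1", "a1", "a2"),
                       subject_id = c("b1", "b2", "b2"),
                       evalue = c(1e-30, 1e-10, 1e-20),
                       bitscore = c(300, 100, 200))
  ba <- tibble::tibble(query_gene = c("b1", "b2"),
                       subject_id = c("a1", "a1"),
                       evalue = c(1e-30, 1e-18),
                       bitscore = c(300, 150))
  rbh <- reciprocal_best_hits(ab, ba)
  # a1<->b1 mutual; a2's best is b2 but b2's best is a1 -> no pair with a2
  expect_equal(rbh$gene_a, "a1")
  expect_equal(rbh$gene_b, "b1")
})

test_that("best-hit ties break by bitscore then subject id, matching enumeration", {
  ab <- tibble::tibble(query_gene = rep("a1", 3),
                       subject_id = c("b3", "b1", "b2"),
                       evalue = c(1e-20, 1e-20, 1e-20),
                       bitscore = c(180, 250, 250))
  ba <- tibble::tibble(query_gene = c("b1", "b2", "b3"),
                       subject_id = rep("a1", 3),
                       evalue = c(1e-20, 1e-9, 1e-4),
                       bitscore = c(250, 90, 60))
  # brute force: qualifying hits for a1 all tie on evalue; highest bitscore is
  # {b1, b2} at 250; smallest id b1. b1's best is a1. -> (a1, b1)
  rbh <- reciprocal_best_hits(ab, ba, evalue_cutoff = 1e-5)
  expect_equal(rbh$gene_b, "b1")
  # the 1e-4 hit never qualifies
  expect_false("b3" %in% rbh$gene_b)
})

test_that("RBH is symmetric and one-to-one on random toy tables", {
  withr::with_seed(5, {
    for (rep in 1:10) {
      ab <- tibble::tibble(
        query_gene = sample(paste0("a", 1:6), 20, replace = TRUE),
        subject_id = sample(paste0("b", 1:6), 20, replace = TRUE),
        evalue = 10^runif(20, -40, -6),
        bitscore = runif(20, 50, 300))
      ba <- tibble::tibble(
        query_gene = sample(paste0("b", 1:6), 20, replace = TRUE),
        subject_id = sample(paste0("a", 1:6), 20, replace = TRUE),
        evalue = 10^runif(20, -40, -6),
        bitscore = runif(20, 50, 300))
      fwd <- reciprocal_best_hits(ab, ba)
      rev <- reciprocal_best_hits(ba, ab)
      expect_setequal(paste(fwd$gene_a, fwd$gene_b),
                      paste(rev$gene_b, rev$gene_a))
      expect_false(anyDuplicated(fwd$gene_a) > 0)
      expect_false(anyDuplicated(fwd$gene_b) > 0)
    }
  })
})

make_pair <- function(ma, mb) {
  orth <- tibble::tibble(gene_a = rownames(ma), gene_b = rownames(mb))
  list(a = expr_table(ma), b = expr_table(mb), orth = orth)
}

test_that("Spearman similarity is exact on enumerated ranks", {
  # ranks (1..5) vs (2,1,4,3,5): sum d^2 = 4 -> rho = 1 - 24/120 = 0.8
  ma <- matrix(1:5, 5, 1, dimnames = list(paste0("a", 1:5), "sA"))
  mb <- matrix(c(2, 1, 4, 3, 5), 5, 1, dimnames = list(paste0("b", 1:5), "sB"))
  pr <- make_pair(ma, mb)
  grid <- stage_similarity(pr$a, pr$b, pr$orth)
  expect_equal(grid$rho, 0.8)
})

test_that("Spearman similarity is invariant to monotone transforms and antitone to reversal", {
  withr::with_seed(8, x <- runif(9, 1, 100))
  ma <- matrix(x, 9, 1, dimnames = list(paste0("a", 1:9), "sA"))
  mb <- matrix(exp(x / 20), 9, 1, dimnames = list(paste0("b", 1:9), "sB"))
  pr <- make_pair(ma, mb)
  expect_equal(stage_similarity(pr$a, pr$b, pr$orth)$rho, 1)
  mb_rev <- matrix(max(x) + 1 - x, 9, 1,
                   dimnames = list(paste0("b", 1:9), "sB"))
  pr2 <- make_pair(ma, mb_rev)
  expect_equal(stage_similarity(pr2$a, pr2$b, pr2$orth)$rho, -1)
})

test_that("the similarity grid transposes correctly between species", {
  withr::with_seed(13, {
    ma <- matrix(rpois(40, 30) + 1, 10, 4,
                 dimnames = list(paste0("a", 1:10), paste0("sA", 1:4)))
    mb <- matrix(rpois(30, 30) + 1, 10, 3,
                 dimnames = list(paste0("b", 1:10), paste0("sB", 1:3)))
  })
  pr <- make_pair(ma, mb)
  g_ab <- stage_similarity(pr$a, pr$b, pr$orth)
  orth_rev <- tibble::tibble(gene_a = pr$orth$gene_b, gene_b = pr$orth$gene_a)
  g_ba <- stage_similarity(pr$b, pr$a, orth_rev)
  merged <- dplyr::inner_join(
    g_ab, g_ba, by = c(stage_a = "stage_b", stage_b = "stage_a"))
  expect_equal(merged$rho.x, merged$rho.y)
})

test_that("silent ortholog pairs are dropped and tiny maps rejected", {
  ma <- rbind(a1 = c(1, 2), a2 = c(3, 1), a3 = c(2, 5), a4 = c(0, 0))
  mb <- rbind(b1 = c(2, 1), b2 = c(4, 4), b3 = c(1, 9), b4 = c(0, 0))
  pr <- make_pair(ma, mb)
  expect_message(g <- stage_similarity(pr$a, pr$b, pr$orth), "silent")
  expect_equal(attr(g, "n_orthologs"), 3)
  expect_error(quiet(stage_similarity(pr$a, pr$b, pr$orth[1:2, ])),
               "at least 3")
})

test_that("best matching stage is the diagonal for self-similarity", {
  withr::with_seed(4, m <- matrix(rpois(50, 40) + 1, 10, 5,
                                  dimnames = list(paste0("a", 1:10),
                                                  paste0("s", 1:5))))
  ex <- expr_table(m)
  orth <- tibble::tibble(gene_a = rownames(m), gene_b = rownames(m))
  grid <- stage_similarity(ex, ex, orth)
  best <- best_matching_stage(grid)
  expect_equal(as.character(best$best_stage_b), as.character(best$stage_a))
  expect_equal(best$rho, rep(1, 5))
})

test_that("argmax ties resolve to the earliest partner stage with a message", {
  grid <- tibble::tibble(
    stage_a = factor(rep("s1", 3), "s1"),
    stage_b = factor(c("t1", "t2", "t3"), c("t1", "t2", "t3")),
    rho = c(0.4, 0.9, 0.9))
  class(grid) <- c("similarity_grid", class(grid))
  expect_message(best <- best_matching_stage(grid), "tie")
  expect_equal(as.character(best$best_stage_b), "t2")
})
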