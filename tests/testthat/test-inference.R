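test_that("bootstrap band collapses for identical genes and brackets the estimate", {
  m <- matrix(rep(c(2, 5, 3), each = 4), 4, 3,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  ex <- expr_table(m)
  genes <- toy_genes(ex, phylostratum = rep(6L, 4))
  ci <- bootstrap_ci(ex, genes, "TAI", n_boot = 100, seed = 1)
  expect_equal(ci$ci_low, ci$value)
  expect_equal(ci$ci_high, ci$value)

  withr::with_seed(10, m2 <- matrix(rpois(60, 40) + 1, 12, 5))
  ex2 <- toy_expr(m2)
  genes2 <- toy_genes(ex2, phylostratum = sample(1:11, 12, replace = TRUE))
  ci2 <- bootstrap_ci(ex2, genes2, "TAI", n_boot = 500, seed = 2)
  expect_true(all(ci2$ci_low <= ci2$value & ci2$value <= ci2$ci_high))
  # determinism under a fixed seed
  ci3 <- bootstrap_ci(ex2, genes2, "TAI", n_boot = 500, seed = 2)
  expect_identical(ci2, ci3)
  expect_error(bootstrap_ci(ex2, genes2, n_boot = 50), "at least 100")
})

test_that("a constant covariate gives surrogates equal to the observed index and p = 1", {
  withr::with_seed(6, m <- matrix(rpois(40, 30) + 1, 8, 5))
  ex <- toy_expr(m)
  genes <- toy_genes(ex, phylostratum = rep(4L, 8))
  expect_warning(null <- permutation_null(ex, genes, "TAI", n_perm = 100,
                                          seed = 3),
                 "degenerate")
  expect_true(all(abs(null$surrogates - 4) < 1e-12))
  expect_equal(null$p_stage, rep(1, 5))
  expect_equal(null$p_combined, 1)
})

test_that("permutations are deterministic under a fixed seed", {
  withr::with_seed(14, m <- matrix(rpois(50, 25) + 1, 10, 5))
  ex <- toy_expr(m)
  genes <- toy_genes(ex, phylostratum = sample(1:11, 10, replace = TRUE))
  n1 <- permutation_null(ex, genes, "TAI", n_perm = 150, seed = 42)
  n2 <- permutation_null(ex, genes, "TAI", n_perm = 150, seed = 42)
  expect_identical(n1$surrogates, n2$surrogates)
  expect_identical(n1$p_combined, n2$p_combined)
})

test_that("sampled surrogates match exhaustive enumeration on a 4-gene toy", {
  # 4! = 24 equally likely pairings: exact mean and variance by enumeration
  cov <- c(1, 2, 3, 11)
  w <- c(0.4, 0.3, 0.2, 0.1)
  perms <- as.matrix(expand.grid(rep(list(1:4), 4)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ]
  exact <- apply(perms, 1, function(p) sum(cov[p] * w))
  exact_mean <- mean(exact)
  exact_var <- var(exact) * (length(exact) - 1) / length(exact)

  ex <- toy_expr(matrix(w * 100, 4, 1))
  genes <- toy_genes(ex, phylostratum = as.integer(cov))
  null <- permutation_null(ex, genes, "TAI", n_perm = 4000, seed = 9)
  s <- null$surrogates[, 1]
  se_mean <- sd(s) / sqrt(length(s))
  expect_lt(abs(mean(s) - exact_mean), 4 * se_mean)
  se_var <- var(s) * sqrt(2 / (length(s) - 1))
  expect_lt(abs(var(s) * (length(s) - 1) / length(s) - exact_var), 4 * se_var)
})

test_that("gamma moment fit inverts sample moments and recovers simulated parameters", {
  # mean 2, variance 1 -> shape 4, scale 0.5
  x <- c(1, 2, 3)  # mean 2, var 1
  fit <- gamma_moment_fit(x)
  expect_equal(unname(fit), c(4, 0.5))

  withr::with_seed(77, y <- rgamma(1e5, shape = 4, scale = 0.5))
  fit2 <- gamma_moment_fit(y)
  expect_lt(abs(fit2[["shape"]] - 4) / 4, 0.05)
  expect_lt(abs(fit2[["scale"]] - 0.5) / 0.5, 0.05)

  expect_error(gamma_moment_fit(rep(3, 10)), "degenerate")
})

test_that("stage p-values follow the fitted gamma tail", {
  med <- qgamma(0.5, shape = 4, scale = 0.5)
  expect_equal(stage_p_value(med, 4, 0.5), 1)
  expect_lt(stage_p_value(1e4, 4, 0.5), 1e-12)
  expect_equal(stage_p_value(qgamma(0.975, 4, scale = 0.5), 4, 0.5), 0.05,
               tolerance = 1e-10)
  expect_warning(p0 <- stage_p_value(0, 4, 0.5), "boundary")
  expect_gt(p0, 0)
  expect_error(stage_p_value(1, -1, 0.5), "invalid gamma")
})

test_that("gamma p agrees with an empirical-null p within a factor of two", {
  # empirical oracle: rank among a large Monte Carlo null sample
  withr::with_seed(31, draws <- rgamma(1e6, shape = 4, scale = 0.5))
  obs <- 0.40
  emp <- 2 * min(mean(draws <= obs), mean(draws >= obs))
  gam <- stage_p_value(obs, 4, 0.5)
  expect_gt(gam / emp, 0.5)
  expect_lt(gam / emp, 2)
})

test_that("Fisher combination matches the closed form and is monotone", {
  expect_equal(combine_p(c(1, 1, 1)), 1)
  # p = (0.05, 0.05): X = -4 log 0.05, df 4 -> exp(-X/2) * (1 + X/2)
  x <- -4 * log(0.05)
  expect_equal(combine_p(c(0.05, 0.05)), exp(-x / 2) * (1 + x / 2))
  withr::with_seed(2, {
    for (rep in 1:20) {
      p <- runif(6)
      smaller <- p * runif(6)
      expect_lte(combine_p(smaller), combine_p(p))
    }
  })
  expect_warning(pz <- combine_p(c(0, 0.5)), "clamped")
  expect_gt(pz, 0)
  expect_error(combine_p(c(0.5, 1.2)), "at most 1")
  # stouffer sanity: symmetric around p = 0.5
  expect_equal(combine_p(c(0.5, 0.5), method = "stouffer"), 0.5)
})

test_that("gamma-fit and empirical permutation p agree on a matched null", {
  withr::with_seed(17, {
    w <- rlnorm(60, 0, 1); w <- w / sum(w)
    cov <- sample(1:11, 60, replace = TRUE)
    surr <- vapply(1:20000, function(i) sum(cov[sample.int(60)] * w),
                   numeric(1))
  })
  fit <- gamma_moment_fit(surr)
  for (q in c(0.8, 0.9, 0.975)) {
    obs <- quantile(surr, q, names = FALSE)
    emp <- 2 * min(mean(surr <= obs), mean(surr >= obs))
    gam <- stage_p_value(obs, fit[["shape"]], fit[["scale"]])
    if (emp >= 1e-3) {
      expect_gt(gam / emp, 0.5)
      expect_lt(gam / emp, 2)
    }
  }
})

test_that("tidy and glance expose the null model as tibbles", {
  withr::with_seed(23, m <- matrix(rpois(40, 30) + 1, 8, 5))
  ex <- toy_expr(m)
  genes <- toy_genes(ex, phylostratum = sample(1:11, 8, replace = TRUE))
  null <- permutation_null(ex, genes, "TAI", n_perm = 100, seed = 1)
  td <- tidy(null)
  expect_equal(nrow(td), 5)
  expect_true(all(c("stage", "observed", "shape", "scale", "p") %in% names(td)))
  gl <- glance(null)
  expect_equal(nrow(gl), 1)
  expect_true(gl$p_combined > 0 && gl$p_combined <= 1)
})
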