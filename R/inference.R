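# shared setup for TAI/TPI resampling: aligned covariate + expression matrix
prepare_index <- function(expr, genes, index, kilo_scale = TRUE) {
  index <- match.arg(index, c("TAI", "TPI"))
  covariate <- if (index == "TAI") "phylostratum" else "theta"
  g <- align_genes(expr, genes, need = covariate)
  expr <- drop_silent_genes(expr, quiet = TRUE)
  g <- g[match(expr$gene_id, g$gene_id), , drop = FALSE]
  m <- expr_values(expr)
  cov <- as.numeric(g[[covariate]])
  if (anyNA(cov)) abort(paste0("missing `", covariate, "` for some genes"))
  if (index == "TPI" && any(cov < 0)) abort("negative theta")
  scale <- if (index == "TPI" && kilo_scale) 1e3 else 1
  list(m = m, cov = cov * scale, stages = colnames(m), index = index)
}

observed_index <- function(prep) {
  as.numeric(crossprod(prep$m, prep$cov)) / colSums(prep$m)
}

#' Gene-resampling bootstrap confidence band for an index profile
#'
#' Genes are resampled with replacement; by default the same resample is
#' applied at every stage within a replicate, so the band reflects profile-
#' coherent sampling variation (set `shared_resample = FALSE` for independent
#' per-stage resampling). Percentile intervals at `(1 - level)/2` and
#' `1 - (1 - level)/2` are attached per stage. A degenerate resample in which
#' some stage totals zero expression is redrawn, up to 100 attempts.
#'
#' @inheritParams tai
#' @param index `"TAI"` or `"TPI"`.
#' @param n_boot Number of bootstrap replicates (at least 100; default 1000).
#' @param level Interval coverage level (default 0.95).
#' @param seed Integer seed for reproducibility (optional).
#' @param shared_resample Share one resample across stages per replicate
#'   (default `TRUE`).
#' @param kilo_scale For TPI, report per kilobase (default `TRUE`).
#' @return A `stage_profile` tibble with `stage`, `value`, `ci_low`,
#'   `ci_high`; attributes `n_boot`, `level`.
#' @export
bootstrap_ci <- function(expr, genes, index = "TAI", n_boot = 1000,
                         level = 0.95, seed = NULL, shared_resample = TRUE,
                         kilo_scale = TRUE) {
  if (n_boot < 100) abort("n_boot must be at least 100")
  prep <- prepare_index(expr, genes, index, kilo_scale)
  n <- nrow(prep$m)
  if (n < 2) abort("need at least 2 genes to bootstrap")
  obs <- observed_index(prep)
  boots <- with_seed_if(seed, {
    t(vapply(seq_len(n_boot), function(b) {
      boot_one(prep, shared_resample)
    }, numeric(length(prep$stages))))
  })
  alpha <- (1 - level) / 2
  ci <- apply(boots, 2, quantile, probs = c(alpha, 1 - alpha), names = FALSE)
  out <- stage_profile(prep$stages, obs, prep$index)
  out$ci_low <- unname(ci[1, ])
  out$ci_high <- unname(ci[2, ])
  attr(out, "n_boot") <- n_boot
  attr(out, "level") <- level
  out
}

boot_one <- function(prep, shared_resample, max_retry = 100) {
  n <- nrow(prep$m)
  for (try in seq_len(max_retry)) {
    if (shared_resample) {
      idx <- sample.int(n, n, replace = TRUE)
      tot <- colSums(prep$m[idx, , drop = FALSE])
      if (all(tot > 0))
        return(as.numeric(crossprod(prep$m[idx, , drop = FALSE],
                                    prep$cov[idx])) / tot)
    } else {
      val <- vapply(seq_along(prep$stages), function(s) {
        idx <- sample.int(n, n, replace = TRUE)
        tot <- sum(prep$m[idx, s])
        if (tot <= 0) return(NA_real_)
        sum(prep$m[idx, s] * prep$cov[idx]) / tot
      }, numeric(1))
      if (!anyNA(val)) return(val)
    }
  }
  abort("bootstrap resampling kept producing zero-expression stages")
}

#' Per-stage permutation null for an index profile
#'
#' Within each developmental stage, the per-gene covariate (phylostratum
#' rank for TAI, theta for TPI) is permuted across genes `n_perm` times and
#' the surrogate index recomputed, breaking the gene-to-expression pairing
#' while preserving both marginals. Each stage's surrogate distribution is
#' summarized by a gamma fitted with the method of moments; the observed
#' index is converted to a per-stage p-value under that gamma; and the
#' per-stage p-values are combined into one pattern p-value.
#'
#' The per-stage p-values are strongly dependent — every stage shares the
#' same covariate pairing, and expression weights are correlated across
#' development — so a combination that assumes independence is
#' anti-conservative. The default therefore re-uses one permutation across
#' all stages within each surrogate replicate and refers the observed
#' Fisher statistic `X = -2 * sum(log(p_s))` to the empirical distribution
#' of the surrogate replicates' own `X` values, a permutation-calibrated
#' combination whose type-I error is controlled by construction (its
#' resolution is `1 / (n_perm + 1)`). Setting `combine = "fisher"` or
#' `"stouffer"` instead applies the closed-form independence combiners, and
#' `share_permutations = FALSE` draws fresh permutations per stage.
#'
#' When the covariate is constant across genes every surrogate equals the
#' observed value; such stages get `p = 1` by convention.
#'
#' @inheritParams bootstrap_ci
#' @param n_perm Number of permutations per stage (at least 100; default
#'   1000).
#' @param alternative `"two.sided"` (default), `"less"`, or `"greater"`.
#' @param combine `"empirical"` (default; permutation-calibrated Fisher),
#'   `"fisher"`, or `"stouffer"`.
#' @param share_permutations Re-use one permutation across stages within a
#'   surrogate replicate (default `TRUE`; required for the empirical
#'   combination to respect cross-stage dependence).
#' @return An object of class `index_null`: use [tidy()] for the per-stage
#'   table (observed value, gamma shape/scale, p), [glance()] for the
#'   one-row summary with the combined p.
#' @export
permutation_null <- function(expr, genes, index = "TAI", n_perm = 1000,
                             seed = NULL, alternative = "two.sided",
                             combine = "empirical", kilo_scale = TRUE,
                             share_permutations = TRUE) {
  if (n_perm < 100) abort("n_perm must be at least 100")
  alternative <- match.arg(alternative, c("two.sided", "less", "greater"))
  combine <- match.arg(combine, c("empirical", "fisher", "stouffer"))
  prep <- prepare_index(expr, genes, index, kilo_scale)
  n <- nrow(prep$m)
  if (length(unique(prep$cov)) < 3)
    warn("fewer than 3 distinct covariate values: permutation null is nearly degenerate")
  obs <- observed_index(prep)
  surr <- with_seed_if(seed, {
    if (share_permutations) {
      idx <- matrix(0L, n, n_perm)
      for (j in seq_len(n_perm)) idx[, j] <- sample.int(n)
      perm_cov <- matrix(prep$cov[idx], n, n_perm)
      w <- sweep(prep$m, 2, colSums(prep$m), "/")
      crossprod(perm_cov, w)                     # n_perm x n_stages
    } else {
      vapply(seq_along(prep$stages), function(s) {
        w <- prep$m[, s] / sum(prep$m[, s])
        idx <- matrix(0L, n, n_perm)
        for (j in seq_len(n_perm)) idx[, j] <- sample.int(n)
        as.numeric(crossprod(matrix(prep$cov[idx], n, n_perm), w))
      }, numeric(n_perm))
    }
  })
  colnames(surr) <- prep$stages

  fits <- purrr::map(seq_along(prep$stages), function(s) {
    x <- surr[, s]
    if (var(x) == 0)
      return(list(shape = NA_real_, scale = NA_real_, p = 1))
    fit <- gamma_moment_fit(x)
    list(shape = fit[["shape"]], scale = fit[["scale"]],
         p = stage_p_value(obs[s], fit[["shape"]], fit[["scale"]],
                           alternative = alternative))
  })
  p_stage <- purrr::map_dbl(fits, "p")
  shape <- purrr::map_dbl(fits, "shape")
  scale <- purrr::map_dbl(fits, "scale")

  p_combined <- if (combine == "empirical") {
    empirical_pattern_p(obs, surr, shape, scale, alternative)
  } else {
    combine_p(p_stage, method = combine)
  }
  structure(
    list(stages = prep$stages,
         observed = obs,
         surrogates = surr,
         shape = shape,
         scale = scale,
         p_stage = p_stage,
         p_combined = p_combined,
         index_kind = prep$index,
         n_perm = n_perm,
         seed = seed,
         alternative = alternative,
         combine = combine),
    class = "index_null")
}

# observed Fisher X referred to the surrogate replicates' own X values;
# degenerate (zero-variance) stages contribute log(1) = 0 throughout
empirical_pattern_p <- function(obs, surr, shape, scale, alternative) {
  ok <- which(is.finite(shape))
  if (length(ok) == 0) return(1)
  tail_p <- function(f) {
    p <- switch(alternative,
                two.sided = 2 * pmin(f, 1 - f),  # pmin keeps dim of f
                less = f,
                greater = 1 - f)
    p[p > 1] <- 1
    p[p < .Machine$double.xmin] <- .Machine$double.xmin
    p
  }
  f_surr <- vapply(ok, function(s) {
    pgamma(surr[, s], shape = shape[s], scale = scale[s])
  }, numeric(nrow(surr)))
  x_surr <- -2 * rowSums(log(tail_p(f_surr)))
  f_obs <- pgamma(obs[ok], shape = shape[ok], scale = scale[ok])
  x_obs <- -2 * sum(log(tail_p(f_obs)))
  (1 + sum(x_surr >= x_obs)) / (nrow(surr) + 1)
}

#' @export
print.index_null <- function(x, ...) {
  cat("Permutation null for ", x$index_kind, " profile\n",
      "  stages: ", length(x$stages),
      ", permutations per stage: ", x$n_perm, "\n",
      "  combined p (", x$combine, ", ", x$alternative, "): ",
      format(x$p_combined, digits = 3), "\n", sep = "")
  invisible(x)
}

#' @rdname permutation_null
#' @param x An `index_null` object.
#' @param ... Unused.
#' @export
tidy.index_null <- function(x, ...) {
  tibble::tibble(stage = factor(x$stages, levels = x$stages),
                 observed = x$observed,
                 shape = x$shape,
                 scale = x$scale,
                 p = x$p_stage)
}

#' @rdname permutation_null
#' @export
glance.index_null <- function(x, ...) {
  tibble::tibble(index_kind = x$index_kind,
                 n_stages = length(x$stages),
                 n_perm = x$n_perm,
                 alternative = x$alternative,
                 combine = x$combine,
                 p_combined = x$p_combined,
                 seed = if (is.null(x$seed)) NA_integer_ else as.integer(x$seed))
}

#' Method-of-moments gamma fit
#'
#' `shape = mean^2 / var`, `scale = var / mean`, with the sample mean and
#' (n-1 denominator) sample variance. Zero variance signals a degenerate
#' null and is an error.
#'
#' @param x Positive numeric vector of surrogate values.
#' @return Named numeric vector `c(shape=, scale=)`.
#' @export
#' @examples
#' gamma_moment_fit(c(1.5, 2, 2.5))  # mean 2, var 0.25 -> shape 16, scale 0.125
gamma_moment_fit <- function(x) {
  m <- mean(x); v <- var(x)
  if (!is.finite(v) || v == 0) abort("degenerate null: zero surrogate variance")
  if (m <= 0) abort("gamma moment fit needs positive-mean surrogates")
  c(shape = m^2 / v, scale = v / m)
}

#' P-value of an observed index under a fitted gamma null
#'
#' Two-sided by default: `p = min(1, 2 * min(F(x), 1 - F(x)))` with `F` the
#' fitted gamma CDF. An observed value at or below 0 sits on the boundary of
#' the gamma support; its p is computed there and a warning raised.
#'
#' @param observed Observed index value.
#' @param shape,scale Gamma parameters (e.g. from [gamma_moment_fit()]).
#' @param alternative `"two.sided"`, `"less"`, or `"greater"`.
#' @return A p-value in `(0, 1]`.
#' @export
stage_p_value <- function(observed, shape, scale,
                          alternative = "two.sided") {
  alternative <- match.arg(alternative, c("two.sided", "less", "greater"))
  if (!is.finite(shape) || !is.finite(scale) || shape <= 0 || scale <= 0)
    abort("invalid gamma fit")
  if (observed <= 0)
    warn("observed value at the boundary of the gamma support")
  f <- pgamma(observed, shape = shape, scale = scale)
  p <- switch(alternative,
              two.sided = min(1, 2 * min(f, 1 - f)),
              less = f,
              greater = 1 - f)
  max(p, .Machine$double.xmin)
}

#' Combine per-stage p-values into one pattern p-value
#'
#' Fisher's method by default: `X = -2 * sum(log(p))` referred to a
#' chi-square with `2 * length(p)` degrees of freedom. Stouffer's Z is
#' available as an alternative. Zero p-values are clamped to the smallest
#' positive double with a warning.
#'
#' @param p Vector of p-values in `(0, 1]`.
#' @param method `"fisher"` (default) or `"stouffer"`.
#' @return Combined p-value in `(0, 1]`.
#' @export
#' @examples
#' combine_p(c(0.05, 0.05))
combine_p <- function(p, method = c("fisher", "stouffer")) {
  method <- match.arg(method)
  if (any(p > 1)) abort("p-values must be at most 1")
  if (any(p <= 0)) {
    warn("zero p-value clamped to the smallest positive double")
    p <- pmax(p, .Machine$double.xmin)
  }
  k <- length(p)
  out <- switch(method,
                fisher = pchisq(-2 * sum(log(p)), df = 2 * k,
                                lower.tail = FALSE),
                stouffer = pnorm(sum(qnorm(p, lower.tail = FALSE)) / sqrt(k),
                                 lower.tail = FALSE))
  min(max(out, .Machine$double.xmin), 1)
}

# run code under a temporary RNG state when seed is given
with_seed_if <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}
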