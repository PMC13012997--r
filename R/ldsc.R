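# Cross-trait LD score regression: SNP heritability and genetic
# correlation from z-statistics and LD scores. This is a simplified
# one-step-weighted implementation ("simplified-LDSC"): heteroskedasticity
# weights come from a single unweighted pass rather than the reference
# two-step scheme.

# weighted 2-parameter regression (intercept + slope) with a
# delete-one-block jackknife computed from per-block moment sums
block_wls <- function(x, y, w, n_blocks) {
  n <- length(x)
  n_blocks <- min(n_blocks, n)
  blk <- ceiling(seq_along(x) / (n / n_blocks))
  blk[blk > n_blocks] <- n_blocks
  X <- cbind(1, x)
  xtwx_b <- array(0, c(2, 2, n_blocks))
  xtwy_b <- matrix(0, 2, n_blocks)
  for (b in seq_len(n_blocks)) {
    i <- blk == b
    xtwx_b[, , b] <- crossprod(X[i, , drop = FALSE], X[i, , drop = FALSE] * w[i])
    xtwy_b[, b] <- crossprod(X[i, , drop = FALSE], y[i] * w[i])
  }
  xtwx <- apply(xtwx_b, c(1, 2), sum)
  xtwy <- rowSums(xtwy_b)
  full <- solve(xtwx, xtwy)
  loo <- matrix(NA_real_, 2, n_blocks)
  for (b in seq_len(n_blocks)) {
    loo[, b] <- solve(xtwx - xtwx_b[, , b], xtwy - xtwy_b[, b])
  }
  list(coef = full, loo = loo, n_blocks = n_blocks)
}

jackknife_se <- function(loo_vals) {
  g <- length(loo_vals)
  sqrt((g - 1) / g * sum((loo_vals - mean(loo_vals))^2))
}

#' SNP heritability by LD score regression
#'
#' Regresses per-SNP `z^2` on `N * l / M` (intercept free): the slope is
#' the SNP heritability `h2` and the intercept is near 1 absent
#' confounding. Standard errors come from a delete-one-block jackknife
#' over contiguous blocks in input (genome) order.
#'
#' @param ld_scores per-SNP LD scores (sum of r^2 with all SNPs).
#' @param z per-SNP z-statistics.
#' @param n GWAS sample size (scalar or per-SNP).
#' @param M number of SNPs in the reference panel.
#' @param n_blocks jackknife blocks (default 200, reduced with a warning
#'   when there are fewer SNPs).
#' @return list with `h2`, `intercept`, `se_h2`, `se_intercept`,
#'   `n_blocks`, `degenerate`.
#' @export
h2_regression <- function(ld_scores, z, n, M, n_blocks = 200) {
  stopifnot(length(ld_scores) == length(z), all(ld_scores >= 0))
  if (length(z) < n_blocks) {
    warning("fewer SNPs than jackknife blocks; block count reduced")
    n_blocks <- max(2, length(z) %/% 2)
  }
  if (stats::sd(ld_scores) < 1e-12) {
    warning("all LD scores equal: heritability slope unidentifiable")
    return(list(h2 = NA_real_, intercept = NA_real_, se_h2 = NA_real_,
                se_intercept = NA_real_, n_blocks = n_blocks,
                degenerate = TRUE))
  }
  x <- n * ld_scores / M
  # initial unweighted pass for heteroskedasticity weights
  init <- block_wls(x, z^2, rep(1, length(x)), n_blocks)
  h2_0 <- max(0, min(1, init$coef[2]))
  w <- 1 / (1 + n * h2_0 * ld_scores / M)^2
  fit <- block_wls(x, z^2, w, n_blocks)
  list(h2 = fit$coef[2], intercept = fit$coef[1],
       se_h2 = jackknife_se(fit$loo[2, ]),
       se_intercept = jackknife_se(fit$loo[1, ]),
       n_blocks = fit$n_blocks, degenerate = FALSE, weights = w,
       x = x, fit = fit)
}

#' Cross-trait genetic correlation by LD score regression
#'
#' Regresses the per-SNP product `z1 * z2` on `sqrt(N1 N2) * l / M`; the
#' slope is the genetic covariance and
#' `rg = gencov / sqrt(h2_1 * h2_2)`. The jackknife runs over the full
#' pipeline (both heritabilities and the covariance are re-estimated with
#' each block deleted) so `se_rg` reflects all three sources. The p-value
#' is `2 * Phi(-|rg/se_rg|)`.
#'
#' @param ld_scores,z1,z2 per-SNP LD scores and z-statistics.
#' @param n1,n2 trait sample sizes.
#' @param M reference-panel SNP count.
#' @param n_blocks jackknife blocks (default 200).
#' @return list with `h2_1`, `h2_2`, `gencov`, `rg`, `se_rg`, `pval`,
#'   `intercepts` (trait1, trait2, bivariate).
#' @export
rg_regression <- function(ld_scores, z1, z2, n1, n2, M, n_blocks = 200) {
  stopifnot(length(z1) == length(z2), length(z1) == length(ld_scores))
  if (length(z1) < n_blocks) {
    warning("fewer SNPs than jackknife blocks; block count reduced")
    n_blocks <- max(2, length(z1) %/% 2)
  }
  f1 <- h2_regression(ld_scores, z1, n1, M, n_blocks)
  f2 <- h2_regression(ld_scores, z2, n2, M, n_blocks)
  if (is.na(f1$h2) || is.na(f2$h2) || f1$h2 <= 0 || f2$h2 <= 0) {
    stop("nonpositive heritability estimate (h2_1 = ",
         signif(f1$h2, 3), ", h2_2 = ", signif(f2$h2, 3),
         "): rg undefined", call. = FALSE)
  }
  x <- sqrt(n1 * n2) * ld_scores / M
  w <- sqrt(f1$weights * f2$weights)
  fx <- block_wls(x, z1 * z2, w, n_blocks)
  gencov <- fx$coef[2]
  rg <- gencov / sqrt(f1$h2 * f2$h2)
  # full-pipeline jackknife: per deleted block, recompute both slopes
  # and the covariance from the same block partitions
  g <- fx$n_blocks
  rg_loo <- vapply(seq_len(g), function(b) {
    h1 <- f1$fit$loo[2, b]; h2 <- f2$fit$loo[2, b]
    gc <- fx$loo[2, b]
    if (h1 <= 0 || h2 <= 0) return(NA_real_)
    gc / sqrt(h1 * h2)
  }, numeric(1))
  ok <- !is.na(rg_loo)
  se_rg <- jackknife_se(rg_loo[ok])
  if (abs(rg) > 1) warning("|rg| exceeds 1")
  list(h2_1 = f1$h2, h2_2 = f2$h2, gencov = gencov, rg = rg,
       se_rg = se_rg,
       pval = 2 * stats::pnorm(-abs(rg / se_rg)),
       intercepts = c(trait1 = f1$intercept, trait2 = f2$intercept,
                      bivariate = fx$coef[1]),
       n_blocks = g)
}
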