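# Univariable two-sample MR estimators and sensitivity analyses.
# All operate on harmonized pairs: columns beta_x, se_x, beta_y, se_y.

mr_estimate <- function(method, beta, se, pval = NULL, k = NA_integer_,
                        phi = NA_real_, df = NULL) {
  if (is.null(pval)) {
    pval <- if (is.null(df)) 2 * stats::pnorm(-abs(beta / se))
            else 2 * stats::pt(-abs(beta / se), df = df)
  }
  crit <- if (is.null(df)) stats::qnorm(0.975) else stats::qt(0.975, df = df)
  structure(list(method = method, beta = beta, se = se, pval = pval,
                 ci_low = beta - crit * se, ci_high = beta + crit * se,
                 k = as.integer(k), phi = phi),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  or <- to_odds_ratio(x$beta, x$se)
  cat(sprintf("MR estimate [%s]: beta=%.4f se=%.4f p=%.3g (k=%d)\n",
              x$method, x$beta, x$se, x$pval, x$k))
  cat(sprintf("  OR %.4f (95%% CI %.4f-%.4f)\n", or$or, or$ci_low, or$ci_high))
  invisible(x)
}

check_pairs <- function(pairs, k_min, caller) {
  k <- nrow(pairs)
  if (k < k_min) {
    stop(caller, " requires at least ", k_min, " instruments (got ", k, ")",
         if (k == 1L) "; use wald_ratio() for a single SNP" else "",
         call. = FALSE)
  }
  k
}

#' Wald ratio causal estimate from a single instrument
#'
#' beta = beta_y / beta_x. The first-order standard error is
#' `|se_y / beta_x|`; the second-order option adds the exposure sampling
#' term `beta_y^2 se_x^2 / beta_x^4` under the square root.
#'
#' @param pair one-row harmonized pair (or list with beta_x, se_x, beta_y,
#'   se_y).
#' @param se_order `"first"` (default) or `"second"`.
#' @return an `mr_estimate`.
#' @export
wald_ratio <- function(pair, se_order = c("first", "second")) {
  se_order <- match.arg(se_order)
  if (pair$beta_x == 0) stop("beta_x must be nonzero for a Wald ratio",
                             call. = FALSE)
  beta <- pair$beta_y / pair$beta_x
  se <- if (se_order == "first") abs(pair$se_y / pair$beta_x) else
    sqrt(pair$se_y^2 / pair$beta_x^2 +
           pair$beta_y^2 * pair$se_x^2 / pair$beta_x^4)
  mr_estimate("wald", beta, se, k = 1L)
}

#' Inverse-variance weighted MR estimate
#'
#' The primary two-sample MR estimator: the per-SNP Wald ratios pooled
#' with inverse outcome-variance weights, equivalent to weighted
#' no-intercept regression of outcome on exposure effects. Random-effects
#' mode inflates the SE multiplicatively by `sqrt(max(1, Q/(k-1)))`.
#'
#' @param pairs harmonized pairs (k >= 2).
#' @param mode `"fixed"` or `"random"`.
#' @return an `mr_estimate` with the heterogeneity scale in `phi`.
#' @export
mr_ivw <- function(pairs, mode = c("fixed", "random")) {
  mode <- match.arg(mode)
  k <- check_pairs(pairs, 2L, "mr_ivw")
  w <- 1 / pairs$se_y^2
  sxx <- sum(pairs$beta_x^2 * w)
  beta <- sum(pairs$beta_x * pairs$beta_y * w) / sxx
  se <- 1 / sqrt(sxx)
  q <- cochran_q(pairs, beta)
  phi <- max(1, q$Q / (k - 1))
  if (mode == "random") se <- se * sqrt(phi)
  est <- mr_estimate(if (mode == "fixed") "ivw_fe" else "ivw_re",
                     beta, se, k = k, phi = phi)
  est$Q <- q$Q
  est$Q_pval <- q$pval
  est
}

#' MR-Egger regression
#'
#' Weighted least-squares regression of outcome on exposure effects with
#' an intercept, weights `1/se_y^2`, after orienting all pairs so
#' `beta_x > 0`. A nonzero intercept indicates directional horizontal
#' pleiotropy. SEs are scaled by `sqrt(max(1, RSS_w/(k-2)))` and inference
#' uses the t distribution with k-2 df.
#'
#' @param pairs harmonized pairs (k >= 3).
#' @return list with `slope` and `intercept` `mr_estimate`s.
#' @export
mr_egger <- function(pairs) {
  k <- check_pairs(pairs, 3L, "mr_egger")
  flip <- sign(pairs$beta_x)
  flip[flip == 0] <- 1
  bx <- pairs$beta_x * flip
  by <- pairs$beta_y * flip
  w <- 1 / pairs$se_y^2
  fit <- wls_fit(cbind(1, bx), by, w)
  rss_w <- sum(w * (by - fit$fitted)^2)
  scale <- sqrt(max(1, rss_w / (k - 2)))
  se <- sqrt(diag(fit$xtwx_inv)) * scale
  list(
    slope = mr_estimate("egger_slope", fit$coef[2], se[2], k = k,
                        phi = scale^2, df = k - 2),
    intercept = mr_estimate("egger_intercept", fit$coef[1], se[1], k = k,
                            phi = scale^2, df = k - 2)
  )
}

# closed-form weighted least squares; returns coefficients, fitted values
# and the unscaled covariance (X'WX)^{-1}
wls_fit <- function(X, y, w) {
  xtwx <- crossprod(X, X * w)
  qrx <- qr(xtwx)
  if (qrx$rank < ncol(X)) stop("design matrix is rank deficient",
                               call. = FALSE)
  xtwx_inv <- solve(xtwx)
  coef <- unname(drop(xtwx_inv %*% crossprod(X, y * w)))
  list(coef = coef, fitted = drop(X %*% coef), xtwx_inv = xtwx_inv)
}

#' Debiased inverse-variance weighted estimate
#'
#' Corrects the weak-instrument attenuation of IVW by subtracting the
#' exposure sampling variance from the denominator:
#' `beta = sum(bx*by/se_y^2) / sum((bx^2 - se_x^2)/se_y^2)`. The SE is a
#' seeded nonparametric bootstrap over instruments.
#'
#' @param pairs harmonized pairs (k >= 2).
#' @param n_boot bootstrap resamples (default 2000).
#' @param seed integer seed for the bootstrap.
#' @return an `mr_estimate`.
#' @export
mr_divw <- function(pairs, n_boot = 2000, seed = 1L) {
  k <- check_pairs(pairs, 2L, "mr_divw")
  w <- 1 / pairs$se_y^2
  point <- function(idx) {
    den <- sum((pairs$beta_x[idx]^2 - pairs$se_x[idx]^2) * w[idx])
    if (den <= 0) return(NA_real_)
    sum(pairs$beta_x[idx] * pairs$beta_y[idx] * w[idx]) / den
  }
  beta <- point(seq_len(k))
  if (is.na(beta)) stop("instruments too weak: debiased denominator is nonpositive",
                        call. = FALSE)
  reps <- local_seed_eval(seed, {
    vapply(seq_len(n_boot), function(b) {
      point(sample.int(k, k, replace = TRUE))
    }, numeric(1))
  })
  se <- stats::sd(reps, na.rm = TRUE)
  mr_estimate("divw", beta, se, k = k)
}

# evaluate expr under a local RNG seed, restoring the caller's RNG state
local_seed_eval <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Robust adjusted profile score estimate
#'
#' Maximizes the profile log-likelihood
#' `-0.5 * sum((by - theta*bx)^2 / (se_y^2 + theta^2 se_x^2))` over theta
#' by bounded 1-D optimization, accounting for sampling error in both the
#' exposure and outcome effects. With `overdispersion = TRUE` a pleiotropy
#' variance `tau^2 >= 0` is added to every denominator and jointly
#' profiled. The SE comes from the numerical curvature of the profile
#' log-likelihood at the optimum.
#'
#' @param pairs harmonized pairs (k >= 3).
#' @param overdispersion profile an additive overdispersion variance.
#' @param bound symmetric search bound on theta (default 10).
#' @return an `mr_estimate` (tau^2 reported in `phi` when profiled).
#' @export
mr_raps <- function(pairs, overdispersion = FALSE, bound = 10) {
  k <- check_pairs(pairs, 3L, "mr_raps")
  bx <- pairs$beta_x; by <- pairs$beta_y
  sx2 <- pairs$se_x^2; sy2 <- pairs$se_y^2
  # theta-only: the profile log-likelihood (no log-determinant term);
  # with overdispersion the full Gaussian likelihood is needed so that
  # tau^2 has an interior optimum
  nll <- function(theta, tau2 = 0, full = overdispersion) {
    v <- sy2 + theta^2 * sx2 + tau2
    0.5 * sum((by - theta * bx)^2 / v + if (full) log(v) else 0)
  }
  if (!overdispersion) {
    opt <- stats::optimize(nll, c(-bound, bound), tol = 1e-10)
    theta <- opt$minimum
    tau2 <- 0
  } else {
    opt <- stats::optim(c(0, 0), function(p) nll(p[1], exp(p[2])),
                        method = "L-BFGS-B",
                        lower = c(-bound, -30), upper = c(bound, 5))
    if (opt$convergence != 0)
      stop("RAPS optimizer failed to converge: ", opt$message, call. = FALSE)
    theta <- opt$par[1]
    tau2 <- exp(opt$par[2])
  }
  if (abs(theta) > bound - 1e-6)
    stop("RAPS estimate at search bound; optimization unreliable",
         call. = FALSE)
  h <- 1e-4 * max(1, abs(theta))
  curv <- (nll(theta + h, tau2) - 2 * nll(theta, tau2) +
             nll(theta - h, tau2)) / h^2
  if (!is.finite(curv) || curv <= 0)
    stop("RAPS curvature nonpositive; no interior optimum", call. = FALSE)
  mr_estimate("raps", theta, 1 / sqrt(curv), k = k, phi = tau2)
}

#' Cochran's Q heterogeneity test
#'
#' Q = sum over instruments of `w_j (r_j - beta_hat)^2` where `r_j` are
#' per-SNP Wald ratios and `w_j = beta_x_j^2/se_y_j^2` are first-order
#' weights; chi-square with k-1 df under homogeneity.
#'
#' @param pairs harmonized pairs (k >= 2).
#' @param beta_hat pooled causal estimate the ratios are compared against.
#' @return list with `Q`, `df`, `pval`.
#' @export
cochran_q <- function(pairs, beta_hat) {
  k <- check_pairs(pairs, 2L, "cochran_q")
  r <- pairs$beta_y / pairs$beta_x
  w <- pairs$beta_x^2 / pairs$se_y^2
  Q <- sum(w * (r - beta_hat)^2)
  list(Q = Q, df = k - 1L,
       pval = stats::pchisq(Q, df = k - 1L, lower.tail = FALSE))
}

#' Upper-tail chi-square p-value for a heterogeneity statistic
#'
#' @param Q Cochran statistic.
#' @param df degrees of freedom.
#' @return p-value.
#' @export
q_pvalue <- function(Q, df) stats::pchisq(Q, df = df, lower.tail = FALSE)

#' Leave-one-out sensitivity analysis
#'
#' Re-estimates random-effects IVW excluding each instrument in turn and
#' flags SNPs whose removal changes the sign of the estimate or its
#' significance at 0.05.
#'
#' @param pairs harmonized pairs (k >= 3).
#' @return data frame with one row per excluded SNP: `snp, beta, se, pval,
#'   flagged`.
#' @export
leave_one_out <- function(pairs) {
  k <- check_pairs(pairs, 3L, "leave_one_out")
  full <- mr_ivw(pairs, mode = "random")
  rows <- lapply(seq_len(k), function(i) {
    est <- mr_ivw(pairs[-i, , drop = FALSE], mode = "random")
    data.frame(snp = pairs$snp[i], beta = est$beta, se = est$se,
               pval = est$pval, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$flagged <- sign(out$beta) != sign(full$beta) |
    ((out$pval < 0.05) != (full$pval < 0.05))
  out
}

#' Steiger test of causal directionality
#'
#' Compares the variance the instruments explain in the exposure versus
#' the outcome: per trait `r^2 = sum_j F_j/(F_j + n - 2)`. The causal
#' direction exposure -> outcome is supported when `r2_exposure >
#' r2_outcome`; the one-sided p-value comes from the difference of
#' Fisher-transformed correlations,
#' `Z = (atanh r_x - atanh r_y)/sqrt(1/(n_x-3) + 1/(n_y-3))`.
#'
#' @param pairs harmonized pairs.
#' @param n_x,n_y trait sample sizes (> 3); taken from the pairs when
#'   missing.
#' @return list with `r2_exposure`, `r2_outcome`, `direction_ok`, `pval`.
#' @export
steiger <- function(pairs, n_x = NULL, n_y = NULL) {
  if (is.null(n_x)) n_x <- stats::median(pairs$n_x)
  if (is.null(n_y)) n_y <- stats::median(pairs$n_y)
  stopifnot(n_x > 3, n_y > 3)
  r2_of <- function(beta, se, n) {
    f <- (beta / se)^2
    r2 <- sum(f / (f + n - 2))
    if (r2 >= 1) {
      warning("summed r^2 >= 1; capped")
      r2 <- 1 - 1e-12
    }
    r2
  }
  r2x <- r2_of(pairs$beta_x, pairs$se_x, n_x)
  r2y <- r2_of(pairs$beta_y, pairs$se_y, n_y)
  z <- (atanh(sqrt(r2x)) - atanh(sqrt(r2y))) /
    sqrt(1 / (n_x - 3) + 1 / (n_y - 3))
  list(r2_exposure = r2x, r2_outcome = r2y,
       direction_ok = r2x > r2y,
       pval = stats::pnorm(z, lower.tail = FALSE))
}

#' Convert a log-odds effect to an odds ratio with 95% CI
#'
#' `or = exp(beta)`, CI `exp(beta +/- 1.96 se)`. The inverse operation
#' recovers the point estimate as the geometric mean of the CI bounds.
#'
#' @param beta log-odds effect.
#' @param se standard error (>= 0).
#' @return list with `or`, `ci_low`, `ci_high`.
#' @export
to_odds_ratio <- function(beta, se) {
  stopifnot(se >= 0)
  z <- stats::qnorm(0.975)
  list(or = exp(beta), ci_low = exp(beta - z * se),
       ci_high = exp(beta + z * se))
}

#' Reconstruct an odds ratio from its confidence bounds
#'
#' The geometric mean of symmetric (log-scale) CI bounds equals the point
#' estimate; useful for checking published tables.
#'
#' @param ci_low,ci_high odds-ratio CI bounds.
#' @return the implied odds ratio.
#' @export
or_from_ci <- function(ci_low, ci_high) sqrt(ci_low * ci_high)

#' Percent excess risk implied by an odds ratio
#'
#' @param or odds ratio.
#' @return `100 * (or - 1)`.
#' @export
percent_excess_risk <- function(or) 100 * (or - 1)

#' Run a panel of univariable MR methods
#'
#' @param pairs harmonized pairs.
#' @param methods subset of `c("ivw", "egger", "divw", "raps")`; a single
#'   pair always falls back to the Wald ratio.
#' @param seed seed for the dIVW bootstrap.
#' @return data frame: method, nsnp, beta, se, pval, or, or_lci, or_uci,
#'   Q, Q_pval, egger_intercept, egger_intercept_pval.
#' @export
mr_panel <- function(pairs, methods = c("ivw", "egger", "divw", "raps"),
                     seed = 1L) {
  k <- nrow(pairs)
  row_of <- function(est, Q = NA, Q_pval = NA, ei = NA, ei_p = NA) {
    or <- to_odds_ratio(est$beta, est$se)
    data.frame(method = est$method, nsnp = est$k, beta = est$beta,
               se = est$se, pval = est$pval, or = or$or,
               or_lci = or$ci_low, or_uci = or$ci_high,
               Q = Q, Q_pval = Q_pval, egger_intercept = ei,
               egger_intercept_pval = ei_p, stringsAsFactors = FALSE)
  }
  if (k == 1L) return(row_of(wald_ratio(pairs)))
  out <- list()
  if ("ivw" %in% methods) {
    est <- mr_ivw(pairs, mode = "random")
    out$ivw <- row_of(est, Q = est$Q, Q_pval = est$Q_pval)
  }
  if ("egger" %in% methods && k >= 3) {
    eg <- mr_egger(pairs)
    out$egger <- row_of(eg$slope, ei = eg$intercept$beta,
                        ei_p = eg$intercept$pval)
  }
  if ("divw" %in% methods) {
    est <- tryCatch(mr_divw(pairs, seed = seed), error = function(e) NULL)
    if (!is.null(est)) out$divw <- row_of(est)
  }
  if ("raps" %in% methods && k >= 3) {
    est <- tryCatch(mr_raps(pairs), error = function(e) NULL)
    if (!is.null(est)) out$raps <- row_of(est)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
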