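# Multivariable IVW: joint direct effects of several exposures.

#' Assemble a multivariable instrument set
#'
#' Joins per-exposure harmonized pairs (each against the same outcome) on
#' SNP id. The default pooling rule is the strict intersection of SNPs
#' present in every exposure; `pooling = "union"` keeps the union and
#' imputes missing exposure effects as 0 (appropriate only when absent
#' SNPs were screened genome-wide in the source GWAS).
#'
#' @param pair_list named list of harmonized-pairs data frames, one per
#'   exposure, all sharing the outcome columns `beta_y`, `se_y`.
#' @param pooling `"intersection"` (default) or `"union"`.
#' @return list of class `mv_instrument_set`: `snp`, matrix `beta_x`
#'   (k x p), matrix `se_x`, vectors `beta_y`, `se_y`, `exposures`.
#' @export
mv_instrument_set <- function(pair_list,
                              pooling = c("intersection", "union")) {
  pooling <- match.arg(pooling)
  stopifnot(length(pair_list) >= 1, !is.null(names(pair_list)))
  snp_sets <- lapply(pair_list, `[[`, "snp")
  snps <- if (pooling == "intersection") Reduce(intersect, snp_sets)
          else Reduce(union, snp_sets)
  if (length(snps) == 0) stop("no SNPs shared across exposures", call. = FALSE)
  p <- length(pair_list)
  k <- length(snps)
  bx <- matrix(0, k, p, dimnames = list(snps, names(pair_list)))
  sx <- matrix(0, k, p, dimnames = list(snps, names(pair_list)))
  for (j in seq_len(p)) {
    idx <- match(snps, pair_list[[j]]$snp)
    hit <- !is.na(idx)
    bx[hit, j] <- pair_list[[j]]$beta_x[idx[hit]]
    sx[hit, j] <- pair_list[[j]]$se_x[idx[hit]]
  }
  # outcome effects: take from the first exposure set that carries the SNP
  beta_y <- se_y <- rep(NA_real_, k)
  for (j in seq_len(p)) {
    idx <- match(snps, pair_list[[j]]$snp)
    hit <- !is.na(idx) & is.na(beta_y)
    beta_y[hit] <- pair_list[[j]]$beta_y[idx[hit]]
    se_y[hit] <- pair_list[[j]]$se_y[idx[hit]]
  }
  structure(list(snp = snps, beta_x = bx, se_x = sx,
                 beta_y = beta_y, se_y = se_y,
                 exposures = names(pair_list)),
            class = "mv_instrument_set")
}

#' Multivariable IVW
#'
#' Weighted no-intercept multiple regression of the outcome effects on
#' the exposure-effect matrix with weights `1/se_y^2`:
#' `theta = (B'WB)^{-1} B'W beta_y`. SEs come from `(B'WB)^{-1}` scaled by
#' `max(1, Q_mv/(k-p))`, where `Q_mv` is the weighted residual sum of
#' squares.
#'
#' @param mvset an `mv_instrument_set` (k > p >= 2; p = 1 reduces exactly
#'   to univariable IVW).
#' @return list with `estimates` (data frame exposure, nsnp, beta, se,
#'   pval, or, or_lci, or_uci) and `heterogeneity` (Q_mv, df, pval).
#' @export
mv_ivw <- function(mvset) {
  B <- mvset$beta_x
  k <- nrow(B); p <- ncol(B)
  if (k <= p) stop("need more instruments than exposures (k > p)",
                   call. = FALSE)
  w <- 1 / mvset$se_y^2
  xtwx <- crossprod(B, B * w)
  qrx <- qr(xtwx)
  if (qrx$rank < p) {
    sing <- colnames(B)[abs(diag(qr.R(qr(sqrt(w) * B)))) < 1e-10]
    stop("collinear exposure effects: ",
         paste(if (length(sing)) sing else colnames(B), collapse = ", "),
         call. = FALSE)
  }
  xtwx_inv <- solve(xtwx)
  theta <- drop(xtwx_inv %*% crossprod(B, mvset$beta_y * w))
  resid <- mvset$beta_y - drop(B %*% theta)
  Q <- sum(w * resid^2)
  scale <- max(1, Q / (k - p))
  se <- sqrt(diag(xtwx_inv) * scale)
  pval <- 2 * stats::pnorm(-abs(theta / se))
  z <- stats::qnorm(0.975)
  est <- data.frame(exposure = colnames(B), nsnp = k, beta = theta,
                    se = se, pval = pval, or = exp(theta),
                    or_lci = exp(theta - z * se),
                    or_uci = exp(theta + z * se),
                    stringsAsFactors = FALSE, row.names = NULL)
  list(estimates = est,
       heterogeneity = list(Q = Q, df = k - p,
                            pval = stats::pchisq(Q, k - p,
                                                 lower.tail = FALSE)))
}

#' Per-exposure instrument strength in a multivariable set
#'
#' A regression-based statistic: each exposure's effects are regressed on
#' the other exposures' effects (weighted by that exposure's inverse
#' variance) and the mean scaled residual chi-square is reported. With a
#' single exposure this is the mean univariable F. It is a simplified
#' conditional-strength statistic, not the Sanderson-Windmeijer
#' conditional F, and is labeled as such.
#'
#' @param mvset an `mv_instrument_set`.
#' @return data frame: exposure, F_stat, weak (F <= 10), statistic label.
#' @export
mv_instrument_strength <- function(mvset) {
  B <- mvset$beta_x; S <- mvset$se_x
  p <- ncol(B)
  f <- numeric(p)
  for (j in seq_len(p)) {
    se2 <- S[, j]^2
    se2[se2 == 0] <- min(se2[se2 > 0], 1e-12)
    bj <- B[, j]
    if (p > 1) {
      others <- B[, -j, drop = FALSE]
      fit <- wls_fit(others, bj, 1 / se2)
      resid <- bj - fit$fitted
    } else {
      resid <- bj
    }
    f[j] <- mean(resid^2 / se2)
  }
  data.frame(exposure = colnames(B), F_stat = f, weak = f <= 10,
             statistic = "simplified conditional F",
             stringsAsFactors = FALSE)
}
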