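# Summary-data-based MR (SMR) of molecular QTL on an outcome, with HEIDI
# heterogeneity filtering to separate a shared causal variant from linkage.

#' Construct a cis region for SMR/HEIDI
#'
#' @param probe probe / gene identifier.
#' @param snp SNP ids (shared order in all per-SNP vectors and the LD
#'   matrix).
#' @param beta_qtl,se_qtl molecular-QTL effects and SEs.
#' @param beta_gwas,se_gwas outcome GWAS effects and SEs.
#' @param ld LD matrix (signed r) over the region SNPs.
#' @return list of class `cis_region`; the top SNP is the one attaining
#'   the smallest QTL p-value.
#' @export
cis_region <- function(probe, snp, beta_qtl, se_qtl, beta_gwas, se_gwas,
                       ld = NULL) {
  stopifnot(length(snp) == length(beta_qtl),
            length(snp) == length(beta_gwas))
  if (!is.null(ld)) {
    ld <- ld_matrix(ld)
    if (!all(snp %in% rownames(ld)))
      stop("LD matrix must cover all region SNPs", call. = FALSE)
    ld <- ld[snp, snp]
  }
  z2 <- (beta_qtl / se_qtl)^2
  structure(list(probe = probe, snp = snp,
                 beta_qtl = beta_qtl, se_qtl = se_qtl,
                 beta_gwas = beta_gwas, se_gwas = se_gwas,
                 ld = ld, top = which.max(z2)),
            class = "cis_region")
}

#' SMR test at the top QTL variant
#'
#' `b_xy = beta_gwas / beta_qtl` at the top SNP; the test statistic is
#' `T = z_qtl^2 z_gwas^2 / (z_qtl^2 + z_gwas^2)`, chi-square with 1 df
#' under the null, and `se_xy = |b_xy| / sqrt(T)`. A top-SNP QTL F below
#' 10 triggers a weak-instrument error.
#'
#' @param region a `cis_region`.
#' @return list with `b_xy`, `se_xy`, `p_smr`, `top_snp`.
#' @export
smr_test <- function(region) {
  i <- region$top
  if (region$beta_qtl[i] == 0) stop("top-SNP QTL effect is zero", call. = FALSE)
  z_q2 <- (region$beta_qtl[i] / region$se_qtl[i])^2
  if (z_q2 < 10) stop("top-SNP QTL F < 10: instrument too weak for SMR",
                      call. = FALSE)
  z_g2 <- (region$beta_gwas[i] / region$se_gwas[i])^2
  T_smr <- z_q2 * z_g2 / (z_q2 + z_g2)
  b_xy <- region$beta_gwas[i] / region$beta_qtl[i]
  list(b_xy = b_xy,
       se_xy = if (T_smr > 0) abs(b_xy) / sqrt(T_smr) else Inf,
       p_smr = stats::pchisq(T_smr, df = 1, lower.tail = FALSE),
       top_snp = region$snp[i])
}

#' HEIDI test for heterogeneity in dependent instruments
#'
#' Distinguishes a single shared causal variant (SMR ratios identical
#' across LD-linked SNPs up to sampling noise) from linkage of distinct
#' variants. Eligible non-top SNPs have QTL chi-square > 10 (p below
#' `include_p_qtl_max`) and LD with the top SNP satisfying
#' `r2_top_min <= r^2 <= r2_top_max`, capped at the `max_snps` most
#' significant. For each eligible SNP, `d_i = b_xy(i) - b_xy(top)`; the
#' covariance of `d` follows from the delta method using the LD
#' correlations, and `T = sum (d_i/sd_i)^2` is referred to a seeded
#' Monte-Carlo null of correlated squared normals.
#'
#' @param region a `cis_region` with an LD matrix.
#' @param include_p_qtl_max maximum QTL p for eligibility (1.57e-3,
#'   i.e. chi-square 10).
#' @param r2_top_max,r2_top_min LD bounds with the top SNP.
#' @param max_snps maximum SNPs used (default 20).
#' @param mc_draws Monte-Carlo null draws (default 10000).
#' @param seed RNG seed for the null draws.
#' @return list with `p_heidi`, `n_used`, and `reason` when not testable.
#' @export
heidi_test <- function(region, include_p_qtl_max = 1.57e-3,
                       r2_top_max = 0.9, r2_top_min = 0.05,
                       max_snps = 20, mc_draws = 10000, seed = 1L) {
  if (is.null(region$ld)) stop("HEIDI requires an LD matrix", call. = FALSE)
  top <- region$top
  z_q <- region$beta_qtl / region$se_qtl
  p_qtl <- stats::pchisq(z_q^2, 1, lower.tail = FALSE)
  r_top <- region$ld[, top]
  elig <- which(seq_along(region$snp) != top &
                  p_qtl <= include_p_qtl_max &
                  r_top^2 >= r2_top_min & r_top^2 <= r2_top_max)
  if (length(elig) > max_snps) {
    elig <- elig[order(p_qtl[elig])][seq_len(max_snps)]
  }
  if (length(elig) < 3) {
    return(list(p_heidi = NA_real_, n_used = length(elig),
                reason = "insufficient SNPs"))
  }
  idx <- c(top, elig)
  bq <- region$beta_qtl[idx]; sq <- region$se_qtl[idx]
  bg <- region$beta_gwas[idx]; sg <- region$se_gwas[idx]
  R <- region$ld[idx, idx]
  b_xy <- bg / bq
  m <- length(elig)
  # delta-method covariance of b_xy across SNPs: GWAS and QTL estimates
  # each correlated through LD r
  cov_bxy <- matrix(0, m + 1, m + 1)
  for (i in seq_len(m + 1)) {
    for (j in i:(m + 1)) {
      cv <- R[i, j] * sg[i] * sg[j] / (bq[i] * bq[j]) +
        bg[i] * bg[j] * R[i, j] * sq[i] * sq[j] / (bq[i]^2 * bq[j]^2)
      cov_bxy[i, j] <- cov_bxy[j, i] <- cv
    }
  }
  d <- b_xy[-1] - b_xy[1]
  A <- cbind(-1, diag(m))  # d = A %*% b_xy
  V <- A %*% cov_bxy %*% t(A)
  sd_d <- sqrt(diag(V))
  T_obs <- sum((d / sd_d)^2)
  C <- V / tcrossprod(sd_d)
  ch <- tryCatch(chol(C), error = function(e) {
    warning("singular correlation of d; ridge regularized")
    chol(C + diag(1e-6, m))
  })
  null_T <- local_seed_eval(seed, {
    Z <- matrix(stats::rnorm(mc_draws * m), mc_draws, m) %*% ch
    rowSums(Z^2)
  })
  list(p_heidi = (sum(null_T >= T_obs) + 1) / (mc_draws + 1),
       n_used = m)
}

#' Screen many probes with SMR + HEIDI and FDR control
#'
#' Runs the SMR test for every region, converts SMR p-values to
#' Benjamini-Hochberg q-values across probes, runs HEIDI where an LD
#' matrix is present, and flags probes passing both filters
#' (`q < fdr` and `p_heidi > 0.05`).
#'
#' @param regions list of `cis_region`s.
#' @param fdr FDR threshold (default 0.05).
#' @param heidi run the HEIDI filter (default TRUE when LD is available).
#' @param seed seed for the HEIDI Monte-Carlo null.
#' @return data frame: probe, top_snp, b_xy, se_xy, p_smr, p_heidi,
#'   nsnp_heidi, q_value, passes.
#' @export
smr_screen <- function(regions, fdr = 0.05, heidi = TRUE, seed = 1L) {
  stopifnot(length(regions) >= 1)
  rows <- lapply(regions, function(rg) {
    sm <- tryCatch(smr_test(rg), error = function(e) NULL)
    if (is.null(sm)) {
      return(data.frame(probe = rg$probe, top_snp = NA, b_xy = NA,
                        se_xy = NA, p_smr = NA, p_heidi = NA,
                        nsnp_heidi = NA, stringsAsFactors = FALSE))
    }
    hd <- if (heidi && !is.null(rg$ld)) heidi_test(rg, seed = seed)
          else list(p_heidi = NA_real_, n_used = NA_integer_)
    data.frame(probe = rg$probe, top_snp = sm$top_snp, b_xy = sm$b_xy,
               se_xy = sm$se_xy, p_smr = sm$p_smr, p_heidi = hd$p_heidi,
               nsnp_heidi = hd$n_used, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  est <- !is.na(out$p_smr)
  out$q_value <- NA_real_
  out$q_value[est] <- bh_fdr(out$p_smr[est])
  out$passes <- !is.na(out$q_value) & out$q_value < fdr &
    (is.na(out$p_heidi) | out$p_heidi > 0.05)
  rownames(out) <- NULL
  out
}

#' Join discovery and replication SMR screens
#'
#' @param discovery,replication `smr_screen` outputs.
#' @return merged table with a `concordant` column (sign agreement of
#'   `b_xy`); symmetric in the role of the two tables.
#' @export
smr_concordance <- function(discovery, replication) {
  m <- merge(discovery, replication, by = "probe",
             suffixes = c("_disc", "_repl"))
  m$concordant <- sign(m$b_xy_disc) == sign(m$b_xy_repl)
  m
}
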