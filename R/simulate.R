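# Seeded synthetic-data generators producing every input the analysis
# chain consumes, with the statistical structure the methods assume.
# All generators are pure functions of (config, seed): the caller's RNG
# state is saved and restored.

# non-palindromic allele pairs so default QC retains every SNP
CLEAN_ALLELES <- list(c("A", "G"), c("G", "A"), c("C", "T"), c("T", "C"),
                      c("A", "C"), c("C", "A"), c("G", "T"), c("T", "G"))

# continuous-trait convention for a standardized phenotype:
# se = 1/sqrt(2 n eaf (1-eaf))
analytic_se <- function(n, eaf) 1 / sqrt(2 * n * eaf * (1 - eaf))

sumstats_frame <- function(snp, chr, pos, beta, se, eaf, n,
                           allele_idx = NULL) {
  k <- length(snp)
  if (is.null(allele_idx)) allele_idx <- ((seq_len(k) - 1) %% 8) + 1
  al <- do.call(rbind, CLEAN_ALLELES[allele_idx])
  data.frame(snp = snp, chr = as.character(chr), pos = as.integer(pos),
             ea = al[, 1], oa = al[, 2], eaf = eaf, beta = beta, se = se,
             # floored to stay representable in text output
             pval = pmax(2 * stats::pnorm(-abs(beta / se)), 1e-300), n = n,
             stringsAsFactors = FALSE)
}

#' Simulate two-sample MR summary statistics
#'
#' Generating model for instrument j:
#' `beta_x_j = gamma_j + e_xj`, `beta_y_j = theta * gamma_j + alpha_j + e_yj`
#' with `gamma_j ~ N(0, gamma_sd^2)`, sampling noise
#' `e ~ N(0, se^2)` where `se = 1/sqrt(2 n eaf (1-eaf))`
#' (continuous-trait convention), and pleiotropy `alpha_j` drawn as 0
#' (`none`), `N(0, sd^2)` (`balanced`) or `N(mean, sd^2)` (`directional`).
#' Directional pleiotropy is expressed relative to the
#' exposure-increasing allele (`alpha_j * sign(gamma_j)` enters the
#' outcome effect), the orientation under which an Egger intercept is
#' defined.
#' Effect-allele frequencies are uniform on (0.1, 0.9) and allele pairs
#' are non-palindromic, so the output passes default QC unchanged.
#'
#' @param k number of instruments.
#' @param theta true causal effect.
#' @param gamma_sd instrument -> exposure effect scale (default 0.1).
#' @param pleiotropy `"none"`, `"balanced"`, or `"directional"`.
#' @param pleio_mean,pleio_sd directional mean and spread of the
#'   pleiotropic effects.
#' @param n_x,n_y sample sizes of the two (non-overlapping) GWAS.
#' @param seed integer seed; the same seed reproduces the data exactly.
#' @return list with `exposure` and `outcome` summary-statistics data
#'   frames and the true `gamma` and `alpha` vectors.
#' @export
simulate_two_sample <- function(k = 50, theta = 0.2, gamma_sd = 0.1,
                                pleiotropy = c("none", "balanced",
                                               "directional"),
                                pleio_mean = 0.02, pleio_sd = 0.01,
                                n_x = 200000, n_y = 200000, seed = 1L) {
  pleiotropy <- match.arg(pleiotropy)
  stopifnot(k >= 1, n_x > 0, n_y > 0)
  local_seed_eval(seed, {
    eaf <- stats::runif(k, 0.1, 0.9)
    gamma <- stats::rnorm(k, 0, gamma_sd)
    alpha <- switch(pleiotropy,
                    none = rep(0, k),
                    balanced = stats::rnorm(k, 0, pleio_sd),
                    directional = stats::rnorm(k, pleio_mean, pleio_sd))
    se_x <- analytic_se(n_x, eaf)
    se_y <- analytic_se(n_y, eaf)
    beta_x <- gamma + stats::rnorm(k, 0, se_x)
    orient <- sign(gamma)
    orient[orient == 0] <- 1
    beta_y <- theta * gamma + alpha * orient + stats::rnorm(k, 0, se_y)
    snp <- sprintf("rs%06d", seq_len(k))
    pos <- seq_len(k) * 2e6  # spaced beyond any clumping window
    list(exposure = sumstats_frame(snp, 1, pos, beta_x, se_x, eaf, n_x),
         outcome = sumstats_frame(snp, 1, pos, beta_y, se_y, eaf, n_y),
         gamma = gamma, alpha = alpha)
  })
}

#' AR(1) linkage-disequilibrium matrix
#'
#' @param m number of SNPs.
#' @param rho lag-one correlation; entry (i,j) is `rho^|i-j|`.
#' @param snp optional SNP ids for the dimnames.
#' @return an LD matrix.
#' @export
ar1_ld <- function(m, rho, snp = NULL) {
  if (is.null(snp)) snp <- sprintf("rs%06d", seq_len(m))
  R <- rho^abs(outer(seq_len(m), seq_len(m), "-"))
  dimnames(R) <- list(snp, snp)
  R
}

#' Simulate a colocalization region pair
#'
#' Draws per-trait z-vectors from `MVN(R lambda, R)` where `R` is the LD
#' matrix (AR(1) with parameter `rho` by default) and `lambda` carries the
#' causal effect(s) at scenario-dependent positions:
#' H0 no causal variant, H1/H2 one trait only, H3 distinct causal
#' variants for the two traits (low LD apart), H4 one shared variant.
#'
#' @param m SNPs in the region.
#' @param scenario one of `"H0"`, `"H1"`, `"H2"`, `"H3"`, `"H4"`.
#' @param z_causal causal-variant z magnitude (default 8).
#' @param rho AR(1) LD parameter (default 0.9).
#' @param n1,n2 trait sample sizes (set the beta/se scale only).
#' @param h3_separation index distance between the two causal variants in
#'   the H3 scenario. The default places them far apart (r^2 < 0.01,
#'   the distinct-aetiology colocalization scenario); small values give
#'   the linkage scenario (e.g. 3 with rho = 0.9 gives r^2 ~ 0.5).
#' @param seed integer seed.
#' @return list with `region` (a [region_pair()]) and `ld`.
#' @export
simulate_region_pair <- function(m = 100, scenario = c("H4", "H0", "H1",
                                                       "H2", "H3"),
                                 z_causal = 8, rho = 0.9,
                                 n1 = 30000, n2 = 30000,
                                 h3_separation = NULL, seed = 1L) {
  scenario <- match.arg(scenario)
  R <- ar1_ld(m, rho)
  i1 <- max(1L, round(m / 3))        # causal index, trait 1
  i2 <- if (is.null(h3_separation))
    min(m, round(2 * m / 3 + m %/% 6))  # distant index, trait 2 (H3)
  else min(m, i1 + as.integer(h3_separation))
  lam1 <- lam2 <- rep(0, m)
  if (scenario %in% c("H1", "H3", "H4")) lam1[i1] <- z_causal
  if (scenario == "H4") lam2[i1] <- z_causal
  if (scenario %in% c("H2", "H3")) lam2[if (scenario == "H3") i2 else i1] <- z_causal
  ch <- tryCatch(chol(R), error = function(e) {
    warning("LD matrix not positive definite; ridge fix applied")
    chol(R + diag(1e-8, m))
  })
  local_seed_eval(seed, {
    z1 <- drop(R %*% lam1) + drop(crossprod(ch, stats::rnorm(m)))
    z2 <- drop(R %*% lam2) + drop(crossprod(ch, stats::rnorm(m)))
    se1 <- rep(1 / sqrt(n1), m)
    se2 <- rep(1 / sqrt(n2), m)
    list(region = region_pair(rownames(R), z1 * se1, se1, z2 * se2, se2,
                              type1 = "quant", type2 = "cc",
                              label = scenario),
         ld = R)
  })
}

#' Simulate a cis region for SMR/HEIDI
#'
#' Builds a molecular-QTL / outcome-GWAS region pair with a causal QTL
#' variant of strength `z_qtl`. Under `mode = "shared"` the outcome signal
#' is driven by the same variant with expression-on-outcome effect
#' `b_xy` (the SMR estimand; HEIDI null). Under `mode = "linkage"` the
#' outcome's causal variant sits `separation` SNPs away (distinct
#' variants in LD; HEIDI alternative).
#'
#' @param b_xy true effect of the molecular trait on the outcome.
#' @param z_qtl QTL z at the causal variant (default 10).
#' @param m,rho region size and AR(1) LD parameter.
#' @param n1,n2 QTL and GWAS sample sizes. The defaults (30,000 and
#'   480,000) mirror the typical blood-eQTL versus biobank-GWAS scale
#'   imbalance and give a top-SNP GWAS z comparable to the QTL z.
#' @param mode `"shared"` or `"linkage"`.
#' @param separation causal-variant index distance in linkage mode
#'   (default 3; r^2 ~ 0.5 at rho = 0.9).
#' @param probe probe label.
#' @param seed integer seed.
#' @return a [cis_region()].
#' @export
simulate_smr_region <- function(b_xy = 0.25, z_qtl = 10, m = 60,
                                rho = 0.9, n1 = 30000, n2 = 480000,
                                mode = c("shared", "linkage"),
                                separation = 3, probe = "probe_1",
                                seed = 1L) {
  mode <- match.arg(mode)
  R <- ar1_ld(m, rho)
  i1 <- max(1L, round(m / 3))
  se1 <- rep(1 / sqrt(n1), m)
  se2 <- rep(1 / sqrt(n2), m)
  lam1 <- rep(0, m); lam1[i1] <- z_qtl
  lam2 <- rep(0, m)
  if (mode == "shared") {
    # outcome z-mean implied by beta_gwas = b_xy * beta_qtl at the causal
    lam2[i1] <- b_xy * z_qtl * se1[i1] / se2[i1]
  } else {
    i2 <- min(m, i1 + as.integer(separation))
    lam2[i2] <- b_xy * z_qtl * se1[i1] / se2[i1]
  }
  ch <- chol(R)
  local_seed_eval(seed, {
    z1 <- drop(R %*% lam1) + drop(crossprod(ch, stats::rnorm(m)))
    z2 <- drop(R %*% lam2) + drop(crossprod(ch, stats::rnorm(m)))
    cis_region(probe, rownames(R), z1 * se1, se1, z2 * se2, se2, ld = R)
  })
}

#' Simulate LD score regression input
#'
#' For SNP j with LD score `l_j`, the z-pair is drawn from the bivariate
#' normal with `Var(z_i) = 1 + N_i h2_i l_j / M` and
#' `Cov(z1, z2) = sqrt(N1 N2) * gencov * l_j / M`,
#' `gencov = rg * sqrt(h2_1 h2_2)` — exactly the generating model the
#' regression estimates. LD scores are drawn once per seed from a gamma
#' distribution (mean ~ 40) and sorted to mimic genome-ordered structure.
#'
#' @param M SNP count.
#' @param h2_1,h2_2 SNP heritabilities.
#' @param rg genetic correlation (|rg| <= 1).
#' @param n1,n2 GWAS sample sizes.
#' @param seed integer seed.
#' @return list with `ld_scores`, `z1`, `z2`, `n1`, `n2`, `M`.
#' @export
simulate_ldsc <- function(M = 20000, h2_1 = 0.2, h2_2 = 0.1, rg = 0.22,
                          n1 = 50000, n2 = 50000, seed = 1L) {
  if (abs(rg) > 1) stop("|rg| must be <= 1", call. = FALSE)
  local_seed_eval(seed, {
    l <- stats::rgamma(M, shape = 2, scale = 20)
    gencov <- rg * sqrt(h2_1 * h2_2)
    v1 <- 1 + n1 * h2_1 * l / M
    v2 <- 1 + n2 * h2_2 * l / M
    cv <- sqrt(n1 * n2) * gencov * l / M
    # conditional bivariate draw per SNP
    z1 <- stats::rnorm(M, 0, sqrt(v1))
    mu2 <- cv / v1 * z1
    s2 <- sqrt(pmax(v2 - cv^2 / v1, 1e-12))
    z2 <- stats::rnorm(M, mu2, s2)
    list(ld_scores = l, z1 = z1, z2 = z2, n1 = n1, n2 = n2, M = M)
  })
}

#' Simulate a mediation chain of summary statistics
#'
#' Builds three analysis-ready two-sample data sets encoding the chain
#' exposure -> mediator -> outcome with direct-path remainder:
#' exposure instruments (effects `gamma`) act on the mediator with slope
#' `a` and on the outcome with total slope `direct + a*b`; mediator
#' instruments (effects `delta`, independent of the exposure) act on the
#' outcome with slope `b`. The true proportion mediated is
#' `a*b / (direct + a*b)`.
#'
#' @param a exposure -> mediator effect.
#' @param b mediator -> outcome effect.
#' @param direct direct exposure -> outcome effect.
#' @param k_x,k_m instrument counts for exposure and mediator.
#' @param gamma_sd,delta_sd instrument effect scales.
#' @param n sample size used for every GWAS.
#' @param seed integer seed.
#' @return list of three elements `exposure_mediator`,
#'   `mediator_outcome`, `exposure_outcome`, each with `$exposure` and
#'   `$outcome` summary-statistics frames, plus `truth`.
#' @export
simulate_mediation_chain <- function(a = 0.4, b = 0.25, direct = 0.05,
                                     k_x = 30, k_m = 30,
                                     gamma_sd = 0.1, delta_sd = 0.1,
                                     n = 200000, seed = 1L) {
  total <- direct + a * b
  local_seed_eval(seed, {
    # exposure instruments G1 (true effects gamma on the exposure) and
    # mediator instruments G2 (true effects delta on the mediator);
    # one GWAS draw per trait, reused across legs like real data
    eaf_x <- stats::runif(k_x, 0.1, 0.9)
    eaf_m <- stats::runif(k_m, 0.1, 0.9)
    gamma <- stats::rnorm(k_x, 0, gamma_sd)
    delta <- stats::rnorm(k_m, 0, delta_sd)
    se_x <- analytic_se(n, eaf_x)
    se_m <- analytic_se(n, eaf_m)
    snp_x <- sprintf("rsx%05d", seq_len(k_x))
    snp_m <- sprintf("rsm%05d", seq_len(k_m))
    pos_x <- seq_len(k_x) * 2e6
    pos_m <- seq_len(k_m) * 2e6
    noisy <- function(mu, se) mu + stats::rnorm(length(mu), 0, se)
    exposure_g1 <- sumstats_frame(snp_x, 1, pos_x, noisy(gamma, se_x),
                                  se_x, eaf_x, n)
    mediator_g1 <- sumstats_frame(snp_x, 1, pos_x, noisy(a * gamma, se_x),
                                  se_x, eaf_x, n)
    mediator_g2 <- sumstats_frame(snp_m, 2, pos_m, noisy(delta, se_m),
                                  se_m, eaf_m, n)
    outcome_g1 <- sumstats_frame(snp_x, 1, pos_x, noisy(total * gamma, se_x),
                                 se_x, eaf_x, n)
    outcome_g2 <- sumstats_frame(snp_m, 2, pos_m, noisy(b * delta, se_m),
                                 se_m, eaf_m, n)
    list(
      exposure_mediator = list(exposure = exposure_g1, outcome = mediator_g1),
      mediator_outcome = list(exposure = mediator_g2, outcome = outcome_g2),
      exposure_outcome = list(exposure = exposure_g1, outcome = outcome_g1),
      truth = list(a = a, b = b, direct = direct, total = total,
                   proportion = a * b / total)
    )
  })
}
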