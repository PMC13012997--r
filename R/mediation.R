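# Two-step mediation MR: decomposition of a total causal effect into an
# indirect (mediated, product of coefficients a*b) and direct component,
# plus the phenome-wide MR screen with FDR control.

#' Mediation decomposition from three MR coefficients
#'
#' Product-of-coefficients decomposition: `indirect = a * b` with Sobel
#' standard error `sqrt(a^2 se_b^2 + b^2 se_a^2)`;
#' `direct = total_c - indirect` (difference method, so
#' `indirect + direct = total_c` exactly) with
#' `se_direct = sqrt(se_c^2 + se_indirect^2)` under an independence
#' approximation; `proportion = indirect / total_c` with a delta-method
#' CI assuming zero covariance between the two estimates. All effects are
#' also reported on the odds-ratio scale.
#'
#' @param a,se_a exposure -> mediator effect and SE.
#' @param b,se_b mediator -> outcome effect and SE.
#' @param total_c,se_c total exposure -> outcome effect and SE.
#' @return list of class `mediation_result` with components `indirect`,
#'   `direct`, `total`, `proportion` (each a list with beta/se/ci/or where
#'   applicable) and `sobel_p`.
#' @export
mediate <- function(a, se_a, b, se_b, total_c, se_c) {
  stopifnot(se_a > 0, se_b > 0, se_c > 0)
  z975 <- stats::qnorm(0.975)
  indirect <- a * b
  se_ind <- sqrt(a^2 * se_b^2 + b^2 * se_a^2)
  sobel_p <- if (se_ind > 0) 2 * stats::pnorm(-abs(indirect / se_ind)) else NA_real_
  direct <- total_c - indirect
  se_dir <- sqrt(se_c^2 + se_ind^2)
  eff <- function(beta, se) {
    or <- to_odds_ratio(beta, se)
    list(beta = beta, se = se,
         ci_low = beta - z975 * se, ci_high = beta + z975 * se,
         or = or$or, or_ci_low = or$ci_low, or_ci_high = or$ci_high)
  }
  if (total_c == 0) {
    proportion <- list(estimate = NA_real_, se = NA_real_,
                       ci_low = NA_real_, ci_high = NA_real_,
                       note = "total effect is zero; proportion undefined")
  } else {
    prop <- indirect / total_c
    # delta method on (indirect, total) with zero covariance
    se_prop <- abs(prop) *
      sqrt((se_ind / indirect)^2 + (se_c / total_c)^2)
    if (!is.finite(se_prop)) se_prop <- abs(se_ind / total_c)
    proportion <- list(estimate = prop, se = se_prop,
                       ci_low = prop - z975 * se_prop,
                       ci_high = prop + z975 * se_prop)
  }
  structure(list(a = a, se_a = se_a, b = b, se_b = se_b,
                 indirect = eff(indirect, se_ind),
                 direct = eff(direct, se_dir),
                 total = eff(total_c, se_c),
                 proportion = proportion,
                 sobel_p = sobel_p),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  line <- function(nm, e) {
    cat(sprintf("  %-9s beta=%8.4f se=%.4f  OR %.4f (%.4f-%.4f)\n", nm,
                e$beta, e$se, e$or, e$or_ci_low, e$or_ci_high))
  }
  cat("Two-step mediation decomposition\n")
  line("total", x$total); line("indirect", x$indirect); line("direct", x$direct)
  if (!is.na(x$proportion$estimate)) {
    cat(sprintf("  proportion mediated %.1f%% (95%% CI %.1f%%-%.1f%%), Sobel p=%.4g\n",
                100 * x$proportion$estimate, 100 * x$proportion$ci_low,
                100 * x$proportion$ci_high, x$sobel_p))
  }
  invisible(x)
}

#' Two-step mediation MR pipeline from summary statistics
#'
#' Estimates each leg by univariable IVW after harmonization and
#' instrument selection, then decomposes with [mediate()]:
#' step a = exposure -> mediator, step b = mediator -> outcome
#' (optionally conditioned on the exposure through multivariable IVW),
#' total = exposure -> outcome.
#'
#' @param exposure_gwas,mediator_gwas,outcome_gwas summary-statistics data
#'   frames.
#' @param ld optional LD matrix for clumping.
#' @param p_threshold,r2_threshold,window_kb instrument-selection
#'   thresholds.
#' @param b_conditioned estimate b with MVMR adjusting for the exposure
#'   instead of univariable IVW (default FALSE).
#' @param seed seed passed to stochastic components.
#' @return a `mediation_result` with an `instruments` attribute recording
#'   per-step instrument counts.
#' @export
two_step_mediation <- function(exposure_gwas, mediator_gwas, outcome_gwas,
                               ld = NULL, p_threshold = 5e-8,
                               r2_threshold = 0.001, window_kb = 10000,
                               b_conditioned = FALSE, seed = 1L) {
  if (identical(mediator_gwas$snp, exposure_gwas$snp) &&
      isTRUE(all.equal(mediator_gwas$beta, exposure_gwas$beta)))
    warning("mediator summary statistics identical to exposure; degenerate instruments")
  step <- function(xg, yg, label) {
    pairs <- harmonize(xg, yg)
    inst <- select_instruments(pairs, ld, p_threshold, r2_threshold,
                               window_kb)
    if (nrow(inst) == 0)
      stop("zero instruments in mediation step: ", label, call. = FALSE)
    est <- if (nrow(inst) == 1) wald_ratio(inst) else mr_ivw(inst, "random")
    list(est = est, k = nrow(inst))
  }
  sa <- step(exposure_gwas, mediator_gwas, "exposure->mediator")
  sc <- step(exposure_gwas, outcome_gwas, "exposure->outcome")
  if (!b_conditioned) {
    sb <- step(mediator_gwas, outcome_gwas, "mediator->outcome")
    b <- sb$est$beta; se_b <- sb$est$se; kb <- sb$k
  } else {
    pm <- harmonize(mediator_gwas, outcome_gwas)
    im <- select_instruments(pm, ld, p_threshold, r2_threshold, window_kb)
    if (nrow(im) == 0) stop("zero instruments in mediation step: mediator->outcome",
                            call. = FALSE)
    px <- harmonize(exposure_gwas, outcome_gwas)
    mv <- mv_instrument_set(list(mediator = im, exposure = px),
                            pooling = "union")
    fit <- mv_ivw(mv)
    row <- fit$estimates[fit$estimates$exposure == "mediator", ]
    b <- row$beta; se_b <- row$se; kb <- row$nsnp
  }
  res <- mediate(sa$est$beta, sa$est$se, b, se_b, sc$est$beta, sc$est$se)
  attr(res, "instruments") <- c(a = sa$k, b = kb, total = sc$k)
  res
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment with enforced monotonicity
#' (`q_i = min over j >= i of p_(j) * m / j`).
#'
#' @param pvals p-values in (0, 1].
#' @return q-values in the input order; empty input gives empty output.
#' @export
bh_fdr <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  stopifnot(all(pvals > 0 & pvals <= 1))
  stats::p.adjust(pvals, method = "BH")
}

#' Phenome-wide MR screen of one exposure against an outcome panel
#'
#' Applies Wald-ratio (single instrument) or random-effects IVW MR of the
#' given instruments against every outcome, then Benjamini-Hochberg
#' q-values across the panel. Outcomes with no overlapping SNPs get a
#' missing estimate and are excluded from the FDR denominator.
#'
#' @param instruments summary-statistics data frame of the exposure's
#'   instruments (already clumped, e.g. at r^2 < 0.1 within 10,000 kb for
#'   cis-protein instruments).
#' @param outcome_list named list of outcome summary-statistics data
#'   frames.
#' @param fdr significance threshold on q (default 0.05).
#' @return data frame sorted by -log10 p: outcome, method, nsnp, beta,
#'   se, pval, q_value, significant.
#' @export
phewas_screen <- function(instruments, outcome_list, fdr = 0.05) {
  stopifnot(length(outcome_list) >= 1, !is.null(names(outcome_list)))
  rows <- lapply(names(outcome_list), function(nm) {
    pairs <- harmonize(instruments, outcome_list[[nm]])
    if (nrow(pairs) == 0) {
      return(data.frame(outcome = nm, method = NA_character_, nsnp = 0L,
                        beta = NA_real_, se = NA_real_, pval = NA_real_,
                        stringsAsFactors = FALSE))
    }
    est <- if (nrow(pairs) == 1) wald_ratio(pairs) else mr_ivw(pairs, "random")
    data.frame(outcome = nm, method = est$method, nsnp = est$k,
               beta = est$beta, se = est$se, pval = est$pval,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  est <- !is.na(out$pval)
  out$q_value <- NA_real_
  out$q_value[est] <- bh_fdr(out$pval[est])
  out$significant <- !is.na(out$q_value) & out$q_value < fdr
  out <- out[order(out$pval), , drop = FALSE]
  rownames(out) <- NULL
  out
}
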