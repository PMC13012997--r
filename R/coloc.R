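# Bayesian colocalization of two traits over a region via single-variant
# approximate Bayes factors (one causal variant per trait assumed).

#' Wakefield log approximate Bayes factor
#'
#' For a single variant with estimate `beta`, standard error `se` and a
#' N(0, prior_sd^2) prior on the true effect,
#' `labf = 0.5 * (log(se^2/(se^2+W)) + z^2 * W/(se^2+W))` with
#' `W = prior_sd^2` and `z = beta/se`. Positive values favour association.
#'
#' @param beta,se effect and standard error (vectorized; `se > 0`).
#' @param prior_sd prior standard deviation of the true effect.
#' @return log approximate Bayes factor(s).
#' @export
wakefield_labf <- function(beta, se, prior_sd) {
  if (any(se <= 0)) stop("se must be positive", call. = FALSE)
  if (prior_sd <= 0) stop("prior_sd must be positive", call. = FALSE)
  W <- prior_sd^2
  z2 <- (beta / se)^2
  r <- W / (se^2 + W)
  0.5 * (log(1 - r) + z2 * r)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b, stable
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

#' Construct a region pair for colocalization
#'
#' @param snp SNP ids (shared order for both traits).
#' @param beta1,se1 trait-1 effects and SEs.
#' @param beta2,se2 trait-2 effects and SEs.
#' @param type1,type2 `"quant"` or `"cc"` (case-control, log-odds scale).
#' @param label region label.
#' @return list of class `region_pair`.
#' @export
region_pair <- function(snp, beta1, se1, beta2, se2,
                        type1 = "quant", type2 = "cc", label = NULL) {
  stopifnot(length(snp) == length(beta1), length(beta1) == length(se1),
            length(beta1) == length(beta2), length(beta2) == length(se2))
  if (length(snp) < 10) warning("fewer than 10 SNPs in region; posteriors unstable")
  structure(list(snp = snp, beta1 = beta1, se1 = se1, beta2 = beta2,
                 se2 = se2, type1 = type1, type2 = type2, label = label),
            class = "region_pair")
}

#' Bayesian colocalization over a region
#'
#' Enumerates the five hypotheses about causal variants in the region —
#' H0 none, H1 trait 1 only, H2 trait 2 only, H3 both but distinct
#' variants, H4 one shared variant — with per-configuration priors `p1`,
#' `p2`, `p12` and per-SNP Wakefield log-ABFs. All sums are assembled in
#' log space; the H3 sum uses
#' `sum_i(exp l1_i) * sum_j(exp l2_j) - sum_i(exp(l1_i + l2_i))`.
#'
#' @param region a `region_pair` (or anything with the same fields).
#' @param p1,p2 prior probability a SNP is causal for trait 1 / trait 2
#'   only (defaults 1e-4).
#' @param p12 prior probability a SNP is causal for both (default 1e-5).
#' @param prior_sd_quant,prior_sd_cc prior effect SDs for quantitative
#'   traits (0.15) and case-control log-odds (0.2).
#' @return list of class `coloc_result`: `pp` (named pp_h0..pp_h4),
#'   `priors`, `n_snps`, `classification`.
#' @export
coloc_abf <- function(region, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      prior_sd_quant = 0.15, prior_sd_cc = 0.2) {
  m <- length(region$snp)
  if (m < 2) stop("colocalization needs at least 2 SNPs", call. = FALSE)
  sd_of <- function(type) if (identical(type, "cc")) prior_sd_cc else prior_sd_quant
  l1 <- wakefield_labf(region$beta1, region$se1, sd_of(region$type1))
  l2 <- wakefield_labf(region$beta2, region$se2, sd_of(region$type2))
  s1 <- logsumexp(l1)
  s2 <- logsumexp(l2)
  s12 <- logsumexp(l1 + l2)
  lw <- c(
    h0 = 0,
    h1 = log(p1) + s1,
    h2 = log(p2) + s2,
    h3 = log(p1) + log(p2) + logdiffexp(s1 + s2, s12),
    h4 = log(p12) + s12
  )
  pp <- exp(lw - logsumexp(lw))
  names(pp) <- paste0("pp_", names(lw))
  res <- structure(list(pp = pp, priors = c(p1 = p1, p2 = p2, p12 = p12),
                        n_snps = m, label = region$label),
                   class = "coloc_result")
  res$classification <- classify_coloc(res)
  res
}

#' Classify a colocalization result
#'
#' `shared_causal` when PP.H4 exceeds `h4_threshold` (the primary rule);
#' otherwise `distinct_or_shared` when PP.H3 + PP.H4 reaches
#' `combined_threshold` (the expanded inclusion rule); else `unresolved`.
#'
#' @param result a `coloc_result`, or a named vector with `pp_h3`, `pp_h4`.
#' @param h4_threshold PP.H4 cutoff (default 0.8).
#' @param combined_threshold PP.H3 + PP.H4 cutoff (default 0.8).
#' @return character classification.
#' @export
classify_coloc <- function(result, h4_threshold = 0.8,
                           combined_threshold = 0.8) {
  pp <- if (inherits(result, "coloc_result")) result$pp else result
  if (pp[["pp_h4"]] > h4_threshold) return("shared_causal")
  if (pp[["pp_h3"]] + pp[["pp_h4"]] >= combined_threshold)
    return("distinct_or_shared")
  "unresolved"
}

#' @export
print.coloc_result <- function(x, ...) {
  cat("Colocalization", if (!is.null(x$label)) paste0("[", x$label, "]"),
      "over", x$n_snps, "SNPs\n")
  print(round(x$pp, 4))
  cat("classification:", x$classification, "\n")
  invisible(x)
}
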