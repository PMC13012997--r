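# shared fixture builders: everything is generated in code at test time

# a minimal harmonized-pairs frame from raw effect vectors
make_pairs <- function(beta_x, se_x, beta_y, se_y, snp = NULL) {
  k <- length(beta_x)
  data.frame(
    snp = if (is.null(snp)) sprintf("rs%03d", seq_len(k)) else snp,
    chr = "1", pos = seq_len(k) * 1e6,
    beta_x = beta_x, se_x = se_x, pval_x = 2 * pnorm(-abs(beta_x / se_x)),
    eaf_x = 0.3, n_x = 1e5,
    beta_y = beta_y, se_y = se_y, pval_y = 2 * pnorm(-abs(beta_y / se_y)),
    eaf_y = 0.3, n_y = 1e5,
    action = "kept", stringsAsFactors = FALSE
  )
}

# write a small canonical sumstats file and return its path
write_sumstats_fixture <- function(lines, file = tempfile(fileext = ".tsv")) {
  writeLines(lines, file)
  file
}

# independent brute-force greedy clumping oracle: explicit loops, the
# same selection rules written from the definition
clump_oracle <- function(df, ld, p_threshold, r2_threshold, window_kb) {
  cand <- df[df$pval < p_threshold, , drop = FALSE]
  cand <- cand[order(cand$pval, cand$chr, cand$pos, cand$snp), ,
               drop = FALSE]
  chosen <- character(0)
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    for (s in chosen) {
      j <- which(df$snp == s)
      same_chr <- df$chr[j] == cand$chr[i]
      close_by <- FALSE
      if (same_chr) close_by <- abs(df$pos[j] - cand$pos[i]) <= window_kb * 1000
      if (same_chr && close_by) {
        r2 <- if (cand$snp[i] %in% rownames(ld) && s %in% rownames(ld))
          ld[cand$snp[i], s]^2 else 1
        if (r2 >= r2_threshold) ok <- FALSE
      }
    }
    if (ok) chosen <- c(chosen, cand$snp[i])
  }
  chosen
}

# brute-force Benjamini-Hochberg from the definition:
# q_i = min over j with p_(j) >= p_(i) of p_(j) * m / rank(j)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(vapply(i:m, function(j) p[o[j]] * m / j, numeric(1)))
  }
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# numeric-quadrature oracle for the single-variant Bayes factor:
# BF = integral N(bhat; b, se^2) N(b; 0, W) db / N(bhat; 0, se^2)
labf_quadrature <- function(beta, se, prior_sd) {
  num <- integrate(function(b) dnorm(beta, b, se) * dnorm(b, 0, prior_sd),
                   -Inf, Inf, rel.tol = 1e-12)$value
  log(num) - dnorm(beta, 0, se, log = TRUE)
}
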