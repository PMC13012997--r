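# canonical column order for summary-statistics tables
SUMSTATS_COLS <- c("snp", "chr", "pos", "ea", "oa", "eaf", "beta", "se", "pval", "n")
SUMSTATS_HEADER <- c("SNP", "CHR", "POS", "EA", "OA", "EAF", "BETA", "SE", "P", "N")

VALID_ALLELES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

is_palindromic <- function(ea, oa) {
  unname(COMPLEMENT[ea] == oa)
}

is_indel <- function(ea, oa) {
  nchar(ea) > 1L | nchar(oa) > 1L |
    !(ea %in% VALID_ALLELES) | !(oa %in% VALID_ALLELES)
}

#' Read GWAS/QTL summary statistics from a delimited text file
#'
#' Reads a tab- or whitespace-delimited file with a header row into a
#' validated summary-statistics data frame. The canonical header is
#' `SNP CHR POS EA OA EAF BETA SE P N`; nonstandard column names are
#' resolved through `column_map`. Rows violating basic invariants
#' (nonpositive SE, identical alleles, EAF outside (0,1), p outside (0,1],
#' or a p-value inconsistent with |beta/se| beyond a 10% z-to-p round-trip
#' tolerance) are collected in the `rejects` attribute with a reason, and
#' input row order is preserved for the retained records.
#'
#' @param path file path.
#' @param column_map named character vector mapping canonical names
#'   (`SNP`, `CHR`, `POS`, `EA`, `OA`, `EAF`, `BETA`, `SE`, `P`, `N`) to
#'   the names used in the file header. Canonical names found directly in
#'   the header need not be mapped. `EAF`, `CHR`, `POS` and `N` are
#'   optional columns.
#' @return a data frame with columns
#'   `snp, chr, pos, ea, oa, eaf, beta, se, pval, n` and an attribute
#'   `rejects` (data frame of `row`, `snp`, `reason`).
#' @export
read_sumstats <- function(path, column_map = NULL) {
  raw <- utils::read.table(path, header = TRUE, sep = "",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = NA)
  hdr <- names(raw)
  resolve <- function(canon) {
    if (!is.null(column_map) && canon %in% names(column_map)) {
      nm <- column_map[[canon]]
      if (!nm %in% hdr) stop("mapped column '", nm, "' for ", canon,
                             " not in header", call. = FALSE)
      return(nm)
    }
    if (canon %in% hdr) return(canon)
    NA_character_
  }
  mandatory <- c("SNP", "EA", "OA", "BETA", "SE", "P")
  cols <- vapply(SUMSTATS_HEADER, resolve, character(1))
  names(cols) <- SUMSTATS_HEADER
  missing <- intersect(mandatory, names(cols)[is.na(cols)])
  if (length(missing)) {
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  get_col <- function(canon, as = "numeric") {
    if (is.na(cols[[canon]])) return(rep(NA, nrow(raw)))
    v <- raw[[cols[[canon]]]]
    if (as == "character") as.character(v) else suppressWarnings(as.numeric(v))
  }
  df <- data.frame(
    snp  = get_col("SNP", "character"),
    chr  = get_col("CHR", "character"),
    pos  = suppressWarnings(as.integer(get_col("POS"))),
    ea   = toupper(get_col("EA", "character")),
    oa   = toupper(get_col("OA", "character")),
    eaf  = get_col("EAF"),
    beta = get_col("BETA"),
    se   = get_col("SE"),
    pval = get_col("P"),
    n    = get_col("N"),
    stringsAsFactors = FALSE
  )
  validate_sumstats(df)
}

#' Validate a summary-statistics data frame
#'
#' Applies the record invariants and splits the input into retained
#' records and rejected rows with reasons.
#'
#' @param df data frame with the canonical lower-case columns.
#' @return validated data frame with a `rejects` attribute.
#' @export
validate_sumstats <- function(df) {
  reason <- rep(NA_character_, nrow(df))
  bad <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    reason[is.na(reason) & cond] <<- why
  }
  bad(is.na(df$beta), "missing beta")
  bad(is.na(df$se) | df$se <= 0, "nonpositive SE")
  bad(is.na(df$pval) | df$pval <= 0 | df$pval > 1, "p outside (0,1]")
  bad(df$ea == df$oa, "identical alleles")
  bad(!is.na(df$eaf) & (df$eaf <= 0 | df$eaf >= 1), "EAF outside (0,1)")
  # z -> p round trip: reject gross inconsistencies only (10% tolerance on
  # -log10 scale, skipped for p at numeric underflow)
  ok <- is.na(reason) & !is.na(df$pval) & !is.na(df$beta) & !is.na(df$se) &
    df$se > 0 & df$pval < 1 & df$pval > 1e-300
  z <- abs(df$beta / df$se)
  p_imp <- 2 * stats::pnorm(-z)
  with_p <- ok & p_imp > 1e-300
  lr <- abs(log10(df$pval[with_p]) - log10(p_imp[with_p]))
  incons <- rep(FALSE, nrow(df))
  incons[with_p] <- lr > 0.1 * pmax(1, abs(log10(p_imp[with_p])))
  bad(incons, "p inconsistent with beta/se")

  keep <- is.na(reason)
  rejects <- data.frame(row = which(!keep), snp = df$snp[!keep],
                        reason = reason[!keep], stringsAsFactors = FALSE)
  if (sum(keep) == 0) stop("zero valid rows in summary statistics",
                           call. = FALSE)
  out <- df[keep, SUMSTATS_COLS, drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejects") <- rejects
  out
}

#' Write summary statistics in the canonical tab-delimited dialect
#'
#' @param df summary-statistics data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(df, path) {
  out <- df[, SUMSTATS_COLS, drop = FALSE]
  names(out) <- SUMSTATS_HEADER
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Quality-control filter for summary statistics
#'
#' Removes, in order: non-SNP variants (indels / non-ACGT alleles),
#' strand-ambiguous (palindromic) SNPs, duplicate SNP ids, and SNPs with
#' minor allele frequency below `maf_min`. This is the variant filter
#' applied before LD score regression and instrument selection.
#'
#' @param df summary-statistics data frame.
#' @param maf_min minimum minor allele frequency (default 0.01). SNPs with
#'   missing EAF are not removed by the MAF rule.
#' @param drop_ambiguous drop A/T and C/G SNPs.
#' @param drop_duplicates drop all but the first occurrence of a SNP id.
#' @param drop_indels drop variants whose alleles are not single ACGT bases.
#' @return filtered data frame with a `qc_report` attribute counting
#'   removals per rule.
#' @export
qc_filter <- function(df, maf_min = 0.01, drop_ambiguous = TRUE,
                      drop_duplicates = TRUE, drop_indels = TRUE) {
  n0 <- nrow(df)
  report <- c(indel = 0L, ambiguous = 0L, duplicate = 0L, low_maf = 0L)
  if (drop_indels) {
    rm <- is_indel(df$ea, df$oa)
    report["indel"] <- sum(rm)
    df <- df[!rm, , drop = FALSE]
  }
  if (drop_ambiguous && nrow(df)) {
    rm <- is_palindromic(df$ea, df$oa)
    report["ambiguous"] <- sum(rm)
    df <- df[!rm, , drop = FALSE]
  }
  if (drop_duplicates && nrow(df)) {
    rm <- duplicated(df$snp)
    report["duplicate"] <- sum(rm)
    df <- df[!rm, , drop = FALSE]
  }
  if (nrow(df)) {
    maf <- pmin(df$eaf, 1 - df$eaf)
    rm <- !is.na(maf) & maf < maf_min
    report["low_maf"] <- sum(rm)
    df <- df[!rm, , drop = FALSE]
  }
  if (nrow(df) == 0) warning("qc_filter removed every SNP")
  stopifnot(sum(report) == n0 - nrow(df))
  rownames(df) <- NULL
  attr(df, "qc_report") <- report
  df
}

#' Per-SNP instrument strength F-statistic
#'
#' F = (beta/se)^2, the squared z-statistic. Instruments with F < 10 are
#' conventionally flagged as weak.
#'
#' @param beta,se effect and standard error (vectorized).
#' @return numeric vector of F statistics with attribute `weak`
#'   (logical, F < 10).
#' @export
f_statistic <- function(beta, se) {
  if (any(se <= 0)) stop("se must be positive", call. = FALSE)
  f <- (beta / se)^2
  attr(f, "weak") <- f < 10
  f
}

#' Harmonize exposure and outcome summary statistics to shared effect alleles
#'
#' Restricts to SNPs present in both data sets and aligns the outcome
#' effect to the exposure's effect allele. When outcome alleles are swapped
#' the outcome beta's sign and EAF are flipped; strand flips
#' (complementary coding) are recognised for non-palindromic SNPs.
#' Palindromic SNPs are resolved by allele frequency: they are kept only
#' when both EAFs lie outside the ambiguity window
#' `[0.5 - palindrome_eaf_window, 0.5 + palindrome_eaf_window]`; same-side
#' frequencies keep the coding, opposite sides flip the outcome effect.
#' Incompatible allele sets are dropped with reason `allele mismatch`.
#'
#' @param exposure,outcome summary-statistics data frames.
#' @param palindrome_eaf_window half-width of the EAF ambiguity window
#'   around 0.5 (default 0.08).
#' @return data frame of class `harmonized_pairs` with columns
#'   `snp, chr, pos, beta_x, se_x, pval_x, eaf_x, n_x, beta_y, se_y,
#'   pval_y, eaf_y, n_y, action`; dropped SNPs are recorded in the
#'   `dropped` attribute with reasons.
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_window = 0.08) {
  shared <- intersect(exposure$snp, outcome$snp)
  ex <- exposure[match(shared, exposure$snp), , drop = FALSE]
  ou <- outcome[match(shared, outcome$snp), , drop = FALSE]
  n <- length(shared)
  action <- character(n)
  flip <- logical(n)
  reason <- rep(NA_character_, n)
  w <- palindrome_eaf_window
  for (i in seq_len(n)) {
    pal <- is_palindromic(ex$ea[i], ex$oa[i])
    same    <- ou$ea[i] == ex$ea[i] && ou$oa[i] == ex$oa[i]
    swapped <- ou$ea[i] == ex$oa[i] && ou$oa[i] == ex$ea[i]
    comp_ea <- unname(COMPLEMENT[ou$ea[i]]); comp_oa <- unname(COMPLEMENT[ou$oa[i]])
    csame    <- !pal && identical(comp_ea, ex$ea[i]) && identical(comp_oa, ex$oa[i])
    cswapped <- !pal && identical(comp_ea, ex$oa[i]) && identical(comp_oa, ex$ea[i])
    if (pal && (same || swapped)) {
      fx <- ex$eaf[i]; fy <- ou$eaf[i]
      # swapped palindromic coding is the same physical SNP; compare the
      # outcome frequency on the exposure's effect-allele scale
      if (swapped && !is.na(fy)) fy <- 1 - fy
      if (is.na(fx) || is.na(fy) ||
          abs(fx - 0.5) <= w || abs(fy - 0.5) <= w) {
        action[i] <- "dropped"; reason[i] <- "palindromic ambiguous"
      } else if ((fx < 0.5) == (fy < 0.5)) {
        action[i] <- "palindromic_inferred"; flip[i] <- FALSE
      } else {
        action[i] <- "palindromic_inferred"; flip[i] <- TRUE
      }
    } else if (same || csame) {
      action[i] <- "kept"
    } else if (swapped || cswapped) {
      action[i] <- "allele_flipped"; flip[i] <- TRUE
    } else {
      action[i] <- "dropped"; reason[i] <- "allele mismatch"
    }
  }
  beta_y <- ifelse(flip, -ou$beta, ou$beta)
  eaf_y <- ifelse(flip, 1 - ou$eaf, ou$eaf)
  pairs <- data.frame(
    snp = shared, chr = ex$chr, pos = ex$pos,
    ea = ex$ea, oa = ex$oa,
    beta_x = ex$beta, se_x = ex$se, pval_x = ex$pval, eaf_x = ex$eaf,
    n_x = ex$n,
    beta_y = beta_y, se_y = ou$se, pval_y = ou$pval, eaf_y = eaf_y,
    n_y = ou$n,
    action = action, stringsAsFactors = FALSE
  )
  dropped <- data.frame(snp = shared[action == "dropped"],
                        reason = reason[action == "dropped"],
                        stringsAsFactors = FALSE)
  out <- pairs[action != "dropped", , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  class(out) <- c("harmonized_pairs", "data.frame")
  out
}

#' Read / construct an LD matrix
#'
#' An LD matrix is a square matrix of signed correlations `r` with SNP ids
#' as dimnames. `read_ld_matrix` reads the TSV dialect (SNP ids in the
#' first row and column); `ld_matrix` validates an in-memory matrix.
#'
#' @param path TSV file path.
#' @return validated LD matrix.
#' @export
read_ld_matrix <- function(path) {
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   row.names = 1, check.names = FALSE))
  ld_matrix(m)
}

#' @rdname read_ld_matrix
#' @param m square numeric matrix with SNP-id dimnames.
#' @export
ld_matrix <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("LD matrix needs SNP-id dimnames", call. = FALSE)
  if (max(abs(m - t(m))) > 1e-8) stop("LD matrix not symmetric", call. = FALSE)
  if (max(abs(diag(m) - 1)) > 1e-8) stop("LD diagonal must be 1", call. = FALSE)
  if (max(abs(m)) > 1 + 1e-8) stop("|r| must be <= 1", call. = FALSE)
  m
}

#' @rdname read_ld_matrix
#' @param ld LD matrix.
#' @export
write_ld_matrix <- function(ld, path) {
  utils::write.table(ld, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' Greedy LD clumping of genome-wide significant SNPs
#'
#' Selects approximately independent instruments: candidates with
#' `p < p_threshold` are visited in order of ascending p (ties broken by
#' chromosome, position, SNP id) and accepted iff their squared LD
#' correlation with every previously accepted SNP within `window_kb` on
#' the same chromosome is below `r2_threshold`. Missing LD entries within
#' the window are treated conservatively as r^2 = 1 (blocking
#' co-selection); pairs on different chromosomes or beyond the window as
#' r^2 = 0.
#'
#' @param df summary statistics (or harmonized pairs with `pval_x`).
#' @param ld LD matrix (signed r) covering candidate SNPs, or NULL.
#' @param p_threshold genome-wide significance threshold (default 5e-8).
#' @param r2_threshold maximum pairwise r^2 among instruments (default 0.001).
#' @param window_kb clumping window in kilobases (default 10000).
#' @return the rows of `df` retained, in selection order, with attribute
#'   `selection` recording the thresholds.
#' @export
clump <- function(df, ld = NULL, p_threshold = 5e-8, r2_threshold = 0.001,
                  window_kb = 10000) {
  p <- if ("pval_x" %in% names(df)) df$pval_x else df$pval
  cand <- which(p < p_threshold)
  if (length(cand) == 0) {
    warning("no SNP passes the p-value threshold")
    out <- df[integer(0), , drop = FALSE]
    attr(out, "selection") <- list(p_threshold = p_threshold,
                                   r2_threshold = r2_threshold,
                                   window_kb = window_kb)
    return(out)
  }
  ord <- cand[order(p[cand], df$chr[cand], df$pos[cand], df$snp[cand])]
  r2_between <- function(i, j) {
    same_chr <- !is.na(df$chr[i]) && !is.na(df$chr[j]) &&
      df$chr[i] == df$chr[j]
    if (!same_chr) return(0)
    in_window <- is.na(df$pos[i]) || is.na(df$pos[j]) ||
      abs(df$pos[i] - df$pos[j]) <= window_kb * 1000
    if (!in_window) return(0)
    if (is.null(ld) || !(df$snp[i] %in% rownames(ld)) ||
        !(df$snp[j] %in% rownames(ld))) return(1)  # conservative
    ld[df$snp[i], df$snp[j]]^2
  }
  accepted <- integer(0)
  for (i in ord) {
    ok <- all(vapply(accepted, function(j) r2_between(i, j) < r2_threshold,
                     logical(1)))
    if (ok) accepted <- c(accepted, i)
  }
  out <- df[accepted, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "selection") <- list(p_threshold = p_threshold,
                                 r2_threshold = r2_threshold,
                                 window_kb = window_kb)
  out
}

#' Assemble an instrument set from harmonized pairs
#'
#' Convenience wrapper: clump on the exposure p-values, compute per-SNP
#' F-statistics, and record selection metadata.
#'
#' @inheritParams clump
#' @param pairs harmonized pairs.
#' @param f_min minimum F-statistic; weaker instruments are removed.
#' @return harmonized pairs subset with columns `F` added and attributes
#'   `selection` and `mean_F`.
#' @export
select_instruments <- function(pairs, ld = NULL, p_threshold = 5e-8,
                               r2_threshold = 0.001, window_kb = 10000,
                               f_min = 10) {
  sel <- clump(pairs, ld, p_threshold, r2_threshold, window_kb)
  if (nrow(sel)) {
    f <- f_statistic(sel$beta_x, sel$se_x)
    sel$F <- as.numeric(f)
    sel <- sel[sel$F >= f_min, , drop = FALSE]
    rownames(sel) <- NULL
  }
  attr(sel, "selection") <- list(p_threshold = p_threshold,
                                 r2_threshold = r2_threshold,
                                 window_kb = window_kb, f_min = f_min)
  attr(sel, "mean_F") <- if (nrow(sel)) mean(sel$F) else NA_real_
  sel
}
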