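test_that("read_sumstats parses well-formed rows and rejects invalid ones", {
  f <- write_sumstats_fixture(c(
    "SNP\tEA\tOA\tBETA\tSE\tP\tN",
    "rs1\tA\tG\t0.10\t0.02\t5.7e-7\t10000",
    "rs2\tC\tT\t-0.05\t0.03\t0.096\t10000",
    "rs3\tA\tG\t0.10\t0\t0.01\t10000"
  ))
  ss <- read_sumstats(f)
  expect_equal(nrow(ss), 2L)
  expect_equal(ss$snp, c("rs1", "rs2"))
  rej <- attr(ss, "rejects")
  expect_equal(nrow(rej), 1L)
  expect_equal(rej$reason, "nonpositive SE")
})

test_that("column_map resolves nonstandard headers; missing mandatory column errors", {
  f <- write_sumstats_fixture(c(
    "rsid\teffect_allele\tother\tb\tstderr\tpvalue",
    "rs1\ta\tg\t0.10\t0.02\t5.7e-7"
  ))
  ss <- read_sumstats(f, column_map = c(SNP = "rsid", EA = "effect_allele",
                                        OA = "other", BETA = "b",
                                        SE = "stderr", P = "pvalue"))
  expect_equal(ss$ea, "A")
  expect_equal(ss$beta, 0.1)
  f2 <- write_sumstats_fixture(c("SNP\tEA\tOA\tBETA\tSE", "rs1\tA\tG\t0.1\t0.02"))
  expect_error(read_sumstats(f2), "missing mandatory column")
})

test_that("write -> read round-trip is identity on all fields", {
  sim <- simulate_two_sample(k = 40, theta = 0.1, seed = 42)
  f <- tempfile(fileext = ".tsv")
  write_sumstats(sim$exposure, f)
  back <- read_sumstats(f)
  expect_equal(nrow(attr(back, "rejects")), 0L)
  for (col in names(sim$exposure)) {
    expect_equal(back[[col]], sim$exposure[[col]], tolerance = 1e-12,
                 info = col)
  }
})

test_that("qc_filter applies the removal rules in order and counts add up", {
  df <- data.frame(
    snp = c("rs1", "rs2", "rs3", "rs3", "rs4", "rs5"),
    chr = "1", pos = 1:6,
    ea = c("A", "A", "C", "C", "G", "AT"),
    oa = c("T", "G", "T", "T", "A", "A"),
    eaf = c(0.4, 0.995, 0.3, 0.3, 0.5, 0.2),
    beta = 0.1, se = 0.05, pval = 0.0455, n = 1e4,
    stringsAsFactors = FALSE
  )
  out <- qc_filter(df)
  rep <- attr(out, "qc_report")
  expect_equal(unname(rep["indel"]), 1L)      # rs5 AT allele
  expect_equal(unname(rep["ambiguous"]), 1L)  # rs1 A/T
  expect_equal(unname(rep["duplicate"]), 1L)  # second rs3
  expect_equal(unname(rep["low_maf"]), 1L)    # rs2 MAF 0.005
  expect_equal(sum(rep), nrow(df) - nrow(out))
  expect_equal(out$snp, c("rs3", "rs4"))
})

test_that("simulated clean SNPs all survive default QC", {
  sim <- simulate_two_sample(k = 100, theta = 0, seed = 3)
  expect_equal(nrow(qc_filter(sim$exposure)), 100L)
})

test_that("harmonize flips swapped alleles and resolves palindromes by EAF", {
  ex <- data.frame(snp = c("rs1", "rs2", "rs3", "rs4"), chr = "1",
                   pos = 1:4, ea = c("A", "A", "A", "A"),
                   oa = c("G", "T", "T", "C"),
                   eaf = c(0.3, 0.5, 0.2, 0.3), beta = 0.1, se = 0.02,
                   pval = 5.7e-7, n = 1e4, stringsAsFactors = FALSE)
  ou <- data.frame(snp = c("rs1", "rs2", "rs3", "rs4"), chr = "1",
                   pos = 1:4, ea = c("G", "A", "A", "A"),
                   oa = c("A", "T", "T", "G"),
                   eaf = c(0.7, 0.5, 0.25, 0.3), beta = 0.2, se = 0.02,
                   pval = 2.2e-23, n = 1e4, stringsAsFactors = FALSE)
  h <- harmonize(ex, ou)
  # rs1: swapped coding -> sign flip
  expect_equal(h$beta_y[h$snp == "rs1"], -0.2)
  expect_equal(h$action[h$snp == "rs1"], "allele_flipped")
  # rs2: palindromic at EAF 0.5 -> dropped
  expect_false("rs2" %in% h$snp)
  expect_true("palindromic ambiguous" %in% attr(h, "dropped")$reason)
  # rs3: palindromic, both EAF < 0.42 same side -> kept without flip
  expect_equal(h$beta_y[h$snp == "rs3"], 0.2)
  expect_equal(h$action[h$snp == "rs3"], "palindromic_inferred")
  # rs4: A/C vs A/G -> allele mismatch
  expect_false("rs4" %in% h$snp)
  expect_true("allele mismatch" %in% attr(h, "dropped")$reason)
})

test_that("harmonizing simulator output needs no flips and is idempotent", {
  sim <- simulate_two_sample(k = 30, theta = 0.2, seed = 5)
  h <- harmonize(sim$exposure, sim$outcome)
  expect_equal(nrow(h), 30L)
  expect_true(all(h$action == "kept"))
  # convert harmonized pairs back into two record sets and re-harmonize
  to_records <- function(h, side) {
    data.frame(snp = h$snp, chr = h$chr, pos = h$pos, ea = h$ea, oa = h$oa,
               eaf = h[[paste0("eaf_", side)]],
               beta = h[[paste0("beta_", side)]],
               se = h[[paste0("se_", side)]],
               pval = h[[paste0("pval_", side)]],
               n = h[[paste0("n_", side)]], stringsAsFactors = FALSE)
  }
  h2 <- harmonize(to_records(h, "x"), to_records(h, "y"))
  expect_equal(h2$beta_y, h$beta_y)
  expect_equal(h2$beta_x, h$beta_x)
})

test_that("f_statistic matches the squared z on a grid and flags weak SNPs", {
  expect_equal(as.numeric(f_statistic(0.1, 0.02)), 25)
  f0 <- f_statistic(0, 0.1)
  expect_equal(as.numeric(f0), 0)
  expect_true(attr(f0, "weak"))
  set.seed(1)
  beta <- rnorm(50); se <- runif(50, 0.01, 1)
  expect_equal(as.numeric(f_statistic(beta, se)), (beta / se)^2)
  expect_error(f_statistic(0.1, 0), "positive")
})

test_that("clump applies the greedy r2 rule and the chromosome/window rule", {
  df <- data.frame(snp = c("a", "b"), chr = "1", pos = c(1e6, 2e6),
                   ea = "A", oa = "G", eaf = 0.3,
                   beta = c(0.1, 0.1), se = c(0.015, 0.016),
                   pval = c(1e-10, 1e-9), n = 1e4, stringsAsFactors = FALSE)
  ld <- matrix(c(1, sqrt(0.5), sqrt(0.5), 1), 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(clump(df, ld)$snp, "a")
  df2 <- df; df2$chr <- c("1", "2")
  expect_equal(sort(clump(df2, ld = NULL)$snp), c("a", "b"))
})

test_that("clump is row-order invariant and matches the brute-force oracle", {
  set.seed(7)
  m <- 50
  blocks <- rep(1:10, each = 5)
  R <- outer(blocks, blocks, function(a, b) ifelse(a == b, 0.8, 0))
  diag(R) <- 1
  snps <- sprintf("rs%02d", 1:m)
  dimnames(R) <- list(snps, snps)
  df <- data.frame(snp = snps, chr = "1", pos = (1:m) * 1e5,
                   ea = "A", oa = "G", eaf = 0.3,
                   beta = 0.1, se = 0.1 / sqrt(qchisq(1e-9, 1, lower.tail = FALSE)),
                   pval = 10^-runif(m, 8.5, 20), n = 1e4,
                   stringsAsFactors = FALSE)
  got <- clump(df, R, r2_threshold = 0.5)
  expect_equal(sort(got$snp),
               sort(clump_oracle(df, R, 5e-8, 0.5, 10000)))
  shuf <- df[sample(m), ]
  expect_equal(sort(clump(shuf, R, r2_threshold = 0.5)$snp),
               sort(got$snp))
})

test_that("missing LD entries block co-selection within the window", {
  df <- data.frame(snp = c("a", "b"), chr = "1", pos = c(1e6, 2e6),
                   ea = "A", oa = "G", eaf = 0.3, beta = 0.1,
                   se = 0.012, pval = c(1e-10, 1e-9), n = 1e4,
                   stringsAsFactors = FALSE)
  expect_equal(clump(df, ld = NULL)$snp, "a")  # no LD info -> conservative
})

test_that("LD matrix validation enforces symmetry, unit diagonal and bounds", {
  R <- ar1_ld(5, 0.5)
  expect_silent(ld_matrix(R))
  f <- tempfile()
  write_ld_matrix(R, f)
  expect_equal(read_ld_matrix(f), R, tolerance = 1e-12)
  bad <- R; bad[1, 2] <- 0.9
  expect_error(ld_matrix(bad), "symmetric")
  bad2 <- R; diag(bad2) <- 2; bad2[lower.tri(bad2)] <- t(bad2)[lower.tri(bad2)]
  expect_error(ld_matrix(bad2), "diagonal")
})
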