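test_that("mediate: degenerate a = 0 and the decomposition identity", {
  m0 <- mediate(0, 0.01, 0.3, 0.05, 0.2, 0.04)
  expect_equal(m0$indirect$beta, 0)
  expect_equal(m0$indirect$se, 0.3 * 0.01)
  expect_equal(m0$proportion$estimate, 0)
  set.seed(41)
  for (i in 1:25) {
    m <- mediate(rnorm(1), runif(1, .01, .1), rnorm(1), runif(1, .01, .1),
                 rnorm(1), runif(1, .01, .1))
    expect_lt(abs(m$indirect$beta + m$direct$beta - m$total$beta),
              1e-12 * max(1, abs(m$total$beta)))
  }
})

test_that("mediate reproduces the published decomposition arithmetic", {
  # printed inputs: indirect CI 0.0292-0.1716 (se from its width),
  # total 0.1518 with OR CI 1.0280-1.3180
  se_ind <- (0.1716 - 0.0292) / (2 * qnorm(0.975))
  se_tot <- (log(1.3180) - log(1.0280)) / (2 * qnorm(0.975))
  m <- mediate(a = 0.1004, se_a = se_ind, b = 1, se_b = 1e-12,
               total_c = 0.1518, se_c = se_tot)
  expect_equal(round(m$indirect$or, 3), 1.106)
  expect_equal(round(100 * m$proportion$estimate, 1), 66.1)
  expect_equal(m$direct$beta, 0.0514, tolerance = 1e-12)
  # CI midpoint identity of the printed indirect effect
  expect_equal((0.0292 + 0.1716) / 2, 0.1004)
})

test_that("Sobel p is symmetric in the two mediation legs", {
  m1 <- mediate(0.4, 0.05, 0.25, 0.08, 0.15, 0.05)
  m2 <- mediate(0.25, 0.08, 0.4, 0.05, 0.15, 0.05)
  expect_equal(m1$sobel_p, m2$sobel_p)
  expect_equal(m1$indirect$se, m2$indirect$se)
})

test_that("odds-ratio CI brackets the point estimate for every positive se", {
  set.seed(42)
  for (i in 1:30) {
    beta <- rnorm(1); se <- runif(1, 1e-4, 2)
    or <- to_odds_ratio(beta, se)
    expect_lt(or$ci_low, or$or)
    expect_gt(or$ci_high, or$or)
  }
})

test_that("zero total effect leaves the proportion undefined", {
  m <- mediate(0.1, 0.02, 0.2, 0.03, 0, 0.05)
  expect_true(is.na(m$proportion$estimate))
})

test_that("BH q-values match the brute-force step-up definition", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(43)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-14)
  }
  # q >= p and step-up monotonicity
  p <- runif(30)
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-15))
})

test_that("two-step pipeline recovers a full-mediation chain and warns on
           degenerate mediator input", {
  ch <- simulate_mediation_chain(a = 0.4, b = 0.25, direct = 0, seed = 55)
  m <- run_mediation_on_chain(ch)
  expect_true(m$proportion$ci_low <= 1 && 1 <= m$proportion$ci_high)
  sim <- simulate_two_sample(k = 10, theta = 0.2, seed = 5)
  expect_warning(
    try(two_step_mediation(sim$exposure, sim$exposure, sim$outcome),
        silent = TRUE),
    "identical")
})

test_that("Sobel p is uniform when there is nothing to mediate", {
  ps <- vapply(1:200, function(s) {
    ch <- simulate_mediation_chain(a = 0, b = 0.25, direct = 0.1,
                                   seed = 7000 + s)
    run_mediation_on_chain(ch)$sobel_p
  }, numeric(1))
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.05)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("proportion-mediated CI covers the generating value", {
  cover <- vapply(1:200, function(s) {
    p <- run_mediation_on_chain(simulate_mediation_chain(seed = s))$proportion
    p$ci_low <= 2 / 3 && 2 / 3 <= p$ci_high
  }, logical(1))
  expect_gte(mean(cover), 0.9)
})

test_that("phewas screen: BH hand computation, single outcome, missing overlap", {
  sim <- simulate_two_sample(k = 6, theta = 0.3, seed = 61)
  inst <- sim$exposure
  outcomes <- list(o1 = sim$outcome)
  scr1 <- phewas_screen(inst, outcomes)
  expect_equal(scr1$q_value, scr1$pval)
  # outcome with disjoint SNPs gets a missing row outside the FDR count
  other <- sim$outcome
  other$snp <- paste0("zz", other$snp)
  scr2 <- phewas_screen(inst, list(hit = sim$outcome, none = other))
  expect_true(is.na(scr2$pval[scr2$outcome == "none"]))
  expect_equal(scr2$q_value[scr2$outcome == "hit"],
               scr2$pval[scr2$outcome == "hit"])  # FDR denominator is 1
})

test_that("phewas screen ranks a true causal outcome first with q < 0.05", {
  top <- vapply(1:20, function(rep) {
    sim <- simulate_two_sample(k = 5, theta = 0.26, seed = 8000 + rep)
    nulls <- lapply(1:100, function(i) {
      simulate_two_sample(k = 5, theta = 0, seed = 8000 + rep * 200 + i)$outcome
    })
    names(nulls) <- sprintf("null_%03d", 1:100)
    scr <- phewas_screen(sim$exposure, c(list(truth = sim$outcome), nulls))
    scr$outcome[1] == "truth" && scr$significant[1]
  }, logical(1))
  expect_gte(mean(top), 0.9)
})
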