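test_that("wald ratio point estimate, SEs and degenerate cases", {
  p <- list(beta_x = 0.5, se_x = 0.05, beta_y = 0.2, se_y = 0.1)
  w <- wald_ratio(p)
  expect_equal(w$beta, 0.4)
  expect_equal(w$se, 0.2)
  p0 <- list(beta_x = 0.5, se_x = 0.05, beta_y = 0, se_y = 0.1)
  w0 <- wald_ratio(p0)
  expect_equal(w0$beta, 0)
  expect_equal(w0$pval, 1)
  expect_error(wald_ratio(list(beta_x = 0, se_x = 1, beta_y = 1, se_y = 1)),
               "nonzero")
  # second-order se dominates first-order on a grid
  set.seed(2)
  for (i in 1:30) {
    p <- list(beta_x = runif(1, 0.05, 1), se_x = runif(1, 0.01, 0.5),
              beta_y = rnorm(1), se_y = runif(1, 0.01, 0.5))
    expect_gte(wald_ratio(p, "second")$se, wald_ratio(p, "first")$se)
  }
})

test_that("IVW closed form, k=1 rejection, and random-effects inflation", {
  pr <- make_pairs(rep(1, 4), rep(0.01, 4), rep(0.1, 4), rep(1, 4))
  est <- mr_ivw(pr, "fixed")
  expect_equal(est$beta, 0.1)
  expect_equal(est$se, 0.5)
  expect_error(mr_ivw(pr[1, ]), "wald_ratio")
  # single pair: the IVW formula limit equals the Wald ratio
  one <- make_pairs(0.4, 0.01, 0.12, 0.05)
  expect_equal(sum(one$beta_x * one$beta_y / one$se_y^2) /
                 sum(one$beta_x^2 / one$se_y^2),
               wald_ratio(one)$beta)
  set.seed(4)
  pr2 <- make_pairs(runif(8, 0.1, 1), rep(0.01, 8), rnorm(8, 0.2, 0.2),
                    runif(8, 0.05, 0.2))
  expect_gte(mr_ivw(pr2, "random")$se, mr_ivw(pr2, "fixed")$se)
})

test_that("IVW equals a generic weighted no-intercept regression to 1e-10", {
  set.seed(11)
  for (i in 1:20) {
    k <- sample(3:30, 1)
    pr <- make_pairs(rnorm(k, 0.3, 0.2), runif(k, 0.005, 0.05),
                     rnorm(k, 0.05, 0.1), runif(k, 0.01, 0.3))
    fit <- lm(beta_y ~ beta_x + 0, data = pr, weights = 1 / pr$se_y^2)
    expect_equal(mr_ivw(pr, "fixed")$beta, unname(coef(fit)),
                 tolerance = 1e-10)
  }
})

test_that("Egger recovers an exact line and matches a WLS oracle", {
  bx <- c(0.2, 0.35, 0.5, 0.7, 0.9)
  pr <- make_pairs(bx, rep(0.01, 5), 0.01 + 0.3 * bx, rep(0.05, 5))
  eg <- mr_egger(pr)
  expect_equal(eg$slope$beta, 0.3, tolerance = 1e-10)
  expect_equal(eg$intercept$beta, 0.01, tolerance = 1e-10)
  set.seed(21)
  for (i in 1:20) {
    k <- sample(4:25, 1)
    pr <- make_pairs(abs(rnorm(k, 0.4, 0.2)) + 0.01, runif(k, 0.005, 0.05),
                     rnorm(k), runif(k, 0.02, 0.3))
    fit <- lm(beta_y ~ beta_x, data = pr, weights = 1 / pr$se_y^2)
    eg <- mr_egger(pr)
    expect_equal(eg$slope$beta, unname(coef(fit)[2]), tolerance = 1e-10)
    expect_equal(eg$intercept$beta, unname(coef(fit)[1]), tolerance = 1e-10)
  }
  expect_error(mr_egger(make_pairs(c(1, 1), c(.1, .1), c(1, 1), c(.1, .1))),
               "at least 3")
})

test_that("Egger intercept is centred at zero without pleiotropy and near the
           planted mean under directional pleiotropy", {
  ints <- vapply(1:300, function(s) {
    sim <- simulate_two_sample(k = 30, theta = 0.2, seed = s)
    mr_egger(harmonize(sim$exposure, sim$outcome))$intercept$beta
  }, numeric(1))
  expect_lt(abs(mean(ints)), 0.002)
  ints_d <- vapply(1:300, function(s) {
    sim <- simulate_two_sample(k = 30, theta = 0.2,
                               pleiotropy = "directional",
                               pleio_mean = 0.02, seed = s)
    mr_egger(harmonize(sim$exposure, sim$outcome))$intercept$beta
  }, numeric(1))
  expect_lt(abs(mean(ints_d) - 0.02), 0.005)
})

test_that("dIVW closed forms: IVW limit at se_x = 0 and the debiased ratio", {
  pr <- make_pairs(c(0.5, 0.8, 0.3), rep(0, 3), c(0.1, 0.15, 0.07),
                   c(0.05, 0.06, 0.04))
  expect_equal(mr_divw(pr, n_boot = 50)$beta, mr_ivw(pr, "fixed")$beta,
               tolerance = 1e-12)
  pr2 <- make_pairs(c(1, 1), c(0.1, 0.1), c(0.5, 0.5), c(1, 1))
  expect_equal(mr_divw(pr2, n_boot = 50)$beta, 0.5 / 0.99,
               tolerance = 1e-12)
  weak <- make_pairs(c(0.01, 0.02), c(0.5, 0.5), c(0.1, 0.1), c(1, 1))
  expect_error(mr_divw(weak), "weak")
})

test_that("dIVW is less biased than IVW under weak instruments", {
  # mean F ~ 10: gamma_sd comparable to the exposure SE
  res <- vapply(1:300, function(s) {
    sim <- simulate_two_sample(k = 80, theta = 0.2, gamma_sd = 0.04,
                               n_x = 20000, n_y = 20000, seed = s)
    h <- harmonize(sim$exposure, sim$outcome)
    divw <- tryCatch(mr_divw(h, n_boot = 2)$beta, error = function(e) NA)
    c(ivw = mr_ivw(h, "fixed")$beta, divw = divw)
  }, numeric(2))
  bias_ivw <- abs(mean(res["ivw", ]) - 0.2)
  bias_divw <- abs(mean(res["divw", ], na.rm = TRUE) - 0.2)
  expect_lt(bias_divw, bias_ivw)
})

test_that("RAPS limits: IVW at se_x = 0 and exact-line recovery", {
  pr <- make_pairs(c(0.5, 0.8, 0.3, 0.6), rep(0, 4),
                   c(0.1, 0.18, 0.05, 0.14), rep(0.05, 4))
  expect_equal(mr_raps(pr)$beta, mr_ivw(pr, "fixed")$beta,
               tolerance = 1e-6)
  bx <- c(0.2, 0.4, 0.6, 0.8)
  line <- make_pairs(bx, rep(0.01, 4), 0.3 * bx, rep(0.05, 4))
  expect_equal(mr_raps(line)$beta, 0.3, tolerance = 1e-6)
  expect_error(mr_raps(pr[1:2, ]), "at least 3")
})

test_that("RAPS recovers the causal effect with both-sided sampling error", {
  ths <- vapply(1:200, function(s) {
    sim <- simulate_two_sample(k = 100, theta = 0.15, seed = 400 + s)
    mr_raps(harmonize(sim$exposure, sim$outcome))$beta
  }, numeric(1))
  expect_lt(abs(mean(ths) - 0.15), 0.01)
})

test_that("Cochran's Q: zero under homogeneity, chi-square tail matches
           published sensitivity statistics, relabeling invariance", {
  bx <- c(0.2, 0.4, 0.5)
  pr <- make_pairs(bx, rep(0.01, 3), 0.3 * bx, rep(0.05, 3))
  q <- cochran_q(pr, 0.3)
  expect_equal(q$Q, 0)
  expect_equal(q$pval, 1)
  expect_equal(round(q_pvalue(17.02, 18), 2), 0.52)
  expect_equal(round(q_pvalue(30.74, 25), 1), 0.2)
  set.seed(31)
  pr2 <- make_pairs(runif(9, .2, 1), rep(.01, 9), rnorm(9, .2, .1),
                    runif(9, .02, .2))
  est <- mr_ivw(pr2, "fixed")$beta
  q1 <- cochran_q(pr2, est)
  q2 <- cochran_q(pr2[sample(9), ], est)
  expect_equal(q1$Q, q2$Q)
  expect_equal(q1$df, 8L)
})

test_that("leave-one-out flags a planted outlier and returns k rows", {
  set.seed(5)
  bx <- runif(12, 0.3, 0.8)
  by <- rnorm(12, 0, 0.02)   # null ratios with sampling noise
  by[7] <- 3 * bx[7]         # one SNP carries the whole signal
  pr <- make_pairs(bx, rep(0.01, 12), by, rep(0.02, 12))
  loo <- leave_one_out(pr)
  expect_equal(nrow(loo), 12L)
  expect_true(loo$flagged[7])
  expect_false(any(loo$flagged[-7]))
  sim <- simulate_two_sample(k = 20, theta = 0.2, seed = 8)
  loo2 <- leave_one_out(harmonize(sim$exposure, sim$outcome))
  expect_false(any(loo2$flagged))
  three <- make_pairs(c(.3, .4, .5), rep(.01, 3), c(.1, .12, .16),
                      rep(.05, 3))
  expect_equal(nrow(leave_one_out(three)), 3L)
})

test_that("Steiger directionality separates and is antisymmetric", {
  pr <- make_pairs(rep(0.15, 10), rep(0.005, 10), rep(0.002, 10),
                   rep(0.005, 10))
  st <- steiger(pr, n_x = 5e4, n_y = 5e4)
  expect_true(st$direction_ok)
  expect_lt(st$pval, 1e-6)
  swapped <- pr
  swapped[, c("beta_x", "se_x", "beta_y", "se_y")] <-
    pr[, c("beta_y", "se_y", "beta_x", "se_x")]
  st2 <- steiger(swapped, n_x = 5e4, n_y = 5e4)
  expect_false(st2$direction_ok)
  expect_equal(st$r2_exposure, st2$r2_outcome)
})

test_that("Steiger supports the generating direction on simulated chains", {
  ok <- vapply(1:200, function(s) {
    sim <- simulate_two_sample(k = 30, theta = 0.2, seed = 900 + s)
    steiger(harmonize(sim$exposure, sim$outcome))$direction_ok
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("odds-ratio transforms reproduce published effect arithmetic", {
  expect_equal(round(to_odds_ratio(0.1004, 0.0363)$or, 3), 1.106)
  or0 <- to_odds_ratio(0, 0.1)
  expect_equal(or0$or, 1)
  expect_equal(or0$ci_low * or0$ci_high, 1, tolerance = 1e-12)
  expect_equal(round(or_from_ci(1.1226, 1.5057), 4), 1.3001)
  expect_equal(round(percent_excess_risk(1.1586), 1), 15.9)
})

test_that("IVW p-values are uniform under the causal null", {
  rej <- vapply(1:1000, function(s) {
    sim <- simulate_two_sample(k = 50, theta = 0, seed = 5000 + s)
    mr_ivw(harmonize(sim$exposure, sim$outcome), "random")$pval < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.02)
})
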