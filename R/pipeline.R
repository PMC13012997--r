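# Orchestration of the multi-stage analytical framework: LDSC genetic
# correlation -> bidirectional MR -> univariable panel -> multivariable
# models -> SMR/COLOC -> PheWAS -> two-step mediation, from a single
# structured configuration with per-stage seed derivation and a
# consolidated report.

#' Bidirectional MR with a directionality verdict
#'
#' Runs the univariable MR panel in both directions (harmonizing and
#' selecting instruments separately for each) and combines the forward
#' estimate, the reverse estimate, and the Steiger directionality test
#' into a verdict: `"forward"` when the forward IVW is significant, the
#' reverse is null and Steiger supports exposure -> outcome;
#' `"ambiguous"` when both directions are significant; `"none"` when
#' neither is.
#'
#' @param exposure,outcome summary-statistics data frames.
#' @param ld optional LD matrix for clumping.
#' @param p_threshold,r2_threshold,window_kb instrument selection
#'   thresholds.
#' @param alpha significance level for the verdict (default 0.05).
#' @param steiger_filter drop individual SNPs whose single-SNP Steiger
#'   test fails to confirm the instrumented direction (one-sided
#'   p >= 0.05), per the exclusion-restriction screening rule (default
#'   TRUE).
#' @param seed seed for stochastic estimators.
#' @return list with `forward`, `reverse` (MR panel tables or NULL when
#'   not estimable), `steiger`, `verdict`.
#' @export
bidirectional_mr <- function(exposure, outcome, ld = NULL,
                             p_threshold = 5e-8, r2_threshold = 0.001,
                             window_kb = 10000, alpha = 0.05,
                             steiger_filter = TRUE, seed = 1L) {
  run_dir <- function(xg, yg) {
    pairs <- harmonize(xg, yg)
    inst <- suppressWarnings(
      select_instruments(pairs, ld, p_threshold, r2_threshold, window_kb))
    if (steiger_filter && nrow(inst) > 0) {
      keep <- vapply(seq_len(nrow(inst)), function(i) {
        st <- steiger(inst[i, , drop = FALSE])
        st$direction_ok && st$pval < 0.05
      }, logical(1))
      inst <- inst[keep, , drop = FALSE]
    }
    if (nrow(inst) == 0) return(NULL)
    list(panel = mr_panel(inst, seed = seed),
         steiger = steiger(inst), k = nrow(inst))
  }
  fwd <- run_dir(exposure, outcome)
  rev <- run_dir(outcome, exposure)
  p_of <- function(dir) {
    if (is.null(dir)) return(NA_real_)
    dir$panel$pval[dir$panel$method %in% c("ivw_re", "ivw_fe", "wald")][1]
  }
  p_f <- p_of(fwd); p_r <- p_of(rev)
  sig_f <- !is.na(p_f) && p_f < alpha
  sig_r <- !is.na(p_r) && p_r < alpha
  steiger_ok <- !is.null(fwd) && fwd$steiger$direction_ok &&
    fwd$steiger$pval < alpha
  verdict <- if (sig_f && sig_r) "ambiguous"
    else if (sig_f && !sig_r && steiger_ok) "forward"
    else if (sig_r && !sig_f) "reverse"
    else "none"
  list(forward = fwd, reverse = rev, verdict = verdict,
       reverse_estimable = !is.null(rev))
}

default_pipeline_config <- function() {
  list(
    seed = 1L,
    stages = list(ldsc = TRUE, bidirectional = TRUE, uvmr = TRUE,
                  mvmr = TRUE, smr_coloc = TRUE, pqtl_coloc = TRUE,
                  phewas = TRUE, mediation = TRUE),
    thresholds = list(p = 5e-8, r2 = 0.001, window_kb = 10000, f_min = 10,
                      pph4 = 0.8, pph34 = 0.8, heidi = 0.05, fdr = 0.05),
    simulate = list(theta = 0.15, k = 40, n = 200000,
                    h2_1 = 0.2, h2_2 = 0.1, rg = 0.22, M = 5000,
                    mediation = list(a = 0.4, b = 0.25, direct = 0.05),
                    n_phewas_null = 20, coloc_m = 100)
  )
}

read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML configs",
           call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  base <- default_pipeline_config()
  merge_lists <- function(a, b) {
    for (nm in names(b)) {
      a[[nm]] <- if (is.list(a[[nm]]) && is.list(b[[nm]]))
        merge_lists(a[[nm]], b[[nm]]) else b[[nm]]
    }
    a
  }
  cfg <- merge_lists(base, config)
  errs <- character(0)
  # mediator_file is validated at stage time so an absent mediator only
  # fails the mediation stage, not the whole run
  for (f in c("exposure_file", "outcome_file")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      errs <- c(errs, paste0(f, " does not exist: ", cfg[[f]]))
  }
  if (!is.numeric(cfg$seed)) errs <- c(errs, "seed must be numeric")
  if (length(errs)) stop("invalid pipeline config:\n  ",
                         paste(errs, collapse = "\n  "), call. = FALSE)
  cfg
}

#' Run the full multi-stage analysis pipeline
#'
#' Executes the stages enabled in the configuration in dependency order,
#' deriving each stage's seed as `seed + stage index` so a rerun with the
#' same config reproduces every table. Input data come from
#' `exposure_file`/`outcome_file`/`mediator_file` (canonical TSV dialect)
#' when given, otherwise from the synthetic generators using the
#' `simulate` block of the config. A failing stage is recorded with its
#' error and does not halt independent stages.
#'
#' @param config a named list or the path to a YAML file; see
#'   `default_pipeline_config()` for the recognised fields. All
#'   thresholds default to the study's values (p < 5e-8, r^2 < 0.001,
#'   10,000 kb, F >= 10, PP.H4 > 0.8, PP.H3+PP.H4 >= 0.8,
#'   p_HEIDI > 0.05, FDR < 0.05).
#' @return list of class `mr_report` with one element per executed stage
#'   plus `meta` (config digest, seeds, package version).
#' @export
run_pipeline <- function(config = list()) {
  cfg <- read_pipeline_config(config)
  th <- cfg$thresholds
  sp <- cfg$simulate
  seed0 <- as.integer(cfg$seed)
  report <- list()
  errors <- list()
  stage <- function(name, idx, fun) {
    if (!isTRUE(cfg$stages[[name]])) return(invisible(NULL))
    res <- tryCatch(fun(seed0 + idx), error = function(e) e)
    if (inherits(res, "error")) {
      errors[[name]] <<- conditionMessage(res)
    } else {
      report[[name]] <<- res
    }
    invisible(NULL)
  }

  load_or_sim_pair <- function(seed) {
    if (!is.null(cfg$exposure_file) && !is.null(cfg$outcome_file)) {
      list(exposure = read_sumstats(cfg$exposure_file),
           outcome = read_sumstats(cfg$outcome_file))
    } else {
      simulate_two_sample(k = sp$k, theta = sp$theta, n_x = sp$n,
                          n_y = sp$n, seed = seed)
    }
  }

  stage("ldsc", 1L, function(seed) {
    sim <- simulate_ldsc(M = sp$M, h2_1 = sp$h2_1, h2_2 = sp$h2_2,
                         rg = sp$rg, seed = seed)
    rg_regression(sim$ld_scores, sim$z1, sim$z2, sim$n1, sim$n2, sim$M,
                  n_blocks = min(200, sim$M %/% 50))
  })
  stage("bidirectional", 2L, function(seed) {
    dat <- load_or_sim_pair(seed)
    bidirectional_mr(dat$exposure, dat$outcome,
                     p_threshold = th$p, r2_threshold = th$r2,
                     window_kb = th$window_kb, seed = seed)
  })
  stage("uvmr", 3L, function(seed) {
    dat <- load_or_sim_pair(seed)
    pairs <- harmonize(dat$exposure, dat$outcome)
    inst <- select_instruments(pairs, p_threshold = th$p,
                               r2_threshold = th$r2,
                               window_kb = th$window_kb, f_min = th$f_min)
    list(panel = mr_panel(inst, seed = seed),
         loo = leave_one_out(inst), mean_F = attr(inst, "mean_F"))
  })
  stage("mvmr", 4L, function(seed) {
    d1 <- simulate_two_sample(k = sp$k, theta = sp$theta, n_x = sp$n,
                              n_y = sp$n, seed = seed)
    d2 <- simulate_two_sample(k = sp$k, theta = 0, n_x = sp$n, n_y = sp$n,
                              seed = seed + 100L)
    p1 <- harmonize(d1$exposure, d1$outcome)
    p2 <- harmonize(d2$exposure, d2$outcome)
    p2$snp <- p1$snp  # shared instrument panel across exposures
    mv <- mv_instrument_set(list(primary = p1, covariate = p2))
    list(fit = mv_ivw(mv), strength = mv_instrument_strength(mv))
  })
  stage("smr_coloc", 5L, function(seed) {
    simH4 <- simulate_region_pair(m = sp$coloc_m, scenario = "H4",
                                  seed = seed)
    cl <- coloc_abf(simH4$region)
    rg <- cis_region("probe_1", simH4$region$snp,
                     simH4$region$beta1, simH4$region$se1,
                     simH4$region$beta2, simH4$region$se2, ld = simH4$ld)
    list(smr = smr_screen(list(rg), fdr = th$fdr, seed = seed),
         coloc = cl)
  })
  stage("pqtl_coloc", 6L, function(seed) {
    sim <- simulate_region_pair(m = sp$coloc_m, scenario = "H4",
                                z_causal = 7, seed = seed)
    coloc_abf(sim$region)
  })
  stage("phewas", 7L, function(seed) {
    sim <- simulate_two_sample(k = 5, theta = 0.26, n_x = sp$n, n_y = sp$n,
                               seed = seed)
    outcomes <- c(list(true_outcome = sim$outcome),
                  lapply(seq_len(sp$n_phewas_null), function(i) {
                    simulate_two_sample(k = 5, theta = 0, n_x = sp$n,
                                        n_y = sp$n, seed = seed + i)$outcome
                  }))
    names(outcomes) <- c("true_outcome",
                         sprintf("null_%02d", seq_len(sp$n_phewas_null)))
    phewas_screen(sim$exposure, outcomes, fdr = th$fdr)
  })
  stage("mediation", 8L, function(seed) {
    if (!is.null(cfg$mediator_file)) {
      if (!file.exists(cfg$mediator_file))
        stop("mediator file not found: ", cfg$mediator_file, call. = FALSE)
      two_step_mediation(read_sumstats(cfg$exposure_file),
                         read_sumstats(cfg$mediator_file),
                         read_sumstats(cfg$outcome_file),
                         p_threshold = th$p, r2_threshold = th$r2,
                         window_kb = th$window_kb, seed = seed)
    } else {
      md <- sp$mediation
      sim <- simulate_mediation_chain(a = md$a, b = md$b,
                                      direct = md$direct, n = sp$n,
                                      seed = seed)
      run_mediation_on_chain(sim, seed = seed)
    }
  })
  structure(list(stages = report, errors = errors,
                 meta = list(seed = seed0, thresholds = th,
                             stage_seeds = seed0 + seq_len(8L),
                             package_version =
                               as.character(utils::packageVersion("mrchain")),
                             timestamp = format(Sys.time(), "%Y-%m-%d"))),
            class = "mr_report")
}

#' Estimate the mediation decomposition from a simulated chain
#'
#' Applies IVW to each leg of a [simulate_mediation_chain()] output and
#' decomposes with [mediate()].
#'
#' @param chain output of [simulate_mediation_chain()].
#' @param p_threshold instrument p threshold (default 5e-8).
#' @param seed seed for stochastic components.
#' @return a `mediation_result`.
#' @export
run_mediation_on_chain <- function(chain, p_threshold = 5e-8, seed = 1L) {
  leg <- function(d, label) {
    pairs <- harmonize(d$exposure, d$outcome)
    inst <- suppressWarnings(
      select_instruments(pairs, p_threshold = p_threshold))
    if (nrow(inst) == 0)
      stop("zero instruments in mediation step: ", label, call. = FALSE)
    if (nrow(inst) == 1) wald_ratio(inst) else mr_ivw(inst, "random")
  }
  ea <- leg(chain$exposure_mediator, "exposure->mediator")
  eb <- leg(chain$mediator_outcome, "mediator->outcome")
  ec <- leg(chain$exposure_outcome, "exposure->outcome")
  mediate(ea$beta, ea$se, eb$beta, eb$se, ec$beta, ec$se)
}

#' @export
print.mr_report <- function(x, ...) {
  cat("mrchain pipeline report (seed", x$meta$seed, ")\n")
  cat("stages completed:", paste(names(x$stages), collapse = ", "), "\n")
  if (length(x$errors))
    cat("stages failed:", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}
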