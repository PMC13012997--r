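#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# The generators stand in for the consortium downloads the real study
# uses (exposure and outcome GWAS, a mediator pQTL trait, LD scores):
# an exposure -> outcome chain with 40 instruments and causal effect
# 0.15, plus the mediation chain a = 0.4, b = 0.25, direct = 0.05.
suppressPackageStartupMessages(library(mrchain))

args <- commandArgs(trailingOnly = TRUE)
seed <- as.integer(if (length(args) >= 2 && args[1] == "--seed") args[2] else 1)
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

two <- simulate_two_sample(k = 40, theta = 0.15, n_x = 200000,
                           n_y = 200000, seed = seed)
write_sumstats(two$exposure, "results/data/exposure_gwas.tsv")
write_sumstats(two$outcome, "results/data/outcome_gwas.tsv")

chain <- simulate_mediation_chain(a = 0.4, b = 0.25, direct = 0.05,
                                  seed = seed + 1)
write_sumstats(chain$exposure_mediator$outcome,
               "results/data/mediator_gwas.tsv")
write_sumstats(chain$mediator_outcome$exposure,
               "results/data/mediator_instruments.tsv")
write_sumstats(chain$mediator_outcome$outcome,
               "results/data/outcome_for_mediator.tsv")

cat("Simulated GWAS written under results/data/:",
    "40 exposure instruments (theta = 0.15),",
    "mediation chain with true proportion mediated 2/3.\n")
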