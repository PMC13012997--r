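#!/usr/bin/env Rscript
# Stage 6: phenome-wide MR screen of the mediator protein.
#
# The mediator's cis instruments are tested against one truly affected
# outcome and 100 null phenotypes; the screen should rank the true
# outcome first and pass it alone at FDR < 0.05 (trait specificity).
suppressPackageStartupMessages(library(mrchain))

args <- commandArgs(trailingOnly = TRUE)
seed <- as.integer(if (length(args) >= 2 && args[1] == "--seed") args[2] else 1)
dir.create("results", showWarnings = FALSE)

sim <- simulate_two_sample(k = 5, theta = 0.26, seed = seed)
nulls <- lapply(1:100, function(i)
  simulate_two_sample(k = 5, theta = 0, seed = seed + 200 + i)$outcome)
names(nulls) <- sprintf("phenotype_%03d", 1:100)
scr <- phewas_screen(sim$exposure, c(list(target_disease = sim$outcome),
                                     nulls))
write.table(scr, "results/06_phewas.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
cat(sprintf(
  "PheWAS over %d outcomes: top hit '%s' (OR %.3f, q = %.2e); %d outcome(s) at FDR < 0.05.\n",
  nrow(scr), scr$outcome[1], exp(scr$beta[1]), scr$q_value[1],
  sum(scr$significant)))
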