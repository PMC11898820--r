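#!/usr/bin/env Rscript
# Step 4 — breed comparison and marker-trait association scan.
#
# Runs on the simulated study from step 1 (rerun it if results/study is
# absent). The breed summary reproduces the published table's shape:
# per-breed mean ± SD with compact letters per trait. The association
# scan fits trait ~ genotype for all 7 x 8 locus-trait pairs, pooled
# across breeds. Because the generator couples both trait baselines and
# genotype frequencies to breed, breed confounds the pooled scan — the
# scan's significances on this study illustrate report structure, not
# calibrated genotype effects (see step 5 for the calibrated null).

suppressPackageStartupMessages(library(npyassoc))

if (!file.exists("results/study/genotypes.tsv"))
  source("analysis/01_simulate_study.R")

res <- run_association("results/study/genotypes.tsv",
                       "results/study/traits.tsv",
                       "results/association")

cat("breed summary (mean ± SD, shared letters = not separated):\n")
print(format_breed_report(res$breed_summary), right = FALSE)

scan <- res$scan
cells <- unique(scan[scan$testable, c("locus_id", "trait", "p_value")])
cat(sprintf("\nassociation scan: %d locus x trait cells, %d with p < 0.05\n",
            nrow(cells), sum(cells$p_value < 0.05)))
cat("reports in results/association/\n")
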