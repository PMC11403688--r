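#!/usr/bin/env Rscript
# Stage 1: generate the synthetic glioma cohort.
#
# 450 samples (150 per glioma type) x 120 genes. Twelve connected
# 5-gene blocks (partial correlation 0.2) rotate through the types:
# every fourth block is active for all three, the rest are type-
# exclusive. 30% of gene columns are exponentially distorted, 15% of
# samples carry discordant 2016-vs-2021 labels, and survival follows a
# 5-gene sparse Cox model with ~30% censoring.

suppressPackageStartupMessages(library(glionet))

out <- file.path("results", "data")
cfg <- sim_config(seed = 1)
cohort <- simulate_cohort(cfg)
write_cohort(cohort, out)

print(cfg)
print(cohort)
cat("\nTrue prognostic genes:",
    paste(cohort$truth$prognostic_genes, collapse = ", "), "\n")
cat("Wrote expression.tsv, clinical.tsv, truth.json, config.yaml to",
    out, "\n")
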