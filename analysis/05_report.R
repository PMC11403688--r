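#!/usr/bin/env Rscript
# Stage 5: cross-case stability, signature overlap, and the run summary.
#
# Checks how consistently samples keep their risk label across the three
# case datasets, how much of the case-1 Cox signature reappears in cases
# 2 and 3, and collates the per-case results into a single JSON report.

suppressPackageStartupMessages(library(glionet))

clinical <- read_clinical_tsv(file.path("results", "data", "clinical.tsv"))
summary <- list()

for (sc in c("2016", "2021")) {
  groups <- list()
  models <- list()
  for (cs in 1:3) {
    base <- file.path("results", sprintf("%s_case%d", sc, cs))
    strat <- read.delim(paste0(base, "_strat.tsv"))
    groups[[cs]] <- strat$group
    models[[cs]] <- jsonlite::read_json(paste0(base, "_model.json"),
                                        simplifyVector = TRUE)
  }
  stab <- stability_overlap(groups)
  a1 <- models[[1]]$active_set
  a23 <- union(models[[2]]$active_set, models[[3]]$active_set)
  overlap_pct <- if (length(a1))
    100 * length(intersect(a1, a23)) / length(a1) else 0

  cat(sprintf("\n-- scheme %s --\n", sc))
  cat(sprintf("risk-label stability across cases: LR %s, HR %s, overall %s\n",
              format_pct(100 * stab$per_label[["LR"]]),
              format_pct(100 * stab$per_label[["HR"]]),
              format_pct(100 * stab$overall)))
  cat(sprintf("case-1 signature: %d genes, %s rediscovered in case 2/3\n",
              length(a1), format_pct(overlap_pct)))
  for (cs in 1:3)
    cat(sprintf("  case %d: %d active genes, log-rank p = %.3g (%s threshold)\n",
                cs, length(models[[cs]]$active_set), models[[cs]]$logrank_p,
                models[[cs]]$threshold_method))

  summary[[sc]] <- list(
    stability = list(per_label = as.list(stab$per_label),
                     overall = stab$overall),
    case1_signature_overlap_pct = overlap_pct,
    cases = setNames(models, paste0("case", 1:3)))
}

jsonlite::write_json(summary, file.path("results", "analysis_summary.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("\nWrote results/analysis_summary.json\n")
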