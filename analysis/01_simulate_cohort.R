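#!/usr/bin/env Rscript

# Stage 1 — generate the synthetic study cohort.
#
# 132 treatment-naive men with metabolic syndrome, 917 annotated
# metabolites with left-censored missingness, and glycerol clamp tracer
# time courses for a 39-subject lipolysis subset. Ground truth (IR
# labels, planted metabolite effects, true suppression) is written
# alongside so later stages can be checked against it.

library(metsynflux)

seed <- 20260922L
out <- "results/cohort"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

config <- sim_config(seed = seed)
cohort <- gen_clinical(config)
table_raw <- gen_metabolites(cohort$records, cohort$truth, config)

set.seed(seed + 3L)
clamp_idx <- sort(sample.int(nrow(cohort$records), 39))
clamp_truth <- cohort$truth
clamp_truth$true_suppression <- cohort$truth$true_suppression[clamp_idx]
series <- gen_clamp(cohort$records[clamp_idx, ], clamp_truth, config)

write_clinical_csv(cohort$records, file.path(out, "clinical.csv"))
write_metabolite_tsv(table_raw, file.path(out, "abundances.tsv"),
                     file.path(out, "annotations.tsv"))
write_clamp_csv(series, file.path(out, "clamp.csv"))
write_truth_json(cohort$truth, file.path(out, "truth.json"))

cat(sprintf(
  "cohort: %d subjects (%d IR), %d metabolites (%.1f%% cells censored), clamp n = %d\n",
  nrow(cohort$records), sum(cohort$truth$is_ir), ncol(table_raw$abundances),
  100 * mean(is.na(table_raw$abundances)), length(series)
))
cat(sprintf("median BMI %.1f kg/m2, median fasting insulin %.0f pmol/L\n",
            median(cohort$records$bmi), median(cohort$records$fasting_insulin)))
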