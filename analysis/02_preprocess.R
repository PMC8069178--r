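#!/usr/bin/env Rscript

# Stage 2 — normalize and impute the metabolite panel.
#
# Median rescaling (every metabolite's non-missing median becomes 1),
# then half-minimum imputation of left-censored cells, in that pinned
# order.

library(metsynflux)

tab <- read_metabolite_tsv("results/cohort/abundances.tsv",
                           "results/cohort/annotations.tsv")
pp <- preprocess_table(tab)
write_metabolite_tsv(pp, "results/cohort/abundances_preprocessed.tsv",
                     "results/cohort/annotations.tsv")

meds <- apply(pp$abundances, 2, median)
cat(sprintf(
  "preprocessed %d x %d; %d cells imputed; post-imputation column medians in [%.3f, 1]\n",
  nrow(pp$abundances), ncol(pp$abundances), sum(is.na(tab$abundances)),
  min(meds)
))
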