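#!/usr/bin/env Rscript

# Stage 4 — Framingham 10-year general CVD risk and IR classification.

library(metsynflux)

clinical <- read_clinical_csv("results/cohort/clinical.csv")
risk <- framingham_risk(clinical)
groups <- dichotomize_framingham(risk, cutoff = 12)
ir <- classify_ir(clinical$rd)

out <- data.frame(subject_id = clinical$subject_id,
                  framingham_pct = risk, framingham_group = groups,
                  ir_status = ir)
write.csv(out, "results/framingham.csv", row.names = FALSE)

cat(sprintf(
  "Framingham: median %.1f%%, %d high / %d low at the 12%% cutoff\n",
  median(risk), sum(groups == "high"), sum(groups == "low")
))
cat(sprintf("insulin resistance (Rd < 37.3): %d IR / %d N-IR\n",
            sum(ir == "IR"), sum(ir == "N-IR")))
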