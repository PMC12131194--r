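#!/usr/bin/env Rscript
# The in silico drug trial: applies the packaged pore-block profiles of
# compound 6f (1, 10, 100 uM) to the calibrated AF population.
# Single-cell arm: steady-state APD90 at 2 Hz. Cable arm: ERP (10 S1 at
# 500 ms, S2 binary search at 1 ms) and 1:1 propagation at 6 Hz, on the
# CV-calibrated cable. Reads the outputs of 03 and 04.

library(afsilico)
dir.create("results", showWarnings = FALSE)

acc <- read.csv("results/population_accepted.csv")
scal <- as.matrix(acc[, colnames(lhs_sample(2, 8))])
cable_cal <- jsonlite::read_json("results/cable_calibration.json",
                                 simplifyVector = TRUE)
cfg <- cable_config(diff_coef = cable_cal$AF$diff_coef)

## single-cell APD arm (full population)
cat(sprintf("APD arm: %d models x {0, 1, 10, 100} uM at 2 Hz ...\n",
            nrow(scal)))
apd <- run_apd_trial(scal, rates = 2, max_beats = 40)
s_apd <- summarize_trial(apd, "apd90_ms")
print(s_apd)
cat(sprintf("Control %.1f +- %.1f ms vs 100 uM %.1f +- %.1f ms at 2 Hz\n",
            s_apd$mean[s_apd$concentration_uM == 0],
            s_apd$sd[s_apd$concentration_uM == 0],
            s_apd$mean[s_apd$concentration_uM == 100],
            s_apd$sd[s_apd$concentration_uM == 100]))
write.csv(apd, "results/trial_apd.csv", row.names = FALSE)

## cable arm on a 10-model subset
set.seed(99)
idx <- sort(sample(nrow(scal), min(10, nrow(scal))))
cat(sprintf("ERP arm: %d models on the CV-calibrated cable ...\n",
            length(idx)))
erp <- run_erp_trial(scal[idx, , drop = FALSE], config = cfg, rates = 6)
s_erp <- summarize_trial(erp$erp, "d_erp_ms", by = "concentration_uM")
print(s_erp)
fr <- propagation_fractions(erp$propagation)
print(fr)
write.csv(erp$erp, "results/trial_erp.csv", row.names = FALSE)
write.csv(erp$propagation, "results/trial_propagation.csv",
          row.names = FALSE)

jsonlite::write_json(
  list(apd_2hz = s_apd, d_erp = s_erp, propagation_6hz = fr),
  "results/trial_summary.json", auto_unbox = TRUE, digits = NA)
cat("Wrote results/trial_apd.csv, results/trial_erp.csv,",
    "results/trial_propagation.csv, results/trial_summary.json\n")
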