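#!/usr/bin/env Rscript
# Builds the calibrated AF population of atrial cardiomyocyte models:
# 100 Latin Hypercube scaling vectors (+-50% on 8 conductances) over the
# AF-remodeled CRN+IK2P baseline, calibrated against the packaged AF
# biomarker ranges at 1 Hz, subsampled to at most 45 members.

library(afsilico)
dir.create("results", showWarnings = FALSE)

pop <- gen_population_fixture(n_target = 45, phenotype = "AF", seed = 7,
                              n_lhs = 100)
calib <- pop$calibration
cat(sprintf("%d of 100 sampled models passed calibration; keeping %d\n",
            sum(calib$accepted), nrow(pop$scalings)))
print(summary(pop$biomarkers))
rej <- table(calib$audit$rejection_reason[!calib$accepted])
cat("Rejection reasons:\n"); print(rej)

write_population_csv(calib, "results/population_audit.csv")
write.csv(cbind(data.frame(model_id = pop$model_ids),
                as.data.frame(pop$scalings), pop$biomarkers),
          "results/population_accepted.csv", row.names = FALSE)
jsonlite::write_json(list(seed = pop$seed, phenotype = pop$phenotype,
                          n_accepted = sum(calib$accepted),
                          n_kept = nrow(pop$scalings)),
                     "results/population_meta.json",
                     auto_unbox = TRUE, digits = NA)
cat("Wrote results/population_audit.csv, results/population_accepted.csv\n")
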