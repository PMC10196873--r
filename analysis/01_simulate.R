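#!/usr/bin/env Rscript
# Step 1 — simulate a multi-facility inpatient cohort.
#
# Generates the default study cohort (20 facilities, 20 000 admissions,
# covariate-dependent NV-HAP onset from day 3, doubled post-onset death
# hazard, halved post-onset discharge hazard) and writes the four EHR
# tables plus the ground-truth file. Everything downstream reads these CSVs.

library(nvhap)

out_dir <- "results/cohort"
cfg <- sim_config(n_hospitalizations = 20000, n_facilities = 20,
                  seed = 20230518)
g <- generate_cohort(cfg)
write_ehr_tables(g$dataset, out_dir)
data.table::fwrite(g$truth, file.path(out_dir, "truth.csv"), na = "")

cat("cohort written to", out_dir, "\n")
print(g$dataset)
cat(sprintf("true NV-HAP events: %d (%.2f per 100 admissions)\n",
            sum(!is.na(g$truth$true_nvhap_day)),
            100 * mean(!is.na(g$truth$true_nvhap_day))))
cat(sprintf("in-hospital deaths: %d (%.1f%%)\n",
            sum(g$dataset$hospitalizations$disposition == "death"),
            100 * mean(g$dataset$hospitalizations$disposition == "death")))
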