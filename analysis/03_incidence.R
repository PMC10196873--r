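#!/usr/bin/env Rscript
# Step 3 — descriptive incidence reporting.
#
# Overall NV-HAP rates per 100 admissions and per 1000 patient-days,
# facility-level variation (the caterpillar table, plus a plot when ggplot2
# is available), and the disposition / length-of-stay contrast between
# surveillance-positive and all admissions.

library(nvhap)

ds <- read_ehr_tables("results/cohort")
events <- data.table::fread("results/events.csv", na.strings = "")
hosp <- ds$hospitalizations

overall <- rbind(
  rate(nrow(events), nrow(hosp), "per100"),
  rate(nrow(events), sum(hosp$los), "per1000"))
data.table::fwrite(overall, "results/incidence.csv")
cat(sprintf("NV-HAP incidence: %.2f per 100 admissions (95%% CI %.2f-%.2f)\n",
            overall$rate[1], overall$ci_low[1], overall$ci_high[1]))
cat(sprintf("                  %.2f per 1000 patient-days (95%% CI %.2f-%.2f)\n",
            overall$rate[2], overall$ci_low[2], overall$ci_high[2]))

fi <- facility_incidence(events, hosp)
data.table::fwrite(fi$rates, "results/facility_rates.csv")
cat(sprintf("facility rates: median %.2f per 100 (IQR %.2f-%.2f)\n",
            fi$median, fi$iqr[1], fi$iqr[2]))
if (requireNamespace("ggplot2", quietly = TRUE)) {
  p <- plot_facility_rates(fi)
  ggplot2::ggsave("results/facility_rates.png", p, width = 7, height = 4,
                  dpi = 150)
}

out <- outcome_table(events, hosp)
data.table::fwrite(out$dispositions, "results/outcomes.csv")
nv <- out$dispositions[group == "nvhap"]
cat(sprintf("NV-HAP admissions: %.1f%% died, %.1f%% hospice, %.1f%% home\n",
            nv[disposition == "death", pct], nv[disposition == "hospice", pct],
            nv[disposition == "home", pct]))
cat(sprintf("median LOS: %d d (NV-HAP) vs %d d (all)\n",
            out$los[group == "nvhap", median], out$los[group == "all", median]))
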