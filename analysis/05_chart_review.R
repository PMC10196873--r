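#!/usr/bin/env Rscript
# Step 5 — chart-review validation statistics.
#
# Simulates a dual-physician review of 250 surveillance-positive cases
# (synthetic judgments with a shared latent truth, so agreement is
# imperfect but above chance) and computes the validation statistics the
# package provides: positive predictive value against several reference
# standards and interrater agreement (simple agreement + Cohen kappa).

library(nvhap)

set.seed(20230521)
n <- 250
latent <- runif(n) < 0.80                  # latent "truly pneumonia"
judge <- function(truth, sens = 0.9, spec = 0.7)
  ifelse(truth, runif(n) < sens, runif(n) < 1 - spec)
reviews <- data.frame(
  case_id = sprintf("C%03d", seq_len(n)),
  reviewer1 = judge(latent),
  reviewer2 = judge(latent),
  clinician_documented = judge(latent, sens = 0.85, spec = 0.75),
  nhsn_met = judge(latent, sens = 0.75, spec = 0.8))
data.table::fwrite(reviews, "results/reviews_synthetic.csv")

any_pos <- with(reviews, reviewer1 | reviewer2 | clinician_documented)
p1 <- ppv(sum(any_pos), n)
p2 <- ppv(sum(reviews$nhsn_met), n)
cat(sprintf("PPV vs any reviewer/clinician: %d%% (95%% CI %.0f-%.0f%%)\n",
            p1$ppv_pct, 100 * p1$ci_low, 100 * p1$ci_high))
cat(sprintf("PPV vs NHSN criteria:          %d%% (95%% CI %.0f-%.0f%%)\n",
            p2$ppv_pct, 100 * p2$ci_low, 100 * p2$ci_high))

k <- cohen_kappa(reviews$reviewer1, reviews$reviewer2)
cat(sprintf("interrater: simple agreement %.0f%%, Cohen kappa %.2f\n",
            100 * k$agreement, k$kappa))
stats <- data.frame(metric = c("ppv_any", "ppv_nhsn", "agreement", "kappa"),
                    value = c(p1$ppv, p2$ppv, k$agreement, k$kappa))
data.table::fwrite(stats, "results/review_stats.csv")
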