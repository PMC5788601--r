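#!/usr/bin/env Rscript
# Overall survival in the DM group: Kaplan-Meier by THYT1 status,
# log-rank test, and univariate plus covariate-adjusted Cox models for
# each signature feature (the layout of the study's survival table).

source("analysis/00_config.R")

flags <- read.delim(file.path(RESULTS_DIR, "signature.tsv"))
samples <- read.delim(file.path(RESULTS_DIR, "samples.tsv"))
dm <- cbind(samples,
            flags[match(samples$sample, flags$sample),
                  c("chr1q_dup", "tert_dup", "tert_mut", "thyt1_positive")])
dm <- dm[dm$group == "dm", ]
for (f in c("chr1q_dup", "tert_dup", "tert_mut", "thyt1_positive")) {
  dm[[f]] <- as.logical(dm[[f]])
}
message(sprintf("DM group: n = %d, %d deaths", nrow(dm), sum(dm$event)))

km_pos <- km_estimate(dm[dm$thyt1_positive, ])
km_neg <- km_estimate(dm[!dm$thyt1_positive, ])
tsv(cbind(thyt1 = "positive", km_pos), "km_thyt1_positive.tsv")
tsv(cbind(thyt1 = "negative", km_neg), "km_thyt1_negative.tsv")

lr <- logrank_test(dm, dm$thyt1_positive)
message(sprintf("log-rank THYT1 +/-: chi2 = %.2f, p = %.4g",
                lr$statistic, lr$p))

surv <- survival_report(dm)
tsv(surv, "survival.tsv")
for (i in seq_len(nrow(surv))) {
  r <- surv[i, ]
  message(sprintf("%-15s %-12s HR %5.2f (95%% CI %5.2f-%5.2f)  p = %.3g",
                  r$feature, r$model, r$hr, r$lower, r$upper, r$p))
}
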