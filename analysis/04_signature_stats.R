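#!/usr/bin/env Rscript
# Per-feature association statistics (counts, percentages, Fisher p)
# between the DM and control groups, in the layout of the study's
# feature tables, plus MSI classification of every sample.

source("analysis/00_config.R")

flags <- read.delim(file.path(RESULTS_DIR, "signature.tsv"))
samples <- read.delim(file.path(RESULTS_DIR, "samples.tsv"))

for (f in c("chr1q_dup", "tert_dup", "chr9q_loss", "tert_mut", "braf",
            "thyt1_positive")) {
  flags[[f]] <- as.logical(flags[[f]])
}
report <- contingency_report(
  flags, c("chr1q_dup", "tert_dup", "tert_mut", "thyt1_positive",
           "chr9q_loss", "braf"))
tsv(report, "contingency.tsv")
for (i in seq_len(nrow(report))) {
  r <- report[i, ]
  message(sprintf("%-15s DM %2d/%2d (%4.1f%%)  control %2d/%2d (%4.1f%%)  p = %.3g",
                  r$feature, r$pos_case, r$n_case, r$pct_case,
                  r$pos_control, r$n_control, r$pct_control, r$fisher_p))
}

msi <- table(flags$msi, flags$group)
message("MSI status by group:")
print(msi)
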