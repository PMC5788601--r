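# Shared configuration for the analysis drivers: the desk-scale study
# emulation (300 Mb mini-genome, 10 kb probe spacing, 34 DM + 61
# control samples at the published alteration frequencies).
library(thyt1)

ANALYSIS_SEED <- 20260924L
RESULTS_DIR <- "results/analysis"

analysis_config <- function() {
  pipeline_config(seed = ANALYSIS_SEED,
                  cohort = cohort_config(seed = ANALYSIS_SEED))
}

dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)

tsv <- function(df, name) {
  utils::write.table(df, file.path(RESULTS_DIR, name), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  message("  wrote ", file.path(RESULTS_DIR, name))
}
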