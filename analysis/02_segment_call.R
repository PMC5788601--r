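#!/usr/bin/env Rscript
# Segment every profile (wave correction + HMM), call allelic imbalance
# and LOH, classify segments into the copy-number event classes, and
# derive per-sample burden and alteration flags. The cohort is
# regenerated deterministically from the shared seed, so this driver is
# self-contained.

source("analysis/00_config.R")

cfg <- analysis_config()
genome <- build_genome_model(cfg$genome)
grid <- make_probe_grid(genome, cfg$probe_spacing, seed = cfg$seed)
cohort <- simulate_cohort(cfg$cohort, grid)

message("segmenting ", length(cohort$profiles), " profiles")
calltracks <- lapply(cohort$profiles, function(pr) {
  pr <- wave_correct(pr)
  classify_segments(call_allelic(pr, segment_lrr(pr, cfg$segmentation),
                                 cfg$loh),
                    cfg$thresholds)
})

write_seg(lapply(calltracks, function(tr)
  tr[c("chrom", "start", "end", "n_probes", "mean_lrr")]),
  file.path(RESULTS_DIR, "calls.seg"))
message("  wrote ", file.path(RESULTS_DIR, "calls.seg"))

burden_tbl <- do.call(rbind, lapply(names(calltracks), function(id) {
  b <- burden(calltracks[[id]], genome)
  b$sample <- id
  b$group <- cohort$samples$group[match(id, cohort$samples$sample)]
  b
}))
tsv(burden_tbl, "burden.tsv")

flags <- derive_flags(calltracks, cohort$samples, cohort$mutations,
                      genome, cfg)
tsv(flags, "signature.tsv")

tot <- burden_tbl[burden_tbl$class == "total", ]
message(sprintf("%% genome altered: DM %.2f +/- %.2f, control %.2f +/- %.2f",
                mean(tot$relative_length_pct[tot$group == "dm"]),
                sd(tot$relative_length_pct[tot$group == "dm"]),
                mean(tot$relative_length_pct[tot$group == "control"]),
                sd(tot$relative_length_pct[tot$group == "control"])))
message(sprintf("THYT1 positive: %d/%d DM, %d/%d control",
                sum(flags$thyt1_positive[flags$group == "dm"]),
                sum(flags$group == "dm"),
                sum(flags$thyt1_positive[flags$group == "control"]),
                sum(flags$group == "control")))
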