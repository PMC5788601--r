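#!/usr/bin/env Rscript
# Case-control differential-region analysis: per-probe CNA frequencies
# by group, Fisher tests with BH adjustment, the study's frequency and
# difference gates, and merged differential regions for gains and
# losses separately. Reads the call tracks written by
# analysis/02_segment_call.R.

source("analysis/00_config.R")

cfg <- analysis_config()
genome <- build_genome_model(cfg$genome)
grid <- make_probe_grid(genome, cfg$probe_spacing, seed = cfg$seed)

calls <- read_seg(file.path(RESULTS_DIR, "calls.seg"), min_probes = 1)
samples <- read.delim(file.path(RESULTS_DIR, "samples.tsv"))
calltracks <- lapply(calls, classify_segments, thresholds = cfg$thresholds)
groups <- samples$group[match(names(calltracks), samples$sample)]
by_group <- split(calltracks, groups)[c("dm", "control")]

regions <- do.call(rbind, lapply(c("gain", "loss"), function(dir) {
  res <- compare_groups(frequency_tracks(by_group, grid, dir),
                        cfg$comparison)
  message(dir, ": ", nrow(res$regions), " differential region(s)")
  res$regions
}))
tsv(regions, "regions.tsv")
if (nrow(regions)) {
  regions$name <- paste0(regions$direction, "_", seq_len(nrow(regions)))
  write_bed(regions[order(regions$chrom, regions$start), ],
            file.path(RESULTS_DIR, "regions.bed"))
  message("  wrote ", file.path(RESULTS_DIR, "regions.bed"))
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    message(sprintf(
      "  %s chr%s:%.1f-%.1f Mb  DM %.0f%% vs control %.0f%% (adj p <= %.2g)",
      r$direction, r$chrom, r$start / 1e6, r$end / 1e6,
      100 * r$freq_a, 100 * r$freq_b, r$min_adj_p))
  }
}
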