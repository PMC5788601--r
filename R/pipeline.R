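#' Pipeline configuration
#'
#' Aggregates every stage's parameters; all thresholds default to the
#' study's values. The configuration round-trips through YAML via
#' [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param genome Genome config list (default [desk_genome_config()]).
#' @param probe_spacing Mean probe spacing in bp.
#' @param cohort A [cohort_config()].
#' @param segmentation A [seg_params()].
#' @param loh A [loh_params()].
#' @param thresholds A [calling_thresholds()].
#' @param comparison A [comparison_params()].
#' @param arm_coverage_fraction Arm-event coverage rule.
#' @param msi_high_fraction MSI-H threshold.
#' @param min_reads,min_fraction Variant-support filter settings.
#' @param seed Global seed; seeds every stage, including the cohort
#'   generator (overriding the seed inside `cohort`), so one value
#'   determines the whole run.
#' @param verbose Emit progress messages.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(genome = desk_genome_config(),
                            probe_spacing = 10e3,
                            cohort = cohort_config(),
                            segmentation = seg_params(),
                            loh = loh_params(),
                            thresholds = calling_thresholds(),
                            comparison = comparison_params(),
                            arm_coverage_fraction = 0.5,
                            msi_high_fraction = 0.30,
                            min_reads = 10L, min_fraction = 0.05,
                            seed = 1L, verbose = FALSE) {
  cohort$seed <- as.integer(seed)
  structure(list(genome = genome, probe_spacing = probe_spacing,
                 cohort = cohort, segmentation = segmentation, loh = loh,
                 thresholds = thresholds, comparison = comparison,
                 arm_coverage_fraction = arm_coverage_fraction,
                 msi_high_fraction = msi_high_fraction,
                 min_reads = as.integer(min_reads),
                 min_fraction = min_fraction,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML path.
#' @export
write_pipeline_config <- function(config, path) {
  # yaml drops the names of named atomic vectors; promote them to maps
  to_plain <- function(x) {
    if (is.list(x)) {
      lapply(unclass(x), to_plain)
    } else if (!is.null(names(x)) && length(x) > 1L) {
      as.list(x)
    } else {
      unname(x)
    }
  }
  yaml::write_yaml(to_plain(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  relist <- function(x, cls) { class(x) <- cls; x }
  nm <- function(x) if (is.list(x)) unlist(x) else x
  cc <- raw$cohort
  pipeline_config(
    genome = raw$genome, probe_spacing = raw$probe_spacing,
    cohort = cohort_config(
      n_dm = cc$n_dm, n_control = cc$n_control,
      p_chr1q_dup = nm(cc$p_chr1q_dup), p_tert_dup = nm(cc$p_tert_dup),
      p_tert_mut = nm(cc$p_tert_mut), p_braf = nm(cc$p_braf),
      p_chr9q_given_chr1q = cc$p_chr9q_given_chr1q,
      p_chr9q_leak = cc$p_chr9q_leak, p_c228t_share = nm(cc$p_c228t_share),
      p_msi_low = nm(cc$p_msi_low), p_msi_high = nm(cc$p_msi_high),
      bg_events = nm(cc$bg_events),
      baseline_hazard = cc$baseline_hazard,
      hazard_ratio = cc$hazard_ratio, censor_rate = cc$censor_rate,
      max_followup = cc$max_followup, msi_markers = cc$msi_markers,
      noise = noise_model(cc$noise$lrr_sd, cc$noise$baf_sd,
                          cc$noise$het_fraction, nm(cc$noise$shifts)),
      seed = cc$seed),
    segmentation = relist(raw$segmentation, "seg_params"),
    loh = relist(raw$loh, "loh_params"),
    thresholds = relist(raw$thresholds, "calling_thresholds"),
    comparison = relist(raw$comparison, "comparison_params"),
    arm_coverage_fraction = raw$arm_coverage_fraction,
    msi_high_fraction = raw$msi_high_fraction,
    min_reads = raw$min_reads, min_fraction = raw$min_fraction,
    seed = raw$seed, verbose = raw$verbose)
}

#' Derive per-sample alteration flags from call tracks and mutations
#'
#' Arm and locus flags come from the classified segments (Chr1q
#' duplication and Chr9q loss by arm coverage, TERT duplication by
#' locus overlap); the TERT promoter mutation and BRAF flags from the
#' support-filtered mutation table; MSI status from the marker panel;
#' THYT1 from [score_thyt1()].
#'
#' @param calltracks Named list of classified call tracks.
#' @param samples Sample sheet (for group / MSI columns).
#' @param mutations Mutation table.
#' @param genome A `genome_model`.
#' @param config A [pipeline_config()].
#' @return Data.frame of per-sample flags and THYT1 status.
#' @export
derive_flags <- function(calltracks, samples, mutations, genome,
                         config = pipeline_config()) {
  kept <- filter_variants(mutations, config$min_reads, config$min_fraction)
  rows <- lapply(seq_len(nrow(samples)), function(i) {
    id <- samples$sample[i]
    tr <- calltracks[[id]]
    chr1q <- arm_flag(tr, genome, "1q", .gain_classes,
                      config$arm_coverage_fraction)
    tertd <- locus_flag(tr, genome, "TERT", .gain_classes)
    chr9q <- arm_flag(tr, genome, "9q", .loss_classes,
                      config$arm_coverage_fraction)
    mym <- kept[kept$sample == id, , drop = FALSE]
    tertm <- any(mym$gene == "TERT_promoter")
    braf <- any(mym$gene == "BRAF" & mym$variant == "V600E")
    sc <- score_thyt1(chr1q, tertd, tertm)
    data.frame(sample = id, group = samples$group[i],
               chr1q_dup = chr1q, tert_dup = tertd, chr9q_loss = chr9q,
               tert_mut = tertm, braf = braf,
               thyt1_status = sc$status,
               thyt1_positive = sc$status == "positive",
               n_thyt1_alterations = sc$n_alterations,
               msi = classify_msi(samples$msi_unstable[i],
                                  samples$msi_markers[i],
                                  config$msi_high_fraction),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full simulate-segment-call-compare-score-survive pipeline
#'
#' Deterministic under the configured seed. Writes, under `out_dir`:
#' the cohort tables, per-sample calls as SEG, the burden table, the
#' differential regions (TSV + BED), the per-sample signature matrix,
#' the contingency report, the survival report, and a run log with the
#' effective parameters.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return List with `cohort`, `calltracks`, `burden`, `flags`,
#'   `regions` (gain and loss), `contingency`, `survival`, `km`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  vlog <- function(...) if (config$verbose) message("[thyt1] ", ...)
  genome <- build_genome_model(config$genome)
  grid <- make_probe_grid(genome, config$probe_spacing, seed = config$seed)
  vlog("simulating cohort (", config$cohort$n_dm, " DM + ",
       config$cohort$n_control, " control) on ", grid$n, " probes")
  cohort <- simulate_cohort(config$cohort, grid)

  vlog("segmenting and calling")
  calltracks <- lapply(cohort$profiles, function(pr) {
    if (config$segmentation$wave_correction) pr <- wave_correct(pr)
    seg <- segment_lrr(pr, config$segmentation)
    seg <- call_allelic(pr, seg, config$loh)
    classify_segments(seg, config$thresholds)
  })

  burden_tbl <- do.call(rbind, lapply(names(calltracks), function(id) {
    b <- burden(calltracks[[id]], genome)
    b$sample <- id
    b$group <- cohort$samples$group[match(id, cohort$samples$sample)]
    b
  }))

  flags <- derive_flags(calltracks, cohort$samples, cohort$mutations,
                        genome, config)

  vlog("differential region testing")
  by_group <- split(calltracks,
                    cohort$samples$group[match(names(calltracks),
                                               cohort$samples$sample)])
  by_group <- by_group[c("dm", "control")]
  cmp <- lapply(c(gain = "gain", loss = "loss"), function(dir) {
    compare_groups(frequency_tracks(by_group, grid, dir),
                   config$comparison)
  })

  contingency <- contingency_report(
    flags, c("chr1q_dup", "tert_dup", "tert_mut", "thyt1_positive",
             "chr9q_loss", "braf"))

  vlog("survival analysis in the DM group")
  dm <- cbind(cohort$samples, flags[match(cohort$samples$sample,
                                          flags$sample),
                                    c("chr1q_dup", "tert_dup", "tert_mut",
                                      "thyt1_positive")])
  dm <- dm[dm$group == "dm", , drop = FALSE]
  surv_tbl <- NULL; km <- NULL; lr <- NULL
  if (sum(dm$event) >= 1L) {
    km <- lapply(split(dm, dm$thyt1_positive), function(d)
      tryCatch(km_estimate(d), error = function(e) NULL))
    lr <- tryCatch(logrank_test(dm, dm$thyt1_positive),
                   error = function(e) NULL)
    surv_tbl <- tryCatch(
      survival_report(dm), error = function(e) NULL)
  }

  run <- list(cohort = cohort, calltracks = calltracks,
              burden = burden_tbl, flags = flags,
              regions = list(gain = cmp$gain$regions,
                             loss = cmp$loss$regions),
              probes = list(gain = cmp$gain$probes,
                            loss = cmp$loss$probes),
              contingency = contingency, survival = surv_tbl,
              logrank = lr, km = km, genome = genome, config = config)

  if (!is.null(out_dir)) {
    vlog("writing artifacts to ", out_dir)
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    tsv <- function(df, nm) utils::write.table(
      df, file.path(out_dir, nm), sep = "\t", quote = FALSE,
      row.names = FALSE)
    write_cohort(cohort, out_dir)
    write_seg(lapply(calltracks, function(tr)
      tr[c("chrom", "start", "end", "n_probes", "mean_lrr")]),
      file.path(out_dir, "calls.seg"))
    tsv(burden_tbl, "burden.tsv")
    regions <- rbind(cmp$gain$regions, cmp$loss$regions)
    tsv(regions, "regions.tsv")
    if (nrow(regions)) {
      regions$name <- paste0(regions$direction, "_",
                             seq_len(nrow(regions)))
      write_bed(regions[order(regions$chrom, regions$start), ],
                file.path(out_dir, "regions.bed"))
    } else {
      file.create(file.path(out_dir, "regions.bed"))
    }
    tsv(flags, "signature.tsv")
    tsv(contingency, "contingency.tsv")
    if (!is.null(surv_tbl)) tsv(surv_tbl, "survival.tsv")
    else writeLines("survival: not estimable (no events)",
                    file.path(out_dir, "survival.tsv"))
    write_pipeline_config(config, file.path(out_dir, "effective_config.yaml"))
    writeLines(c(paste("thyt1 pipeline run,", format(Sys.time())),
                 paste("seed:", config$seed),
                 paste("probes:", grid$n),
                 paste("samples:", nrow(cohort$samples)),
                 paste("R:", R.version.string)),
               file.path(out_dir, "run_log.txt"))
  }
  invisible(run)
}

#' Human-readable summary of a pipeline run
#'
#' Per-group burden means and SDs for the five event classes, the
#' per-feature contingency rows, and the hazard-ratio table.
#'
#' @param run Result of [run_pipeline()].
#' @return Character vector of report lines (also printable).
#' @export
make_report <- function(run) {
  need <- c("burden", "flags", "contingency")
  miss <- need[!need %in% names(run)]
  if (length(miss)) stop("missing run artifact: ", paste(miss, collapse = ", "))
  if (!any(run$flags$group == "control")) stop("empty control group")
  lines <- c("== CNA burden (% genome altered, mean ± SD) ==")
  for (cl in unique(run$burden$class)) {
    b <- run$burden[run$burden$class == cl, ]
    agg <- vapply(split(b$relative_length_pct, b$group),
                  function(v) c(mean(v), stats::sd(v)), numeric(2))
    lines <- c(lines, sprintf(
      "  %-7s DM %5.2f ± %4.2f %%   Control %5.2f ± %4.2f %%",
      cl, agg[1, "dm"], agg[2, "dm"], agg[1, "control"], agg[2, "control"]))
  }
  lines <- c(lines, "", "== Feature association (DM vs Control) ==")
  for (i in seq_len(nrow(run$contingency))) {
    r <- run$contingency[i, ]
    lines <- c(lines, sprintf(
      "  %-15s %d/%d (%.1f%%) vs %d/%d (%.1f%%)  Fisher p = %.3g",
      r$feature, r$pos_case, r$n_case, r$pct_case,
      r$pos_control, r$n_control, r$pct_control, r$fisher_p))
  }
  lines <- c(lines, "", "== Overall survival in DM (Cox) ==")
  if (is.null(run$survival)) {
    lines <- c(lines, "  not estimable (no events)")
  } else {
    for (i in seq_len(nrow(run$survival))) {
      r <- run$survival[i, ]
      lines <- c(lines, sprintf(
        "  %-15s %-12s HR %5.2f (95%% CI %.2f-%.2f)  p = %.3g",
        r$feature, r$model, r$hr, r$lower, r$upper, r$p))
    }
  }
  lines
}
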