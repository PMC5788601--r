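#' Probe-level noise model for simulated SNP-array profiles
#'
#' Log-R-ratio shifts per event class default to values centred inside
#' the calling bands (dup > 0.1, amp > 0.7, del < -0.15, homdel < -1.1)
#' rather than at ideal log2 ratios, emulating the signal compression
#' seen in FFPE array data.
#'
#' @param lrr_sd Per-probe Gaussian LRR noise sd (default 0.2).
#' @param baf_sd Per-probe BAF noise sd (default 0.03).
#' @param het_fraction Probability that a probe is heterozygous in the
#'   germline (default 0.3).
#' @param shifts Named mean-LRR shift per class; must satisfy
#'   homdel < del < 0 < dup < amp with dup in (0.1, 0.7], amp > 0.7,
#'   del in \[-1.1, -0.15), homdel < -1.1, so planted events are
#'   recoverable under the calling bands.
#' @return A `noise_model` list.
#' @export
noise_model <- function(lrr_sd = 0.2, baf_sd = 0.03, het_fraction = 0.3,
                        shifts = c(homdel = -1.5, del = -0.45, neutral = 0,
                                   dup = 0.3, amp = 0.9)) {
  stopifnot(lrr_sd > 0, baf_sd > 0, het_fraction > 0, het_fraction <= 1)
  need <- c("homdel", "del", "neutral", "dup", "amp")
  stopifnot(all(need %in% names(shifts)))
  s <- shifts[need]
  if (!(s["homdel"] < s["del"] && s["del"] < 0 && s["neutral"] == 0 &&
        0 < s["dup"] && s["dup"] < s["amp"])) {
    stop("class shifts must be ordered homdel < del < 0 = neutral < dup < amp")
  }
  if (!(s["dup"] > 0.1 && s["dup"] <= 0.7 && s["amp"] > 0.7 &&
        s["del"] >= -1.1 && s["del"] < -0.15 && s["homdel"] < -1.1)) {
    stop("class shifts must fall inside the corresponding calling bands")
  }
  structure(list(lrr_sd = lrr_sd, baf_sd = baf_sd,
                 het_fraction = het_fraction, shifts = s),
            class = "noise_model")
}

#' An alteration plan for one simulated sample
#'
#' @param events Data.frame with `chrom`, `start`, `end`, `class`
#'   (one of dup, amp, del, homdel, cnloh); may have zero rows.
#' @param tert_promoter `"C228T"`, `"C250T"` or `NA` (no mutation).
#' @param braf_v600e Logical.
#' @param msi_unstable Number of unstable markers out of `msi_markers`.
#' @param msi_markers Marker panel size (default 13).
#' @return An `alteration_plan` list.
#' @export
alteration_plan <- function(events = NULL, tert_promoter = NA_character_,
                            braf_v600e = FALSE, msi_unstable = 0L,
                            msi_markers = 13L) {
  if (is.null(events)) {
    events <- data.frame(chrom = character(), start = numeric(),
                         end = numeric(), class = character(),
                         stringsAsFactors = FALSE)
  }
  stopifnot(all(events$class %in% c("dup", "amp", "del", "homdel", "cnloh")))
  stopifnot(msi_unstable >= 0, msi_unstable <= msi_markers)
  structure(list(events = events, tert_promoter = tert_promoter,
                 braf_v600e = isTRUE(braf_v600e),
                 msi_unstable = as.integer(msi_unstable),
                 msi_markers = as.integer(msi_markers)),
            class = "alteration_plan")
}

# BAF cluster positions for heterozygous probes under each class.
.baf_het_levels <- list(
  neutral = 0.5, dup = c(1 / 3, 2 / 3), amp = c(0.25, 0.75),
  del = c(0, 1), cnloh = c(0, 1))

#' Simulate a probe-level LRR/BAF profile
#'
#' LRR is the class shift plus Gaussian noise per probe. BAF of
#' heterozygous probes sits at 0.5 under neutral copy number, at
#' \{1/3, 2/3\} under duplication, \{1/4, 3/4\} under amplification and
#' at \{0, 1\} under deletion and copy-neutral LOH; homozygous probes
#' sit at \{0, 1\} throughout. Homozygous-deletion probes have no
#' allelic signal and their BAF is uniform noise.
#'
#' @param plan An [alteration_plan()].
#' @param grid A `probe_grid`.
#' @param noise A [noise_model()].
#' @param seed Integer seed; identical seeds give identical profiles.
#' @return A `sample_profile`: list with `lrr`, `baf`, `het` (germline
#'   heterozygosity mask), `truth_class` per probe, and the `grid`.
#' @export
simulate_profile <- function(plan, grid, noise = noise_model(), seed = 1L) {
  stopifnot(inherits(plan, "alteration_plan"), inherits(grid, "probe_grid"))
  gm <- grid$genome
  ev <- plan$events
  if (nrow(ev)) {
    j <- match(ev$chrom, gm$chromosomes$name)
    if (anyNA(j) || any(ev$start < 0) ||
        any(ev$end > gm$chromosomes$length[j]) || any(ev$start >= ev$end)) {
      stop("planned event outside the genome")
    }
  }
  withr::with_seed(as.integer(seed), {
    n <- grid$n
    cls <- rep("neutral", n)
    for (i in seq_len(nrow(ev))) {
      idx <- grid_probes_in(grid, ev$chrom[i], ev$start[i], ev$end[i])
      cls[idx] <- ev$class[i]
    }
    shift <- ifelse(cls == "cnloh", 0, noise$shifts[cls])
    lrr <- shift + stats::rnorm(n, 0, noise$lrr_sd)
    het <- stats::runif(n) < noise$het_fraction
    baf <- numeric(n)
    hom_levels <- stats::rbinom(n, 1, 0.5)  # which homozygote / which allele
    for (k in names(.baf_het_levels)) {
      sel <- het & cls == k
      lv <- .baf_het_levels[[k]]
      baf[sel] <- if (length(lv) == 1L) lv else lv[1 + hom_levels[sel]]
    }
    baf[!het] <- hom_levels[!het]
    baf <- baf + stats::rnorm(n, 0, noise$baf_sd)
    sel <- cls == "homdel"
    baf[sel] <- stats::runif(sum(sel))
    baf <- pmin(pmax(baf, 0), 1)
    structure(list(grid = grid, lrr = lrr, baf = baf, het = het,
                   truth_class = cls),
              class = "sample_profile")
  })
}

#' Add a deterministic quadratic wave to a profile's LRR
#'
#' Adds `amplitude * (2 u^2 - 1)` per chromosome, where `u` is the probe
#' position rescaled to \[-1, 1\]; used to exercise wave correction.
#'
#' @param profile A `sample_profile`.
#' @param amplitude Peak wave amplitude in LRR units.
#' @return The profile with modified `lrr`.
#' @export
add_wave <- function(profile, amplitude = 0.15) {
  grid <- profile$grid
  for (ch in unique(grid$chrom)) {
    idx <- grid_idx(grid, ch)
    p <- grid$pos[idx]
    u <- 2 * (p - min(p)) / max(1, diff(range(p))) - 1
    profile$lrr[idx] <- profile$lrr[idx] + amplitude * (2 * u^2 - 1)
  }
  profile
}

#' Simulate an MSI marker panel
#'
#' @param n_markers Panel size (the study panel has 13 markers).
#' @param unstable Number of unstable markers.
#' @param seed Optional seed controlling which markers are unstable.
#' @return Logical vector of length `n_markers`, `TRUE` = unstable, with
#'   exactly `unstable` true entries.
#' @export
simulate_msi_panel <- function(n_markers = 13L, unstable = 0L, seed = NULL) {
  if (n_markers < 1 || unstable < 0) stop("counts must be non-negative (panel >= 1)")
  if (unstable > n_markers) stop("unstable exceeds panel size")
  pick <- if (is.null(seed)) seq_len(unstable)
          else withr::with_seed(as.integer(seed),
                                sample.int(n_markers, unstable))
  out <- rep(FALSE, n_markers)
  out[pick] <- TRUE
  out
}

#' Cohort-level simulation configuration
#'
#' Defaults reproduce the study's observed per-group frequencies:
#' Chr1q duplication 35.3% in metastatic (DM) vs 3.3% in control
#' tumors, TERT-locus duplication 23.5% vs 0%, TERT promoter mutation
#' 40.6% vs 3.4%, BRAF V600E 35.4% vs 55%, and a hazard ratio of 7.29
#' for death given THYT1 positivity. Chr9q loss is drawn only for
#' samples with Chr1q duplication (strict coupling) apart from a small
#' configurable leak.
#'
#' @param n_dm,n_control Group sizes (defaults 34 and 61, the SNP-array
#'   denominators).
#' @param p_chr1q_dup,p_tert_dup,p_tert_mut,p_braf Named `c(dm=, control=)`
#'   event probabilities.
#' @param p_chr9q_given_chr1q Probability of 9q loss given 1q duplication.
#' @param p_chr9q_leak Probability of 9q loss without 1q duplication.
#' @param p_c228t_share Share of TERT promoter mutations that are C228T,
#'   per group.
#' @param p_msi_low,p_msi_high Per-group probabilities of a low-level
#'   (1 unstable marker) and high-level (4 unstable markers) MSI panel.
#' @param bg_events Mean number of random background CNA events per
#'   sample, per group.
#' @param baseline_hazard Exponential death hazard per month for
#'   THYT1-negative samples.
#' @param hazard_ratio Multiplier on the hazard for THYT1-positive
#'   samples (default 7.29).
#' @param censor_rate Exponential hazard of random loss to follow-up.
#' @param max_followup Administrative censoring time in months.
#' @param msi_markers MSI panel size.
#' @param noise A [noise_model()].
#' @param seed Global seed; per-sample sub-seeds are derived from it.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_dm = 34L, n_control = 61L,
                          p_chr1q_dup = c(dm = 0.353, control = 0.033),
                          p_tert_dup = c(dm = 0.235, control = 0),
                          p_tert_mut = c(dm = 0.406, control = 0.034),
                          p_braf = c(dm = 0.354, control = 0.55),
                          p_chr9q_given_chr1q = 0.85,
                          p_chr9q_leak = 0.01,
                          p_c228t_share = c(dm = 0.8, control = 0.17),
                          p_msi_low = c(dm = 0, control = 0.022),
                          p_msi_high = c(dm = 0, control = 0.011),
                          bg_events = c(dm = 6, control = 4),
                          baseline_hazard = 0.002,
                          hazard_ratio = 7.29,
                          censor_rate = 0.001,
                          max_followup = 240,
                          msi_markers = 13L,
                          noise = noise_model(),
                          seed = 1L) {
  probs <- c(p_chr1q_dup, p_tert_dup, p_tert_mut, p_braf,
             p_chr9q_given_chr1q, p_chr9q_leak, p_c228t_share,
             p_msi_low, p_msi_high)
  stopifnot(all(probs >= 0), all(probs <= 1), hazard_ratio > 0,
            baseline_hazard > 0, max_followup > 0)
  structure(list(n_dm = as.integer(n_dm), n_control = as.integer(n_control),
                 p_chr1q_dup = p_chr1q_dup, p_tert_dup = p_tert_dup,
                 p_tert_mut = p_tert_mut, p_braf = p_braf,
                 p_chr9q_given_chr1q = p_chr9q_given_chr1q,
                 p_chr9q_leak = p_chr9q_leak,
                 p_c228t_share = p_c228t_share,
                 p_msi_low = p_msi_low, p_msi_high = p_msi_high,
                 bg_events = bg_events,
                 baseline_hazard = baseline_hazard,
                 hazard_ratio = hazard_ratio,
                 censor_rate = censor_rate, max_followup = max_followup,
                 msi_markers = as.integer(msi_markers),
                 noise = noise, seed = as.integer(seed)),
            class = "cohort_config")
}

# Deterministic per-sample sub-seed: a documented counter scheme so any
# single sample is reproducible in isolation. Kept below 2^31.
sub_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 9973) %% 2147483647)
}

# Clinical covariate distributions per group (stage I-IV, histology,
# gender), matching the study's Table-1-style marginals.
.stage_probs <- list(dm = c(0.04, 0.18, 0.16, 0.62),
                     control = c(0.45, 0.05, 0.34, 0.16))
.hist_probs <- list(dm = c(0.50, 0.30, 0.16, 0.04),
                    control = c(0.72, 0.11, 0.15, 0.02))
.hist_levels <- c("classical", "tall_cell", "follicular", "solid_trabecular")
.p_female <- c(dm = 0.64, control = 0.73)

# Draw non-overlapping random background events for one sample.
draw_background <- function(genome, lambda, reserved) {
  k <- stats::rpois(1, lambda)
  if (k == 0) return(NULL)
  out <- reserved
  cls_p <- c(dup = 0.70, del = 0.25, amp = 0.03, homdel = 0.02)
  got <- 0L; tries <- 0L
  rows <- list()
  while (got < k && tries < 50L * k) {
    tries <- tries + 1L
    j <- sample.int(nrow(genome$chromosomes), 1)
    L <- genome$chromosomes$length[j]
    len <- min(stats::rexp(1, 1 / 1.5e6) + 4e5, L / 4)
    start <- stats::runif(1, 0, L - len)
    cand <- data.frame(chrom = genome$chromosomes$name[j],
                       start = floor(start), end = floor(start + len),
                       class = sample(names(cls_p), 1, prob = cls_p),
                       stringsAsFactors = FALSE)
    clash <- any(out$chrom == cand$chrom &
                   out$start < cand$end & cand$start < out$end)
    if (!isTRUE(clash)) {
      rows[[length(rows) + 1L]] <- cand
      out <- rbind(out, cand)
      got <- got + 1L
    }
  }
  do.call(rbind, rows)
}

#' Simulate a two-group cohort with planted alterations and survival
#'
#' Each sample receives an alteration plan (signature arm/locus events
#' plus random background events), a probe-level profile, a mutation
#' table with read support, an MSI panel, and a survival record whose
#' hazard is multiplied by `hazard_ratio` when the sample is
#' truth-THYT1-positive. Chr9q loss is drawn only among Chr1q-duplicated
#' samples apart from the configured leak.
#'
#' @param config A [cohort_config()].
#' @param grid A `probe_grid`; defaults to a 10 kb grid on the desk
#'   mini-genome seeded from `config$seed`.
#' @param keep_profiles If `FALSE`, skip probe-level profile simulation
#'   (truth flags, mutations, MSI and survival only); useful for
#'   survival-oriented simulations.
#' @return A `cohort`: list with `samples` (sample sheet with truth
#'   flags), `mutations`, `truth_events`, `profiles`, `grid`, `config`.
#' @export
simulate_cohort <- function(config = cohort_config(), grid = NULL,
                            keep_profiles = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$n_dm + config$n_control < 2L) stop("need at least 2 samples")
  if (is.null(grid)) {
    grid <- make_probe_grid(build_genome_model(desk_genome_config()),
                            seed = config$seed)
  }
  gm <- grid$genome
  arm1q <- arm_range(gm, "1q")
  arm5p <- arm_range(gm, "5p")
  arm9q <- arm_range(gm, "9q")
  groups <- c(rep("dm", config$n_dm), rep("control", config$n_control))
  ids <- sprintf("%s_%02d", toupper(groups),
                 as.integer(stats::ave(seq_along(groups), groups,
                                       FUN = seq_along)))
  n <- length(ids)

  samples <- list(); muts <- list(); profiles <- list(); truth <- list()
  for (i in seq_len(n)) {
    g <- groups[i]
    si <- sub_seed(config$seed, i)
    rec <- withr::with_seed(si, {
      chr1q <- stats::runif(1) < config$p_chr1q_dup[g]
      tertd <- stats::runif(1) < config$p_tert_dup[g]
      chr9q <- if (chr1q) stats::runif(1) < config$p_chr9q_given_chr1q
               else stats::runif(1) < config$p_chr9q_leak
      tertm <- stats::runif(1) < config$p_tert_mut[g]
      braf <- stats::runif(1) < config$p_braf[g]
      msi_u <- if (stats::runif(1) < config$p_msi_high[g]) 4L
               else if (stats::runif(1) < config$p_msi_low[g]) 1L else 0L
      ev <- data.frame(chrom = character(), start = numeric(),
                       end = numeric(), class = character(),
                       stringsAsFactors = FALSE)
      if (chr1q) ev <- rbind(ev, data.frame(chrom = "1", start = arm1q[1],
                                            end = arm1q[2], class = "dup"))
      if (tertd) ev <- rbind(ev, data.frame(chrom = "5", start = arm5p[1],
                                            end = arm5p[2], class = "dup"))
      if (chr9q) ev <- rbind(ev, data.frame(chrom = "9", start = arm9q[1],
                                            end = arm9q[2], class = "del"))
      bg <- draw_background(gm, config$bg_events[g], ev)
      if (!is.null(bg)) ev <- rbind(ev, bg)
      variant <- if (tertm) {
        if (stats::runif(1) < config$p_c228t_share[g]) "C228T" else "C250T"
      } else NA_character_
      thyt1 <- chr1q || tertd || tertm
      haz <- config$baseline_hazard * if (thyt1) config$hazard_ratio else 1
      t_death <- stats::rexp(1, haz)
      t_cens <- if (config$censor_rate > 0)
        min(stats::rexp(1, config$censor_rate), config$max_followup)
      else config$max_followup
      time <- max(min(t_death, t_cens), 0.5)
      stage <- sample(1:4, 1, prob = .stage_probs[[g]])
      histology <- sample(.hist_levels, 1, prob = .hist_probs[[g]])
      gender <- if (stats::runif(1) < .p_female[g]) "F" else "M"
      mut_rows <- list()
      add_var <- function(gene, var) {
        tot <- round(stats::runif(1, 200, 800))
        vaf <- stats::runif(1, 0.10, 0.45)
        data.frame(sample = ids[i], gene = gene, variant = var,
                   supporting = stats::rbinom(1, tot, vaf), total = tot,
                   forward = TRUE, reverse = TRUE, stringsAsFactors = FALSE)
      }
      if (tertm) mut_rows <- c(mut_rows, list(add_var("TERT_promoter", variant)))
      if (braf) mut_rows <- c(mut_rows, list(add_var("BRAF", "V600E")))
      if (stats::runif(1) < 0.3) {
        # sequencing artifact: fails at least one of the support filters
        tot <- round(stats::runif(1, 150, 600))
        fail <- sample(c("reads", "fraction", "strand"), 1)
        supp <- switch(fail,
                       reads = sample(1:9, 1),
                       fraction = max(10, round(tot * stats::runif(1, 0.005, 0.04))),
                       strand = round(tot * stats::runif(1, 0.06, 0.2)))
        mut_rows <- c(mut_rows, list(data.frame(
          sample = ids[i], gene = sample(c("NRAS", "HRAS", "KRAS", "TP53",
                                           "PTEN", "RET"), 1),
          variant = "artifact", supporting = supp, total = tot,
          forward = TRUE, reverse = fail != "strand",
          stringsAsFactors = FALSE)))
      }
      list(ev = ev, mut = do.call(rbind, mut_rows),
           row = data.frame(
             sample = ids[i], group = g, stage = stage,
             histology = histology, gender = gender,
             time_months = time, event = as.integer(t_death <= t_cens),
             truth_chr1q_dup = chr1q, truth_tert_dup = tertd,
             truth_chr9q_loss = chr9q, truth_tert_mut = tertm,
             truth_braf = braf, truth_thyt1 = thyt1,
             msi_unstable = msi_u, msi_markers = config$msi_markers,
             stringsAsFactors = FALSE))
    })
    samples[[i]] <- rec$row
    truth[[ids[i]]] <- rec$ev
    if (!is.null(rec$mut)) muts[[length(muts) + 1L]] <- rec$mut
    if (keep_profiles) {
      plan <- alteration_plan(rec$ev, tert_promoter = NA,
                              msi_unstable = rec$row$msi_unstable,
                              msi_markers = config$msi_markers)
      profiles[[ids[i]]] <- simulate_profile(plan, grid, config$noise,
                                             seed = sub_seed(config$seed,
                                                             i + n))
    }
  }
  mutations <- if (length(muts)) do.call(rbind, muts) else
    data.frame(sample = character(), gene = character(),
               variant = character(), supporting = integer(),
               total = integer(), forward = logical(), reverse = logical(),
               stringsAsFactors = FALSE)
  structure(list(samples = do.call(rbind, samples), mutations = mutations,
                 truth_events = truth, profiles = profiles, grid = grid,
                 config = config),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("cohort:", sum(x$samples$group == "dm"), "DM +",
      sum(x$samples$group == "control"), "control samples;",
      length(x$profiles), "probe-level profiles\n")
  invisible(x)
}

#' Write a probe-level profile as TSV
#'
#' One row per probe: chromosome, position, LRR, BAF and the germline
#' heterozygosity mask — a plain-text layout any downstream tool can
#' read.
#'
#' @param profile A `sample_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(
    data.frame(chrom = profile$grid$chrom, pos = profile$grid$pos,
               lrr = round(profile$lrr, 5), baf = round(profile$baf, 5),
               het = as.integer(profile$het)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write cohort tables to a directory
#'
#' Writes the sample sheet, mutation table and MSI table as TSV and the
#' planted truth segments as one SEG file; optionally the probe-level
#' profiles (one TSV per sample under `profiles/`).
#'
#' @param cohort A `cohort`.
#' @param dir Output directory (created if missing).
#' @param profiles Also write per-sample probe-level TSVs.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, profiles = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, nm) utils::write.table(
    df, file.path(dir, nm), sep = "\t", quote = FALSE, row.names = FALSE)
  tsv(cohort$samples, "samples.tsv")
  tsv(cohort$mutations, "mutations.tsv")
  tsv(cohort$samples[c("sample", "msi_unstable", "msi_markers")], "msi.tsv")
  truth <- cohort$truth_events
  keep <- vapply(truth, nrow, 1L) > 0
  if (any(keep)) {
    seg <- lapply(truth[keep], function(ev) {
      data.frame(chrom = ev$chrom, start = ev$start, end = ev$end,
                 n_probes = NA_integer_,
                 mean_lrr = unname(noise_model()$shifts[
                   ifelse(ev$class == "cnloh", "neutral", ev$class)]),
                 stringsAsFactors = FALSE)
    })
    write_seg(seg, file.path(dir, "truth_segments.seg"))
  }
  if (profiles && length(cohort$profiles)) {
    pdir <- file.path(dir, "profiles")
    dir.create(pdir, showWarnings = FALSE)
    for (id in names(cohort$profiles)) {
      write_profile(cohort$profiles[[id]],
                    file.path(pdir, paste0(id, ".tsv")))
    }
  }
  invisible(dir)
}
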