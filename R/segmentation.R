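#' Segmentation parameters
#'
#' The segmentation is a per-chromosome Gaussian-emission hidden Markov
#' model over copy-number levels, in the spirit of the HMM segmenters
#' used by commercial SNP-array suites. The sensitivity knob is the
#' per-probe breakpoint prior (state-change probability), default
#' 1e-7, and segments shorter than `min_probes` (default 10) are merged
#' into a flank.
#'
#' @param min_probes Minimum probes per emitted segment (default 10).
#' @param breakpoint_prior Per-probe probability of a state change
#'   (default 1e-7).
#' @param state_means Strictly increasing hidden-state mean LRRs; the
#'   default five states (-1.5, -0.45, 0, 0.3, 0.9) sit at the centres
#'   of the homozygous-deletion, deletion, neutral, duplication and
#'   amplification bands.
#' @param emission_sd Shared emission sd; `NULL` (default) estimates it
#'   per sample as `mad(diff(lrr)) / sqrt(2)`, self-calibrating to the
#'   noise level.
#' @param wave_correction Apply [wave_correct()] before segmenting.
#' @return A `seg_params` list.
#' @export
seg_params <- function(min_probes = 10L, breakpoint_prior = 1e-7,
                       state_means = c(-1.5, -0.45, 0, 0.3, 0.9),
                       emission_sd = NULL, wave_correction = TRUE) {
  stopifnot(min_probes >= 1, breakpoint_prior > 0, breakpoint_prior < 1,
            length(state_means) >= 2, !is.unsorted(state_means, strictly = TRUE))
  if (!is.null(emission_sd)) stopifnot(emission_sd > 0)
  structure(list(min_probes = as.integer(min_probes),
                 breakpoint_prior = breakpoint_prior,
                 state_means = state_means, emission_sd = emission_sd,
                 wave_correction = isTRUE(wave_correction)),
            class = "seg_params")
}

#' LOH / allelic-imbalance calling parameters
#'
#' @param imbalance_threshold Mean allelic-ratio cut for heterozygous
#'   imbalance (default 0.4).
#' @param homozygosity_ratio Per-probe allelic-ratio cut counting a
#'   probe as homozygous (default 0.8).
#' @param homozygous_fraction Minimum fraction of homozygous probes in a
#'   segment for an LOH call (default 0.85).
#' @param min_length Minimum segment length in bp for an LOH call
#'   (default 500 kb).
#' @return A `loh_params` list.
#' @export
loh_params <- function(imbalance_threshold = 0.4, homozygosity_ratio = 0.8,
                       homozygous_fraction = 0.85, min_length = 5e5) {
  stopifnot(imbalance_threshold > 0, imbalance_threshold <= 1,
            homozygosity_ratio > 0, homozygosity_ratio <= 1,
            homozygous_fraction > 0, homozygous_fraction <= 1,
            min_length > 0)
  structure(list(imbalance_threshold = imbalance_threshold,
                 homozygosity_ratio = homozygosity_ratio,
                 homozygous_fraction = homozygous_fraction,
                 min_length = min_length),
            class = "loh_params")
}

#' Quadratic wave correction of a probe-level profile
#'
#' Removes a per-chromosome least-squares quadratic trend in probe
#' position from the LRR and re-centres the profile median to zero.
#' Because a naive quadratic fit absorbs genuine arm-level copy-number
#' steps, the copy-number signal is first estimated with the same HMM
#' used for segmentation and the quadratic is fit to the
#' state-mean-subtracted residuals, iterating the two steps. On
#' trend-only input this reduces to the plain least-squares fit and
#' annihilates an exact quadratic. BAF is untouched; chromosomes with
#' fewer than 30 probes are passed through with a warning.
#'
#' @param profile A `sample_profile`.
#' @param state_means Copy-number level means used for the signal
#'   estimate (defaults to the segmentation states).
#' @param breakpoint_prior Per-probe state-change probability of the
#'   inner HMM.
#' @param max_iter Maximum signal/trend refit iterations.
#' @return The profile with detrended `lrr`.
#' @export
wave_correct <- function(profile,
                         state_means = c(-1.5, -0.45, 0, 0.3, 0.9),
                         breakpoint_prior = 1e-7,
                         max_iter = 5L) {
  grid <- profile$grid
  lrr <- profile$lrr
  for (ch in unique(grid$chrom)) {
    idx <- grid_idx(grid, ch)
    if (length(idx) < 30L) {
      warning("chromosome ", ch, " has < 30 probes; wave correction skipped")
      next
    }
    p <- grid$pos[idx]
    u <- (p - mean(p)) / stats::sd(p)  # rescale for conditioning
    X <- cbind(1, u, u^2)
    y <- lrr[idx]
    sd_hat <- stats::mad(diff(y)) / sqrt(2)
    if (!is.finite(sd_hat) || sd_hat <= 0) sd_hat <- 0.01
    wave <- numeric(length(idx))
    level <- numeric(length(idx))
    for (it in seq_len(max_iter)) {
      path <- .viterbi_gauss(y - wave, state_means, sd_hat,
                             breakpoint_prior)
      new_level <- state_means[path]
      wave <- stats::lm.fit(X, y - new_level)$fitted.values
      if (identical(new_level, level)) break
      level <- new_level
    }
    lrr[idx] <- y - wave
  }
  profile$lrr <- lrr - stats::median(lrr)
  profile
}

# run-length encode a state path into segment row indices
path_to_runs <- function(path) {
  r <- rle(path)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(first = starts, last = ends, state = r$values)
}

# Merge runs shorter than min_probes into the flanking run whose state
# mean is closer to the short run's observed mean. Keeps the partition.
merge_short_runs <- function(runs, x, means, min_probes) {
  repeat {
    len <- runs$last - runs$first + 1L
    if (nrow(runs) <= 1L || all(len >= min_probes)) break
    i <- which(len < min_probes)[which.min(len[len < min_probes])]
    obs <- mean(x[runs$first[i]:runs$last[i]])
    cand <- c(if (i > 1L) i - 1L, if (i < nrow(runs)) i + 1L)
    d <- abs(means[runs$state[cand]] - obs)
    j <- cand[which.min(d)]
    runs$state[i] <- runs$state[j]
    # collapse adjacent equal-state runs
    keep <- c(TRUE, runs$state[-1] != runs$state[-nrow(runs)])
    grp <- cumsum(keep)
    runs <- data.frame(first = tapply(runs$first, grp, min),
                       last = tapply(runs$last, grp, max),
                       state = runs$state[keep])
  }
  runs
}

#' HMM segmentation of an LRR profile
#'
#' Computes the Viterbi path of a per-chromosome Gaussian-emission HMM
#' whose hidden states are copy-number levels, with self-transition
#' probability `1 - breakpoint_prior * (K - 1)`. Runs shorter than
#' `min_probes` are merged into the flanking state with the closer
#' mean, so the segments always partition the probe grid. Segment
#' `mean_lrr` is the mean of the member probes.
#'
#' @param profile A `sample_profile` (wave-corrected when the pipeline
#'   default applies).
#' @param params A [seg_params()].
#' @return Data.frame of segments: `chrom`, `start`, `end`, `n_probes`,
#'   `mean_lrr`, `first_probe`, `last_probe` (global probe indices).
#' @export
segment_lrr <- function(profile, params = seg_params()) {
  grid <- profile$grid
  if (any(!is.finite(profile$lrr))) {
    stop("non-finite LRR at probe indices: ",
         paste(utils::head(which(!is.finite(profile$lrr)), 10), collapse = ", "))
  }
  sd_hat <- params$emission_sd
  if (is.null(sd_hat)) {
    sd_hat <- stats::mad(diff(profile$lrr)) / sqrt(2)
    if (!is.finite(sd_hat) || sd_hat <= 0) sd_hat <- 0.01
  }
  means <- params$state_means
  out <- list()
  for (ch in unique(grid$chrom)) {
    idx <- grid_idx(grid, ch)
    x <- profile$lrr[idx]
    path <- .viterbi_gauss(x, means, sd_hat, params$breakpoint_prior)
    runs <- path_to_runs(path)
    runs <- merge_short_runs(runs, x, means, params$min_probes)
    pos <- grid$pos[idx]
    out[[ch]] <- data.frame(
      chrom = ch,
      start = pos[runs$first],
      end = pos[runs$last] + 1,
      n_probes = runs$last - runs$first + 1L,
      mean_lrr = vapply(seq_len(nrow(runs)),
                        function(i) mean(x[runs$first[i]:runs$last[i]]), 0),
      first_probe = idx[runs$first],
      last_probe = idx[runs$last],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Allelic-ratio and LOH calls per segment
#'
#' The per-probe allelic ratio is `r = |2 BAF - 1|`, computed on
#' heterozygous-informative probes (so the stated cuts 0.4 and 0.8
#' correspond to BAF splits 0.3/0.7 and 0.1/0.9). A segment is flagged
#' as allelic imbalance when its mean ratio exceeds
#' `imbalance_threshold`, and as LOH when it is at least `min_length`
#' long and at least `homozygous_fraction` of its informative probes
#' have ratio above `homozygosity_ratio`.
#'
#' @param profile A `sample_profile` with BAF and a heterozygosity mask.
#' @param segments Segments from [segment_lrr()].
#' @param params A [loh_params()].
#' @return `segments` with added columns `mean_ar`, `n_informative`,
#'   `imbalance`, `loh` (NA where a segment has no informative probes).
#' @export
call_allelic <- function(profile, segments, params = loh_params()) {
  if (is.null(profile$baf)) stop("profile carries no BAF")
  r_all <- abs(2 * profile$baf - 1)
  n <- nrow(segments)
  mean_ar <- rep(NA_real_, n); n_inf <- integer(n)
  imb <- rep(NA, n); loh <- rep(NA, n)
  for (i in seq_len(n)) {
    idx <- segments$first_probe[i]:segments$last_probe[i]
    idx <- idx[profile$het[idx]]
    n_inf[i] <- length(idx)
    if (length(idx) == 0L) {
      message("segment ", i, " has no informative probes; allelic flags NA")
      next
    }
    r <- r_all[idx]
    mean_ar[i] <- mean(r)
    imb[i] <- mean_ar[i] > params$imbalance_threshold
    loh[i] <- (segments$end[i] - segments$start[i]) >= params$min_length &&
      mean(r > params$homozygosity_ratio) >= params$homozygous_fraction
  }
  segments$mean_ar <- mean_ar
  segments$n_informative <- n_inf
  segments$imbalance <- imb
  segments$loh <- loh
  segments
}
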