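#' Copy-number calling thresholds on segment mean LRR
#'
#' Mean intensities above 0.1 call duplications and above 0.7
#' amplifications (high gain); below -0.15 hemizygous deletions and
#' below -1.1 homozygous deletions. The bands are half-open exactly as
#' ordered in [classify_segments()], so every mean maps to one class.
#'
#' @param dup_low,amp_low,del_high,homdel_high Band edges; must satisfy
#'   `homdel_high < del_high < 0 < dup_low < amp_low`.
#' @return A `calling_thresholds` list.
#' @export
calling_thresholds <- function(dup_low = 0.1, amp_low = 0.7,
                               del_high = -0.15, homdel_high = -1.1) {
  if (!(homdel_high < del_high && del_high < 0 && 0 < dup_low &&
        dup_low < amp_low)) {
    stop("thresholds must satisfy homdel_high < del_high < 0 < dup_low < amp_low")
  }
  structure(list(dup_low = dup_low, amp_low = amp_low,
                 del_high = del_high, homdel_high = homdel_high),
            class = "calling_thresholds")
}

.cna_classes <- c("dup", "amp", "del", "homdel")
.gain_classes <- c("dup", "amp")
.loss_classes <- c("del", "homdel")

#' Classify segments into copy-number event classes
#'
#' amp if `mean_lrr > amp_low`; dup if `dup_low < mean_lrr <= amp_low`;
#' homdel if `mean_lrr < homdel_high`; del if
#' `homdel_high <= mean_lrr < del_high`; neutral otherwise. The classes
#' are mutually exclusive and exhaustive.
#'
#' @param segments Segment data.frame with `mean_lrr`.
#' @param thresholds A [calling_thresholds()].
#' @return `segments` with an added `class` column (a call track).
#' @export
classify_segments <- function(segments, thresholds = calling_thresholds()) {
  x <- segments$mean_lrr
  cls <- rep("neutral", length(x))
  cls[x > thresholds$amp_low] <- "amp"
  cls[x > thresholds$dup_low & x <= thresholds$amp_low] <- "dup"
  cls[x < thresholds$homdel_high] <- "homdel"
  cls[x >= thresholds$homdel_high & x < thresholds$del_high] <- "del"
  segments$class <- cls
  segments
}

#' Per-sample CNA burden
#'
#' Relative altered length per class as a percentage of the covered
#' autosomal genome, and the number of (non-neutral) events per class.
#' Sex chromosomes are excluded from both numerator and denominator by
#' default to avoid gender-driven artifacts.
#'
#' @param calltrack Classified segments from [classify_segments()].
#' @param genome A `genome_model` (used to identify autosomes).
#' @param covered_length Denominator in bp; defaults to the summed
#'   length of the track's autosomal segments.
#' @param autosomes_only Restrict to autosomes (default `TRUE`).
#' @return Data.frame with rows dup, amp, del, homdel, total and
#'   columns `class`, `relative_length_pct`, `n_events`.
#' @export
burden <- function(calltrack, genome, covered_length = NULL,
                   autosomes_only = TRUE) {
  stopifnot("class" %in% names(calltrack))
  if (autosomes_only) {
    calltrack <- calltrack[calltrack$chrom %in% autosomes(genome), ,
                           drop = FALSE]
  }
  len <- calltrack$end - calltrack$start
  if (is.null(covered_length)) covered_length <- sum(len)
  if (covered_length <= 0) stop("covered_length must be > 0")
  per <- vapply(.cna_classes, function(k) {
    sel <- calltrack$class == k
    c(100 * sum(len[sel]) / covered_length, sum(sel))
  }, numeric(2))
  out <- data.frame(class = c(.cna_classes, "total"),
                    relative_length_pct = c(per[1, ], sum(per[1, ])),
                    n_events = as.integer(c(per[2, ], sum(per[2, ]))),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# total overlap (bp) of segments of given classes with [start, end) on chrom
overlap_bp <- function(calltrack, chrom, start, end, classes) {
  sel <- calltrack$chrom == chrom & calltrack$class %in% classes
  if (!any(sel)) return(0)
  s <- pmax(calltrack$start[sel], start)
  e <- pmin(calltrack$end[sel], end)
  sum(pmax(e - s, 0))
}

#' Arm-level alteration flag
#'
#' TRUE when segments of the given classes cover at least
#' `coverage_fraction` of the arm (default 50%), the operational
#' definition of an arm-level event such as the Chr1q duplication or
#' Chr9q loss.
#'
#' @param calltrack Classified segments.
#' @param genome A `genome_model`.
#' @param arm Arm id, e.g. `"1q"`.
#' @param classes Class set, e.g. `c("dup", "amp")` for gains.
#' @param coverage_fraction Minimum covered fraction of the arm.
#' @return Logical.
#' @export
arm_flag <- function(calltrack, genome, arm, classes = .gain_classes,
                     coverage_fraction = 0.5) {
  rng <- arm_range(genome, arm)
  chrom <- normalize_chrom(sub("[pq]$", "", arm))
  ov <- overlap_bp(calltrack, chrom, rng[1], rng[2], classes)
  ov >= coverage_fraction * (rng[2] - rng[1])
}

#' Locus-level alteration flag
#'
#' TRUE when any segment of the given classes overlaps the named locus
#' by at least 1 bp (e.g. a duplication spanning the TERT locus on 5p).
#'
#' @inheritParams arm_flag
#' @param locus Locus name defined in the genome model.
#' @return Logical.
#' @export
locus_flag <- function(calltrack, genome, locus, classes = .gain_classes) {
  i <- match(locus, genome$loci$name)
  if (is.na(i)) stop("unknown locus: ", locus)
  li <- genome$loci[i, ]
  overlap_bp(calltrack, li$chrom, li$start, li$end, classes) > 0
}

#' Per-probe class labels of a call track
#'
#' @param calltrack Classified segments with `first_probe`/`last_probe`
#'   indices (tracks from [segment_lrr()]); falls back to coordinate
#'   lookup otherwise.
#' @param grid The `probe_grid` the track partitions.
#' @return Character vector of length `grid$n` with the class at each
#'   probe ("neutral" where uncovered).
#' @export
calls_at_probes <- function(calltrack, grid) {
  out <- rep("neutral", grid$n)
  if (all(c("first_probe", "last_probe") %in% names(calltrack))) {
    for (i in seq_len(nrow(calltrack))) {
      out[calltrack$first_probe[i]:calltrack$last_probe[i]] <- calltrack$class[i]
    }
  } else {
    for (i in seq_len(nrow(calltrack))) {
      idx <- grid_probes_in(grid, calltrack$chrom[i], calltrack$start[i],
                            calltrack$end[i])
      out[idx] <- calltrack$class[i]
    }
  }
  out
}
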