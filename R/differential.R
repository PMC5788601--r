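#' Comparison parameters for differential-region testing
#'
#' Defaults follow the study settings: differential regions require a
#' BH-adjusted p-value below 0.05 and a between-group frequency
#' difference of at least 15 percentage points, with gains and losses
#' tested in separate passes. The 25% overall frequency threshold
#' parameterizes the aggregate calling track (the cohort-level
#' frequency display): probes whose alteration frequency reaches it in
#' the more frequent group are annotated as aggregate calls. It does
#' not gate differential regions — a recurrent lesion present in a
#' quarter of one group would otherwise be unreportable in a
#' case-control design whose recurrent arm events run at 23-35% of
#' cases and ~3% of controls.
#'
#' @param adj_p_threshold BH-adjusted p-value cut.
#' @param overall_freq_threshold Aggregate-calling frequency threshold
#'   (annotation, not a region gate).
#' @param min_freq_difference Minimum |freqA - freqB|.
#' @param gap_tolerance Probes allowed to fail inside a merged region.
#' @return A `comparison_params` list.
#' @export
comparison_params <- function(adj_p_threshold = 0.05,
                              overall_freq_threshold = 0.25,
                              min_freq_difference = 0.15,
                              gap_tolerance = 1L) {
  stopifnot(adj_p_threshold > 0, adj_p_threshold < 1,
            overall_freq_threshold > 0, overall_freq_threshold < 1,
            min_freq_difference > 0, min_freq_difference < 1,
            gap_tolerance >= 0)
  structure(list(adj_p_threshold = adj_p_threshold,
                 overall_freq_threshold = overall_freq_threshold,
                 min_freq_difference = min_freq_difference,
                 gap_tolerance = as.integer(gap_tolerance)),
            class = "comparison_params")
}

#' Per-probe alteration counts and frequencies per group
#'
#' For each probe, counts the samples whose call belongs to the
#' direction's class set (gain = dup/amp, loss = del/homdel).
#'
#' @param calltracks_by_group Named list of two groups, each a list of
#'   classified call tracks (one per sample).
#' @param grid The shared `probe_grid`.
#' @param direction `"gain"` or `"loss"`.
#' @return A `freq_tracks` list: `counts` (named list of integer
#'   vectors), `sizes` (group sizes), `freq`, `direction`, `grid`.
#' @export
frequency_tracks <- function(calltracks_by_group, grid,
                             direction = c("gain", "loss")) {
  direction <- match.arg(direction)
  stopifnot(length(calltracks_by_group) == 2L)
  classes <- if (direction == "gain") .gain_classes else .loss_classes
  if (any(vapply(calltracks_by_group, length, 1L) == 0L)) {
    stop("empty group in frequency_tracks")
  }
  counts <- lapply(calltracks_by_group, function(tracks) {
    acc <- integer(grid$n)
    for (tr in tracks) {
      acc <- acc + (calls_at_probes(tr, grid) %in% classes)
    }
    acc
  })
  sizes <- vapply(calltracks_by_group, length, 1L)
  structure(list(counts = counts, sizes = sizes,
                 freq = Map(function(cnt, nn) cnt / nn, counts, sizes),
                 direction = direction, grid = grid),
            class = "freq_tracks")
}

# Fisher p for many probes sharing few distinct (a, b) pairs: memoized
# two-sided test on (altered, not altered) x group.
fisher_p_vec <- function(a, b, nA, nB) {
  key <- a * (nB + 1L) + b
  ukey <- unique(key)
  up <- vapply(ukey, function(k) {
    ai <- k %/% (nB + 1L); bi <- k %% (nB + 1L)
    stats::fisher.test(matrix(c(ai, nA - ai, bi, nB - bi), 2L,
                              byrow = TRUE))$p.value
  }, 0)
  up[match(key, ukey)]
}

#' Case-control comparison of CNA frequency tracks
#'
#' Per probe, a two-sided Fisher exact test on
#' (altered, not altered) x (group A, group B), with Benjamini-Hochberg
#' adjustment across probes. A probe passes when adjusted p <
#' `adj_p_threshold` and |freqA - freqB| >= `min_freq_difference`;
#' probes with max(freqA, freqB) >= `overall_freq_threshold` are
#' additionally annotated as aggregate calls. Maximal runs of passing
#' probes (tolerating `gap_tolerance` failing probes between them, never
#' across a chromosome boundary) are merged into regions.
#'
#' @param tracks A `freq_tracks` object from [frequency_tracks()].
#' @param params A [comparison_params()].
#' @return List with `probes` (per-probe data.frame: chrom, pos, counts,
#'   freqs, p, adj_p, pass) and `regions` (data.frame of merged
#'   differential regions with per-group mean frequencies and the
#'   minimum adjusted p).
#' @export
compare_groups <- function(tracks, params = comparison_params()) {
  stopifnot(inherits(tracks, "freq_tracks"))
  grid <- tracks$grid
  a <- tracks$counts[[1]]; b <- tracks$counts[[2]]
  nA <- tracks$sizes[[1]]; nB <- tracks$sizes[[2]]
  p <- fisher_p_vec(a, b, nA, nB)
  adj <- stats::p.adjust(p, method = "BH")
  fA <- a / nA; fB <- b / nB
  pass <- adj < params$adj_p_threshold &
    abs(fA - fB) >= params$min_freq_difference
  probes <- data.frame(chrom = grid$chrom, pos = grid$pos,
                       count_a = a, count_b = b, freq_a = fA, freq_b = fB,
                       max_freq = pmax(fA, fB),
                       aggregate_call = pmax(fA, fB) >=
                         params$overall_freq_threshold,
                       p = p, adj_p = adj,
                       pass = pass, stringsAsFactors = FALSE)
  regions <- merge_passing(probes, grid, params$gap_tolerance,
                           tracks$direction)
  list(probes = probes, regions = regions)
}

merge_passing <- function(probes, grid, gap, direction) {
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_probes = integer(),
                      direction = character(), freq_a = numeric(),
                      freq_b = numeric(), min_adj_p = numeric(),
                      stringsAsFactors = FALSE)
  idx <- which(probes$pass)
  if (length(idx) == 0L) return(empty)
  same_run <- c(FALSE, diff(idx) <= gap + 1L &
                  probes$chrom[idx[-1]] == probes$chrom[idx[-length(idx)]])
  run_id <- cumsum(!same_run)
  rows <- lapply(split(idx, run_id), function(ii) {
    data.frame(chrom = probes$chrom[ii[1]],
               start = probes$pos[ii[1]],
               end = probes$pos[ii[length(ii)]] + 1,
               n_probes = length(ii),
               direction = direction,
               freq_a = mean(probes$freq_a[ii]),
               freq_b = mean(probes$freq_b[ii]),
               min_adj_p = min(probes$adj_p[ii]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# minimal GFF3 reader: seqid, start (1-based), end (inclusive), Name/ID
read_gff3_features <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  rows <- lapply(which(keep), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9L) stop("malformed GFF3 line ", i, ": fewer than 9 fields")
    start <- suppressWarnings(as.numeric(f[4]))
    end <- suppressWarnings(as.numeric(f[5]))
    if (anyNA(c(start, end))) stop("malformed GFF3 line ", i, ": non-numeric coordinate")
    m <- regmatches(f[9], regexec("(?:Name|ID)=([^;]+)", f[9]))[[1]]
    data.frame(chrom = normalize_chrom(f[1]), start = start - 1, end = end,
               name = if (length(m) == 2L) m[2] else paste0("feature_", i),
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), name = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Annotate regions with overlapping features
#'
#' @param regions Region data.frame (`chrom`, `start`, `end`).
#' @param features Path to a BED or GFF3 feature file, or a data.frame
#'   with `chrom`, `start`, `end`, `name`.
#' @return `regions` with added `features` (comma-separated overlapping
#'   feature names, >= 1 bp overlap) and `n_features`.
#' @export
annotate_regions <- function(regions, features) {
  if (is.character(features)) {
    features <- if (grepl("\\.gff3?$", features, ignore.case = TRUE)) {
      read_gff3_features(features)
    } else {
      read_bed(features)
    }
  }
  hits <- character(nrow(regions)); nf <- integer(nrow(regions))
  if (nrow(features) > 0L && nrow(regions) > 0L) {
    q <- IRanges::IRanges(start = regions$start + 1, end = regions$end)
    s <- IRanges::IRanges(start = features$start + 1, end = features$end)
    ov <- IRanges::findOverlaps(q, s, minoverlap = 1L)
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    same <- regions$chrom[qh] == features$chrom[sh]
    qh <- qh[same]; sh <- sh[same]
    for (i in seq_len(nrow(regions))) {
      nm <- features$name[sh[qh == i]]
      hits[i] <- paste(nm, collapse = ",")
      nf[i] <- length(nm)
    }
  }
  regions$features <- hits
  regions$n_features <- nf
  regions
}
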