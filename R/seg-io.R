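#' Read a SEG file of segmented copy-number data
#'
#' Parses the tab-separated SEG dialect with header
#' `Sample Chromosome Start End Num_Probes Segment_Mean` (1-based
#' inclusive coordinates, as written by TCGA level-3 pipelines and by
#' [write_seg()]). Coordinates are converted to the internal 0-based
#' half-open convention and chromosome names normalized. Segments with
#' fewer than `min_probes` probes are dropped, following the convention
#' of selecting somatic CNV segments supported by a minimum number of
#' probes.
#'
#' @param path Path to a SEG file.
#' @param min_probes Minimum `Num_Probes` for a segment to be retained
#'   (default 5, the usual cut for array segment files).
#' @return A named list, one element per sample, each a data.frame with
#'   columns `chrom`, `start`, `end`, `n_probes`, `mean_lrr`.
#' @export
read_seg <- function(path, min_probes = 5L) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty SEG file (no header): ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  expect <- c("Sample", "Chromosome", "Start", "End", "Num_Probes",
              "Segment_Mean")
  if (length(header) < 6L || !all(tolower(header[1:6]) == tolower(expect))) {
    stop("SEG header mismatch at line 1: expected '",
         paste(expect, collapse = "\t"), "'")
  }
  out <- list()
  known <- NULL
  if (length(lines) > 1L) {
    for (i in 2:length(lines)) {
      if (!nzchar(lines[i])) next
      f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
      if (length(f) < 6L) stop("malformed SEG row at line ", i)
      start1 <- suppressWarnings(as.numeric(f[3]))
      end1 <- suppressWarnings(as.numeric(f[4]))
      np <- suppressWarnings(as.numeric(f[5]))
      mu <- suppressWarnings(as.numeric(f[6]))
      if (anyNA(c(start1, end1, np, mu))) {
        stop("malformed SEG row at line ", i, ": non-numeric field")
      }
      chrom <- normalize_chrom(f[2])
      if (!grepl("^([0-9]+|X|Y|MT?)$", chrom)) {
        warning("skipping unknown chromosome '", f[2], "' at line ", i)
        next
      }
      out[[f[1]]] <- c(out[[f[1]]], list(data.frame(
        chrom = chrom, start = start1 - 1, end = end1,
        n_probes = as.integer(np), mean_lrr = mu,
        stringsAsFactors = FALSE)))
    }
  }
  lapply(out, function(rows) {
    df <- do.call(rbind, rows)
    df <- df[df$n_probes >= min_probes, , drop = FALSE]
    rownames(df) <- NULL
    df
  })
}

# shared validation for writers: sorted, non-overlapping per chromosome
validate_track <- function(segments) {
  stopifnot(is.data.frame(segments),
            all(c("chrom", "start", "end") %in% names(segments)))
  if (any(segments$start >= segments$end)) {
    stop("segment with start >= end")
  }
  for (ch in unique(segments$chrom)) {
    s <- segments[segments$chrom == ch, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) > 1L && any(s$start[-1] < s$end[-nrow(s)])) {
      stop("overlapping segments on chromosome ", ch)
    }
  }
  invisible(TRUE)
}

#' Write segments to a SEG file
#'
#' Writes 1-based inclusive coordinates with the standard header, one
#' track per sample. Round-trips losslessly through [read_seg()].
#'
#' @param calls Named list of segment data.frames (as from [read_seg()]
#'   or [segment_lrr()]), or a single data.frame with a `sample` column
#'   (or none, in which case `sample_id` is used).
#' @param path Output path.
#' @param sample_id Sample name used when `calls` is a single unnamed
#'   data.frame.
#' @return `path`, invisibly.
#' @export
write_seg <- function(calls, path, sample_id = "sample1") {
  if (is.data.frame(calls)) {
    nm <- if ("sample" %in% names(calls)) NULL else sample_id
    if (is.null(nm)) {
      calls <- split(calls[setdiff(names(calls), "sample")], calls$sample)
    } else {
      calls <- stats::setNames(list(calls), nm)
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("Sample", "Chromosome", "Start", "End", "Num_Probes",
                     "Segment_Mean"), collapse = "\t"), con)
  for (nm in names(calls)) {
    seg <- calls[[nm]]
    if (nrow(seg) == 0L) next
    validate_track(seg)
    np <- if ("n_probes" %in% names(seg)) seg$n_probes else rep(NA, nrow(seg))
    mu <- if ("mean_lrr" %in% names(seg)) seg$mean_lrr else rep(NA, nrow(seg))
    writeLines(paste(nm, seg$chrom,
                     format(seg$start + 1, scientific = FALSE, trim = TRUE),
                     format(seg$end, scientific = FALSE, trim = TRUE),
                     np, formatC(mu, digits = 15, format = "g"),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Write regions to a BED file
#'
#' BED is 0-based half-open, matching the internal convention, so
#' coordinates are written unchanged. A fourth `name` column is taken
#' from a `name` column if present.
#'
#' @param regions Data.frame with `chrom`, `start`, `end` and optional
#'   `name`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  validate_track(regions)
  nm <- if ("name" %in% names(regions)) regions$name
        else sprintf("region_%d", seq_len(nrow(regions)))
  lines <- paste(regions$chrom,
                 format(regions$start, scientific = FALSE, trim = TRUE),
                 format(regions$end, scientific = FALSE, trim = TRUE),
                 nm, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED3+ feature file
#'
#' @param path Path to a BED file (0-based half-open; 3 or more columns,
#'   column 4 taken as the feature name when present).
#' @return Data.frame with `chrom`, `start`, `end`, `name`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), name = character(),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop("malformed BED line ", i, ": fewer than 3 fields")
    start <- suppressWarnings(as.numeric(f[2]))
    end <- suppressWarnings(as.numeric(f[3]))
    if (anyNA(c(start, end))) stop("malformed BED line ", i, ": non-numeric coordinate")
    data.frame(chrom = normalize_chrom(f[1]), start = start, end = end,
               name = if (length(f) >= 4L) f[4] else paste0("feature_", i),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
}
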