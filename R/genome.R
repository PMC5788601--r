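#' Build a validated genome coordinate model
#'
#' A `genome_model` holds ordered chromosomes with lengths, centromere
#' positions splitting each chromosome into a p and a q arm, and named
#' loci. All coordinates are 0-based, half-open base pairs.
#'
#' @param config A list (or path to a YAML file) with elements
#'   `chromosomes` — a list of `list(name=, length=, centromere=)` — and
#'   `loci` — a named list of `list(chrom=, start=, end=)`.
#' @return An object of class `genome_model` with elements `chromosomes`
#'   (data.frame: name, length, centromere), and `loci`
#'   (data.frame: name, chrom, start, end).
#' @examples
#' gm <- build_genome_model(desk_genome_config())
#' arm_range(gm, "1q")
#' @export
build_genome_model <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config), !is.null(config$chromosomes))
  chrs <- do.call(rbind, lapply(config$chromosomes, function(ch) {
    stopifnot(!is.null(ch$name), !is.null(ch$length), !is.null(ch$centromere))
    data.frame(name = normalize_chrom(ch$name),
               length = as.numeric(ch$length),
               centromere = as.numeric(ch$centromere),
               stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(chrs$name)) {
    stop("duplicated chromosome names in genome config")
  }
  bad <- chrs$centromere <= 0 | chrs$centromere >= chrs$length
  if (any(bad)) {
    stop("centromere not strictly inside (0, length) for chromosome(s): ",
         paste(chrs$name[bad], collapse = ", "))
  }
  loci <- config$loci
  if (is.null(loci) || length(loci) == 0L) {
    loci_df <- data.frame(name = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          stringsAsFactors = FALSE)
  } else {
    loci_df <- do.call(rbind, lapply(names(loci), function(nm) {
      lc <- loci[[nm]]
      data.frame(name = nm, chrom = normalize_chrom(lc$chrom),
                 start = as.numeric(lc$start), end = as.numeric(lc$end),
                 stringsAsFactors = FALSE)
    }))
    for (i in seq_len(nrow(loci_df))) {
      li <- loci_df[i, ]
      j <- match(li$chrom, chrs$name)
      if (is.na(j)) {
        stop("locus '", li$name, "' placed on unknown chromosome ", li$chrom)
      }
      if (li$start < 0 || li$end > chrs$length[j] || li$start >= li$end) {
        stop("locus '", li$name, "' interval [", li$start, ", ", li$end,
             ") does not lie within chromosome ", li$chrom)
      }
    }
  }
  structure(list(chromosomes = chrs, loci = loci_df), class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat("genome_model:", nrow(x$chromosomes), "chromosomes,",
      format(sum(x$chromosomes$length), big.mark = ","), "bp,",
      nrow(x$loci), "named loci\n")
  invisible(x)
}

#' Desk-scale mini-genome configuration
#'
#' Six chromosomes totalling 300 Mb, with analogues of chromosomes
#' 1, 5, 9 and 17 (the chromosomes carrying the recurrent alterations:
#' 1q duplication, 5p/TERT duplication, 9q loss, 17 gain in metastases)
#' plus two filler autosomes. TERT sits on the 5p analogue.
#'
#' @return A config list accepted by [build_genome_model()].
#' @export
desk_genome_config <- function() {
  list(
    chromosomes = list(
      list(name = "1",  length = 60e6, centromere = 30e6),
      list(name = "2",  length = 60e6, centromere = 30e6),
      list(name = "3",  length = 50e6, centromere = 22e6),
      list(name = "5",  length = 50e6, centromere = 25e6),
      list(name = "9",  length = 50e6, centromere = 20e6),
      list(name = "17", length = 30e6, centromere = 10e6)
    ),
    loci = list(
      TERT = list(chrom = "5", start = 1.25e6, end = 1.30e6)
    )
  )
}

#' hg19-like genome configuration
#'
#' The 22 autosomes plus X and Y with approximate hg19 lengths and
#' centromere midpoints, and the TERT locus at its hg19 position on 5p.
#' Intended for full-scale runs; coordinates are rounded to 0.1 Mb and
#' are not a substitute for a real assembly index.
#'
#' @return A config list accepted by [build_genome_model()].
#' @export
hg19_genome_config <- function() {
  len <- c(249.3, 243.2, 198.0, 191.2, 180.9, 171.1, 159.1, 146.4,
           141.2, 135.5, 135.0, 133.9, 115.2, 107.3, 102.5, 90.4,
           81.2, 78.1, 59.1, 63.0, 48.1, 51.3, 155.3, 59.4) * 1e6
  cen <- c(125.0, 93.3, 91.0, 50.4, 48.4, 61.0, 59.9, 45.6,
           49.0, 40.2, 53.7, 35.8, 17.9, 17.6, 19.0, 36.6,
           24.0, 17.2, 26.5, 27.5, 13.2, 14.7, 60.6, 12.5) * 1e6
  nm <- c(as.character(1:22), "X", "Y")
  list(
    chromosomes = lapply(seq_along(nm), function(i)
      list(name = nm[i], length = len[i], centromere = cen[i])),
    loci = list(
      TERT = list(chrom = "5", start = 1253287, end = 1295162)
    )
  )
}

#' Normalize chromosome names to "1".."22", "X", "Y"
#'
#' Strips a leading "chr" prefix and converts 23/24 to X/Y, so mixed
#' dialects (as in TCGA SEG files) compare equal.
#' @param x Character vector of chromosome names.
#' @return Normalized character vector.
#' @export
normalize_chrom <- function(x) {
  x <- sub("^chr", "", as.character(x), ignore.case = TRUE)
  x[x == "23"] <- "X"
  x[x == "24"] <- "Y"
  x
}

#' Coordinates of a chromosome arm
#'
#' @param genome A `genome_model`.
#' @param arm Arm id such as `"1q"` or `"5p"`.
#' @return Numeric `c(start, end)` in 0-based half-open coordinates.
#' @export
arm_range <- function(genome, arm) {
  m <- regmatches(arm, regexec("^(.+)([pq])$", arm))[[1]]
  if (length(m) != 3L) stop("malformed arm id: ", arm)
  chrom <- normalize_chrom(m[2])
  j <- match(chrom, genome$chromosomes$name)
  if (is.na(j)) stop("unknown chromosome in arm id: ", arm)
  cen <- genome$chromosomes$centromere[j]
  if (m[3] == "p") c(0, cen) else c(cen, genome$chromosomes$length[j])
}

#' Autosome names of a genome model
#' @param genome A `genome_model`.
#' @return Character vector of chromosome names excluding X and Y.
#' @export
autosomes <- function(genome) {
  setdiff(genome$chromosomes$name, c("X", "Y"))
}

#' Lay a jittered-uniform probe grid over a genome
#'
#' Probes are placed at roughly `mean_spacing` intervals with uniform
#' jitter of up to +/- 40% of the spacing, mimicking the irregular
#' spacing of SNP-array probe sets. Reproducible under `seed`.
#'
#' @param genome A `genome_model`.
#' @param mean_spacing Mean inter-probe distance in bp (default 10 kb).
#' @param seed Integer seed.
#' @return A `probe_grid`: list with parallel vectors `chrom` and `pos`
#'   (sorted within chromosome), `n` total probes, and the `genome`.
#' @export
make_probe_grid <- function(genome, mean_spacing = 10e3, seed = 1L) {
  stopifnot(inherits(genome, "genome_model"))
  if (!is.numeric(mean_spacing) || mean_spacing <= 0) {
    stop("mean_spacing must be > 0")
  }
  if (mean_spacing > min(genome$chromosomes$length)) {
    stop("mean_spacing exceeds the smallest chromosome length")
  }
  withr::with_seed(as.integer(seed), {
    chrom <- character(0); pos <- numeric(0)
    for (j in seq_len(nrow(genome$chromosomes))) {
      L <- genome$chromosomes$length[j]
      k <- floor(L / mean_spacing)
      centers <- (seq_len(k) - 0.5) * mean_spacing
      p <- centers + stats::runif(k, -0.4, 0.4) * mean_spacing
      p <- sort(round(p))
      # jitter is < spacing/2 on each side so ties are the only hazard
      dup <- duplicated(p)
      p[dup] <- p[dup] + 1
      p <- pmin(pmax(p, 0), L - 1)
      chrom <- c(chrom, rep(genome$chromosomes$name[j], k))
      pos <- c(pos, p)
    }
    structure(list(chrom = chrom, pos = pos, n = length(pos),
                   genome = genome),
              class = "probe_grid")
  })
}

#' @export
print.probe_grid <- function(x, ...) {
  cat("probe_grid:", x$n, "probes on",
      length(unique(x$chrom)), "chromosomes\n")
  invisible(x)
}

# Indices of a grid's probes on one chromosome (contiguous by construction).
grid_idx <- function(grid, chrom) which(grid$chrom == chrom)

# Indices of probes falling in [start, end) on chrom.
grid_probes_in <- function(grid, chrom, start, end) {
  which(grid$chrom == chrom & grid$pos >= start & grid$pos < end)
}
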