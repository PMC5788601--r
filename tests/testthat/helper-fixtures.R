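# Shared fixtures built in code; kept small so the default run stays fast.

desk_model <- function() build_genome_model(desk_genome_config())

# coarse grid (50 kb spacing, 6000 probes) for tests that loop over seeds
coarse_grid <- function(seed = 1L) {
  make_probe_grid(desk_model(), mean_spacing = 5e4, seed = seed)
}

# standard grid matching the pipeline default
fine_grid <- function(seed = 1L) {
  make_probe_grid(desk_model(), mean_spacing = 1e4, seed = seed)
}

# one-chromosome toy genome for segmentation unit tests
toy_genome <- function(len = 50e6, cen = round(0.4 * len)) {
  build_genome_model(list(
    chromosomes = list(list(name = "1", length = len, centromere = cen)),
    loci = list()))
}

toy_grid <- function(n_probes = 2000, len = 50e6, seed = 1L) {
  make_probe_grid(toy_genome(len), mean_spacing = len / n_probes, seed = seed)
}

# profile with given per-probe LRR on a toy grid (BAF balanced het)
profile_from_lrr <- function(lrr, grid) {
  structure(list(grid = grid, lrr = lrr,
                 baf = rep(0.5, grid$n), het = rep(TRUE, grid$n),
                 truth_class = rep("neutral", grid$n)),
            class = "sample_profile")
}

# independent changepoint oracle: exact least-squares single changepoint
ls_changepoint <- function(x) {
  n <- length(x)
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  k <- seq_len(n - 1)
  sse <- (cs2[k] - cs[k]^2 / k) +
    ((cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k))
  which.min(sse)  # last index of the left segment
}

# windowed LS-changepoint check: TRUE when the boundary between probe
# `bp - 1` and `bp` (absolute index) is within `tol` probes of the exact
# least-squares changepoint computed on the same data around it
boundary_matches_oracle <- function(lrr, chrom_idx, bp, tol = 5,
                                    half_window = 30) {
  lo <- max(min(chrom_idx), bp - half_window)
  hi <- min(max(chrom_idx), bp + half_window - 1)
  k <- ls_changepoint(lrr[lo:hi])
  abs((lo + k - 1) - (bp - 1)) <= tol
}

# independent two-sided Fisher oracle by hypergeometric enumeration
fisher_enum <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0L, c1 - (n - r1)); hi <- min(r1, c1)
  support <- lo:hi
  pr <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}
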