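# Build a minimal call-track list on a grid: `carriers` of the event get
# one altered segment, everyone else an empty track.
toy_tracks <- function(grid, n, carriers, start, end, lrr, chrom = "1") {
  lapply(seq_len(n), function(i) {
    if (i %in% carriers) {
      classify_segments(data.frame(chrom = chrom, start = start, end = end,
                                   n_probes = 10L, mean_lrr = lrr))
    } else {
      classify_segments(data.frame(chrom = character(), start = numeric(),
                                   end = numeric(), n_probes = integer(),
                                   mean_lrr = numeric()))
    }
  })
}

test_that("frequency tracks count class-set membership per probe", {
  grid <- toy_grid(500, len = 5e6)
  tracks <- list(
    A = toy_tracks(grid, 10, 1:4, 1e6, 2e6, 0.3),
    B = toy_tracks(grid, 5, integer(0), 0, 1, 0))
  ft <- frequency_tracks(tracks, grid, "gain")
  inside <- grid$pos >= 1e6 & grid$pos < 2e6
  expect_true(all(ft$counts$A[inside] == 4))
  expect_true(all(ft$freq$A[inside] == 0.4))
  expect_true(all(ft$counts$A[!inside] == 0))
  # an amplification counts toward gains too
  tracks$A[[1]]$mean_lrr <- 0.9
  tracks$A[[1]] <- classify_segments(tracks$A[[1]])
  ft2 <- frequency_tracks(tracks, grid, "gain")
  expect_identical(ft2$counts$A, ft$counts$A)
  # but not toward losses
  ft3 <- frequency_tracks(tracks, grid, "loss")
  expect_true(all(ft3$counts$A == 0))
  expect_error(frequency_tracks(list(A = list(), B = tracks$B), grid, "gain"),
               "empty group")
})

test_that("compare_groups reports a planted differential region", {
  grid <- toy_grid(2000, len = 20e6)
  # 40% of 34 DMs vs ~3% of 61 controls over a 5 Mb plant
  tracks <- list(
    dm = toy_tracks(grid, 34, 1:14, 5e6, 10e6, 0.3),
    control = toy_tracks(grid, 61, 1:2, 5e6, 10e6, 0.3))
  res <- compare_groups(frequency_tracks(tracks, grid, "gain"))
  expect_equal(nrow(res$regions), 1L)
  expect_lte(res$regions$start, 5.1e6)
  expect_gte(res$regions$end, 9.9e6)
  expect_equal(res$regions$freq_a, 14 / 34)

  # 40% vs 30%: fails the minimum frequency difference
  tracks2 <- list(
    dm = toy_tracks(grid, 40, 1:16, 5e6, 10e6, 0.3),
    control = toy_tracks(grid, 40, 1:12, 5e6, 10e6, 0.3))
  res2 <- compare_groups(frequency_tracks(tracks2, grid, "gain"))
  expect_equal(nrow(res2$regions), 0L)

  # 20% in one group only: differential (reported as a region) but
  # below the 25% aggregate-calling threshold in the overall sample
  tracks3 <- list(
    dm = toy_tracks(grid, 100, 1:20, 5e6, 10e6, 0.3),
    control = toy_tracks(grid, 100, 1:20, 12e6, 17e6, 0.3))
  res3 <- compare_groups(frequency_tracks(tracks3, grid, "gain"))
  expect_equal(nrow(res3$regions), 2L)
  inside <- res3$probes$pos >= 5e6 & res3$probes$pos < 10e6
  expect_true(all(!res3$probes$aggregate_call[inside]))
  # raising the frequency in one group above the threshold flags the
  # aggregate call
  tracks4 <- list(
    dm = toy_tracks(grid, 100, 1:30, 5e6, 10e6, 0.3),
    control = toy_tracks(grid, 100, integer(0), 0, 1, 0))
  res4 <- compare_groups(frequency_tracks(tracks4, grid, "gain"))
  expect_true(all(res4$probes$aggregate_call[inside]))
})

test_that("null comparisons control the FDR and regions ignore sample order", {
  grid <- toy_grid(400, len = 4e6)
  frac_flagged <- vapply(1:40, function(s) {
    withr::with_seed(3000 + s, {
      tracks <- list(
        A = toy_tracks(grid, 30, which(runif(30) < 0.2), 1e6, 3e6, 0.3),
        B = toy_tracks(grid, 30, which(runif(30) < 0.2), 1e6, 3e6, 0.3))
      res <- compare_groups(frequency_tracks(tracks, grid, "gain"))
      mean(res$probes$adj_p < 0.05)
    })
  }, 0)
  expect_lte(mean(frac_flagged), 0.05)

  tracks <- list(
    dm = toy_tracks(grid, 20, 1:8, 1e6, 3e6, 0.3),
    control = toy_tracks(grid, 20, 1:2, 1e6, 3e6, 0.3))
  r1 <- compare_groups(frequency_tracks(tracks, grid, "gain"))
  tracks_perm <- list(dm = rev(tracks$dm), control = tracks$control)
  r2 <- compare_groups(frequency_tracks(tracks_perm, grid, "gain"))
  expect_identical(r1$regions, r2$regions)
})

test_that("annotate_regions lists overlapping features", {
  regions <- data.frame(chrom = "1", start = 2e6, end = 5e6)
  feats <- data.frame(chrom = c("1", "1", "1", "1", "2"),
                      start = c(1e6, 2.5e6, 4.9e6, 6e6, 2e6),
                      end = c(1.5e6, 3e6, 5.5e6, 7e6, 3e6),
                      name = c("gA", "gB", "gC", "gD", "gE"))
  ann <- annotate_regions(regions, feats)
  expect_equal(ann$n_features, 2L)
  expect_setequal(strsplit(ann$features, ",")[[1]], c("gB", "gC"))

  bed <- withr::local_tempfile(fileext = ".bed")
  write_bed(feats[order(feats$chrom, feats$start), ], bed)
  ann2 <- annotate_regions(regions, bed)
  expect_equal(ann2$n_features, 2L)

  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "1\tsrc\tgene\t2500001\t3000000\t.\t+\t.\tID=gB",
               "1\tsrc\tgene\t6000001\t7000000\t.\t+\t.\tName=gD"), gff)
  ann3 <- annotate_regions(regions, gff)
  expect_equal(ann3$features, "gB")

  badgff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", "1\tsrc\tgene\ttoo\tfew"), badgff)
  expect_error(annotate_regions(regions, badgff), "line 2")

  none <- annotate_regions(data.frame(chrom = "9", start = 0, end = 1e6),
                           feats)
  expect_equal(none$n_features, 0L)
  empty <- annotate_regions(regions,
                            data.frame(chrom = character(),
                                       start = numeric(), end = numeric(),
                                       name = character()))
  expect_equal(empty$n_features, 0L)
})
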