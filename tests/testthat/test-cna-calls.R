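test_that("classification maps mean LRR to the calling bands", {
  seg <- data.frame(chrom = "1", start = (0:6) * 1e6, end = (0:6) * 1e6 + 1e5,
                    n_probes = 10L,
                    mean_lrr = c(0.3, 0.8, -0.2, -1.2, 0.05, 0.1, 0.7))
  cls <- classify_segments(seg)$class
  expect_equal(cls, c("dup", "amp", "del", "homdel", "neutral",
                      "neutral",  # 0.1 is not > 0.1
                      "dup"))     # 0.7 is not > 0.7
  # exhaustive over a fine sweep: classes are mutually exclusive
  sweep <- data.frame(chrom = "1", start = 0, end = 1,
                      mean_lrr = seq(-2, 2, by = 0.01))
  cls2 <- classify_segments(sweep)$class
  expect_true(all(cls2 %in% c("dup", "amp", "del", "homdel", "neutral")))
  expect_error(calling_thresholds(dup_low = 0.8, amp_low = 0.7), "satisfy")
})

test_that("burden reports planted fractions and is additive", {
  gm <- desk_model()
  total <- sum(gm$chromosomes$length)
  L <- 0.1 * total
  track <- data.frame(
    chrom = c("1", "2", "2"),
    start = c(0, 0, 30e6), end = c(L, 20e6, 30e6 + 20e6),
    n_probes = 100L, mean_lrr = c(0.3, 0.3, -0.4))
  track <- classify_segments(track)
  b <- burden(track, gm, covered_length = total)
  expect_equal(b$relative_length_pct[b$class == "dup"],
               100 * (L + 20e6) / total)
  expect_equal(b$relative_length_pct[b$class == "del"], 100 * 20e6 / total)
  # additivity: total equals the sum of the classes
  expect_equal(b$relative_length_pct[b$class == "total"],
               sum(b$relative_length_pct[b$class != "total"]))
  expect_equal(b$n_events[b$class == "total"], 3L)

  neutral <- classify_segments(data.frame(
    chrom = "1", start = 0, end = 1e6, n_probes = 10L, mean_lrr = 0))
  b0 <- burden(neutral, gm)
  expect_true(all(b0$relative_length_pct == 0))
  expect_error(burden(track, gm, covered_length = 0), "covered_length")
})

test_that("burden is preserved through a SEG round-trip", {
  grid <- coarse_grid()
  plan <- alteration_plan(data.frame(chrom = c("1", "9"),
                                     start = c(30e6, 20e6),
                                     end = c(60e6, 50e6),
                                     class = c("dup", "del")))
  pr <- simulate_profile(plan, grid, noise_model(), seed = 21)
  ct <- classify_segments(segment_lrr(pr))
  path <- withr::local_tempfile(fileext = ".seg")
  write_seg(ct[c("chrom", "start", "end", "n_probes", "mean_lrr")], path)
  back <- classify_segments(read_seg(path, min_probes = 1)$sample1)
  gm <- grid$genome
  expect_equal(burden(ct, gm), burden(back, gm), tolerance = 1e-9)
})

test_that("arm flags follow the coverage rule and locus flags 1 bp overlap", {
  gm <- desk_model()
  mk <- function(start, end, lrr, chrom = "1") classify_segments(
    data.frame(chrom = chrom, start = start, end = end, n_probes = 100L,
               mean_lrr = lrr))
  # 1q is 30-60 Mb; 80% coverage -> flag, 20% -> no flag
  expect_true(arm_flag(mk(32e6, 56e6, 0.3), gm, "1q"))
  expect_false(arm_flag(mk(32e6, 38e6, 0.3), gm, "1q"))
  # deletions do not trigger the gain flag
  expect_false(arm_flag(mk(30e6, 60e6, -0.4), gm, "1q"))
  expect_true(arm_flag(mk(30e6, 60e6, -0.4), gm, "1q",
                       classes = c("del", "homdel")))
  empty <- classify_segments(data.frame(chrom = character(),
                                        start = numeric(), end = numeric(),
                                        n_probes = integer(),
                                        mean_lrr = numeric()))
  expect_false(arm_flag(empty, gm, "1q"))
  expect_error(arm_flag(mk(0, 1e6, 0.3), gm, "7q"), "unknown chromosome")

  # TERT locus on 5p: whole-arm dup overlaps, 5q dup does not
  expect_true(locus_flag(mk(0, 25e6, 0.3, "5"), gm, "TERT"))
  expect_false(locus_flag(mk(25e6, 50e6, 0.3, "5"), gm, "TERT"))
  # amplification counts as a gain
  expect_true(locus_flag(mk(1.0e6, 1.4e6, 0.9, "5"), gm, "TERT"))
  expect_error(locus_flag(mk(0, 1e6, 0.3), gm, "NOPE"), "unknown locus")
})

test_that("segmentation plus calling recovers planted classes", {
  # events of >= 50 probes across classes, over several seeds
  n_events <- 0L; n_correct <- 0L; bp_err <- integer(0)
  for (s in 1:8) {
    grid <- coarse_grid()
    plan <- alteration_plan(data.frame(
      chrom = c("1", "2", "3", "9", "17"),
      start = c(30e6, 10e6, 40e6, 20e6, 5e6),
      end = c(60e6, 14e6, 47e6, 50e6, 8.5e6),
      class = c("dup", "amp", "homdel", "del", "dup")))
    pr <- simulate_profile(plan, grid, noise_model(), seed = 700 + s)
    ct <- classify_segments(segment_lrr(wave_correct(pr)))
    for (i in seq_len(nrow(plan$events))) {
      ev <- plan$events[i, ]
      n_events <- n_events + 1L
      hit <- ct$chrom == ev$chrom & ct$class == ev$class &
        pmin(ct$end, ev$end) - pmax(ct$start, ev$start) >
          0.8 * (ev$end - ev$start)
      if (any(hit)) {
        n_correct <- n_correct + 1L
        truth_first <- min(thyt1:::grid_probes_in(grid, ev$chrom,
                                                  ev$start, ev$end))
        bp_err <- c(bp_err, abs(ct$first_probe[which(hit)[1]] - truth_first))
      }
    }
  }
  expect_gte(n_correct / n_events, 0.95)
  expect_true(all(bp_err <= 5))
})
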