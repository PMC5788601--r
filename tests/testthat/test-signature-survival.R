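test_that("THYT1 scoring distinguishes positive, negative and indeterminate", {
  expect_equal(score_thyt1(TRUE, FALSE, FALSE),
               list(status = "positive", n_alterations = 1))
  expect_equal(score_thyt1(FALSE, FALSE, FALSE)$status, "negative")
  expect_equal(score_thyt1(TRUE, TRUE, TRUE),
               list(status = "positive", n_alterations = 3))
  # no positive flag + any missing flag -> indeterminate, not negative
  expect_equal(score_thyt1(FALSE, NA, FALSE)$status, "indeterminate")
  expect_equal(score_thyt1(NA, NA, NA)$status, "indeterminate")
  # a positive flag decides even with missing companions
  expect_equal(score_thyt1(NA, TRUE, NA)$status, "positive")

  # monotone: adding a TRUE flag never flips positive -> negative
  vals <- list(TRUE, FALSE, NA)
  for (a in vals) for (b in vals) for (d in vals) {
    base <- score_thyt1(a, b, d)$status
    for (slot in 1:3) {
      args <- list(a, b, d); args[[slot]] <- TRUE
      upgraded <- do.call(score_thyt1, args)$status
      expect_identical(upgraded, "positive")
      if (base == "positive") expect_identical(upgraded, base)
    }
  }
})

test_that("variant-support filter applies reads, fraction and strand rules", {
  rec <- function(supp, tot, fwd = TRUE, rev = TRUE) {
    data.frame(gene = "G", variant = "v", supporting = supp, total = tot,
               forward = fwd, reverse = rev)
  }
  expect_equal(nrow(filter_variants(rec(9, 90))), 0)    # 9 reads, 10%
  expect_equal(nrow(filter_variants(rec(12, 300))), 0)  # 12 reads, 4%
  expect_equal(nrow(filter_variants(rec(12, 200))), 1)  # 12 reads, 6%
  expect_equal(nrow(filter_variants(rec(12, 200, rev = FALSE))), 0)
  expect_equal(nrow(filter_variants(rec(12, 200, rev = FALSE),
                                    require_both_strands = FALSE)), 1)
  # boundary: exactly 10 reads and exactly 5% are kept
  expect_equal(nrow(filter_variants(rec(10, 200))), 1)
  expect_error(filter_variants(rec(0, 0)), "zero total")
  expect_error(filter_variants(rec(30, 20)), "exceed")
})

test_that("MSI classification follows the 30% rule on a 13-marker panel", {
  expect_equal(classify_msi(simulate_msi_panel(13, 0)), "MSS")
  expect_equal(classify_msi(simulate_msi_panel(13, 1)), "MSI-L")  # 7.7%
  expect_equal(classify_msi(simulate_msi_panel(13, 3)), "MSI-L")  # 23%
  expect_equal(classify_msi(simulate_msi_panel(13, 4)), "MSI-H")  # 30.8%
  expect_equal(classify_msi(4, n_markers = 13), "MSI-H")
  # >= on the threshold: exactly 30% is MSI-H
  expect_equal(classify_msi(3, n_markers = 10), "MSI-H")
  expect_error(classify_msi(logical(0)), "empty")
})

test_that("fisher and chi-square wrappers validate tables", {
  t1 <- matrix(c(2, 0, 0, 2), 2, byrow = TRUE)
  expect_equal(fisher_exact_2x2(t1), 1 / 3, tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(c(21, 12, 3, 56), 2, byrow = TRUE)),
               1.5e-9, tolerance = 0.05)
  expect_error(fisher_exact_2x2(matrix(c(0, 0, 3, 5), 2)), "zero margin")

  even <- matrix(c(10, 10, 10, 10), 2)
  cs <- chi_square_2x2(even)
  expect_equal(cs$statistic, 0)
  expect_equal(cs$p, 1)
  # closed form sum (O-E)^2/E for the diagonal table
  diag40 <- matrix(c(20, 0, 0, 20), 2)
  expect_equal(chi_square_2x2(diag40, yates = FALSE)$statistic, 40)
  expect_gte(chi_square_2x2(diag40, yates = TRUE)$statistic, 0)
})

test_that("fisher p equals hypergeometric enumeration over small tables", {
  # spot grid of margins; the exhaustive N <= 40 sweep runs in acceptance
  set.seed(8)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    a <- sample(0:n, 1); b <- sample(0:(n - a), 1)
    c_ <- sample(0:(n - a - b), 1); d <- n - a - b - c_
    tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_2x2(tab), fisher_enum(a, b, c_, d),
                 tolerance = 1e-9)
  }
})

test_that("KM estimate matches hand-computed product limits", {
  three <- data.frame(time_months = 1:3, event = 1)
  km <- km_estimate(three)
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  expect_true(all(diff(km$surv) <= 0))

  censored <- data.frame(time_months = c(2, 4, 6), event = 0)
  expect_true(all(km_estimate(censored)$surv == 1))

  # ties: 2 deaths at t=1 among 4 at risk
  tied <- data.frame(time_months = c(1, 1, 5, 7), event = c(1, 1, 0, 1))
  expect_equal(km_estimate(tied)$surv[1], 0.5)

  # with no censoring KM equals the empirical survival function
  set.seed(2)
  tt <- rexp(40) + 0.1
  km2 <- km_estimate(data.frame(time_months = tt, event = 1))
  expect_equal(km2$surv, 1 - ecdf(tt)(km2$time))
  expect_error(km_estimate(data.frame(time_months = c(1, 0), event = 1)),
               "non-positive")
})

test_that("log-rank behaves under identity, symmetry and power", {
  same <- data.frame(time_months = rep(c(1, 3, 5, 8), 2),
                     event = rep(c(1, 0, 1, 1), 2))
  lr <- logrank_test(same, rep(c("a", "b"), each = 4))
  expect_equal(lr$statistic, 0, tolerance = 1e-9)

  set.seed(31)
  d <- data.frame(time_months = rexp(60) + 0.1,
                  event = rbinom(60, 1, 0.7))
  grp <- rep(c("x", "y"), 30)
  swapped <- ifelse(grp == "x", "y", "x")
  expect_equal(logrank_test(d, grp)$statistic,
               logrank_test(d, swapped)$statistic)
  expect_error(logrank_test(d, rep("x", 60)), "2 groups")

  # power at the study hazard ratio: p < 0.05 in >= 90% of seeds
  hits <- vapply(1:60, function(s) {
    cfg <- cohort_config(n_dm = 50, n_control = 50, hazard_ratio = 7.29,
                         baseline_hazard = 0.002, seed = 5000 + s)
    co <- simulate_cohort(cfg, keep_profiles = FALSE)
    sam <- co$samples
    if (length(unique(sam$truth_thyt1)) < 2 || sum(sam$event) < 1) {
      return(NA)
    }
    logrank_test(sam, sam$truth_thyt1)$p < 0.05
  }, NA)
  expect_gte(mean(hits, na.rm = TRUE), 0.9)
})

test_that("cox_fit matches a direct partial-likelihood maximization", {
  # four deaths, alternating binary covariate, no ties: the partial
  # likelihood is explicit; maximize it on a grid as the oracle
  toy <- data.frame(time_months = 1:4, event = 1, x = c(1, 0, 1, 0))
  grid_b <- seq(-5, 5, by = 1e-4)
  logpl <- function(b) {
    2 * b - log(2 * exp(b) + 2) - log(exp(b) + 2) - log(exp(b) + 1)
  }
  oracle_b <- grid_b[which.max(logpl(grid_b))]
  fit <- cox_fit(toy, "x")
  expect_equal(fit$coef, oracle_b, tolerance = 1e-3)
  expect_equal(fit$hr, exp(oracle_b), tolerance = 1e-3)

  # sign agreement with the log-rank direction for a binary covariate
  set.seed(44)
  d <- data.frame(time_months = c(rexp(30, 1), rexp(30, 0.3)) + 0.05,
                  event = 1, x = rep(c(1, 0), each = 30))
  fit2 <- cox_fit(d, "x")
  expect_gt(fit2$coef, 0)  # x = 1 has higher hazard
  expect_lt(fit2$p, 0.05)

  expect_error(cox_fit(data.frame(time_months = 1:4, event = c(1, 1, 0, 0),
                                  z = 0), "z"), "constant covariate")
  expect_error(cox_fit(d, "nope"), "unknown covariate")
  # breslow ties give a (slightly) different estimate than efron
  tied <- data.frame(time_months = rep(c(1, 2, 3), each = 4),
                     event = rbinom(12, 1, 0.8),
                     x = rep(c(0, 1), 6))
  fe <- cox_fit(tied, "x", ties = "efron")
  fb <- cox_fit(tied, "x", ties = "breslow")
  expect_false(identical(fe$coef, fb$coef))
})

test_that("cox recovers the generator's hazard ratio", {
  fits <- vapply(1:30, function(s) {
    cfg <- cohort_config(n_dm = 120, n_control = 120, hazard_ratio = 7.29,
                         baseline_hazard = 0.002, seed = 7000 + s)
    sam <- simulate_cohort(cfg, keep_profiles = FALSE)$samples
    sam$x <- as.numeric(sam$truth_thyt1)
    fit <- cox_fit(sam, "x")
    c(fit$coef, fit$se)
  }, numeric(2))
  covered <- abs(fits[1, ] - log(7.29)) <= 3 * fits[2, ]
  expect_gte(mean(covered), 0.9)
})

test_that("contingency report reproduces feature tables", {
  flags <- data.frame(
    group = rep(c("dm", "control"), c(34, 61)),
    feat = c(rep(TRUE, 12), rep(FALSE, 22), rep(TRUE, 2), rep(FALSE, 59)))
  rep1 <- contingency_report(flags, "feat")
  expect_equal(rep1$pos_case, 12)
  expect_equal(rep1$n_control, 61)
  expect_equal(rep1$fisher_p,
               fisher_exact_2x2(matrix(c(12, 22, 2, 59), 2, byrow = TRUE)))
  # missing values reduce the assessed denominator
  flags$feat[1:2] <- NA
  rep2 <- contingency_report(flags, "feat")
  expect_equal(rep2$n_case, 32)
})
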