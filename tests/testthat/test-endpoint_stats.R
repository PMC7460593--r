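# The F-then-t comparison procedure and the endpoint summaries.

test_that("pooled t-test branch reproduces the hand-computed example", {
  cr <- compare_groups(c(1, 2, 3), c(5, 6, 7))
  expect_true(cr$equal_variance_assumed)
  expect_equal(abs(cr$t_statistic), 4.899, tolerance = 1e-3)
  expect_equal(cr$df, 4)
  expect_equal(cr$p_t, 0.008, tolerance = 0.05)
  expect_true(cr$significant)
})

test_that("identical samples give t = 0, p = 1, not significant", {
  cr <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(cr$t_statistic, 0)
  expect_equal(cr$p_t, 1)
  expect_false(cr$significant)
})

test_that("a gross variance difference selects the Welch branch", {
  x <- c(1, 2, 3)
  y <- 2 + (c(1, 2, 3) - 2) * 100   # same mean, x100 spread
  cr <- compare_groups(x, y)
  # brute-force check of the gate: two-sided F p-value under 0.05
  f <- var(y) / var(x)
  expect_lt(min(2 * pf(f, 2, 2, lower.tail = FALSE), 1), 0.05)
  expect_false(cr$equal_variance_assumed)
  # the F branch decision is invariant to swapping the groups
  cr_swap <- compare_groups(y, x)
  expect_equal(cr_swap$equal_variance_assumed, cr$equal_variance_assumed)
  expect_equal(cr_swap$f_statistic, cr$f_statistic)
  expect_equal(cr_swap$p_f, cr$p_f)
})

test_that("the F-test p-value agrees with the base variance-ratio test", {
  set.seed(23)
  for (i in 1:50) {
    x <- rnorm(sample(3:8, 1)); y <- rnorm(sample(3:8, 1), sd = runif(1, 0.5, 3))
    expect_equal(compare_groups(x, y)$p_f, var.test(x, y)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("rejections agree in direction with a permutation oracle", {
  set.seed(11)
  agree_when_clear <- TRUE
  for (i in 1:100) {
    shift <- sample(c(0, 3), 1)
    x <- rnorm(6)
    y <- rnorm(6) + shift
    p_t <- compare_groups(x, y)$p_t
    p_perm <- permutation_p(x, y)
    # compare rejection direction away from the boundary
    if (min(p_t, p_perm) < 0.02 && max(p_t, p_perm) > 0.15) {
      agree_when_clear <- FALSE
    }
  }
  expect_true(agree_when_clear)
})

test_that("degenerate comparison inputs are errors", {
  expect_error(compare_groups(1, c(1, 2)), "at least 2")
  expect_error(compare_groups(c(2, 2), c(3, 3)), "zero variance")
})

test_that("micronucleus summary counts cells and frequencies correctly", {
  counts <- c(rep(0, 380), rep(1, 16), rep(2, 4))
  s <- mn_summary(counts)
  expect_equal(s$total_bnc, 400)
  expect_equal(s$total_mn, 24)
  expect_equal(s$bnc_with_mn, 20)
  expect_equal(s$pct_bnc_with_mn, 5.0)
  expect_equal(s$mn_frequency, 0.06)
  # 400 BNC with 12 MN -> frequency 0.03
  expect_equal(mn_summary(c(rep(1, 12), rep(0, 388)))$mn_frequency, 0.03)
  z <- mn_summary(rep(0, 50))
  expect_equal(z$mn_frequency, 0)
  expect_equal(z$pct_bnc_with_mn, 0)
  expect_error(mn_summary(numeric(0)), "scored")
})

test_that("MN frequency always dominates the fraction of MN-bearing cells", {
  set.seed(4)
  for (i in 1:50) {
    counts <- rpois(200, runif(1, 0.01, 2))
    s <- mn_summary(counts)
    expect_gte(s$mn_frequency, s$pct_bnc_with_mn / 100)
  }
})

test_that("control subtraction keeps and flags negative excesses", {
  expect_equal(as.numeric(control_subtracted(15, 5)), 10)
  r <- control_subtracted(c(4, 15), 5)
  expect_equal(as.numeric(r), c(-1, 10))
  expect_equal(attr(r, "flagged_negative"), 1L)
  expect_equal(as.numeric(control_subtracted(c(7, 9), 0)), c(7, 9))
  expect_error(control_subtracted(c(1, 2, 3), c(1, 2)), "labels")
})

test_that("endpoint summaries give per-condition sample means and SDs", {
  m <- data.frame(endpoint = "foci_per_nucleus", mode = "PBS", position = 1,
                  dose = 1, time_h = 0, run = 1:2, replicate = 1,
                  value = c(10, 14))
  s <- summarize_endpoint(m)
  expect_equal(s$mean, 12)
  expect_equal(s$sd, sd(c(10, 14)))
  expect_equal(s$sd, 2.83, tolerance = 1e-3)
  single <- summarize_endpoint(m[1, ])
  expect_true(is.na(single$sd))
  dup <- summarize_endpoint(transform(m, value = c(7, 7)))
  expect_equal(dup$mean, 7)
  expect_equal(dup$sd, 0)
})

test_that("full procedure holds its nominal type-I error at n = 6", {
  set.seed(99)
  rej <- replicate(4000, {
    compare_groups(rnorm(6), rnorm(6))$significant
  })
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)
})

test_that("condition-wise comparisons pair the two modes correctly", {
  d <- experiment_design(seed = 21)
  m <- generate_endpoint_data(d, "foci_per_nucleus")
  cmp <- compare_endpoint_conditions(m)
  expect_setequal(unique(c(cmp$group1, cmp$group2)), c("PBS", "DS"))
  expect_true(all(cmp$group1 != cmp$group2))
  # one row per position x dose with >= 2 replicates per arm
  expect_equal(nrow(cmp), length(unique(m$position)) * length(unique(m$dose)))
  expect_true(all(cmp$p_t >= 0 & cmp$p_t <= 1))
  holm <- compare_endpoint_conditions(m, adjust = "holm")
  expect_true(all(holm$p_t >= cmp$p_t - 1e-12))
})
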