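# Surviving fractions, LQ fitting, isoeffect doses and RBE propagation.

test_that("surviving fractions normalise by per-run plating efficiency", {
  records <- data.frame(
    mode = "PBS", position = 1, dose = rep(c(0, 2), each = 2),
    run = 1, well = c(1, 2, 1, 2), seeded = c(100, 100, 200, 200),
    colonies = c(30, 30, 30, 30))
  obs <- surviving_fractions(records)
  expect_equal(obs$sf[obs$dose == 0], 1)          # PE = 0.30 by construction
  expect_equal(obs$sf[obs$dose == 2], 0.5)        # (30/200) / 0.30
  # zero-colony wells are retained and flagged
  records$colonies[3] <- 0
  obs2 <- surviving_fractions(records)
  expect_equal(obs2$zero_wells[obs2$dose == 2], 1)
  expect_equal(obs2$sf[obs2$dose == 2], 0.25)
  # missing or empty controls are errors
  no_ctrl <- records[records$dose > 0, ]
  expect_error(surviving_fractions(no_ctrl), "0 Gy controls")
  dead_ctrl <- records
  dead_ctrl$colonies[dead_ctrl$dose == 0] <- 0
  expect_error(surviving_fractions(dead_ctrl), "zero control colonies")
})

test_that("noiseless LQ data are recovered exactly, including beta = 0", {
  fit <- fit_lq(exact_lq_observations(0.26, 0.05))
  expect_equal(fit$alpha, 0.26, tolerance = 1e-10)
  expect_equal(fit$beta, 0.05, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  # pure-linear truth lands on the beta >= 0 boundary
  fit0 <- fit_lq(exact_lq_observations(0.3, 0))
  expect_equal(fit0$alpha, 0.3, tolerance = 1e-8)
  expect_equal(fit0$beta, 0, tolerance = 1e-8)
  # untransformed-scale optimiser agrees on noiseless data
  fit_lin <- fit_lq(exact_lq_observations(0.26, 0.05), scale = "linear")
  expect_equal(fit_lin$alpha, 0.26, tolerance = 1e-6)
  expect_equal(fit_lin$beta, 0.05, tolerance = 1e-6)
  expect_error(fit_lq(exact_lq_observations(0.26, 0.05, doses = c(0, 2))),
               "3 distinct dose")
})

test_that("fitted parameters track the generative truth on synthetic data", {
  d <- experiment_design(modes = "PBS", positions = 1L, seed = 314)
  counts <- generate_colony_counts(d, lq_truth(0.26, 0.05))
  fit <- fit_lq(surviving_fractions(counts))
  expect_lt(abs(fit$alpha - 0.26), 4 * fit$se_alpha)
  expect_lt(abs(fit$beta - 0.05), 4 * fit$se_beta)
  expect_gt(fit$r_squared, 0.95)
})

test_that("isoeffect dose inverts the survival function", {
  expect_equal(isoeffect_dose(lq_fit(log(2), 0), 0.5), 1.0)
  expect_equal(isoeffect_dose(lq_fit(0, log(2)), 0.5), 1.0)
  expect_equal(isoeffect_dose(lq_fit(0.17, 0.03), 0.5), 2.746,
               tolerance = 1e-3)
  set.seed(3)
  for (i in 1:100) {
    a <- runif(1, 0, 0.6); b <- runif(1, 0, 0.2)
    if (a == 0 && b == 0) next
    s <- runif(1, 0.01, 0.99)
    d <- isoeffect_dose(lq_fit(a, b), s)
    expect_equal(exp(-a * d - b * d^2), s, tolerance = 1e-10)
  }
  expect_error(isoeffect_dose(lq_fit(0.2, 0.05), 1.2), "survival_level")
  expect_error(isoeffect_dose(lq_fit(0.2, 0.05), 0), "survival_level")
})

test_that("RBE identities: self-comparison, antisymmetry, monotonicity", {
  co <- lq_fit(0.17, 0.03, 3.25e-2, 9.99e-3, label = "ref")
  expect_equal(compute_rbe(co, co)$rbe, 1.0)
  set.seed(5)
  for (i in 1:25) {
    f1 <- lq_fit(runif(1, 0.05, 0.5), runif(1, 0, 0.15))
    f2 <- lq_fit(runif(1, 0.05, 0.5), runif(1, 0, 0.15))
    expect_equal(compute_rbe(f1, f2, 0.37)$rbe * compute_rbe(f2, f1, 0.37)$rbe,
                 1.0, tolerance = 1e-12)
  }
  rbes <- sapply(c(0.2, 0.3, 0.4), function(a) {
    compute_rbe(co, lq_fit(a, 0.05))$rbe
  })
  expect_true(all(diff(rbes) > 0))
})

test_that("RBE from the published LQ table matches hand-solved dose ratios", {
  fits <- reference_lq_fits()
  # hand quadratic solves from the rounded published parameters
  expect_equal(isoeffect_dose(fits$Co60, 0.5), 2.746, tolerance = 1e-3)
  expect_equal(isoeffect_dose(fits$PBS1, 0.5), 1.941, tolerance = 1e-3)
  expect_equal(isoeffect_dose(fits$DS1, 0.5), 2.484, tolerance = 1e-3)
  expect_equal(compute_rbe(fits$Co60, fits$PBS1)$rbe, 2.746 / 1.941,
               tolerance = 1e-3)
  expect_equal(compute_rbe(fits$Co60, fits$DS1)$rbe, 2.746 / 2.484,
               tolerance = 1e-3)
})

test_that("delta-method RBE standard error matches a parametric bootstrap", {
  fits <- reference_lq_fits()
  # independent closed-form isoeffect solver for the bootstrap oracle
  dose_at_half <- function(a, b, eff = log(2)) {
    ifelse(b <= 0, eff / a, (-a + sqrt(a^2 + 4 * b * eff)) / (2 * b))
  }
  set.seed(17)
  n_boot <- 20000
  for (lab in c("PBS1", "PBS2", "DS1", "DS2")) {
    est <- compute_rbe(fits$Co60, fits[[lab]])
    a_ref <- pmax(rnorm(n_boot, fits$Co60$alpha, fits$Co60$se_alpha), 1e-6)
    b_ref <- pmax(rnorm(n_boot, fits$Co60$beta, fits$Co60$se_beta), 0)
    a_tst <- pmax(rnorm(n_boot, fits[[lab]]$alpha, fits[[lab]]$se_alpha), 1e-6)
    b_tst <- pmax(rnorm(n_boot, fits[[lab]]$beta, fits[[lab]]$se_beta), 0)
    boot <- dose_at_half(a_ref, b_ref) / dose_at_half(a_tst, b_tst)
    expect_equal(est$se, sd(boot), tolerance = 0.15)
  }
})

test_that("degenerate fits are rejected", {
  expect_error(lq_fit(0, 0), "both")
  expect_error(lq_fit(0.1, 0.02, cov_alpha_beta = 1), "semidefinite")
})
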