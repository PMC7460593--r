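# Generators: seed determinism, mean structure, noise families,
# spectrum fidelity.

test_that("experiment design validates its invariants", {
  expect_s3_class(experiment_design(seed = 1), "experiment_design")
  expect_error(experiment_design(plating_efficiency = 0), "plating_efficiency")
  expect_error(experiment_design(plating_efficiency = 1.2), "plating_efficiency")
  expect_error(experiment_design(doses = c(-1, 2)), "doses")
  expect_error(experiment_design(wells_per_condition = 0), "wells")
  d <- experiment_design(doses = c(1, 3, 5), seed = 1)
  expect_true(0 %in% d$doses)   # controls always present
})

test_that("colony counts are reproducible under a fixed seed", {
  d <- experiment_design(seed = 123)
  tr <- lq_truth(0.26, 0.05)
  expect_identical(generate_colony_counts(d, tr),
                   generate_colony_counts(d, tr))
  d2 <- experiment_design(seed = 124)
  expect_false(identical(generate_colony_counts(d, tr),
                         generate_colony_counts(d2, tr)))
})

test_that("colony counts follow the LQ mean structure", {
  # empirical mean of many wells converges to seeded * PE * exp(-aD-bD^2)
  d <- experiment_design(modes = "PBS", positions = 1L, doses = c(0, 1, 3, 5),
                         runs = 1L, wells_per_condition = 10000L,
                         seeded_cells = 1000, plating_efficiency = 0.3,
                         seed = 42)
  counts <- generate_colony_counts(d, lq_truth(0.26, 0.05))
  means <- tapply(counts$colonies, counts$dose, mean)
  expected <- 1000 * 0.3 * exp(-0.26 * c(0, 1, 3, 5) - 0.05 * c(0, 1, 3, 5)^2)
  expect_equal(as.numeric(means), unname(expected), tolerance = 0.02)
  # hand anchors: control mean 300 at PE 30%; 1 Gy mean ~219.9
  expect_equal(unname(means[["0"]]), 300, tolerance = 0.02)
  expect_equal(unname(means[["1"]]), 219.9, tolerance = 0.02)
})

test_that("missing truth for a condition is a configuration error", {
  d <- experiment_design(seed = 1)
  expect_error(
    generate_colony_counts(d, list(PBS1 = lq_truth(0.2, 0.05))),
    "missing lq_truth.*DS1"
  )
})

test_that("per-run plating-efficiency jitter widens between-run spread", {
  d <- experiment_design(modes = "PBS", positions = 1L, runs = 50L,
                         wells_per_condition = 6L, seed = 5)
  quiet <- generate_colony_counts(d, lq_truth(0.26, 0.05))
  noisy <- generate_colony_counts(d, lq_truth(0.26, 0.05),
                                  pe_jitter_sd = 0.2)
  run_means <- function(x) tapply(x$colonies[x$dose == 0],
                                  x$run[x$dose == 0], mean)
  expect_gt(sd(run_means(noisy)), sd(run_means(quiet)))
})

test_that("endpoint generator covers all kinds with the stated noise families", {
  d <- experiment_design(seed = 2)
  for (kind in c("apoptosis_total_pct", "bnc_with_mn_pct",
                 "mn_frequency", "foci_per_nucleus")) {
    m <- generate_endpoint_data(d, kind)
    expect_true(all(m$value >= 0))
    expect_identical(m, generate_endpoint_data(d, kind))
    if (grepl("pct", kind)) expect_true(all(m$value <= 100))
  }
  expect_error(generate_endpoint_data(d, "comet_assay"))
})

test_that("foci generator hits the expected per-nucleus mean at 1 Gy", {
  d <- experiment_design(runs = 20L, seed = 31)
  m <- generate_endpoint_data(d, "foci_per_nucleus")
  mean_1gy <- mean(m$value[m$dose == 1])
  expect_gt(mean_1gy, 25)
  expect_lt(mean_1gy, 35)
})

test_that("zero dose with zero background gives identically zero values", {
  d <- experiment_design(seed = 9)
  m <- generate_endpoint_data(d, "foci_per_nucleus",
                              params = list(background = 0))
  expect_true(all(m$value[m$dose == 0] == 0))
  a <- generate_endpoint_data(d, "apoptosis_total_pct",
                              params = list(background = c(`24` = 0, `48` = 0,
                                                           `96` = 0)))
  expect_true(all(a$value[a$dose == 0] == 0))
})

test_that("Poisson endpoint kinds have variance ~ mean at large n", {
  d <- experiment_design(modes = "X", positions = 1L, runs = 1L, seed = 77)
  m <- generate_endpoint_data(
    d, "foci_per_nucleus",
    params = list(doses = 1, n_nuclei = 1, replicates = 1e5))
  counts <- m$value   # n_nuclei = 1: raw Poisson counts
  expect_equal(var(counts), mean(counts), tolerance = 0.05)
})

test_that("generated LET spectra reproduce their dose-average targets", {
  targets <- c(protons = 3.17, alphas = 102.58, electrons = 0.19)
  sp <- generate_let_spectrum(targets, position = 2, mode = "PBS", seed = 11)
  for (s in names(targets)) {
    expect_equal(dose_average_let(sp[[s]])$letd, targets[[s]],
                 tolerance = 0.005)
  }
  # deterministic under seed
  sp2 <- generate_let_spectrum(targets, position = 2, mode = "PBS", seed = 11)
  expect_identical(sp, sp2)
  expect_error(generate_let_spectrum(c(protons = -1), seed = 1), "positive")
  expect_error(generate_let_spectrum(c(protons = 1), dose_shares = c(protons = 0.4),
                                     seed = 1), "sum to 1")
})

test_that("neutron spectrum matches configured class fractions", {
  ns <- generate_neutron_spectrum(c(0.5, 0.3, 0.2), n = 1e5, seed = 8)
  cl <- classify_neutrons(ns)
  expect_equal(unname(cl$percent) / 100, c(0.5, 0.3, 0.2), tolerance = 0.01)
  # all below 1 MeV
  low <- generate_neutron_spectrum(c(1, 0, 0), n = 5000, seed = 8)
  expect_true(all(low$energy <= 1))
  expect_error(generate_neutron_spectrum(c(0.5, 0.5, 0), n = 0), "'n'")
  expect_error(generate_neutron_spectrum(c(-0.1, 0.6, 0.5), n = 10),
               "non-negative")
})
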