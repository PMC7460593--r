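# Dose-averaged LET, species aggregation, ICRP-103 neutron weighting
# and classification.

test_that("dose-averaged LET matches hand examples and degenerate cases", {
  expect_equal(dose_average_let(let_spectrum("protons", 3.17, 7))$letd, 3.17)
  expect_equal(dose_average_let(let_spectrum("p", c(1, 3), c(1, 1)))$letd, 2.0)
  expect_equal(dose_average_let(let_spectrum("p", c(1, 3), c(1, 3)))$letd, 2.5)
  # two-line construction solved for target 2.5 needs w' = 3w
  w <- 0.4
  expect_equal(dose_average_let(let_spectrum("p", c(1, 3), c(w, 3 * w)))$letd,
               2.5)
})

test_that("spectrum constructor enforces its invariants", {
  expect_error(let_spectrum("p", c(0, 1), c(1, 1)), "positive")
  expect_error(let_spectrum("p", c(1, 2), c(0, 0)), "positive dose weight")
  expect_error(let_spectrum("p", 1, c(1, 2)), "lengths")
})

test_that("dose-averaged LET equals a brute-force loop oracle", {
  set.seed(42)
  for (i in 1:200) {
    sp <- random_spectrum()
    expect_equal(dose_average_let(sp)$letd,
                 letd_loop_oracle(sp$let, sp$dose_weight),
                 tolerance = 1e-12)
  }
  # and is bounded by the component extremes, scale invariant
  for (i in 1:50) {
    sp <- random_spectrum()
    v <- dose_average_let(sp)$letd
    expect_gte(v, min(sp$let) - 1e-9)
    expect_lte(v, max(sp$let) + 1e-9)
    scaled <- let_spectrum("protons", sp$let, sp$dose_weight * 7.3)
    expect_equal(dose_average_let(scaled)$letd, v, tolerance = 1e-12)
  }
})

test_that("dose-averaged LET dominates the fluence-averaged LET", {
  # with dose weights = fluence x LET, Cauchy-Schwarz gives
  # sum(f L^2)/sum(f L) >= sum(f L)/sum(f)
  set.seed(7)
  for (i in 1:100) {
    n <- sample(2:40, 1)
    let <- runif(n, 0.1, 100)
    fluence <- runif(n, 0, 5) + 1e-6
    dose_avg <- dose_average_let(let_spectrum("p", let, fluence * let))$letd
    fluence_avg <- sum(fluence * let) / sum(fluence)
    expect_gte(dose_avg, fluence_avg - 1e-10)
  }
})

test_that("species aggregation pools components dose-weighted", {
  a <- let_spectrum("speciesA", 2, 1)
  b <- let_spectrum("speciesB", 4, 1)
  expect_equal(combine_species(list(a, b))$letd, 3.0)
  # adding (almost) zero-weight species leaves the result unchanged
  c0 <- let_spectrum("speciesC", 50, 1e-300)
  expect_equal(combine_species(list(a, b, c0))$letd, 3.0)
  # a dose-dominant low-LET species pulls the total below the high-LET
  # species' own LET_d (the all-particles < protons pattern)
  high <- let_spectrum("alphas", 50, 1)
  low <- let_spectrum("electrons", 0.2, 10)
  expect_lt(combine_species(list(high, low))$letd,
            dose_average_let(high)$letd)
  expect_error(combine_species(list()), "empty")
  b2 <- let_spectrum("speciesB", 4, 1, position = 2)
  expect_error(combine_species(list(a, b2)), "share position")
})

test_that("ICRP-103 w_R has the published limits, peak and continuity", {
  expect_equal(icrp103_neutron_wr(1e-8), 2.5, tolerance = 1e-3)
  expect_equal(icrp103_neutron_wr(1), 20.7, tolerance = 1e-2 / 20.7)
  # both branch expressions agree at 50 MeV
  b2 <- 5.0 + 17.0 * exp(-log(2 * 50)^2 / 6)
  b3 <- 2.5 + 3.25 * exp(-log(0.04 * 50)^2 / 6)
  expect_equal(b2, b3, tolerance = 0.01 / b2)
  expect_equal(icrp103_neutron_wr(50), 5.50, tolerance = 0.01)
  # continuity at the branch boundaries
  expect_equal(icrp103_neutron_wr(1 - 1e-9), icrp103_neutron_wr(1 + 1e-9),
               tolerance = 1e-2)
  expect_equal(icrp103_neutron_wr(50 - 1e-9), icrp103_neutron_wr(50 + 1e-9),
               tolerance = 1e-2)
  # bounds and asymptotes
  e <- 10^seq(-9, 4, length.out = 500)
  wr <- icrp103_neutron_wr(e)
  expect_true(all(wr >= 2.5 - 1e-9 & wr <= 20.7 + 1e-2))
  expect_equal(icrp103_neutron_wr(1e-9), 2.5, tolerance = 1e-4)
  expect_equal(icrp103_neutron_wr(1e4), 2.5, tolerance = 1e-2)
  expect_error(icrp103_neutron_wr(0), "positive")
})

test_that("neutron classification totals, percentages and mean w_R", {
  cl <- classify_neutrons(neutron_spectrum(c(0.5, 10, 60)))
  expect_equal(unname(cl$counts), c(1, 1, 1))
  expect_equal(unname(cl$percent), rep(100 / 3, 3))
  expect_equal(sum(cl$percent), 100)
  expect_equal(cl$total, 3)
  # boundary atoms go to the lower class (<=1 and 1-50 labels)
  cl_b <- classify_neutrons(neutron_spectrum(c(1, 50)))
  expect_equal(unname(cl_b$counts), c(1, 1, 0))
  # entirely sub-1 MeV spectrum
  low <- classify_neutrons(neutron_spectrum(runif(100, 0.001, 0.9)))
  expect_equal(unname(low$percent), c(100, 0, 0))
  # thermal spectrum has mean w_R at the low-energy plateau
  thermal <- classify_neutrons(neutron_spectrum(rep(2.5e-8, 10)))
  expect_equal(thermal$mean_wr, 2.5, tolerance = 1e-3)
  expect_error(neutron_spectrum(numeric(0)), "non-empty")
  expect_error(neutron_spectrum(c(-1, 2)), "positive")
})
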