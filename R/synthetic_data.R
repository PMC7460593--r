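# Synthetic study data: clonogenic colony counts, cytogenetic endpoints,
# particle LET spectra and neutron spectra. Every generator is a pure
# function of (parameters, seed).

#' Experiment design for a proton-beam radiobiology study
#'
#' Describes the factorial layout of an in vitro irradiation experiment:
#' delivery modes crossed with positions along the depth-dose curve,
#' absorbed doses, independent experimental runs and wells per condition.
#' The defaults mirror a clinical PBS-vs-DS comparison: two modes, two
#' positions (1 = plateau, 2 = Bragg peak), doses 0/1/3/5 Gy, two
#' independent runs with 6-well plates, and a plating efficiency of 30%.
#'
#' @param modes Character vector of delivery-mode labels, e.g. `c("PBS", "DS")`
#'   for pencil beam scanning and double scattering, or `"Co60"` for a
#'   reference photon irradiation.
#' @param positions Integer vector of irradiation positions (1 = plateau,
#'   2 = Bragg peak).
#' @param doses Absorbed doses in Gy; 0 Gy controls are required for
#'   plating-efficiency normalisation and are added if absent.
#' @param runs Number of independent experimental runs.
#' @param wells_per_condition Wells per plate for each mode/position/dose.
#' @param seeded_cells Cells seeded per well: a single number, or a vector
#'   named by dose (as in practice, where more cells are seeded at higher
#'   doses to keep colony numbers countable).
#' @param plating_efficiency Fraction of unirradiated cells forming
#'   colonies, in (0, 1].
#' @param seed Integer seed making the generated data reproducible.
#'
#' @return An object of class `experiment_design`.
#' @examples
#' experiment_design(doses = c(0, 1, 3, 5), seed = 1)
#' @export
experiment_design <- function(modes = c("PBS", "DS"),
                              positions = c(1L, 2L),
                              doses = c(0, 1, 3, 5),
                              runs = 2L,
                              wells_per_condition = 6L,
                              seeded_cells = c(`0` = 200, `1` = 400,
                                               `3` = 1500, `5` = 5000),
                              plating_efficiency = 0.30,
                              seed = 1L) {
  if (!is.character(modes) || length(modes) < 1) {
    stop_config("'modes' must be a non-empty character vector")
  }
  assert_number(doses, "doses", lower = 0)
  if (!0 %in% doses) doses <- c(0, doses)
  doses <- sort(unique(doses))
  assert_number(runs, "runs", lower = 1)
  assert_number(wells_per_condition, "wells_per_condition", lower = 1)
  assert_number(plating_efficiency, "plating_efficiency")
  if (plating_efficiency <= 0 || plating_efficiency > 1) {
    stop_config("'plating_efficiency' must lie in (0, 1]")
  }
  assert_number(seeded_cells, "seeded_cells", lower = 1)
  if (length(seeded_cells) > 1) {
    if (is.null(names(seeded_cells))) {
      stop_config("per-dose 'seeded_cells' must be named by dose")
    }
    missing <- setdiff(as.character(doses), names(seeded_cells))
    if (length(missing)) {
      # fall back to the largest stated seeding for unlisted doses
      extra <- stats::setNames(rep(max(seeded_cells), length(missing)), missing)
      seeded_cells <- c(seeded_cells, extra)
    }
  }
  assert_number(seed, "seed")
  structure(
    list(modes = modes, positions = as.integer(positions), doses = doses,
         runs = as.integer(runs),
         wells_per_condition = as.integer(wells_per_condition),
         seeded_cells = seeded_cells,
         plating_efficiency = plating_efficiency,
         seed = as.integer(seed)),
    class = "experiment_design"
  )
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("Experiment design:",
      paste(x$modes, collapse = "/"), "x positions",
      paste(x$positions, collapse = "/"), "\n")
  cat("  doses (Gy):", paste(x$doses, collapse = ", "),
      "| runs:", x$runs, "x", x$wells_per_condition, "wells\n")
  cat("  plating efficiency:", x$plating_efficiency,
      "| seed:", x$seed, "\n")
  invisible(x)
}

#' Generative linear-quadratic truth
#'
#' The alpha (Gy^-1) and beta (Gy^-2) parameters of the linear-quadratic
#' survival model S(D) = exp(-alpha D - beta D^2) used to generate
#' synthetic clonogenic data.
#'
#' @param alpha Linear coefficient, Gy^-1, non-negative.
#' @param beta Quadratic coefficient, Gy^-2, non-negative.
#' @return An object of class `lq_truth`.
#' @examples
#' lq_truth(0.26, 0.05)
#' @export
lq_truth <- function(alpha, beta) {
  assert_number(alpha, "alpha", lower = 0)
  assert_number(beta, "beta", lower = 0)
  if (alpha == 0 && beta == 0) {
    stop_config("alpha and beta cannot both be zero")
  }
  structure(list(alpha = alpha, beta = beta), class = "lq_truth")
}

lq_surviving_fraction <- function(truth, dose) {
  exp(-truth$alpha * dose - truth$beta * dose^2)
}

seeded_for_dose <- function(design, dose) {
  s <- design$seeded_cells
  if (length(s) == 1) return(unname(s))
  unname(s[[as.character(dose)]])
}

#' Generate clonogenic colony counts
#'
#' Simulates well-level colony counts for every mode/position/dose/run/well
#' combination of a design. The expected count in a well is
#' `seeded * PE * exp(-alpha D - beta D^2)` and the observed count is
#' Poisson around that mean (colony formation is a counting process).
#' 0 Gy control wells are always included; they carry the plating
#' efficiency used later to convert counts to surviving fractions.
#'
#' @param design An [experiment_design()].
#' @param truth A named list of [lq_truth()] objects, one per condition
#'   label `paste0(mode, position)` (e.g. `"PBS1"`), or a single
#'   `lq_truth` applied to all conditions.
#' @param pe_jitter_sd Optional log-normal standard deviation (on the log
#'   scale) of a per-run multiplicative plating-efficiency factor,
#'   emulating inter-run variability between independent experiments.
#'   Default 0 (off).
#'
#' @return A data frame with one row per well: `mode`, `position`,
#'   `dose`, `run`, `well`, `seeded`, `colonies`.
#' @examples
#' d <- experiment_design(seed = 7)
#' counts <- generate_colony_counts(d, lq_truth(0.26, 0.05))
#' head(counts)
#' @export
generate_colony_counts <- function(design, truth, pe_jitter_sd = 0) {
  stopifnot(inherits(design, "experiment_design"))
  assert_number(pe_jitter_sd, "pe_jitter_sd", lower = 0)
  labels <- as.vector(outer(design$modes, design$positions, label_condition))
  if (inherits(truth, "lq_truth")) {
    truth <- stats::setNames(rep(list(truth), length(labels)), labels)
  }
  missing <- setdiff(labels, names(truth))
  if (length(missing)) {
    stop_config("missing lq_truth for condition(s): ",
                paste(missing, collapse = ", "))
  }
  grid <- expand.grid(mode = design$modes, position = design$positions,
                      dose = design$doses, run = seq_len(design$runs),
                      well = seq_len(design$wells_per_condition),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$mode, grid$position, grid$dose,
                     grid$run, grid$well), , drop = FALSE]
  rownames(grid) <- NULL
  with_seed(design$seed, {
    pe_run <- matrix(design$plating_efficiency,
                     nrow = design$runs, ncol = length(labels),
                     dimnames = list(NULL, labels))
    if (pe_jitter_sd > 0) {
      jitter <- exp(stats::rnorm(design$runs, -pe_jitter_sd^2 / 2,
                                 pe_jitter_sd))
      pe_run <- pe_run * jitter   # shared across conditions within a run
    }
    lab <- label_condition(grid$mode, grid$position)
    sf <- vapply(seq_len(nrow(grid)), function(i) {
      lq_surviving_fraction(truth[[lab[i]]], grid$dose[i])
    }, numeric(1))
    grid$seeded <- vapply(grid$dose, function(d) seeded_for_dose(design, d),
                          numeric(1))
    mu <- grid$seeded * pe_run[cbind(grid$run, match(lab, labels))] * sf
    grid$colonies <- stats::rpois(nrow(grid), mu)
  })
  grid
}

endpoint_kinds <- c("apoptosis_total_pct", "bnc_with_mn_pct",
                    "mn_frequency", "foci_per_nucleus")

#' Default generative models for the cytogenetic endpoints
#'
#' Returns the effect-model parameters used by [generate_endpoint_data()]:
#' \describe{
#'   \item{apoptosis_total_pct}{Caspase-3/7-positive fraction scored at
#'     24/48/96 h; per-cell probability `background(t) + slope(t) * D`,
#'     binomial over `n_cells` scored cells, reported as a percentage.}
#'   \item{bnc_with_mn_pct}{Percentage of binucleated cells carrying at
#'     least one micronucleus; per-cell MN counts are Poisson with mean
#'     `c0 + c1 D + c2 D^2`, so the per-cell probability is
#'     `1 - exp(-lambda(D))`, binomial over `n_bnc` cells.}
#'   \item{mn_frequency}{Total micronuclei per binucleated cell from the
#'     same linear-quadratic Poisson mean.}
#'   \item{foci_per_nucleus}{Mean gamma-H2AX foci per nucleus; Poisson per
#'     nucleus with mean `background + per_gy * D`. The default 28 foci/Gy
#'     sits in the 25-35 double-strand-breaks-per-nucleus range expected
#'     at 1 Gy.}
#' }
#'
#' @param kind One of `r paste0('"', endpoint_kinds, '"', collapse = ", ")`.
#' @return A named list of model parameters.
#' @export
endpoint_model_defaults <- function(kind) {
  kind <- match.arg(kind, endpoint_kinds)
  switch(kind,
    apoptosis_total_pct = list(
      doses = c(0, 1, 3, 5),
      time_points = c(24, 48, 96),
      background = c(`24` = 0.04, `48` = 0.06, `96` = 0.08),
      slope_per_gy = c(`24` = 0.008, `48` = 0.015, `96` = 0.012),
      n_cells = 1000, replicates = 2
    ),
    bnc_with_mn_pct = list(
      doses = c(0, 3, 5),
      mn_lambda = c(0.010, 0.015, 0.008),   # c0 + c1 D + c2 D^2
      n_bnc = 400, replicates = 2
    ),
    mn_frequency = list(
      doses = c(0, 3, 5),
      mn_lambda = c(0.010, 0.015, 0.008),
      n_bnc = 400, replicates = 2
    ),
    foci_per_nucleus = list(
      doses = c(0, 1),
      background = 0.5, per_gy = 28,
      n_nuclei = 500, replicates = 2
    )
  )
}

mn_lambda_at <- function(coef, dose) {
  coef[1] + coef[2] * dose + coef[3] * dose^2
}

#' Generate cytogenetic endpoint measurements
#'
#' Simulates replicate-level endpoint values (apoptosis percentages,
#' micronucleus summaries or foci-per-nucleus means) for every
#' mode/position/dose of a design, with the noise family appropriate to
#' how the endpoint is scored: binomial-derived percentages for
#' apoptosis and %BNC-with-MN, Poisson counts for micronuclei and foci.
#'
#' @inheritParams generate_colony_counts
#' @param kind Endpoint kind, see [endpoint_model_defaults()].
#' @param params Effect-model parameters; defaults from
#'   [endpoint_model_defaults()]. Doses listed in `params$doses` override
#'   the design's doses (the assays use different dose panels: foci are
#'   scored at 1 Gy only, micronuclei at 3 and 5 Gy).
#'
#' @return A data frame with columns `endpoint`, `mode`, `position`,
#'   `dose`, `time_h` (0 where not applicable), `run`, `replicate`,
#'   `value`.
#' @examples
#' d <- experiment_design(seed = 3)
#' foci <- generate_endpoint_data(d, "foci_per_nucleus")
#' aggregate(value ~ dose, foci, mean)
#' @export
generate_endpoint_data <- function(design, kind,
                                   params = endpoint_model_defaults(kind)) {
  stopifnot(inherits(design, "experiment_design"))
  kind <- match.arg(kind, endpoint_kinds)
  defaults <- endpoint_model_defaults(kind)
  params <- utils::modifyList(defaults, params %||% list())
  num <- params[vapply(params, is.numeric, logical(1))]
  if (any(unlist(num) < 0)) stop_config("endpoint model parameters must be non-negative")
  doses <- params$doses %||% design$doses
  times <- if (kind == "apoptosis_total_pct") params$time_points else 0
  grid <- expand.grid(mode = design$modes, position = design$positions,
                      dose = doses, time_h = times,
                      run = seq_len(design$runs),
                      replicate = seq_len(params$replicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$mode, grid$position, grid$dose, grid$time_h,
                     grid$run, grid$replicate), , drop = FALSE]
  rownames(grid) <- NULL
  n <- nrow(grid)
  value <- with_seed(design$seed + match(kind, endpoint_kinds), {
    switch(kind,
      apoptosis_total_pct = {
        bg <- params$background[as.character(grid$time_h)]
        sl <- params$slope_per_gy[as.character(grid$time_h)]
        p <- pmin(unname(bg) + unname(sl) * grid$dose, 1)
        100 * stats::rbinom(n, params$n_cells, p) / params$n_cells
      },
      bnc_with_mn_pct = {
        p <- 1 - exp(-mn_lambda_at(params$mn_lambda, grid$dose))
        100 * stats::rbinom(n, params$n_bnc, p) / params$n_bnc
      },
      mn_frequency = {
        lam <- mn_lambda_at(params$mn_lambda, grid$dose)
        stats::rpois(n, params$n_bnc * lam) / params$n_bnc
      },
      foci_per_nucleus = {
        mu <- params$background + params$per_gy * grid$dose
        stats::rpois(n, params$n_nuclei * mu) / params$n_nuclei
      }
    )
  })
  out <- data.frame(endpoint = kind, grid, stringsAsFactors = FALSE)
  out$value <- value
  out
}

#' Generate LET spectra with prescribed dose-averaged LET
#'
#' Constructs, for each particle species, a spectrum of (LET value, dose
#' weight) components whose dose-averaged LET equals the requested
#' target. Components are drawn from a log-normal centred on the target
#' (a smooth stand-in for transport-code spectral shapes, which are not
#' published); the dose weights of the components below and above the
#' target are then rescaled so the weighted mean hits the target exactly,
#' and each species' total dose weight is set to its dose share.
#'
#' @param targets Named numeric vector: species -> target dose-averaged
#'   LET in keV/um. All targets must be positive.
#' @param dose_shares Named numeric vector of per-species dose fractions,
#'   summing to 1; default equal shares.
#' @param n_components Components per species spectrum.
#' @param spread Log-scale spread of the component LET values.
#' @param position,mode Labels attached to the spectra.
#' @param seed Integer seed.
#'
#' @return A named list of [let_spectrum()] objects, one per species.
#' @examples
#' sp <- generate_let_spectrum(c(protons = 3.17), position = 2,
#'                             mode = "PBS", seed = 1)
#' dose_average_let(sp$protons)
#' @export
generate_let_spectrum <- function(targets, dose_shares = NULL,
                                  n_components = 32, spread = 0.3,
                                  position = 1, mode = "PBS", seed = 1L) {
  if (is.null(names(targets)) || any(!nzchar(names(targets)))) {
    stop_config("'targets' must be named by species")
  }
  assert_number(targets, "targets")
  if (any(targets <= 0)) stop_config("LET_d targets must be positive")
  if (is.null(dose_shares)) {
    dose_shares <- stats::setNames(rep(1 / length(targets), length(targets)),
                                   names(targets))
  }
  assert_number(dose_shares, "dose_shares", lower = 0)
  if (abs(sum(dose_shares) - 1) > 1e-8) {
    stop_config("'dose_shares' must sum to 1")
  }
  assert_number(n_components, "n_components", lower = 2)
  with_seed(seed, {
    out <- lapply(names(targets), function(sp) {
      target <- targets[[sp]]
      let <- stats::rlnorm(n_components, log(target) - spread^2 / 2, spread)
      # guarantee support on both sides of the target
      if (all(let >= target)) let[1] <- target * 0.8
      if (all(let <= target)) let[1] <- target / 0.8
      w <- stats::runif(n_components, 0.2, 1)
      lo <- let < target
      m_lo <- sum(let[lo] * w[lo]) / sum(w[lo])
      m_hi <- sum(let[!lo] * w[!lo]) / sum(w[!lo])
      lam <- (m_hi - target) / (m_hi - m_lo)
      if (!is.finite(lam) || lam <= 0 || lam >= 1) {
        stop_config("target LET_d ", target, " infeasible for species ", sp)
      }
      w[lo] <- w[lo] * lam / sum(w[lo])
      w[!lo] <- w[!lo] * (1 - lam) / sum(w[!lo])
      share <- if (sp %in% names(dose_shares)) dose_shares[[sp]] else 0
      let_spectrum(sp, let, w * 100 * share, position = position, mode = mode)
    })
    stats::setNames(out, names(targets))
  })
}

#' Generate a neutron energy spectrum from class fractions
#'
#' Samples neutron energies whose distribution over the ICRP-103 energy
#' classes (below 1 MeV, 1-50 MeV, above 50 MeV) follows prescribed
#' fractions. Within a class, energies are log-uniform: only the class
#' fractions are constrained by the study's transport summaries, not the
#' in-class shape.
#'
#' @param fractions Numeric length 3: fractions of neutrons in the
#'   classes (<=1, 1-50, >=50) MeV. Must be non-negative and sum to 1.
#' @param n Number of neutrons to sample (>= 1).
#' @param energy_range Overall support in MeV: lowest thermal energy and
#'   the maximum neutron energy (bounded by the primary beam energy).
#' @param class1_max Upper support bound (MeV) of the lowest class.
#'   Neutrons reaching a point at depth in water are heavily moderated,
#'   so the sub-1 MeV class is dominated by thermal and epithermal
#'   energies where the ICRP-103 weighting factor sits at its 2.5
#'   plateau; the default 2.5e-3 MeV confines class-1 sampling to that
#'   region. Set to 1 for support over the full class.
#' @param position,mode Labels attached to the spectrum.
#' @param seed Integer seed.
#'
#' @return A [neutron_spectrum()] with unit weights.
#' @examples
#' ns <- generate_neutron_spectrum(c(1, 0, 0), n = 100, seed = 1)
#' classify_neutrons(ns)
#' @export
generate_neutron_spectrum <- function(fractions, n,
                                      energy_range = c(1e-8, 230),
                                      class1_max = 2.5e-3,
                                      position = 1, mode = "PBS", seed = 1L) {
  assert_number(fractions, "fractions")
  if (length(fractions) != 3 || any(fractions < 0)) {
    stop_config("'fractions' must be 3 non-negative numbers")
  }
  if (abs(sum(fractions) - 1) > 1e-8) stop_config("'fractions' must sum to 1")
  assert_number(n, "n", lower = 1)
  assert_number(class1_max, "class1_max")
  if (class1_max <= energy_range[1] || class1_max > 1) {
    stop_config("'class1_max' must lie in (energy_range[1], 1]")
  }
  bounds <- list(c(energy_range[1], class1_max), c(1, 50),
                 c(50, energy_range[2]))
  with_seed(seed, {
    cls <- sample.int(3, n, replace = TRUE, prob = fractions)
    lo <- log(vapply(bounds, `[`, numeric(1), 1))[cls]
    hi <- log(vapply(bounds, `[`, numeric(1), 2))[cls]
    energy <- exp(stats::runif(n, lo, hi))
    # keep boundary atoms inside their class under the closed-upper rule
    energy <- pmin(energy, exp(hi))
    neutron_spectrum(energy, rep(1, n), position = position, mode = mode)
  })
}
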