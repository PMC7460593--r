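# Simplified analytic proton beam physics: Bragg-Kleeman range-energy,
# Bethe stopping power in water, and a pristine Bragg depth-dose curve
# with Gaussian range straggling. A pedagogical stand-in for full Monte
# Carlo transport: no nuclear interactions, no secondary-particle
# buildup, no lateral profiles.

# Bragg-Kleeman water constants: R = BK_A * E^BK_P (cm, MeV).
BK_A <- 0.0022
BK_P <- 1.77

PROTON_MASS_MEV <- 938.272
ELECTRON_MASS_MEV <- 0.51099895

#' Bragg-Kleeman range-energy relation for protons in water
#'
#' `R(E) = a E^p` with water constants a = 0.0022 cm MeV^-p, p = 1.77.
#' These constants reproduce the clinical pairing of a 190.6 MeV beam
#' with a 23.9 g/cm^2 range in water (density 1, so cm and g/cm^2
#' coincide).
#'
#' @param energy Proton kinetic energy in MeV (vectorised, >= 0).
#' @return CSDA range in cm of water.
#' @examples
#' bragg_kleeman_range(190.6)   # ~23.9 cm
#' @export
bragg_kleeman_range <- function(energy) {
  assert_number(energy, "energy", lower = 0)
  BK_A * energy^BK_P
}

#' Residual proton energy at depth
#'
#' Inverts the Bragg-Kleeman relation along the beam path:
#' `E(z) = ((R(E0) - z) / a)^(1/p)`. Decreasing in depth, with
#' `E(0) = E0` and `E(R) = 0`.
#'
#' @param energy0 Initial kinetic energy in MeV.
#' @param depth Depth in cm of water, in `[0, R(energy0)]`.
#' @return Residual kinetic energy in MeV.
#' @examples
#' energy_at_depth(190.6, 23.6)   # ~16 MeV just proximal to the peak
#' @export
energy_at_depth <- function(energy0, depth) {
  assert_number(energy0, "energy0", lower = 0)
  assert_number(depth, "depth", lower = 0)
  r <- bragg_kleeman_range(energy0)
  if (any(depth > r + 1e-12)) {
    stop_config("depth exceeds the beam range (", signif(r, 4), " cm)")
  }
  (pmax(r - depth, 0) / BK_A)^(1 / BK_P)
}

#' Electronic stopping power of protons in water
#'
#' Unrestricted electronic stopping power from the Bethe formula with a
#' mean excitation energy of 75 eV for water and no shell or density
#' corrections, returned in keV/um (numerically equal to MeV/cm / 10 at
#' unit density). Valid for 1-250 MeV protons; used as the LET proxy.
#'
#' @param energy Proton kinetic energy in MeV, within [1, 250].
#' @return Stopping power in keV/um.
#' @examples
#' stopping_power_water(150)   # ~0.545 keV/um
#' @export
stopping_power_water <- function(energy) {
  assert_number(energy, "energy")
  if (any(energy < 1 | energy > 250)) {
    stop_config("'energy' outside the 1-250 MeV validity window")
  }
  gamma <- 1 + energy / PROTON_MASS_MEV
  beta2 <- 1 - 1 / gamma^2
  i_mev <- 75e-6                      # mean excitation energy of water
  arg <- 2 * ELECTRON_MASS_MEV * beta2 * gamma^2 / i_mev
  # K (Z/A) for water: 0.307075 MeV cm^2/g * 0.5551
  s_mev_cm <- 0.307075 * 0.55509 / beta2 * (log(arg) - beta2)
  s_mev_cm / 10                       # keV/um at 1 g/cm^3
}

#' Beam configuration
#'
#' Holds a delivery mode's nominal energy with its derived
#' Bragg-Kleeman range and the (metadata) modulation width.
#'
#' @param nominal_energy Beam kinetic energy in MeV.
#' @param modulation Modulation width in g/cm^2 (distance between the
#'   proximal and distal 90% dose levels); metadata only, no SOBP is
#'   constructed.
#' @param mode Delivery mode label.
#' @return An object of class `beam_config` with fields
#'   `nominal_energy`, `range_water`, `modulation`, `mode`.
#' @examples
#' beam_config(190.6, mode = "PBS")
#' @export
beam_config <- function(nominal_energy, modulation = 0, mode = "PBS") {
  assert_number(nominal_energy, "nominal_energy")
  if (nominal_energy <= 0) stop_config("'nominal_energy' must be positive")
  structure(
    list(nominal_energy = nominal_energy,
         range_water = bragg_kleeman_range(nominal_energy),
         modulation = modulation, mode = mode),
    class = "beam_config"
  )
}

#' @export
print.beam_config <- function(x, ...) {
  cat(sprintf("Beam config [%s]: %.1f MeV, range %.2f g/cm^2, modulation %.2f g/cm^2\n",
              x$mode, x$nominal_energy, x$range_water, x$modulation))
  invisible(x)
}

#' Pristine Bragg depth-dose curve
#'
#' Builds a percentage depth-dose curve by convolving the
#' continuous-slowing-down dose deposition
#' `dE/dz = (R - z)^(1/p - 1) / (p a^(1/p))` (the depth derivative of the
#' Bragg-Kleeman residual energy, with an integrable singularity at the
#' range) with a Gaussian range-straggling kernel. The default
#' straggling width follows the empirical water scaling
#' `sigma = 0.012 R^0.935`. The maximum is normalised to 100%.
#'
#' @param energy0 Beam kinetic energy in MeV.
#' @param step Output depth-grid step in cm.
#' @param sigma Range-straggling standard deviation in cm; `NULL` for
#'   the default scaling.
#' @param positions Depths (cm) to mark in the returned object, e.g.
#'   sample irradiation positions.
#' @return An object of class `depth_dose_curve`: a data frame with
#'   columns `depth_cm` and `dose_pct`, plus attributes `energy0`,
#'   `sigma`, `positions`.
#' @examples
#' pdd <- depth_dose_curve(190.6, positions = c(2, 23.6))
#' pdd$depth_cm[which.max(pdd$dose_pct)]   # peak near the 23.9 cm range
#' @export
depth_dose_curve <- function(energy0, step = 0.05, sigma = NULL,
                             positions = numeric()) {
  assert_number(energy0, "energy0")
  if (energy0 <= 0) stop_config("'energy0' must be positive")
  assert_number(step, "step")
  if (step <= 0) stop_config("'step' must be positive")
  r <- bragg_kleeman_range(energy0)
  sigma <- sigma %||% (0.012 * r^0.935)
  assert_number(sigma, "sigma")
  if (sigma <= 0) stop_config("'sigma' must be positive")

  # CSDA deposition on a fine midpoint grid (handles the (R - z)^(1/p - 1)
  # singularity by never evaluating at z = R exactly)
  fine <- min(step / 4, sigma / 8, 0.01)
  zmid <- seq(fine / 2, r - fine / 2, by = fine)
  d_csda <- (r - zmid)^(1 / BK_P - 1) / (BK_P * BK_A^(1 / BK_P))

  depth <- seq(0, r + 4 * sigma, by = step)
  dose <- vapply(depth, function(z) {
    sum(d_csda * stats::dnorm(z - zmid, sd = sigma)) * fine
  }, numeric(1))
  dose <- 100 * dose / max(dose)
  out <- data.frame(depth_cm = depth, dose_pct = dose)
  structure(out, class = c("depth_dose_curve", "data.frame"),
            energy0 = energy0, sigma = sigma, positions = positions)
}

#' Relative dose at given depths of a depth-dose curve
#'
#' Linear interpolation of a [depth_dose_curve()] at arbitrary depths.
#'
#' @param curve A `depth_dose_curve`.
#' @param depth Depths in cm.
#' @return Relative dose in percent of the maximum.
#' @export
dose_at_depth <- function(curve, depth) {
  stopifnot(inherits(curve, "depth_dose_curve"))
  stats::approx(curve$depth_cm, curve$dose_pct, xout = depth, rule = 2)$y
}
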