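# Dose-averaged LET over particle spectra, species aggregation, and
# ICRP-103 neutron radiation weighting / energy categorization.

let_species <- c("protons", "electrons", "positrons", "deuterons",
                 "tritons", "helions", "alphas")

#' LET spectrum of one particle species
#'
#' A list of (LET value, dose weight) components for one species at one
#' position/mode: the LET values LET^i and the dose proportions D_i that
#' enter the dose-averaged LET
#' \deqn{LET_d = \sum_i LET^i D_i / \sum_i D_i.}
#' Dose weights are treated as relative; their absolute scale never
#' matters.
#'
#' @param species Species label (e.g. `"protons"`, `"alphas"`); free-form
#'   but the conventional set is protons, electrons, positrons,
#'   deuterons, tritons, helions, alphas.
#' @param let LET values in keV/um, all positive.
#' @param dose_weight Non-negative dose weights, at least one positive.
#' @param position,mode Labels for the irradiation position and delivery
#'   mode.
#' @return An object of class `let_spectrum` (a data frame with columns
#'   `let` and `dose_weight` and attributes `species`, `position`,
#'   `mode`).
#' @examples
#' sp <- let_spectrum("protons", c(1, 3), c(1, 3))
#' dose_average_let(sp)   # 2.5
#' @export
let_spectrum <- function(species, let, dose_weight,
                         position = NA, mode = NA) {
  if (!is.character(species) || length(species) != 1) {
    stop_config("'species' must be a single label")
  }
  assert_number(let, "let")
  assert_number(dose_weight, "dose_weight", lower = 0)
  if (length(let) != length(dose_weight)) {
    stop_config("'let' and 'dose_weight' lengths differ")
  }
  if (any(let <= 0)) stop_config("LET values must be positive")
  if (sum(dose_weight) <= 0) {
    stop_config("at least one component must carry positive dose weight")
  }
  structure(data.frame(let = let, dose_weight = dose_weight),
            class = c("let_spectrum", "data.frame"),
            species = species, position = position, mode = mode)
}

#' @export
print.let_spectrum <- function(x, ...) {
  cat(sprintf("LET spectrum: %s (%d components), position %s, mode %s\n",
              attr(x, "species"), nrow(x), attr(x, "position"),
              attr(x, "mode")))
  cat(sprintf("  LET_d = %.4g keV/um\n", dose_average_let(x)$letd))
  invisible(x)
}

#' Dose-averaged LET of a spectrum
#'
#' The dose-weighted mean of the component LET values,
#' `sum(LET_i * D_i) / sum(D_i)`. The result is necessarily bounded by
#' the smallest and largest component LET and is invariant to rescaling
#' all dose weights.
#'
#' @param spectrum A [let_spectrum()].
#' @return A `letd_result`: list with `species`, `letd` (keV/um),
#'   `position`, `mode`.
#' @examples
#' dose_average_let(let_spectrum("protons", c(1, 3), c(1, 1)))$letd  # 2
#' @export
dose_average_let <- function(spectrum) {
  stopifnot(inherits(spectrum, "let_spectrum"))
  w <- spectrum$dose_weight
  if (sum(w) <= 0) stop_config("all dose weights are zero")
  structure(
    list(species = attr(spectrum, "species"),
         letd = sum(spectrum$let * w) / sum(w),
         position = attr(spectrum, "position"),
         mode = attr(spectrum, "mode")),
    class = "letd_result"
  )
}

#' @export
print.letd_result <- function(x, ...) {
  cat(sprintf("LET_d [%s, position %s, mode %s]: %.4g keV/um\n",
              x$species, x$position, x$mode, x$letd))
  invisible(x)
}

#' All-particle dose-averaged LET
#'
#' Concatenates the components of several per-species spectra (which must
#' share position and mode) and applies the dose-averaged LET to the
#' pooled spectrum. Because low-LET species usually carry most of the
#' dose, the all-particle value sits below the high-LET species' own
#' LET_d.
#'
#' @param spectra A list of [let_spectrum()] objects.
#' @return A `letd_result` with species `"all particles"`.
#' @examples
#' a <- let_spectrum("protons", 2, 1)
#' b <- let_spectrum("alphas", 4, 1)
#' combine_species(list(a, b))$letd   # 3
#' @export
combine_species <- function(spectra) {
  if (!length(spectra)) stop_config("empty spectrum collection")
  stopifnot(all(vapply(spectra, inherits, logical(1), "let_spectrum")))
  pos <- unique(vapply(spectra, function(s) as.character(attr(s, "position")),
                       character(1)))
  mod <- unique(vapply(spectra, function(s) as.character(attr(s, "mode")),
                       character(1)))
  if (length(pos) > 1 || length(mod) > 1) {
    stop_config("spectra must share position and mode")
  }
  let <- unlist(lapply(spectra, `[[`, "let"))
  w <- unlist(lapply(spectra, `[[`, "dose_weight"))
  combined <- let_spectrum("all particles", let, w,
                           position = attr(spectra[[1]], "position"),
                           mode = attr(spectra[[1]], "mode"))
  dose_average_let(combined)
}

#' ICRP-103 neutron radiation weighting factor
#'
#' The continuous energy dependence of the neutron radiation weighting
#' factor w_R recommended by ICRP Publication 103:
#' \deqn{w_R(E) = 2.5 + 18.2 e^{-(\ln E)^2/6}, \quad E < 1\,MeV}
#' \deqn{w_R(E) = 5.0 + 17.0 e^{-(\ln 2E)^2/6}, \quad 1 \le E \le 50\,MeV}
#' \deqn{w_R(E) = 2.5 + 3.25 e^{-(\ln 0.04E)^2/6}, \quad E > 50\,MeV}
#' Continuous at the branch boundaries, bounded in [2.5, 20.7], peaking
#' at 1 MeV and tending to 2.5 at both thermal and very high energies.
#'
#' @param energy Neutron energy in MeV (vectorised, positive).
#' @return Dimensionless weighting factor(s).
#' @examples
#' icrp103_neutron_wr(1e-8)   # ~2.5 (thermal)
#' icrp103_neutron_wr(1)      # 20.7 (maximum)
#' @export
icrp103_neutron_wr <- function(energy) {
  assert_number(energy, "energy")
  if (any(energy <= 0)) stop_config("'energy' must be positive")
  ifelse(energy < 1,
         2.5 + 18.2 * exp(-log(energy)^2 / 6),
         ifelse(energy <= 50,
                5.0 + 17.0 * exp(-log(2 * energy)^2 / 6),
                2.5 + 3.25 * exp(-log(0.04 * energy)^2 / 6)))
}

#' Neutron energy spectrum
#'
#' A histogram-like list of (energy, weight) entries for the neutrons
#' produced at one position/mode. Weights are relative counts; their
#' absolute normalisation is not interpreted.
#'
#' @param energy Neutron energies in MeV, positive.
#' @param weight Non-negative weights (default unit counts).
#' @param position,mode Labels.
#' @return An object of class `neutron_spectrum`.
#' @examples
#' neutron_spectrum(c(0.5, 10, 60))
#' @export
neutron_spectrum <- function(energy, weight = rep(1, length(energy)),
                             position = NA, mode = NA) {
  if (!length(energy)) stop_config("spectrum must be non-empty")
  assert_number(energy, "energy")
  if (any(energy <= 0)) stop_config("'energy' must be positive")
  assert_number(weight, "weight", lower = 0)
  if (length(weight) != length(energy)) {
    stop_config("'energy' and 'weight' lengths differ")
  }
  structure(data.frame(energy = energy, weight = weight),
            class = c("neutron_spectrum", "data.frame"),
            position = position, mode = mode)
}

neutron_class_labels <- c("<=1", "1-50", ">=50")

#' Categorize a neutron spectrum into ICRP-103 energy classes
#'
#' Splits the spectrum into the three energy classes used to summarise
#' neutron production (at or below 1 MeV, 1-50 MeV, above 50 MeV) and
#' reports per-class weights, percentages of the total, and the
#' weight-averaged ICRP-103 radiation weighting factor. Boundary atoms
#' (exactly 1 or 50 MeV) are assigned to the lower class, matching the
#' conventional "<=1 / 1-50 / >=50" table labels; the intervals are
#' therefore (0, 1], (1, 50], (50, Inf).
#'
#' @param spectrum A [neutron_spectrum()].
#' @return A `neutron_classification`: list with `counts` (per-class
#'   summed weights), `percent`, `total`, `mean_wr`, `position`, `mode`.
#' @examples
#' classify_neutrons(neutron_spectrum(c(0.5, 10, 60)))
#' @export
classify_neutrons <- function(spectrum) {
  stopifnot(inherits(spectrum, "neutron_spectrum"))
  if (sum(spectrum$weight) <= 0) stop_config("spectrum has zero total weight")
  cls <- cut(spectrum$energy, c(0, 1, 50, Inf), right = TRUE,
             labels = neutron_class_labels)
  counts <- vapply(split(spectrum$weight, cls), sum, numeric(1))
  total <- sum(counts)
  wr <- icrp103_neutron_wr(spectrum$energy)
  structure(
    list(counts = counts,
         percent = 100 * counts / total,
         total = total,
         mean_wr = sum(wr * spectrum$weight) / sum(spectrum$weight),
         position = attr(spectrum, "position"),
         mode = attr(spectrum, "mode")),
    class = "neutron_classification"
  )
}

#' @export
print.neutron_classification <- function(x, ...) {
  cat(sprintf("Neutron classification (position %s, mode %s):\n",
              x$position, x$mode))
  for (i in seq_along(x$counts)) {
    cat(sprintf("  %-5s MeV: %12.5g  (%s %%)\n",
                names(x$counts)[i], x$counts[i],
                format_sci3(x$percent[i])))
  }
  cat(sprintf("  mean w_R: %.3f\n", x$mean_wr))
  invisible(x)
}

# Scientific display with 3 significant digits, as in neutron summary
# tables ("1.00e+02", "5.99e-06").
format_sci3 <- function(x) formatC(x, format = "e", digits = 2)
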