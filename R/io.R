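# CSV round-trip helpers for the file schemas used by the pipeline, and
# accessors for the bundled reference tables.

check_columns <- function(df, need, what) {
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop_config(what, " is missing column(s): ", paste(missing, collapse = ", "))
  }
  invisible(df)
}

#' Read / write colony-count tables
#'
#' Plain-CSV persistence of well-level colony counts (columns `mode`,
#' `position`, `dose`, `run`, `well`, `seeded`, `colonies`).
#'
#' @param records Colony-count data frame.
#' @param path File path.
#' @return `read_colony_counts()` returns the data frame; the writer
#'   returns `path` invisibly.
#' @export
write_colony_counts <- function(records, path) {
  check_columns(records, c("mode", "position", "dose", "run", "well",
                           "seeded", "colonies"), "colony-count table")
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_colony_counts
#' @export
read_colony_counts <- function(path) {
  check_columns(utils::read.csv(path), c("mode", "position", "dose", "run",
                                         "well", "seeded", "colonies"),
                "colony-count table")
}

#' Read / write endpoint measurement tables
#'
#' CSV schema: `endpoint`, `mode`, `position`, `dose`, `time_h`, `run`,
#' `replicate`, `value`.
#'
#' @param measurements Endpoint data frame.
#' @param path File path.
#' @export
write_endpoint_data <- function(measurements, path) {
  check_columns(measurements, c("endpoint", "mode", "position", "dose",
                                "time_h", "run", "replicate", "value"),
                "endpoint table")
  utils::write.csv(measurements, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_endpoint_data
#' @export
read_endpoint_data <- function(path) {
  check_columns(utils::read.csv(path), c("endpoint", "mode", "position",
                                         "dose", "time_h", "run",
                                         "replicate", "value"),
                "endpoint table")
}

#' Read / write LET spectra
#'
#' CSV schema: `species`, `let_kev_um`, `dose_weight`, `position`,
#' `mode`; one row per spectral component. The reader reassembles one
#' [let_spectrum()] per species/position/mode combination.
#'
#' @param spectra A list of `let_spectrum` objects.
#' @param path File path.
#' @return The reader returns a list of `let_spectrum` objects.
#' @export
write_let_spectra <- function(spectra, path) {
  rows <- do.call(rbind, lapply(spectra, function(s) {
    data.frame(species = attr(s, "species"), let_kev_um = s$let,
               dose_weight = s$dose_weight,
               position = attr(s, "position"), mode = attr(s, "mode"))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_let_spectra
#' @export
read_let_spectra <- function(path) {
  df <- check_columns(utils::read.csv(path),
                      c("species", "let_kev_um", "dose_weight",
                        "position", "mode"), "LET spectrum table")
  key <- paste(df$species, df$position, df$mode, sep = "|")
  lapply(split(df, key), function(g) {
    let_spectrum(g$species[1], g$let_kev_um, g$dose_weight,
                 position = g$position[1], mode = g$mode[1])
  })
}

#' Read / write neutron spectra
#'
#' CSV schema: `energy_MeV`, `weight`, `position`, `mode`.
#'
#' @param spectrum A `neutron_spectrum`, or a list of them.
#' @param path File path.
#' @export
write_neutron_spectrum <- function(spectrum, path) {
  if (inherits(spectrum, "neutron_spectrum")) spectrum <- list(spectrum)
  rows <- do.call(rbind, lapply(spectrum, function(s) {
    data.frame(energy_MeV = s$energy, weight = s$weight,
               position = attr(s, "position"), mode = attr(s, "mode"))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_neutron_spectrum
#' @export
read_neutron_spectrum <- function(path) {
  df <- check_columns(utils::read.csv(path),
                      c("energy_MeV", "weight", "position", "mode"),
                      "neutron spectrum table")
  key <- paste(df$position, df$mode, sep = "|")
  out <- lapply(split(df, key), function(g) {
    neutron_spectrum(g$energy_MeV, g$weight,
                     position = g$position[1], mode = g$mode[1])
  })
  if (length(out) == 1) out[[1]] else out
}

#' Bundled reference tables
#'
#' Published summary tables for the DAOY medulloblastoma PBS-vs-DS
#' proton comparison study that this package models, shipped as plain
#' CSV under `extdata`:
#' \describe{
#'   \item{`reference_lq_parameters()`}{Fitted linear-quadratic
#'     parameters (alpha, beta, their standard errors and R^2) for the
#'     Co-60 reference curve and the four proton conditions PBS1, PBS2,
#'     DS1, DS2 (mode x position; 1 = plateau, 2 = Bragg peak).}
#'   \item{`reference_letd_targets()`}{Dose-averaged LET values
#'     (keV/um) per particle species, position and mode, including the
#'     all-particle rows.}
#'   \item{`reference_neutron_fractions()`}{Fractions of produced
#'     neutrons in the ICRP-103 energy classes per position and mode.}
#' }
#'
#' @return A data frame.
#' @examples
#' reference_lq_parameters()
#' @export
reference_lq_parameters <- function() {
  utils::read.csv(system.file("extdata", "lq_reference_parameters.csv",
                              package = "protonrbe"))
}

#' @rdname reference_lq_parameters
#' @export
reference_letd_targets <- function() {
  utils::read.csv(system.file("extdata", "letd_reference.csv",
                              package = "protonrbe"))
}

#' @rdname reference_lq_parameters
#' @export
reference_neutron_fractions <- function() {
  utils::read.csv(system.file("extdata", "neutron_reference.csv",
                              package = "protonrbe"))
}

#' Reference fits from the bundled LQ parameter table
#'
#' Convenience wrapper turning [reference_lq_parameters()] into named
#' [lq_fit()] objects ready for [compute_rbe()].
#'
#' @return A named list of `lq_fit` objects (`Co60`, `PBS1`, `PBS2`,
#'   `DS1`, `DS2`).
#' @examples
#' fits <- reference_lq_fits()
#' compute_rbe(fits$Co60, fits$PBS2)
#' @export
reference_lq_fits <- function() {
  tab <- reference_lq_parameters()
  fits <- lapply(seq_len(nrow(tab)), function(i) {
    lq_fit(tab$alpha[i], tab$beta[i], tab$se_alpha[i], tab$se_beta[i],
           r_squared = tab$r_squared[i], label = tab$label[i])
  })
  stats::setNames(fits, tab$label)
}
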