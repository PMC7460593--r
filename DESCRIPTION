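Package: protonrbe
Title: Radiobiological Comparison of Passive and Active Proton Beams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing the biological effectiveness of clinical
    proton beam delivery modes (pencil beam scanning versus double
    scattering) at plateau and Bragg-peak positions. Provides a synthetic
    data generator for clonogenic colony counts, apoptosis, micronucleus
    and gamma-H2AX endpoints and for particle LET and neutron spectra; a
    simplified analytic proton beam model (Bragg-Kleeman range-energy,
    Bethe stopping power, pristine Bragg depth-dose); dose-averaged LET
    and ICRP-103 neutron weighting; linear-quadratic survival fitting
    with uncertainties; RBE estimation at a fixed survival level with
    delta-method error propagation; and the two-stage F-test / t-test
    comparison procedure, orchestrated by a reproducible reporting
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
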