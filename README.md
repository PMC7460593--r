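# protonrbe

Tools for the computational side of an in vitro comparison of passive
(double scattering, DS) and active (pencil beam scanning, PBS) clinical
proton beams: does the very different dose rate of the two delivery
modes change their biological effectiveness? The package is aimed at
radiobiologists and medical physicists who want a reproducible,
testable version of the standard analysis chain for such experiments —
from raw colony counts and particle spectra to fitted survival curves,
RBE values and significance calls.

## What it computes

* **Linear-quadratic survival.** Clonogenic data are fitted with
  S(D) = exp(−αD − βD²). `surviving_fractions()` normalises colony
  counts by per-run plating efficiency; `fit_lq()` estimates (α, β)
  with standard errors, propagating the shared plating-efficiency
  error as a correlated covariance term.
* **RBE at a fixed survival level.** `isoeffect_dose()` solves
  αD + βD² = ln(1/S); `compute_rbe()` forms the dose ratio against a
  Co-60 reference (default S = 0.5) with a delta-method standard
  error.
* **Dose-averaged LET.** `dose_average_let()` implements
  LET_d = Σᵢ LETⁱ·Dᵢ / Σᵢ Dᵢ over per-species spectra;
  `combine_species()` pools species into an all-particle value.
* **ICRP-103 neutron weighting.** `icrp103_neutron_wr()` is the
  continuous w_R(E) (2.5 at both energy extremes, peak 20.7 at
  1 MeV); `classify_neutrons()` splits spectra into the ≤1 / 1–50 /
  ≥50 MeV classes and reports the mean w_R.
* **Two-stage statistics.** `compare_groups()` reproduces the
  variance-F-test-gated Student/Welch t-test convention used for all
  endpoints.
* **Analytic beam model.** Bragg-Kleeman range-energy
  (R = 0.0022·E^1.77 cm in water), Bethe stopping power, and a
  pristine Bragg depth-dose curve with Gaussian range straggling.
* **Synthetic study data.** Generators for colony counts (Poisson
  around the LQ mean), apoptosis / micronucleus / γH2AX endpoints
  (binomial and Poisson noise), LET spectra with prescribed dose
  averages, and neutron spectra with prescribed class fractions —
  everything seeded and reproducible.

`run_pipeline()` chains all stages (simulate → analyze → report) into
a deterministic report bundle of CSV tables plus a JSON summary.

## Worked example

```r
library(protonrbe)

# RBE at 50% survival from the bundled published LQ parameter table
fits <- reference_lq_fits()
compute_rbe(fits$Co60, fits$PBS2)
#> RBE_50% [PBS2 vs Co60]: 1.560 +- 0.207  (iso doses 2.746 / 1.761 Gy)
```

The Co-60 curve needs 2.746 Gy to reach 50% survival, the PBS
Bragg-peak condition only 1.761 Gy, so protons at the peak are ~1.56×
as effective per gray; the ±0.207 is the delta-method error from the
published parameter uncertainties.

```r
# a full synthetic replica of the study, end to end
cfg <- default_pipeline_config(seed = 42)
res <- run_pipeline(cfg)
res$rbe[, c("test", "rbe", "se")]
#>   test      rbe         se
#> 1  DS1 1.113476 0.05661823
#> 2  DS2 1.291605 0.06194665
#> 3 PBS1 1.489961 0.09226230
#> 4 PBS2 1.592388 0.10026978
sum(res$comparisons$significant)   # PBS-vs-DS endpoint differences
#> [1] 2
```

The refitted RBE values scatter around the generative truth. The
endpoint models are identical for both modes by default, so PBS-vs-DS
differences are pure noise: 2 significant calls out of 40 comparisons
is right at the 5% per-comparison false-positive rate. A shell entry
point with the same behaviour is
`Rscript scripts/run_pipeline.R --seed 42 --outdir out`.

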