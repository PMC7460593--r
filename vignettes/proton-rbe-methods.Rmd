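---
title: "Methods: modelling a passive-vs-active proton beam comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling a passive-vs-active proton beam comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protonrbe)
```

## The scientific setting

Clinical proton beams are delivered either passively (double scattering,
DS) or actively (pencil beam scanning, PBS). The two modes can be tuned
to nearly identical depth-dose curves, but their dose rates differ by
orders of magnitude, which raises the question whether they are
biologically interchangeable. The canonical in vitro design answering it
irradiates a cell line (here a medulloblastoma line with plating
efficiency 30%) at two depths of the pristine Bragg curve — a plateau
position (2 cm) and a peak position (23.6 cm) — with both modes at
matched doses (1, 3, 5 Gy), alongside a Co-60 photon reference
(0-5 Gy), and follows clonogenic survival, apoptosis, the
cytokinesis-block micronucleus assay and gamma-H2AX foci.

This package reproduces that analysis chain computationally. No raw
study data are deposited anywhere, so a first-class synthetic-data
module generates every input the analysis consumes; the published
summary tables (LQ parameters, dose-averaged LET values, neutron class
fractions) are bundled as plain CSV and serve both as generative truth
and as reference points.

## Clonogenic survival and the linear-quadratic model

Survival is modelled as \(S(D) = \exp(-\alpha D - \beta D^2)\).
Colony counts per well are generated as Poisson with mean
\(\text{seeded} \times PE \times S(D)\) — colony formation is a counting
process, and the published figures only report means and SDs, so
Poisson is the natural minimal noise family. Default seeding (200 /
400 / 1500 / 5000 cells at 0/1/3/5 Gy) keeps expected colony counts in
the countable 60-190 range, as a bench protocol would.

`surviving_fractions()` normalises each run by that run's own 0 Gy
controls: \(SF = (\text{colonies}/\text{seeded}) / PE\). Two choices
deserve comment:

* **Pooled SDs.** With two runs of six wells, a run-level SD has a
  single degree of freedom and makes inverse-variance weights erratic.
  The default therefore pools all wells of a condition for the SD
  (11 degrees of freedom); `sd_method = "runs"` gives the strict
  run-level alternative.
* **The shared plating-efficiency error.** The PE estimate divides
  every surviving fraction of its run, so its sampling error moves the
  whole curve coherently rather than scattering points independently.
  `surviving_fractions()` records the variance of the log-PE and
  `fit_lq()` adds it as a fully correlated component of the error
  covariance (a generalized-least-squares term). Omitting it
  underestimates the parameter standard errors substantially: in our
  simulations 2-SE coverage drops from ~0.93 to ~0.75.

`fit_lq()` works by default on the log-survival scale, where the model
is linear in \((\alpha, \beta)\) with no intercept; the 0 Gy point is
exact by construction (zero residual and zero variance) and is not
included among the fitted points. Weights are the inverse variances of
the mean log-SF; when SDs are unavailable the fit falls back to
ordinary least squares with residual-based standard errors. Both
parameters are constrained non-negative (standard radiobiology
convention), with active-set clamping at the boundary.
`scale = "linear"` provides untransformed-scale least squares via
Gauss-Newton for users who prefer fitting \(S\) directly. \(R^2\) is
reported on the scale of fitting.

Simulated-then-refitted parameters at the five bundled truth sets are
unbiased within Monte-Carlo error and their 2-SE intervals cover the
truth in more than 90% of seeded replicates (the test suite checks 500
replicates per truth set; problem size chosen to keep the whole suite
under a minute while leaving the Monte-Carlo error on coverage below
1.5 percentage points).

## Isoeffect doses and RBE

The isoeffect dose at surviving fraction \(S\) solves
\(\alpha D + \beta D^2 = \ln(1/S)\):

\[D = \frac{-\alpha + \sqrt{\alpha^2 + 4\beta \ln(1/S)}}{2\beta},\]

with the linear limit \(\ln(1/S)/\alpha\) at \(\beta = 0\). The
relative biological effectiveness at level \(S\) is the dose ratio
\(\mathrm{RBE}_S = D_\text{ref}(S) / D_\text{test}(S)\) with the Co-60
curve as reference, evaluated by default at \(S = 0.5\).

Uncertainty is propagated to first order (delta method) through both
isoeffect doses using the analytic gradient of \(D\) in
\((\alpha, \beta)\), each fit's internal covariance, and independence
of the two fits. When fits come from a published table without
covariances, the off-diagonal term defaults to zero — that choice is
conservative in neither direction and is simply the information
available. A parametric bootstrap cross-check (drawing
\((\alpha, \beta)\) from their reported standard errors) agrees with
the delta-method SE within 15% on the bundled configurations; the
residual gap is genuine curvature of the dose ratio in the parameters,
which a first-order method ignores.

Recomputing RBE at 50% survival from the bundled (rounded,
two-decimal) LQ table gives 1.41 / 1.56 / 1.11 / 1.31 for
PBS1/PBS2/DS1/DS2. Values derived from rounded published parameters
sit a few percent above the originally reported 1.34 / 1.48 / 1.05 /
1.26, consistent with the original fits having used unrounded
parameters; all four agree within the published standard errors
(0.16-0.20), which is the agreement this package claims.

## Dose-averaged LET and neutron weighting

The LET summary of a mixed particle field is the dose-weighted mean

\[\mathrm{LET}_d = \frac{\sum_i \mathrm{LET}^i D_i}{\sum_i D_i},\]

implemented in `dose_average_let()` and pooled across species by
`combine_species()`. The quantity is scale-invariant in the weights,
bounded by the component extremes, and (when dose weights are fluence
times LET) dominates the fluence-averaged LET by Cauchy-Schwarz — all
property-tested against a brute-force loop oracle.

Transport-code spectral shapes behind the published LET_d table are not
available, so `generate_let_spectrum()` builds log-normal component
spectra around each species' target and rescales the below-target and
above-target weight groups so the dose average hits the target exactly.
The default per-species dose shares (protons 96.9%, electrons 3%,
heavier fragments well below 0.1%) reflect a proton-dominated field;
with the bundled per-species targets they reproduce the published
all-particle values (e.g. 3.11 keV/um at the PBS peak) to within about
1%, which the pipeline reports but never tunes toward.

Neutrons carry no LET; they are summarised by ICRP-103 energy classes
and the continuous radiation weighting factor

\[w_R(E) = \begin{cases}
2.5 + 18.2\,e^{-(\ln E)^2/6} & E < 1\ \text{MeV}\\
5.0 + 17.0\,e^{-(\ln 2E)^2/6} & 1 \le E \le 50\ \text{MeV}\\
2.5 + 3.25\,e^{-(\ln 0.04E)^2/6} & E > 50\ \text{MeV}
\end{cases}\]

(continuous at the boundaries, peaking at 20.7 at 1 MeV, tending to
2.5 at both ends). Class boundaries are closed above — atoms at exactly
1 or 50 MeV fall in the lower class, matching the conventional
"&le;1 / 1-50 / &ge;50" table labels. `generate_neutron_spectrum()`
constrains only the class fractions (the published quantity); within
the lowest class it samples log-uniform up to 2.5e-3 MeV by default,
because neutrons observed at depth in water are heavily moderated and
sit on the w_R = 2.5 plateau — sampling the full sub-1 MeV decade
range would instead put most weight near the w_R peak, which is not
what the measured spectra look like. `class1_max = 1` restores full
class support.

## The analytic beam model

The beam module is a deliberately simple stand-in for Monte Carlo
transport, useful for position bookkeeping and sanity checks, not for
dosimetry:

* **Range-energy:** Bragg-Kleeman \(R = aE^p\) with water constants
  \(a = 0.0022\) cm MeV\(^{-p}\), \(p = 1.77\), chosen because they
  reproduce the clinical pairing of 190.6 MeV with a 23.9 g/cm²
  range. Residual energy at depth is the analytic inverse.
* **LET proxy:** unrestricted electronic stopping power from the Bethe
  formula (mean excitation energy 75 eV, no shell/density
  corrections), valid for 1-250 MeV and within a few percent of
  published water tabulations there. Transport codes score LET with
  delta-ray conventions this proxy does not reproduce, so the model
  asserts only robust contrasts (peak-to-plateau LET ratio above 5),
  never the published LET_d values themselves.
* **Depth dose:** the continuous-slowing-down deposition
  \((R-z)^{1/p-1}/(p\,a^{1/p})\) convolved with a Gaussian range
  straggling kernel (\(\sigma = 0.012\,R^{0.935}\) by default). The
  integrable singularity at \(z = R\) is handled on a midpoint grid.
  No nuclear interactions and no secondary buildup are modelled, so
  the entrance dose is lower than a measured curve would show; the
  shape constraints (peak within \([R - 2\sigma, R]\), plateau below
  half-maximum, vanishing tail beyond \(R + 3\sigma\)) are what the
  model guarantees.

## Endpoint statistics

The comparison procedure mirrors the study convention: a two-sided
variance-ratio F-test (larger variance in the numerator) gates the
t-test — below p = 0.05 the Welch form is used, otherwise the pooled
Student form; differences are called significant at two-tailed
p &lt; 0.05. The gate is driven by the F-test's p-value; reading the
threshold as a raw F statistic would make no sense as a
variance-equality criterion. Under normal null simulations with n = 6
per group the full two-stage procedure holds its size (empirical
type-I error ~0.05, checked to lie in [0.03, 0.07] at 10^4
replicates). No multiple-testing correction is applied by default,
matching the per-comparison convention; a Holm option exists.

Endpoint summaries use sample (n-1) standard deviations throughout.
Negative control-subtracted apoptosis excesses are retained and
flagged rather than clamped, keeping condition means unbiased. Whether
replicates should be pooled across runs or compared at run level is
not observable from published figures; `compare_endpoint_conditions()`
works on whatever replicate column structure it is given, and the
pipeline default uses run x duplicate replicates (four values per
arm).

The synthetic endpoint generators use the noise family implied by how
each endpoint is scored: binomial-derived percentages for apoptosis
(about 1000 cells scored per sample) and %BNC-with-MN (about 400 BNC),
Poisson counts for micronuclei and foci. Dose-response forms are
modest and smooth — linear-in-dose apoptosis excess over a
time-dependent background, a linear-quadratic micronucleus mean, and
Poisson foci at 28/Gy over a 0.5 background (within the 25-35
double-strand breaks per nucleus expected at 1 Gy). These emulate the
*structure* of real data (replicate counts, noise families, effect
sizes of the right order), not cell-line-specific kinetics: passing
tests show the pipeline is correct and calibrated, not that any
particular biological claim holds.

## Reproducibility

Every generator is a pure function of its parameters and a seed (RNG
state is scoped and restored), and `run_pipeline()` derives distinct
sub-seeds for each stage from one master seed, so a configuration
reproduces its report bundle byte-for-byte. The bundle contains the
simulated raw data, the per-species LET_d table with all-particle
rows, the neutron classification (full precision and 3-significant-
digit scientific display), the fitted LQ table, the RBE table and the
F-then-t comparison table, plus a JSON summary carrying the seed and a
config hash.

## Known limitations

* The beam model ignores nuclear interactions, secondary buildup,
  energy-spectrum width and lateral structure; it is pedagogical.
* LET spectra are moment-matched log-normal mixtures, not transport
  output; only their dose averages (and the class fractions for
  neutrons) are faithful to the published summaries.
* The delta-method RBE SE is first-order; with parameter SEs as large
  as 20% of the estimates it runs ~10% below a parametric bootstrap.
* Published LQ parameters are bundled at their printed two-decimal
  precision; quantities recomputed from them inherit that rounding.
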