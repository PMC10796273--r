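---
title: "Methods: electron-transfer kinetics, survival modelling and tunnelling analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: electron-transfer kinetics, survival modelling and tunnelling analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qbetr)
```

This vignette is the package's account of the science it implements: the
models, their assumptions, the tunable parameters and their defaults, the
numerical choices, and what the synthetic-data tests do and do not
demonstrate about real instrument data.

## The physical setting

Gold nanoparticles carrying reduced cytochrome *c* and a zinc porphyrin on
PEG tethers act as bipolar nanoelectrodes: an external a.c. field polarizes
each particle, and with enough potential difference between its poles the
tethered redox couple can be driven without wired contact. Three
quantitative questions follow:

1. How fast is interfacial electron transfer at the functionalized particle
   (the heterogeneous rate constant $k^0$)?
2. Is classical charge transport across the tether even possible at the
   driving frequency?
3. If not, does the biological response carry the signature of quantum
   tunnelling — an exponential decay with barrier width?

## Voltammetric kinetics

### Simulator

`simulate_voltammogram()` solves one-electron quasi-reversible
Butler–Volmer kinetics with semi-infinite planar diffusion by explicit
finite differences. Both redox forms share the diffusion coefficient, so
total concentration stays uniform and only the reduced-form profile is
propagated; the species stable at the start potential is the initial form.
The surface boundary couples the Butler–Volmer flux
$j = k^0[c_O e^{-\alpha f\eta} - c_R e^{(1-\alpha)f\eta}]$
(with $f = nF/RT$) to a second-order one-sided concentration gradient;
first-order surface differencing was measurably unconverged (peak positions
moved several mV on grid halving), the second-order form brings the change
under 1 mV, which the test suite asserts.

Discretization defaults: potential step `dE = 1 mV` and stability ratio
$\lambda = D\,\Delta t/\Delta x^2 = 0.45$; the scheme refuses $\lambda >
0.5$ by name. The default window follows the instrument program (+1.2 V to
−0.2 V, formal potential 0.25 V), the default $D = 10^{-6}$ cm² s⁻¹ is a
typical literature magnitude for cytochrome *c*, and currents are scaled by
a 0.385 cm² electrode and 1 µM bulk concentration — the current scale does
not affect peak potentials. Adsorbed-species (thin-layer) voltammetry is
deliberately not modelled: the analysis equations themselves assume
diffusive behaviour (the diffusion coefficient appears in the $k^0$
equation), so the generator matches that treatment; a surface-confined
simulator would be an extension, not a drop-in replacement. Double-layer
charging, uncompensated resistance, convection and migration are out of
scope.

### Peak analysis

`detect_redox_peaks()` splits the sweep at the reversal, fits a linear
baseline to the leading 10% of each branch, smooths with a 5-point moving
average and takes the branch extremum; a branch whose extremum does not
exceed 3× the baseline-region residual noise raises a "no peak" error.
Baseline subtraction matters: on the reverse branch the counter-peak rides
on the decaying tail of the forward process, and without correction the
near-reversible peak separation reads ~5 mV high.

### From peak separation to $k^0$

The transfer coefficient comes from the regression of $E_p - E_{formal}$ on
$\log_{10} v$, $\mathrm{slope} = -2.3RT/(\alpha n F)$, run on the cathodic
branch by default (conventional for reductive peak-shift analysis) with the
anodic fit also computed and reported. The decade factor is 2.3 exactly (not
2.303) so printed-form hand checks agree. The kinetic parameter uses the
exponential working function
$\psi = 2.18(\alpha/\pi)^{1/2}\exp[-(\alpha^2F/RT)\,n\,\Delta E_p]$
and $k^0 = \psi\,[\pi D n v F/RT]^{1/2}$. $D$ has **no silent default** in
the analysis functions: it is instrument knowledge the user must supply.
Temperature defaults to 298.15 K.

Two caveats are design-relevant and verified numerically by the test suite:

- **Transfer-coefficient identifiability.** The peak-shift slope reaches its
  irreversible asymptote only at large separations. In the quasi-reversible
  window the regression slope is much shallower, and inverting it yields
  absurdly large $\alpha$; `analyze_study()` therefore accepts an
  independently known `alpha_ct` (recommended), clamps regression values to
  1.5 with a loud warning, and flags anything above 1 as physically suspect.
- **Working-function bias.** The exponential $\psi(\Delta E_p)$ form is an
  irreversible-regime approximation. Against the simulator (an independent
  numerical solution of the same kinetics) it tracks the true relation to
  within ~15% once $\Delta E_p \gtrsim 130$ mV, but *underestimates* $\psi$
  by 2–4× between 61 and ~100 mV. Peak separations below $61/n$ mV are
  excluded outright ("near-reversible" warning); separations in the
  61–130 mV band are retained — they are what the method as published uses —
  so rate constants recovered there are systematically low. In practice:
  with scan rates confined to 0.05–2 V s⁻¹ and $D = 10^{-6}$ cm² s⁻¹, the
  mean-$k^0$ round trip through the simulator is accurate to ~16% at
  $k^0 = 2\times10^{-3}$ cm s⁻¹ but degrades to ~46% at $5\times10^{-3}$
  and ~67% at $10^{-2}$ cm s⁻¹. Users needing accuracy in the
  quasi-reversible band should push scan rates as high as the instrument
  allows or treat the exponential-form $k^0$ as a lower bound.

The peak-separation unit is volts throughout; values above 1.5 V are
rejected as probable millivolt inputs (a millivolt-scale mistake changes
$\psi$ by more than an order of magnitude).

## Survival model and charging rates

With an intrinsic death rate proportional to the donor charging rate, dead
cells accrue as $D(t) = \int_0^t A(t')\,r_d\,dt'$, giving
$M(t) = A/(A+D) = e^{-r_d t}$ and the inverse $r_d = -\ln M(t)/t$.
`evolve_survival()` implements the exact exponential update (total count
conserved identically; two steps of $dt$ equal one of $2dt$ to machine
precision), and `charging_rate_from_activity()` / `predicted_activity()`
are exact mutual inverses, which the tests assert to $10^{-12}$ over
$r_d \in [0, 10]$ h⁻¹.

Aggregation order is per replicate first: $r_d$ is computed for each well,
then averaged within a (cell line, diameter, linker mass) condition, with
the standard error of that mean reported — matching error bars defined on
per-replicate rates and avoiding the log-of-mean/mean-of-log ambiguity.
Control-normalized activity can legitimately exceed 1 (a treated well more
active than control); such wells give negative per-replicate rates, the
condition is tagged, and any condition whose *mean* rate is non-positive is
excluded from barrier fitting with a warning — an activity gain has no
interpretation under a pure-death model.

### Linker mass to barrier width

The tether mass (kDa) converts to a length via the PEG contour convention,
0.35 nm per 44.05 Da ethylene-oxide monomer, so 1, 2, 3.5 and 5 kDa map to
about 7.9, 15.9, 27.8 and 39.7 nm. The conversion is configurable
(`nm_per_monomer`, `monomer_mass_Da`); contour length is an upper bound on
the barrier width of a flexible tether, which is worth remembering when
interpreting absolute (not relative) decay constants.

## Tunnelling-barrier fit

Tunnelling probability decays exponentially with barrier width,
$P \propto e^{-\alpha r}$; identifying the barrier with the linker length
gives the working model $r_d(L) = \beta e^{-\alpha L}$.
`fit_barrier_decay()` estimates $(\alpha, \beta)$ by weighted nonlinear
least squares initialized from the log-linear regression of $\ln r_d$ on
$L$; both estimates are reported and agree to well under 1% on clean data.
$R^2$ is computed on the untransformed scale. A degenerate surface (for
example exactly flat data) falls back to the log-linear solution with
delta-method errors and a warning.

**Weighting.** When the input carries per-condition standard errors and
replicate counts, the within-condition replicate variances are pooled
before forming $1/\mathrm{se}^2$ weights (default
`pool_variances = TRUE`). The justification is the noise model itself:
multiplicative activity noise at a common readout time gives every
condition's per-replicate rate the same variance, so each condition's own
few-replicate variance estimate is just a noisy copy of a shared quantity.
Weighting by the raw 8-degree-of-freedom estimates is measurably harmful on
simulated plates: it inflates the sampling spread of $\hat\alpha$ by ~13%
and leaves the nominal 2-se interval covering the truth in only ~85% of 200
seeded runs, whereas pooling restores ~92% coverage with efficient
estimates. Because pooled weights are treated as known inverse variances,
parameter errors come from the weighted Jacobian without residual-variance
rescaling (the fixed-effect meta-analytic convention); unweighted fits use
the usual residual-variance estimate. Raw per-condition weighting remains
available (`pool_variances = FALSE`) for genuinely heteroscedastic designs,
e.g. conditions read out at different times.

## Classical feasibility

An electron moving at the interfacial velocity $k^0$ (cm s⁻¹) for one field
cycle covers at most $d = k^0/f$, converted to nm ($\times 10^7$).
`max_hop_distance()` reports full precision and one significant figure;
`classical_feasibility()` compares against the linker length with an
*inclusive* boundary ($d = L$ counts as possible — the bound is already an
overestimate of classical reach, so the inclusive convention only makes the
verdict more conservative). For the bifunctionalized-particle regime
($k^0 = 3.75\times10^{-3}$ cm s⁻¹, 3 MHz) the bound is 0.0125 nm against a
~16 nm barrier: classical transport is excluded by three orders of
magnitude, which is the package's one desk-recomputable headline number.

## Spectral analysis

Difference spectra are formed after resampling both spectra onto the
intersection of their ranges at the finer native step (linear
interpolation, no extrapolation) and normalizing each spectrum — by its
maximum by default, since acquisitions from different particles have
arbitrary intensity scales; `none` and trapezoidal `area` are selectable.
Subtraction is exactly antisymmetric, and max-normalization makes the
result invariant to positive rescaling of either input, both asserted
exactly in the tests.

"Quantized dips" are local minima of the difference ranked by topographic
prominence; the dip wavelength is reported at the extremum grid sample with
no sub-grid refinement, because 1 nm grids already resolve the ~10 nm-wide
features of interest. Peak localization (`peak_max()`) smooths with a
5-point moving average inside a window (defaults: Soret 380–450 nm, Q-band
500–580 nm, LSPR 550–800 nm), breaks ties toward the window centre with a
"no distinct peak" warning, and is invariant to constant baselines.

The Soret-band redox call classifies the shift of the absorbance maximum:
blueshift at or beyond 2 nm (configurable) calls the haem oxidized,
redshift reduced, anything smaller unchanged. The 2 nm default sits well
above the 1 nm grid resolution while remaining sensitive to the ~5 nm
blueshift characteristic of ferro- to ferri-cytochrome switching.
Multi-frame scattering acquisitions are accepted as one column per frame
and averaged on read. A reported "20 mV" plasmon-peak shift in this class
of experiments is ambiguous in unit and is deliberately not asserted
anywhere.

## Synthetic data: what it does and does not show

The generators emulate the *statistical structure* the analysis assumes:
quasi-reversible peak pairs whose separation grows with scan rate; activity
plates on the 20/50/100 nm × 1/2/3.5/5 kDa grid decaying as
$e^{-\beta e^{-\alpha L} t}$ with multiplicative log-normal noise (clipped
at 1.5 to emulate control normalization; defaults $\beta = 0.1$ h⁻¹,
$\alpha = 0.1$ nm⁻¹, 12 h readout, 9 replicates, 5% noise — values chosen
once as realistic for a 12 h stimulation assay with a plate-reader CV of a
few percent); and multi-band spectra with Gaussian bands near the
characteristic positions (465, 536, 568, 612, 711 nm). All randomness flows
from one explicit integer seed per call through a private RNG stream; no
global random state is consumed, and equal seeds give bit-identical output.

Passing the recovery tests therefore shows the *estimators are correct and
calibrated under the stated noise models* — it does not validate those
noise models against real instruments. Real voltammograms add double-layer
charging and iR drop; real plates have plate-edge and batch effects and
possibly time-varying death rates; real spectra have wavelength-dependent
(often Poisson) noise and instrument response. The per-condition linker
length is treated as exact; PEG polydispersity can be emulated via a
configurable length jitter rather than asserted.

## Problem sizes and reproducibility

The shipped tests use the default 1 mV potential grid (2,800 time steps per
sweep), 200 seeded plates for the coverage study, and 50 seeded spectra for
dip recovery — sizes chosen so the whole suite runs in well under a minute
while keeping Monte-Carlo standard errors on the checked proportions below
~2 percentage points. The end-to-end pipeline (`run_full_analysis()`) is
byte-deterministic for a fixed configuration and seed, modulo the
provenance timestamp, and its JSON reports record every skipped stage
explicitly.
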