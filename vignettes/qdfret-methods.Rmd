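---
title: "Models and methods behind qdfret"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind qdfret}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qdfret)
```

# The measurement this package models

A glycan-capped quantum dot (QD, emission ~550 nm) acts as a multivalent
binding scaffold and FRET donor; a dye-labelled lectin (emission ~628 nm)
is the acceptor. Because energy transfer only operates over a few
nanometres, acceptor emission under donor excitation reports the amount of
lectin actually bound to the QD surface. The working observable is the
apparent FRET ratio

$$F = I_A / I_D,$$

the acceptor-to-donor intensity ratio after background correction. Being a
ratio of two signals from the same sample, it is independent of absolute
intensity scale — slit widths, detector gain, and (under a fixed
protein:QD molar ratio, PQR) concentration — which is what makes it usable
as a binding fraction readout.

## Spectrum handling

`correct_spectrum()` subtracts a protein-only background recorded on the
identical wavelength grid, removing acceptor direct excitation.
Two numerical choices matter:

* Negative corrected intensities are **kept**, not clipped. Clipping noise
  at zero biases every downstream average upward; the count of negative
  points is reported instead so gross background mismatch is visible.
* Spectra on different grids are never resampled implicitly; an explicit
  `resample_spectrum()` (linear interpolation, no extrapolation) must be
  called. Silent resampling is a classic way to hide unit errors.

Peak intensities are read at the grid point nearest the nominal
wavelength (550/628 nm); a ±2 nm mean window is available because nominal
emission maxima are approximate. On a 1 nm grid the two conventions agree
to well under 1% for peaks of realistic width.

`overlap_integral()` and `forster_radius()` implement standard FRET
theory, $J = \int f_D(\lambda)\,\varepsilon_A(\lambda)\,\lambda^4
d\lambda$ (trapezoidal quadrature, donor area-normalised) and
$R_0 = 0.02108\,(\kappa^2 n^{-4} \Phi_D J)^{1/6}$ nm with $J$ in
M$^{-1}$cm$^{-1}$nm$^4$. Defaults $\kappa^2 = 2/3$ and $n = 1.33$ assume
isotropic dynamic orientational averaging in aqueous buffer — appropriate
for a dye tethered to a tumbling protein, and the convention used when no
anisotropy data exist. Because the integration range and extinction data
behind any particular published $R_0$ are rarely recoverable, the radius
is validated on synthetic spectra by formula inversion, never against a
single published number.

# Equilibrium affinity

Titrations at fixed PQR are fitted with the Hill isotherm

$$F(x) = F_0 + (F_{max} - F_0)\frac{x^n}{K_d^n + x^n},$$

with $n$ fixed at 1 by default: at PQR = 1 most QDs carry at most one
lectin, so no cooperativity between lectins on one QD is expected, and a
free $n$ on 8–14 titration points mostly absorbs noise. $F_0$ is fixed at
0 because the spectra are acceptor-direct-excitation corrected; both
constraints can be released. When per-point replicate SDs are present the
fit weights points by $1/\mathrm{SD}^2$, mirroring practice of weighting
by per-point standard errors; with only three replicates per point these
weights are themselves noisy, so `weights = "none"` is exposed and the
Monte-Carlo calibration below covers both.

Starting values are deterministic (no random restarts): $F_{max}$ from the
curve top, $K_d$ from the concentration nearest half-maximal signal.
Optimisation is Levenberg–Marquardt (`minpack.lm`); tests require the
optimum to match an exhaustive 2-D grid search over the same weighted SSE.

`simulate_fixed_pqr_titration()` offers an `ideal` hyperbola (free ≈
total) and a `mass_balance` mode solving the exact 1:1 quadratic per
point, with the QD treated as a single binding entity at PQR = 1.

## The fixed-QD apparent-Kd floor

Conventional designs titrate protein against a *fixed* QD concentration
and read $K_d$ from the half-maximal signal. With total site concentration
$N \cdot C_{QD}$, ligand depletion pins the half-saturation point at
$C_{QD} \times N \times 50\%$ for any binder much stronger than that:
`apparent_kd_fixed_qd()` simulates this with an independent-site mass
balance and locates half-saturation by monotone interpolation on
log-concentration (avoiding grid-resolution bias). A 0.01 nM binder at
$C_{QD}$ = 10 nM, $N$ = 4 reads ~20 nM; a 1000 nM binder is recovered
within 5%. The ratiometric fixed-PQR design has no such floor, which is
why it can resolve low-nanomolar multivalent avidities.

# Van't Hoff thermodynamics

With $\Delta G^\circ = RT\ln K_d$ ($K_d$ in mol/L against the 1 M standard
state) and $\Delta G^\circ = \Delta H^\circ - T\Delta S^\circ$,
$\ln K_d$ is linear in $1/T$:

$$\ln K_d = \frac{\Delta H^\circ}{R}\cdot\frac{1}{T} -
\frac{\Delta S^\circ}{R}.$$

`vant_hoff_fit()` regresses $\ln K_d$ on $1/T$; $\Delta H^\circ = R \cdot
\mathrm{slope}$, $\Delta S^\circ = -R \cdot \mathrm{intercept}$, and
$\Delta G^\circ$, $-T\Delta S^\circ$ are evaluated at $T_{ref}$ = 298.15 K.
Assumptions and choices:

* Constant $\Delta H, \Delta S$ over the span (no heat-capacity term).
  With three temperatures over 10 K a curved fit is not identifiable, so
  this is out of scope by design.
* **Weighting.** The default is unweighted; `weighting = "sd"` weights by
  $1/\mathrm{var}(\ln K_d)$ with $\mathrm{var}(\ln K_d) \approx
  (K_{d,sd}/K_d)^2$ by error propagation. On the packaged affinity table
  the two modes move $\Delta H^\circ$ by 2–5% while $\Delta G^\circ$
  shifts by under 0.1 kJ/mol — free energy at the middle temperature is
  interpolation, enthalpy is slope, and only the slope is sensitive to
  how the endpoints are weighted. Both modes are reported by the
  thermodynamics analysis script for exactly this reason.
* Temperatures in input files are °C and converted by $T/\mathrm{K} =
  T/°\mathrm{C} + 273.15$; two distinct temperatures fit with a warning
  (zero residual degrees of freedom), one is a rank-deficiency error.

`classify_driving_force()` labels a fit *enthalpy-driven* when
$\Delta H^\circ < 0$ supplies more than half of $|\Delta G^\circ|$,
*entropy-driven* when $\Delta H^\circ \ge 0$ so the favourable
$-T\Delta S^\circ$ must carry all of the binding, and *mixed* otherwise.
The threshold is a parameter, not a law of nature; the default separates
the three lectin profiles in the packaged table cleanly (an
enthalpy-driven wild type, an entropy-driven truncation mutant, and an
enthalpy-driven weak binder with a large entropic penalty).

# Stopped-flow kinetics

Association at equal reactant concentrations $x_0$ is fitted by

$$y(t) = y_{max}\left(1 - e^{-k_{on} x_0 t}\right) - a\,t$$

and dissociation under excess competitor by the pseudo-first-order form

$$y(t) = y_{eq} + (y_0 - y_{eq})\,e^{-k'_{off} t} - a\,t.$$

The drift constant $a$ absorbs slow linear signal change: positive values
correspond to gradual QD dimming in binding buffer; a *negative* fitted
$a$ flags a slow secondary association superimposed on the main rise
(`drift_class = "secondary_association"`), as seen for cross-linking
binders that keep assembling long after the initial contact. An
alternative integrated second-order (`hyperbolic`) association form is
provided; the exponential form is the default because its half-life
identity $t_{1/2} = \ln 2/(x_0 k_{on})$ reproduces the benchmark
half-lives exactly, which the hyperbolic half-rise time $1/(x_0 k_{on})$
does not.

Half-lives are always **computed** from the fitted rates
($\ln 2/(x_0 k_{on})$, $\ln 2/k'_{off}$), never fitted as free
parameters, so they satisfy their defining identities to machine
precision.

Preprocessing follows the instrument workflow: per-wavelength background
subtraction on matched time grids, pointwise replicate averaging, ratio
628/550, and optional non-overlapping block means (block 5 turns a
0.0125 s grid into 0.0625 s). Block means rather than a moving average
because the target is a coarser *sampling resolution*, not a smoothing
kernel — a moving average would correlate adjacent residuals and bias the
fitted standard errors. Zero or negative corrected donor intensity is a
hard error (the ratio is undefined), reported with the offending indices.

## Derived rates

Two reconciliations connect kinetics to equilibrium:

* $K_d' = k'_{off}/k_{on}$ — the affinity implied by the
  competition-measured off-rate. Because the competitor blocks rebinding,
  $k'_{off}$ overestimates the natural off-rate, and $K_d'$ lands roughly
  two orders of magnitude above the equilibrium $K_d$ for strong
  multivalent binders. The package computes it and treats the gap as a
  diagnostic of rebinding, not a contradiction.
* $k_{off} = k_{on} K_d$ — the off-rate consistent with the equilibrium
  affinity, the better estimate of natural dissociation (~0.03–0.05
  s$^{-1}$ on the packaged parameters).

The $K_d' \gg K_d$ relation is asserted only for the two constructs whose
association fits are well determined; the weak binder's apparent $k_{on}$
comes from a low-amplitude trace with a negative drift term and is not a
sound basis for derived rates.

# Cluster-state analysis

Particle centroids from (synthetic) micrographs are grouped by
single-linkage agglomeration cut at a linking distance — default 1.5×
the nominal particle diameter, always an explicit argument because no
universal adjacency criterion exists for micrograph clustering. Fractions
are **per particle** (fraction of QDs in clusters of size 1, 2–3, ≥4),
not per cluster, matching how dispersion states are normally quoted; the
boundary class is ≥4. Classification defaults: *simultaneous* when ≥90%
of particles are isolated, *cross-linking* when ≤30% are isolated and
≥15% sit in clusters of ≥4, *mixed* otherwise.

`detect_particles()` binarises, labels 8-connected components, discards
small components and returns intensity-weighted centroids. Two spots
closer than about one spot diameter merge into a single component — an
irreducible limitation of connectivity-based detection, which is why the
end-to-end image tests use geometry in which particles are resolvable
(spot σ 2 nm, cluster scatter 12 nm, clusters ≥150 nm apart).

# The synthetic-data generator

Every consumer has a seeded generator: titrations (model mean, additive
Gaussian noise per replicate in ratio units, triplicate by default,
per-point SD recorded), temperature series (exact Van't Hoff inverse —
noise-free so round trips are exact), stopped-flow channel pairs, particle
fields, spot images and two-peak spectra. Identical seed and parameters
give bit-identical output, and each generator returns a truth record
sufficient to regenerate its dataset.

Kinetic traces are emitted as *raw channel pairs*, not ratios: the target
ratio curve $r(t)$ is decomposed into a donor falling with bound fraction,
$D(t) = D_0(1 - \varphi f(t))$ with quench depth $\varphi = 0.6$ and
$D_0 = 100$, and an acceptor $A(t) = r(t)D(t)$, so preprocessing exercises
the same division it performs on real data. Channel noise is additive
Gaussian (fixed-gain photodetector readout); the calibration runs use SD 2
on the 40–100-unit channels, i.e. a few percent per sample.

Particle fields: *simultaneous* is a hard-core process (minimum spacing 60
nm, far above the linking distance); *cross-linking* is a Thomas-like
cluster process (hard-core parents, Poisson(6)-sized offspring groups with
minimum 2, Gaussian scatter 4 nm); *mixed* combines isolated particles,
2–3-sized groups and a rare larger cluster with particle-number weights
0.40/0.55/0.05, reproducing the intermediate dispersion pattern.

Construct characterisation helpers are closed-form: valency from the
ligand mass balance (added − unbound)/QD, and inter-glycan spacing by
dividing the sphere surface $\pi D_h^2$ among the ligands (hexagonal
packing by default). The spacing is a flat-packing estimate on a curved
surface and therefore a lower bound; no deflection-angle correction is
attempted.

# Problem sizes, calibration and what the tests do not show

The test suite and analysis scripts run at desk scale: titrations of
10–14 points × 3 replicates, 60 s kinetic traces at 0.0125 s (4801
points), fields of 120–200 particles, and 100-seed Monte-Carlo
calibration blocks. Calibration titrations use a 12-point geometric
dilution series spanning 0.2–50 nM — the standard serial-dilution design
for a low-nanomolar binder, placing several points below $K_d$. With
evenly spaced concentrations over the same range (a design no titration
protocol would use for a 1.5 nM binder, as it leaves a single point below
$K_d$), single-run recovery degrades from ~98% to ~92% within 10%,
although the ensemble bias stays within the calibrated bounds.

Passing tests show the estimators are unbiased and oracle-consistent
*under the generator's assumptions*: additive Gaussian noise, exact
model forms, perfectly matched backgrounds, circular Gaussian spots.
They do not certify behaviour under correlated instrument drift,
photobleaching, inner-filter effects beyond the linearity flag,
non-spherical particles, or detector saturation — the usual gap between
synthetic validation and a real instrument.

# Known limitations

* Free energies assume the 1 M standard state and a two-state binding
  model; no heat-capacity term.
* One drift term per kinetic trace; genuinely biphasic association is
  flagged via the negative drift constant, not fitted with two rates.
* Connectivity-based particle detection merges near-contact spots;
  cluster fractions from dense fields are biased toward larger apparent
  isolation.
* The inter-glycan spacing model ignores ligand deflection and surface
  curvature corrections.
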