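# qdfret

Quantitative analysis of multivalent lectin–glycan interactions measured
by ratiometric quantum-dot FRET.

Multivalent lectin–glycan interactions (MLGIs) — a tetrameric lectin such
as DC-SIGN or DC-SIGNR engaging many glycans displayed on one surface —
reach low-nanomolar avidity from individually weak (high-micromolar)
sugar contacts. A glycan-capped quantum dot (QD, FRET donor) plus a
dye-labelled lectin (acceptor) turns that binding into an apparent FRET
ratio `F = I_A / I_D`, which under a fixed protein:QD molar ratio is
proportional to the bound fraction and independent of absolute signal.
`qdfret` implements the full quantitative chain on that readout, for
biophysicists analysing (or simulating) such assays:

* **Spectra** — background / direct-excitation correction, donor &
  acceptor intensity extraction, FRET ratio, overlap integral and Förster
  radius, inner-filter linearity checks.
* **Equilibrium** — Hill-isotherm fitting, `F = F₀ + (Fmax − F₀)·xⁿ/(K_dⁿ + xⁿ)`
  (n = 1 default), with replicate-SD weighting; exact 1:1 mass-balance
  simulation; the apparent-K_d floor (`C_QD × N × 50%`) of conventional
  fixed-QD titrations.
* **Thermodynamics** — Van't Hoff regression of ln K_d on 1/T giving
  ΔH° = R·slope, ΔS° = −R·intercept, ΔG° and −TΔS° at 298.15 K, plus
  driving-force classification and multivalent/monovalent ratios.
* **Kinetics** — stopped-flow preprocessing (background subtraction,
  replicate averaging, block smoothing), association
  `y = y_max(1 − e^(−k_on·x₀·t)) − a·t` and pseudo-first-order
  dissociation `y = y_eq + (y₀ − y_eq)e^(−k'_off·t) − a·t` fits with a
  linear drift constant, half-lives, and derived rates
  (`K_d′ = k'_off/k_on`, `k_off = k_on·K_d`).
* **Clustering** — single-linkage cluster-state quantification of
  particle fields ({1, 2–3, ≥4} per-particle fractions) and binding-mode
  classification (simultaneous / mixed / cross-linking), with spot
  detection for synthetic micrographs.
* **Synthetic data** — seeded generators for every input above, each
  returning a ground-truth record, so the whole pipeline is testable with
  no instrument.

## Worked example

Van't Hoff decomposition of the packaged temperature-dependent affinities:

```r
library(qdfret)
aff <- affinity_temperature_table()
thermodynamic_summary(aff)
#>      lectin  dH_kJ_mol     dH_sd dS_J_mol_K     dS_sd dG_kJ_mol minus_TdS_kJ_mol   driving_force
#> 1   DC-SIGN -99.227158  1.366421  -169.7389  4.584287 -48.61950         50.60766 enthalpy_driven
#> 2 DC-SIGN-C   2.747497  4.229885   177.5196 14.191094 -50.17996        -52.92746  entropy_driven
#> 3  DC-SIGNR -97.082972 13.613563  -188.8724 45.672959 -40.77067         56.31230 enthalpy_driven
```

Read: DC-SIGN binds with ΔG°(298 K) ≈ −48.6 kJ/mol, driven by a large
favourable enthalpy (−99 kJ/mol) against an entropic penalty (−TΔS° ≈ +51
kJ/mol) — all four carbohydrate-recognition domains engage glycans on one
QD. Truncating its C-terminal segment (DC-SIGN-C) flips the profile to
entropy-driven (ΔH° ≈ +3, −TΔS° ≈ −53 kJ/mol) at nearly unchanged ΔG°,
while DC-SIGNR pays a larger entropic penalty and lands ~8 kJ/mol weaker
(K_d 35 vs 1.5 nM at 20 °C, a >20-fold affinity contrast).

Kinetics, from the packaged stopped-flow parameters at x₀ = 20 nM:

```r
kin <- kinetic_parameter_table()
kd20 <- with(affinity_temperature_table(), setNames(Kd, lectin)[temperature_K == 293.15])
kinetic_summary(kin, x0 = 20e-9, Kd_equilibrium = kd20)[, c(1, 3, 5, 6, 8)]
#>      lectin t_half_assoc_s t_half_dissoc_s   Kd_prime_M k_off_natural_s
#> 1   DC-SIGN      1.5472035       0.2145967 1.441964e-07        0.034496
#> 2 DC-SIGN-C      1.1868959       0.2349651 1.010274e-07        0.047304
#> 3  DC-SIGNR      0.2166085       1.5403271 2.812500e-09        5.600000
```

The competition-derived K_d′ (~140 nM for DC-SIGN) sits two orders of
magnitude above the equilibrium K_d (1.5 nM) because the competitor
blocks rebinding; the equilibrium-consistent natural k_off is ~0.03–0.05
s⁻¹ for the strong binders.

## Analysis workflow

The `analysis/` scripts run the three studies end to end over the package
functions and write tables under `results/`:

```sh
Rscript analysis/01_affinity.R --seed 1        # titration refits + K_d floor
Rscript analysis/02_thermodynamics.R           # Van't Hoff summary table
Rscript analysis/03_kinetics.R --seed 1        # stopped-flow round trip + derived rates
Rscript analysis/04_clustering.R --seed 1      # cluster fractions + binding modes
```

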