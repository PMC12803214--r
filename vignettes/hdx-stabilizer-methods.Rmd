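---
title: "Quantifying kinetic stabilization by differential HDX-MS: models and methods"
author: "hdxlc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying kinetic stabilization by differential HDX-MS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdxlc)
```

This vignette is the package's own account of the science it implements:
the exchange model and its assumptions, the observables and how they are
corrected, the fitting surfaces, what the synthetic-data generator does and
does not emulate, and the numerical choices made where the design was
genuinely open.

## The measurement and its observables

Backbone amide hydrogens of a folded protein exchange with solvent
deuterium at rates governed by hydrogen bonding and solvent exposure. In a
continuous-labeling experiment the protein is diluted into D2O buffer,
quenched at a series of labeling times, digested, and each peptic peptide's
isotopic envelope is measured. Three centroid masses define everything
downstream:

* `m0` — the undeuterated peptide centroid;
* `mt` — the centroid after labeling time `t`;
* `mmaxD` — the centroid of a maximally deuterated control of the same
  peptide, prepared from denatured protein.

Uptake is `mt - m0` (Da). Because some label is lost between quench and
detection (back exchange), absolute uptake understates exchange; the maxD
control experiences the same loss, so the ratio

\[ \%D = 100\,\frac{m_t - m_0}{m_{maxD} - m_0} \]

cancels the per-peptide retention factor exactly. This cancellation is the
central correctness property of the pipeline and is asserted numerically (to
1e-9) against the simulator, where the retention factor is known. Values
slightly outside [0, 100] are legitimate consequences of centroid noise on
small denominators; they are kept, and flagged `out_of_range` only beyond a
±5 %D tolerance (beyond which they are excluded from residue reduction).
The tolerance reflects the stated ±0.20 Da precision of centroid
determination: a short peptide with a 4 Da maxD span can legitimately read
−5 %D from noise alone.

## EX2 forward model

The simulator works in the EX2 limit, where each residue exchanges
independently with observed rate `k_int / P`:

\[ D_i(t) = f_D\,\bigl(1 - e^{-(k_{int,i}/P_i)\,t}\bigr) \]

* `f_D` is the maximal exchangeable fraction, 0.9 by default — a 10-fold
  dilution into D2O labeling buffer leaves 90 % deuterium.
* `P_i = e^{\ln P_i}` is the residue's protection factor; `ln P` is the
  natural stability coordinate.
* `k_int,i` is the intrinsic (unstructured-chain) rate from the standard
  reference-rate method: acid-, base- and water-catalysed terms referenced
  to poly-DL-alanine, with per-residue side-chain inductive factors for the
  residue and its predecessor, terminal-group corrections, and Arrhenius
  temperature correction per catalytic term. The coefficients ship as a
  versioned CSV resource. Titratable side chains are treated in their
  neutral-pD forms, adequate for pD 7–8.5; the uniform `rateOverride` is
  used throughout the test surface so that no asserted value depends on the
  coefficient table. Near pD 7.4 base catalysis dominates, so rates rise
  tenfold per pD unit — one of the suite's checks.

Non-reporting positions: prolines have no amide hydrogen; the protein's
N-terminal residue and the first two residues of every peptide lose label
too fast to report (the standard back-exchange convention; the field's
choice here varies, so it is isolated in one function,
`peptideReporters`). Peptide-level true uptake is the sum of `D_i(t)` times
the deuteron mass increment (1.00628 Da, configurable for unit-mass toys)
over reporters; observed centroids add retention `r` and Gaussian noise
(SD 0.20 Da by default). maxD controls are generated noiseless with the
same retention, matching their per-protein preparation; per-peptide
retention and noisy controls are supported but off by default.

## Ligand coupling

Stabilizer binding (stoichiometry fixed at one ligand per LC dimer; both
protomers assumed equivalent) raises `ln P` by `deltaLogProtection` at
binding-site residues. Two kinetic regimes are modelled:

* `fast_exchange` — free and bound states interconvert quickly on the
  exchange timescale; observed rates mix:
  `k_eff = (1-θ) k_free + θ k_bound`, giving one envelope.
* `slow_two_population` — the two populations exchange separately and the
  spectrum is their weighted sum, producing the bimodal envelopes seen for
  partially bound monomer-dimer mixtures. Mixture centroids are exactly
  θ-linear in this mode; the fast mode is not θ-linear (uptake is convex in
  the mixed rate), though the two agree in the limit
  `deltaLogProtection → 0`, which the suite asserts as a convergence
  sequence.

Occupancy versus total ligand defaults to the phenomenological hyperbola
`θ = L/(EC50 + L)`. A depletion-aware mode solves the exact 1:1
dimer:ligand mass balance at the experiment's 0.25 μM dimer concentration
for users who want `midpoint` read as a thermodynamic Kd; the default stays
phenomenological because titration midpoints of coupled
dimerization-binding systems are operational quantities, not dissociation
constants.

## Residue-level reduction

Peptide %D is projected to residues on the master-alignment coordinate
system (1-based, 219 columns for the light-chain alignment; sequential
numbering is 1-based with inclusive intervals; gap columns map to no
residue). Two schemes:

* **Weighted average** (default): a residue's value is the mean of the %D
  of peptides in which it reports, weighted by `1/N_exch` — short peptides
  localise information better and count more. It is transparent, linear,
  and exact whenever the peptides are mutually consistent.
* **Bounded least squares** (`nnls`): solves peptide uptake =
  sum of reporter residue values, residues constrained to [0, 100],
  minimising squared residual (L-BFGS-B on the quadratic objective; the
  test oracle is an independent projected-gradient solver). On full-rank
  designs the two schemes agree to 1e-6 on consistent input and the
  solution is unique.

The transparent average is the default rather than an exchange-model
refitting scheme because residue maps here serve comparison and
visualisation; a deterministic linear scheme keeps every downstream number
analysable. Difference maps (`Δ%D = A − B`) are formed cellwise where both
conditions are covered — protection is negative Δ%D — and are antisymmetric
by construction.

**Exchange AUC.** The scalar per-protein stability summary integrates each
residue's %D over `log10(t)` by the trapezoid rule and sums over residues.
The time axis is logarithmic because the labeling grid (10 s, 1 min,
10 min, 1 h, 4 h, 16 h) is log-spaced; on a linear axis the 16 h point
would contribute >70 % of the area. A linear-axis option exists. Whether to
integrate per-residue-over-time and then sum, or to integrate across the
residue axis, is underdetermined in the field's usage; the time-integral
reading is implemented because it composes with per-residue coverage masks.
Only residues covered at every time in every compared condition enter the
sum, and that common-coverage set is computed once per comparison group and
returned with the value, so compared AUCs always integrate the same
residues.

## PLIMSTEX fitting

In a PLIMSTEX experiment the labeling time is fixed (90 min here) and
ligand is titrated; binding reads out as reduced uptake of a reporter
peptide. The fit surface is

\[ D(L) = D_0 + \Delta D_{max}\,\frac{L}{EC_{50} + L} \]

by nonlinear least squares (bounded Levenberg–Marquardt) on
replicate-averaged uptakes, with parameter-free initialisation: `D0` from
the lowest concentration, `ΔDmax` from the span, `EC50` from the
concentration nearest the half-change. Duplicates are averaged unweighted;
variance-weighted fits engage when ≥3 replicates are present. Asymptotic
standard errors accompany the estimates. Flat series converge with
`ΔDmax ≈ 0` and are flagged unidentifiable rather than raising.

Two conventions deserve note:

* **ΔD is quoted at the top of the titration.** The package reports
  `deltaAtMax`, the fitted uptake change between the highest tested
  concentration and zero ligand, alongside the asymptotic amplitude.
  Titration endpoints are measured between the centroids of the m/z
  distributions at the top concentration and at baseline, so the generator
  likewise accepts its `deltaD` parameter as the realized change at the
  grid top (`deltaAt = "max"`); with that convention a noiseless
  generate-and-refit round trip returns the quoted (D0, ΔD, EC50) triple
  identically, which is what `scripts/acceptance.R` demonstrates on the
  three AL constructs.
* **Absolute uptake, not ΔD, is fitted**, with `D0` free: equivalent up to
  an offset and better conditioned.

The isolated V_L domain's ΔD is quoted as a magnitude (its printed value
carries no sign although the text describes a reduction); the package
reports signed values and leaves magnitude-taking to the caller.

## Proteolysis kinetics

Fraction-intact timecourses over 24 h are fitted to `F(t) = A e^{-kt}` with
the amplitude free within [0.8, 1.2] — gel densitometry baselines drift,
but a plateau term is deliberately omitted (single exponential decay).
Constant timecourses short-circuit to `k = 0` exactly (the NLS Jacobian is
singular at a perfect constant fit); rising timecourses are fitted but
flagged not-converged, since they violate the decay model. Where fits are
not attainable the trapezoidal AUC over hours is the fallback
protease-sensitivity metric; missing timepoints are dropped, never
interpolated. Single-timepoint protection is the plain signed difference
`stabilized − vehicle`. Pearson correlations (two-sided p from the t
transform, pairwise deletion) compare per-protein proteolysis and HDX
summaries; the units mismatch (hours vs log10 seconds) is harmless because
the correlation consumes unitless per-protein scalars.

## What the simulator does and does not emulate

It emulates: EX2 exchange under per-residue protection; the six-point
log-spaced labeling grid; 90 % label fraction; per-peptide back-exchange
retention with noiseless maxD controls; ±0.20 Da centroid noise;
ligand-coupled protection with 1:1 dimer stoichiometry in fast and slow
regimes; Poisson-binomial isotopic envelopes; exponential proteolytic
decay with fraction noise.

It does not emulate: EX1 kinetics beyond the two-population mixture;
chromatography, ionisation, or overlapping charge states; peptic digestion
(peptide maps are user-specified); solvent effects of the DMSO vehicle
(0.15–0.25 % v/v) on intrinsic rates; correlated or heteroscedastic
centroid noise; gel-densitometry artefacts in proteolysis. Passing tests
therefore certify the arithmetic of the pipeline on idealised data, not
robustness to every pathology of real spectra — in particular, real maxD
controls carry noise (supported, off by default), and real peptide maps
produce rank-deficient reduction designs in which the bounded-LS residue
solution is non-unique and only the fitted peptide-level values are
identifiable.

## Numerical choices and problem sizes

* Nonlinear fits: bounded Levenberg–Marquardt, `ftol = ptol = 1e-14` for
  titrations (the round-trip tolerance is 0.1 %), 1e-15 for decays.
* Bounded least squares: L-BFGS-B, `factr = 1e2`, warm-started from the
  weighted average.
* Degenerate inputs: maxD ≤ m0 is a hard error (a broken control);
  missing centroids are flagged records, never imputed or errors; empty
  replicate sets and single-timepoint integrals are usage errors.
* Determinism: every stochastic generator takes a seed and restores the
  caller's RNG state; reports serialise with fixed key order so identical
  inputs give byte-identical files.
* Suite sizes, chosen to probe the estimators well: 100 random systems for
  the back-exchange invariance; 100 noisy titrations (SD 0.20 Da,
  duplicates) for midpoint recovery, asserting the median within 20 % of
  truth; 200 noisy decay timecourses (duplicate 12-point 24 h courses
  averaged before fitting, noise SD 0.05) for rate recovery, asserting
  median error < 5 %; reduction oracles on ≤ 8-residue designs where the
  bounded-LS solution is unique.

## Known limitations

* Intrinsic-rate coefficients use neutral-pD side-chain forms; strongly
  acidic quench-side chemistry (pD < 4) is outside the validated range even
  though the rate law evaluates there.
* The alignment fixture shipped under `inst/extdata` is a constructed,
  synthetic light-chain-like alignment (real patient sequences are not
  redistributed here); its coordinate structure — gap counts placing
  alignment column 101 at AL sequential residue 98 — is what the
  coordinate tests exercise.
* No global multi-peptide PLIMSTEX fit and no thermodynamic linkage model
  of coupled dimerization and binding: the midpoint is operational by
  design.
* Residue reduction assumes dimer protomer equivalence; systems with
  protomer asymmetry need per-protomer bookkeeping this package does not
  attempt.
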