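---
title: "Nucleation kinetics and conformer analysis: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nucleation kinetics and conformer analysis: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleakit)
```

## The problem

Polymorphic drug compounds can crystallize into different crystal forms
depending on solvent, supersaturation and kinetics; ritonavir is the
canonical cautionary example, with a metastable form I and a stable form II
whose relative nucleation rates decide which appears. `nucleakit`
implements the two quantitative legs of a solvent-screening study of such a
system:

1. **Induction-time kinetics** — from replicate isothermal induction times
   at several supersaturations, estimate per-condition nucleation rates and
   fit the classical nucleation theory (CNT) rate law to extract the
   kinetic and thermodynamic parameters of nucleation.
2. **Conformational-ensemble descriptors** — from multi-frame molecular
   trajectories, classify phenyl torsional states, detect intramolecular
   hydrogen bonds (IMHB), and compute radii of gyration and RMSDs to
   reference crystal conformers.

A seeded synthetic-data module generates inputs with exactly the
statistical structure the estimators assume, so every stage is testable
without access to the original instruments or trajectories.

## The kinetic model

The steady-state nucleation rate is modelled as

$$J = A_0\, S\, \exp\!\left(-\frac{B}{\ln^2 S}\right), \qquad
B = \frac{16\pi\,\gamma^3 v^2}{3 k^3 T^3},$$

with supersaturation $S = C/C^*$ (a mass-ratio concentration quotient),
interfacial energy $\gamma$, molecular volume $v$, and Boltzmann constant
$k$ (SI exact, $1.380649\times 10^{-23}$ J K$^{-1}$). The molar driving
force is $RT\ln S$ with $R = 8.314$ J mol$^{-1}$ K$^{-1}$ — this rounding
reproduces published driving-force tables to their printed 0.01
J mol$^{-1}$, which $R = 8.31446$ does not. Derived quantities are the
critical radius $r_c = 2\gamma v/(kT\ln S)$, the cluster count
$n^* = (4\pi/3) r_c^3 / v = 2B/\ln^3 S$, the Zeldovich factor
$z = \ln^2 S/(2\sqrt{3\pi B})$ and the attachment frequency
$f C_0 = A_0 S / z$.

`fit_cnt()` performs unweighted ordinary least squares of $\ln(J/S)$ on
$1/\ln^2 S$; the intercept is $\ln A_0$ and the negative slope is $B$. The
$S$-linear pre-exponential form is the standard induction-time CNT
parameterization and the one consistent with that linear fit. No weighting
scheme is applied because replicate-level uncertainties on $J$ are rarely
available at the 8-replicate scale; the bootstrap CI on each $J$ is
reported instead. A fit with positive slope (negative $B$) is physically
meaningless and is returned flagged `non_physical` rather than clipped.

### Rate estimation from censored replicates

Under a constant rate $J$ in a vial of volume $V$, the waiting time to the
first nucleus is exponential with rate $JV$. With a detection/growth lag
$t_g$ the observed induction probability is
$P(t) = 1 - \exp(-JV(t - t_g))$, and vials that have not nucleated when the
isothermal hold ends are right-censored at the hold time. The default
estimator (`probability_fit`) is the maximum-likelihood rate of this
censored exponential model, which is closed-form:
$\hat J = d / (V \sum_i (t_i - t_g))$ with $d$ nucleated vials and the sum
over all vials. `mean_inverse` ($1/\bar t V$ over uncensored times) is kept
for comparison; the two coincide with no censoring and $t_g = 0$. The
survival-likelihood default matters because a 20 h hold does censor slow
vials, and dropping them biases rates upward. $t_g$ defaults to 0 (an
unmodelled turbidity-detection delay) and can be fixed at a positive value;
confidence intervals are a seeded nonparametric percentile bootstrap over
replicates (default 1000 resamples), since the source tables publish no
uncertainties.

### Two deliberately separate surfaces

Published per-solvent tables of this kind carry two groups of numbers: the
estimated rates with a fitted $\ln A_0$, and the geometric quantities
($\gamma$, $r_c$, $n^*$). For the ritonavir tables shipped with the
package these two groups are **not** mutually consistent: evaluating
$A_0 S \exp(-B/\ln^2 S)$ with the tabulated $\ln A_0 = 6.33$ (acetone) does
not reproduce the tabulated rates, and refitting the printed $(S, J)$ pairs
gives $\ln A_0 \approx 8.2$, $B \approx 11.3$ — the estimator route behind
the printed intercepts was described only in supplementary material that is
not reproducible from the main tables. The package therefore never forces
agreement: `fit_cnt()` tests and reports its own self-consistent fitting
surface, and the geometric chain ($r_c, n^* \to v \to \gamma$) is validated
independently against the printed radii, cluster counts and interfacial
energies, which *are* mutually consistent to better than 1%.

That geometric consistency is also what fixes the default molecular volume:
$(4\pi/3) r_c^3/n^*$ across all 14 tabulated conditions has a coefficient
of variation of 0.27% and a mean of 903 Å$^3$, which `solute_spec()` adopts
as the ritonavir default (overridable).

The stored toluene supersaturations are another known internal
inconsistency: the printed $S$ values (13.11–15.89) are not the quotient of
the printed concentration and the converted solubility (≈11.3–13.7).
`check_supersaturation_consistency()` flags such rows instead of silently
recomputing them; stored values are treated as authoritative reported data.

## Conformer descriptors

Torsions use the IUPAC sign convention, reported on $[-180°, 180°)$ so the
planar anti arrangement is $-180°$. Phenyl states partition that domain
into three equal-width classes, half-open toward increasing $|{\rm angle}|$:
cis $[-60, 60)$, intermediate $[-120,-60) \cup [60,120)$, trans
$[-180,-120) \cup [120,180)$ — the source binning states ranges without
boundary membership, so the half-open choice is ours and is
property-tested to cover every angle exactly once. (The reference
structures classify as cis at $18.84°$ and trans at $-166.46°$; a figure
caption elsewhere gives $188.84°$ for the former, which normalizes to
$-171.16°$ and would contradict its own cis assignment — the package
follows the textual value.)

IMHB detection is geometric: H···acceptor distance ≤ 2.5 Å and
donor–H···acceptor angle ≥ 120°, the conventional moderate-strength
criterion, both configurable since the underlying study names the
donor/acceptor pair but no cutoffs. RMSD uses Kabsch superposition via SVD
restricted to proper rotations, unweighted by default (mass weighting
optional) because the reference tables do not state a weighting.
Trajectories are read from multi-model PDB (via `bio3d`) or concatenated
XYZ; atom selections come from a plain-text sidecar with 0-based indices.

## The synthetic-data generators

`gen_induction_times()` draws exponential waiting times at the CNT rate,
adds the growth lag, and right-censors at the hold. Defaults emulate the
experimental design the estimators target: 8 replicate 1 mL vials per
supersaturation, a 20 h (72 000 s) isothermal hold, the four-point
supersaturation grid 4.20/4.44/4.75/5.14 of a single-solvent campaign,
$t_g = 0$, and rate parameters $\ln A_0 = 8.2$, $B = 11.3$ (the values
recovered from the published acetone rate pairs, giving mean induction
times of hours and a realistic ~1% censoring fraction).

`gen_dihedral_series()` draws stationary class sequences (independent
frames) with configurable populations, then angles from a von Mises
distribution per class — centred at 0° (cis), ±90° with equal lobe weight
(intermediate, a two-sided bin), 180° (trans) — and a Bernoulli IMHB flag
per class. Sampling uses the Best–Fisher rejection algorithm. The default
concentration $\kappa = 50$ (circular SD ≈ 8°) keeps cross-bin leakage
below 0.1%, so recovered populations match generating ones almost exactly;
the reported class column is still re-derived from the angle so leakage is
visible when $\kappa$ is lowered. Default populations (0.2/0.6/0.2) and
IMHB probabilities (0.90/0.95/0.85) emulate the intermediate-dominant,
high-IMHB ensembles reported for the form-I-selective solvents.

What the generators deliberately do **not** emulate: autocorrelated MD
frames (independent draws overstate effective sample size relative to a
real trajectory), multimodal within-class angle structure, solvent boxes
or force-field energies, and any secondary-nucleation or growth kinetics.
Passing recovery tests on synthetic data therefore validates the
estimators under their stated model, not the model's fidelity to any
particular instrument or simulation.

## Numerical choices

- All internal computation is SI; Å, Å$^3$ and mJ m$^{-2}$ are converted in
  a single utility file to avoid factor drift.
- $R^2$ is computed directly from residuals (exact 1 on noiseless input).
- The censored-exponential MLE is closed-form, so no optimizer tolerances
  enter rate estimation; the bootstrap is the only stochastic stage and is
  sub-seeded deterministically from the master seed.
- Degenerate geometry (coincident or collinear torsion atoms, all-coincident
  RMSD inputs, constant regressors) raises errors rather than returning
  NaN.

## Problem sizes used in the shipped checks

The verification suite runs noiseless round trips (exact to 1e-10), a
stochastic end-to-end study of 200 seeded campaigns of 8 replicates × 4
supersaturations (mean recovered $B$ within 15% of truth; observed
relative error is under 1%), a $10^5$-replicate censoring-fraction check
against its closed form, 50 000-frame population recoveries (within 0.01),
a 0.01°-grid partition check of the classifier, and 1e4 randomized draws
of the $n^* = 2B/\ln^3 S$ identity. These sizes were chosen so the Monte
Carlo error is several times smaller than each tolerance.

## Known limitations

- Heterogeneous nucleation, two-step nucleation models and metastable-zone
  width analysis are out of scope; the CNT single-barrier form is assumed.
- Activity corrections are not applied to supersaturation; $S$ is a
  concentration quotient.
- `estimate_rate()` treats replicates as exchangeable vials at constant
  rate; vial-to-vial heterogeneity (e.g. dust-mediated nucleation) would
  inflate apparent dispersion beyond the exponential model.
- The conformer reader loads whole trajectories into memory; it targets
  single-molecule descriptor analysis, not solvated-box post-processing.
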