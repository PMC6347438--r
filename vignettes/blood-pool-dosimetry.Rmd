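---
title: "Blood-pool agent dosimetry: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blood-pool agent dosimetry: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbcdosim)
```

This vignette is the package's account of its science: what each stage
models, which assumptions it makes, which parameters matter, and where the
design was genuinely open.

## Decay arithmetic

All activities are referred to a common clock by the physical decay law
$A(t) = A_0 \, 2^{-t/T_{1/2}}$. Time is carried everywhere as minutes from
run start (labeling) or injection (dosimetry); no clock-time strings enter
the math layer, and the I/O dialects carry a `t_min` column directly.
Packaged half-lives (F-18: 109.77 min, Tc-99m: 360.6 min) live in
`inst/extdata/nuclides.csv` with provenance comments, never in code.

## Labeling mass balance

A labeling run is the calibrator record of one experiment: activity added
at $t=0$, then the washed cell fraction, the original incubation
supernatant and up to three wash supernatants. Percent incorporation is
the cell share of the *recovered* (measured) activity after decay
correction to run start — not of the nominal added activity, because
relative percentages are what replicate experiments report; the gap to
the nominal activity is surfaced separately by `recovery_fraction()` as a
loss diagnostic. When all compartments are measured simultaneously the
decay correction cancels, so incorporation is invariant to the common
measurement time (a property test enforces this). Compartment fractions
are renormalised to sum to exactly 1, avoiding the familiar artefact of
independently rounded percentages summing to 101%.

A validity check rejects runs whose decay-corrected compartment sum
exceeds the added activity by more than a configurable tolerance (default
5%, the scale of dose-calibrator accuracy).

## Uptake and leakage kinetics

*Uptake.* Incorporation versus incubation time is fitted with the
single-exponential saturation $F(t) = f_\infty(1-e^{-kt})$ — the simplest
form consistent with first-order transporter-mediated (GLUT1) entry
approaching a plateau, which is what the observed 30-min/1-h/2-h
incorporation ratios look like. With exactly two distinct timepoints the
fit is exact: the ratio equation
$F(t_1)/F(t_2) = (1-e^{-kt_1})/(1-e^{-kt_2})$ is monotone in $k$ and is
solved by root bracketing (`uniroot`, tolerance 1e-14) before recovering
$f_\infty$; with more points a Levenberg–Marquardt least-squares fit is
used. A caveat this model makes explicit: a rate constant pinned by a
1-h:2-h ratio of 0.99 implies a 30-min:2-h ratio of about 0.90, slightly
below typical measured values near 0.92 — single-exponential saturation is
an approximation, and alternative forms are deliberately out of scope.

*Leakage.* Release of intracellular tracer into plasma over the first two
hours is slow and gradual, so the default model is an ordinary
least-squares straight line on (minutes, percent leaked), reported with
slope, intercept and $R^2$ (checked in tests against a hand-written
normal-equations oracle). A first-order release variant
(`method = "exponential"`) is available for longer windows where
saturation matters but is not the default. Predictions are clamped to
[0, 100]% and warn when extrapolating more than 30 minutes outside the
fitted window.

*Yield.* The predicted batch yield composes the incorporation fraction
with physical decay over the preparation time,
$A_0 \, f \, 2^{-t_{prep}/T_{1/2}}$; the default preparation time is 65
minutes, the midpoint of a typical 60–70 minute incubate-and-wash
protocol, and is configurable.

## Well-mixed biodistribution

Labeled erythrocytes distribute uniformly through the blood pool within
minutes of injection, so each source region's fraction of the injected
dose equals its fraction of total blood volume. The packaged regional
blood-volume table (adult male, transcribed from ICRP Publication 89)
assigns blood in an organ to that organ as source — the wall, for hollow
organs, which is what makes the wall correction below meaningful — and the
unallocated remainder to a synthetic `rest_of_body` region so the
fractions close to exactly 1. Tests never depend on the transcription:
property tests use synthetic random tables.

Two scenarios bracket in-vivo behaviour:

* **Full retention** — the entire dose decays in the blood pool. Each
  region's time-integrated activity coefficient is
  $\tilde a = f \, T_{1/2}/\ln 2$ hours, and the coefficients sum to
  exactly $T_{1/2}/\ln 2$ (conservation, enforced to 1e-12 in tests).
* **Partial excretion** (default 25%) — a free-tracer sub-pool leaves the
  blood pool for urine. Blood-pool regions keep only the retained share;
  the excreted share feeds a dynamic voiding bladder.

### The voiding-bladder model

The excretion kinetics are genuinely underdetermined by a single stated
excretion percentage, so the package adopts the standard nuclear-medicine
construction and surfaces every parameter: first-order entry into the
bladder with biologic half-time 12 min (free-tracer-like renal clearance),
complete voiding every 3.5 h (a standard adult schedule), physical decay
applying throughout — including to activity still in transit, whose decays
are attributed to no source region. Starting each inter-void interval
empty, the contents follow
$A(nT+u) = f e^{-(\lambda+k_b)nT} e^{-\lambda u}(1-e^{-k_b u})$, so the
integral to infinity is a geometric sum with an exact closed form
(implemented directly; an independent fine-grid trapezoid simulation
serves as the test oracle at 1e-4 relative). The coefficient is monotone
in the voiding interval and in the half-life, and reaches the pure-decay
bound $f\,T_{1/2}/\ln 2$ only in the joint limit of instant entry and no
voiding — with finite entry kinetics some of the sub-pool decays in
transit, which is why the scenario sum is strictly below the bound.

## The dose engine

Absorbed doses follow the MIRD schema,
$D(\mathrm{target}) = \sum_s \tilde a_s \, S(\mathrm{target}\leftarrow s)$,
with the S-value matrix taken as input: phantom S-values are the product
of phantom software and are supplied by the user (or generated
synthetically for tests), never derived here. Consequently the packaged
reference organ-dose table is a *fixture* consumed by downstream steps
(effective dose, limits, comparisons), not an output of the engine.
Validation enforces non-negativity and self-dose dominance
($S(\mathrm{self}\leftarrow\mathrm{self}) \ge
S(\mathrm{other}\leftarrow\mathrm{self})$), and the engine's matrix-vector
product is checked against an element-wise double-loop oracle on random
instances.

*Wall correction.* Stylised phantoms put hollow-organ self-dose activity
in the lumen and credit the wall with half the contents-absorbed electron
dose (the surface convention). For a blood-pool agent the activity sits in
the vascularised wall, so the correction replaces
$\tfrac12 \tilde a \Delta_e/m_{contents}$ with
$\tilde a \Delta_e/m_{wall}$, leaving photon terms untouched. In the
equal-mass, equal-activity limit the corrected electron term is exactly
twice the surface-convention term — a forced consequence of the ½ factor
that the tests pin down.

*Effective dose.* $E = \sum_T w_T H_T$ with equivalent dose numerically
equal to absorbed dose (radiation weighting factor 1 for photons and
electrons/positrons). The ICRP-60 weights and remainder-organ list ship as
a provenance-documented YAML; the remainder tissue receives the unweighted
mean dose of the remainder organs (a mass-weighted variant sits behind
`remainder_method = "mass_weighted"`), and documented surrogates map
weighted tissues without direct entries (oesophagus ← thymus; gonads ←
testes for the adult-male report, ovaries by option). Recomputing the
effective dose from the packaged reference organ-dose table with these
textbook conventions yields a noticeably smaller coefficient than the
published 3.90E-02 mSv/MBq — phantom software uses internal remainder and
surrogate conventions that a textbook recomputation cannot reproduce — so
the published coefficient is carried as an input
(`effective_dose_coefficients.csv`) for total-dose and comparison
arithmetic, and `analysis/03_biodistribution_dosimetry.R` prints the
recomputed value beside it rather than asserting agreement.

*Administration limits.* Research-use limits (21 CFR 361.1) ship as
config: 30 mSv single / 50 mSv annual for the restrictive class (whole
body, blood-forming organs, lens, gonads), 50/150 mSv for other organs.
Each organ's per-administration dose is `dose × activity`; the annual cap
is the floor of the tightest annual-limit ratio and the limiting organ
attains it. A deliberate design choice: the effective dose is *not* used
as the "whole body" entry by default. The regulatory whole-body limit is
an absorbed-dose quantity; treating the risk-weighted effective dose as if
it were a whole-body absorbed dose would roughly halve the administration
cap and contradicts how organ-based limit assessments are reported for
this class of agent. A whole-body entry participates whenever a
total-body absorbed dose is supplied in the dose vector (or explicitly via
`use_effective_as_whole_body = TRUE`).

## The synthetic-data module

Generators exist so every stage is testable with known truth and no
downloads; they are first-class, tested code.

* **Labeling runs** partition the added activity by the truth fractions
  (default regime: incorporation 0.582, wash carry-over 3/2/1%) and apply
  multiplicative lognormal calibrator noise with unit mean (dose
  calibrators have scale-proportional error; CV default 1%). With zero
  noise the analyser returns the truth exactly; at 1000 noisy replicates
  the estimator bias stays within 3 standard errors (a Monte-Carlo test).
* **Leakage series** add the same noise to a linear truth (default
  operating point 0.22 %/min over a 1.147% intercept, sampled at
  46/76/106 min — the measured plasma-incubation design).
* **Synthetic phantoms** (8 organs + rest-of-body, masses 0.02–20 kg so
  wall-correction and remainder logic are both exercised) build S-value
  matrices from per-decay electron and photon energies and a
  row-stochastic geometry coupling; with the default mass-proportional
  coupling, self-dose dominance holds by construction.
* All generators save and restore the RNG state, so they are pure
  functions of their seed and never disturb the caller's stream.

What the generators do *not* emulate: correlated calibrator drift,
incomplete compartment recovery, cell-age-dependent uptake mechanisms,
inter-subject blood-volume variation, or any imaging physics. Passing
tests therefore demonstrate correctness of the computational chain under
the stated statistical model, not robustness to every artefact of real
bench data.

## Numerical choices and problem sizes

* Two-point uptake fits: root bracketing on $k \in [10^{-10}, 10]$ /min,
  tolerance 1e-14; multi-point fits: `minpack.lm::nlsLM` bounded to
  $f_\infty \in [0, 1.5]$.
* Bladder integral: exact closed form; the test oracle integrates on a
  0.02-min grid out to 40 half-lives with an integrating-factor step and
  half-jump values at voiding discontinuities.
* Degenerate inputs fail loudly and early: all-equal timepoints, all-zero
  activities, fractions outside [0, 1], schema mismatches listing the
  offending source regions. All-zero dose vectors yield the sentinel
  "no binding constraint" rather than an error.
* Test problem sizes keep the default suite fast: random-matrix oracles at
  10×10, property loops of 10–50 cases, Monte-Carlo suites at 1000
  replicates of 5-compartment runs and 3-point fits.

## Limitations

* The biodistribution is static: no first-pass extraction, no
  multi-compartment exchange, no species-specific small-animal modelling.
* The engine only ever knows the S-values it is given; no radiation
  transport is performed, and stylised-phantom tables must be transcribed
  by the user for real-phantom work.
* The published effective-dose coefficient cannot be re-derived from the
  organ-dose fixture with textbook ICRP-60 conventions (see above); the
  package treats it as input and reports the recomputation transparently.
* The bladder parameters (entry half-time, voiding interval) are standard
  defaults, not fitted quantities; both are exposed in `scenario_spec()`
  and should be varied in sensitivity analyses.
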