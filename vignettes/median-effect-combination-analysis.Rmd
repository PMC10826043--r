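---
title: "Median-effect analysis of enzyme-inhibitor combinations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Median-effect analysis of enzyme-inhibitor combinations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medsyn)
```

## The model

A single inhibitor acting on an enzyme under mass-action kinetics follows the
median-effect equation

$$\frac{f_a}{f_u} = \left(\frac{D}{D_m}\right)^m,$$

where $D$ is the dose, $f_a$ the fraction of enzymatic activity affected
(inhibited), $f_u = 1 - f_a$ the unaffected fraction, $D_m$ the median-effect
dose (the IC50), and $m$ the sigmoidicity of the dose–effect curve ($m = 1$
hyperbolic, $m > 1$ sigmoidal). This is a reparameterized Hill equation; its
virtue is the linearization

$$\log_{10}\!\frac{f_a}{f_u} = m\,\log_{10} D - m\,\log_{10} D_m,$$

the *median-effect plot*, in which slope and x-intercept deliver $m$ and
$\log_{10} D_m$, and the Pearson correlation $r$ of the transformed points
measures conformity of the data to the mass-action model.

The model's assumptions are worth keeping in view: a monotone, saturating
dose–effect relation; effects expressed as fractions of a defined dynamic
range (here anchored by uninhibited and fully inhibited assay controls); and
doses known without error. Nothing in the fit checks mechanism — a high $r$
says the linearized points are collinear, not that the inhibition is
single-site.

## Estimation choices

`fit_median_effect()` uses **unweighted ordinary least squares** on the
transformed variables, with **base-10** logarithms matching the classic
median-effect plot convention ($D_m$, $m$ and $r$ are invariant to the base so
long as the antilog used for the intercept matches). We deliberately do not
fit the untransformed curve by nonlinear least squares: the transformed-scale
fit is the field's standard, is exactly what published $D_m/m/r$ triples
refer to, and under the package's own noise model (below) it is also the
maximum-likelihood estimator.

Points with $f_a \le 0$ or $f_a \ge 1$ (or $D \le 0$) cannot enter the
log-logit transform. They are **excluded and reported** in a warning listing
their positions — never nudged by an epsilon, which would silently bias $m$,
and never silently dropped. Fewer than 2 usable points is an error; fewer
than 4 a warning. All-equal doses (zero variance in $\log D$) is an error.

Replicates may be fitted jointly or first averaged with
`aggregate_replicates()`, which averages on the $f_a$ scale (not the
absorbance scale) and records the replicate count and spread. The assay
protocol this package descends from does not state its aggregation rule;
mean-of-$f_a$ is our choice and is configurable by simply skipping the
aggregation step.

## From absorbance to effect

For the colorimetric DNS assay, activity is read as absorbance at 540 nm and
converted by

$$\%\,\mathrm{Inh} = 100\left[1 -
  \frac{A_\mathrm{extract} - A_\mathrm{pos}}{A_\mathrm{neg} - A_\mathrm{pos}}\right],$$

with the positive control the fully inhibited reaction and the negative
control the uninhibited one. Measurement noise can push the result slightly
below 0% or above 100%; `percent_inhibition()` **returns such values
unchanged with a warning** (preserving the raw data), and clamping to the
model domain $[0, 1]$ happens once, flagged, in `to_fraction_affected()`.
Equal control absorbances make the denominator vanish and are an explicit
error. CSV columns and dose units are declared in the file header and never
inferred from magnitudes.

## Combination design and interaction metrics

The mixtures this package targets follow an **effect-matched design**: at
each effect level $x$ (default 10, 30, 50, 70, 90%), the two components are
combined at the doses that would *individually* produce $x\%$ inhibition,
i.e. $(\mathrm{IC}_{x,A}, \mathrm{IC}_{x,B})$ from each agent's own fit
(`design_effect_matched_mixtures()`). Because the two curve shapes differ,
the component *ratio drifts* across levels — this is not a fixed-ratio
design, and we adopt the effect-matched reading because it is the only one
that reproduces the published per-level tables. The mixture doses entering
the analysis are these nominal design doses; the published per-level dose
columns are the *single-agent* equi-effective doses at the observed effect,
from which each in-combination dose follows as $\mathrm{IC}_x/\mathrm{DRI}$.

At an observed mixture effect $f_a$, with $\mathrm{IC}_{f_a}$ denoting
`dose_for_effect()` of each single-agent fit:

* **Combination index**
  $CI = C_A/\mathrm{IC}_{f_a,A} + C_B/\mathrm{IC}_{f_a,B}$; $CI<1$
  synergism, $=1$ additivity (the Loewe null), $>1$ antagonism. The default
  classification tolerance is 0 (the strict textbook rule); pass a small
  band via `tolerance=` for noisy data where $CI$ hovers near 1.
* **Dose-reduction index** $\mathrm{DRI} = \mathrm{IC}_{f_a}/C$ per
  component. The classical definition is written at the 50% level; we
  evaluate it at the observed effect level, the form in which per-level
  tables are published. The identity $CI = 1/\mathrm{DRI}_A +
  1/\mathrm{DRI}_B$ then holds exactly and is asserted in the tests.
* **Isobolograms**: the classical per-level diagram in raw dose space, and
  the normalized diagram mapping each observation to
  $(C_A/\mathrm{IC}_{f_a,A},\, C_B/\mathrm{IC}_{f_a,B})$, where the additive
  line is $x + y = 1$ for all levels at once and a point's coordinate sum
  *is* its CI.
* **fa–CI curves** in two modes: per-observation (matching the
  effect-matched design) and constant-ratio (treating the mixture as a third
  drug via its own median-effect fit from
  `combination_median_effect()`).

When a mixture's components carry different dose units (e.g. mM of a pure
compound plus mg/mL of an extract), `combination_median_effect()` still sums
them — the combination's "dose" is the arithmetic total, tagged with a
composite unit label and a warning. This is a formal device, but it is the
standard treatment and the only interpretation under which the published
total-dose combination fits are reproducible; we verified numerically that
the acarbose+kaempferol combination row refits to within 1% of its published
$D_m$ and $m$ from nominal design doses. The acarbose+propolis combination
row does **not** reproduce the same way (refit $D_m \approx 0.31$ vs
published 0.274, $m$ within ~3%), most plausibly because the original
analysis used unrounded single-agent parameters and/or measured rather than
nominal mixture doses; the package documents this rather than forcing it,
and no test asserts that row.

## The synthetic-data generator

`simulate_dose_effect()` draws noise **on the linearized
$\log_{10}(f_a/f_u)$ scale**: $y = m\log_{10}(D/D_m) + \varepsilon$,
$\varepsilon \sim N(0, \sigma^2)$, then maps back. Two reasons: simulated
$f_a$ stays strictly inside $(0,1)$ for any $\sigma$, and the OLS fit is the
exact MLE under this noise, so parameter-recovery tests are sharp rather
than confounded by estimator misspecification. A raw-absorbance mode
(`absorbance = TRUE`) adds Gaussian noise to the extract reading instead,
for end-to-end realism through the reduction step. Each call takes an
explicit `seed` and restores the caller's RNG state, so simulations are
reproducible without global side effects.

`simulate_mixture_fa()` inverts the CI definition: given component doses and
a target interaction strength `ci_true`, it solves
$C_A/\mathrm{IC}_{f_a,A} + C_B/\mathrm{IC}_{f_a,B} = CI_\mathrm{true}$ for
the unique $f_a$. For $m > 0$ both equi-effective doses increase strictly
with $f_a$, so the left side is strictly decreasing and the root is unique;
it is bracketed on $[10^{-12}, 1-10^{-12}]$ and found with `stats::uniroot`
at tolerance $10^{-12}$ (Brent's method; the contract is
$|\Delta f_a| < 10^{-10}$, and a vanished bracket is reported as an explicit
error with the bracket values). With `ci_true = 1` this generates
Loewe-additive null data; re-analyzing such mixtures returns $CI = 1$ to
$10^{-8}$, closing the generator–analyzer loop.

What the generator does *not* emulate: substrate depletion and DNS reaction
chemistry, plate spatial effects, dose-measurement error, and
between-replicate correlation. Passing the recovery tests therefore
validates the statistical pipeline, not the assay itself.

## Validation problem sizes and calibration

The package's validation suite uses problem sizes chosen to make the checks
sharp yet quick to re-run: parameter recovery was calibrated over **1000
seeds** at the reference design (8 log-spaced doses $D_m\cdot 2^{-3..4}$,
$\sigma = 0.05$, 3 replicates), giving worst-case relative errors of about
7% for $D_m$ and 4% for $m$; the asserted envelope is 10%.
Noise-monotonicity of the recovery error is checked in expectation over 100
seeds at $\sigma \in \{0.02, 0.1, 0.3\}$. Dose–effect round-trips are
asserted to $10^{-10}$ relative tolerance; the $CI = 1/\mathrm{DRI}_A +
1/\mathrm{DRI}_B$ identity to $10^{-9}$.

## Reporting

`run_full_analysis()` orchestrates reduce → fit → per-pair combination
metrics → isobologram and returns a deterministic report;
`render_report()` serializes it as JSON (full precision, fixed key order),
CSV, or markdown. Human-readable tables round to **3 significant figures**,
matching the precision at which such tables are conventionally published;
JSON keeps full precision so reports round-trip losslessly
(`parse_report_json()`).

## Known limitations

* No confidence intervals on $D_m$, $m$, CI or DRI (none are published for
  the worked example; a bootstrap layer would be the natural extension).
* Binary mixtures only; no Bliss independence, ZIP, HSA or response-surface
  alternatives — CI here is Loewe-based by construction.
* Published parameter triples are rounded to 2–3 significant figures, which
  propagates visibly: recomputed equi-effective doses can differ from
  published ones by a few units in the last printed digit even though CI
  and DRI agree to ±0.01/±0.02.
* The median-effect fit weights all transformed points equally; extreme
  effect levels (fa near 0 or 1) have inflated leverage on the logit scale,
  which is the classic trade-off of this linearization.
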