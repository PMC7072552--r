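---
title: "Biphasic dose-response analysis: models, fitting and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biphasic dose-response analysis: models, fitting and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biphasr)
library(dplyr)
```

## The model and its assumptions

A targeted kinase inhibitor acting on a cell line whose viability depends
on a single driver produces the classical single-target response,
$I = D/(D + \mathrm{IC}_{50})$. In multi-driver lines the same drug removes
only the fraction of viability its target sustains, and what remains
responds only to micromolar off-target toxicity. `biphasr`'s central model
is the two-site sum

$$I(D) = F_1 \frac{D}{D + K_{d1}} + (1 - F_1)\frac{D}{D + K_{d2}},$$

with three structural assumptions:

* the two phases partition all of viability ($F_1 + F_2 = 1$), so $F_2$
  is derived, never fitted;
* each phase is a simple hyperbolic (non-cooperative) binding isotherm;
  inhibition is zero at zero dose, so there is no intercept term;
* phase 1 is by convention the high-affinity phase ($K_{d1} \le K_{d2}$),
  which resolves the label-switching symmetry of the sum.

The modified Hill equation $I = I_{max} D^n /(IC_{50}^{*n} + D^n)$ is
fitted alongside as a descriptive check: on genuinely biphasic data it
typically returns $I_{max} < 1$ (partial maximal inhibition) and an
apparent Hill coefficient $n < 1$, but it cannot separate the two phases,
so model comparison and classification rest on the monophasic/biphasic
pair. The monophasic model is nested in both others (Hill with
$I_{max} = 1, n = 1$; biphasic with $F_1 = 1$), which the fitter exploits
(see below) and the test suite asserts as an RMSE-ordering invariant.

All concentrations are handled internally in nanomolar; readers accept nM
and µM. The fitting objective is the root-mean-square error between
observed and predicted *viability* ($V = 1 - I$), computed over all
replicate points by default. Fitting to per-dose replicate means is a
configuration switch (`use_means`); all-points fitting is the default
because it weighs doses by their replication and is the stricter
objective.

## Fitting: deterministic multi-start bounded optimization

Spreadsheet solvers fit these models from a single, unstated starting
point, which makes results irreproducible and start-dependent. `biphasr`
instead scans a deterministic coarse lattice and refines the best starts
with bounded local optimization (`nlminb` on box constraints):

* **monophasic** — log-spaced IC50 scan (80 points across the bounded
  range), top starts refined.
* **Hill** — lattice over $I_{max} \in \{0.2..1.2\}$, 10 log-spaced
  IC50* values and 5 slopes, plus the best monophasic fit as the
  $(1, \mathrm{IC}_{50}, 1)$ start.
* **biphasic** — for each ordered $(K_{d1}, K_{d2})$ pair on a log
  lattice the squared RMSE is a quadratic in $F_1$, so the full
  $F_1 \times K_{d1} \times K_{d2}$ lattice is scanned with three dot
  products per pair; the `n_refine` best cells (default 10) are refined,
  again plus the monophasic-equivalent start $(F_1 = 1,
  K_{d1} = \widehat{\mathrm{IC}}_{50})$.

Including the monophasic solution as a start makes the nesting inequality
RMSE(biphasic) ≤ RMSE(monophasic) structural rather than hoped-for. The
whole procedure is a pure function of the data and configuration —
repeated calls are bit-identical — and equivariant under rescaling of the
concentration axis, because bounds and lattices are defined relative to
the tested range.

**Bounds.** IC50 and $K_{d1}$ may range two decades below the lowest and
above the highest tested dose; $K_{d2}$ may range six decades above the
top dose so that "largely resistant" off-target phases are representable.
Parameters ending on a bound are reported in `at_bound`, not treated as
errors: a $K_{d2}$ at its upper bound is the expected outcome for a
resistant second phase and is displayed as `> 1000 uM` (the numeric value
stays in the object). Equal-RMSE ties between refined starts are broken
deterministically: smallest $K_{d1}$, then smallest $F_1$.

**Degenerate representations.** When one phase suffices, the biphasic
parameterization is not unique (all weight on either slot, or
$K_{d1} = K_{d2}$ with arbitrary split). Fits are canonicalized to the
single-phase form $F_1 = 1$, $K_{d1} = \mathrm{IC}_{50}$, which is also
the field's convention for reporting a monophasic response. Zero-response
data under the Hill model similarly admit several boundary
representations; they are canonicalized to $I_{max}$ at its lower bound.

## Model preference

`compare_models()` prefers the biphasic model when the
monophasic/biphasic RMSE ratio exceeds `ratio_threshold` (default 2;
ratios of 5–10 are typical for strongly biphasic curves). Both RMSEs are
floored at `rmse_floor` ($10^{-6}$ viability units) before the ratio is
formed, so two numerically-perfect fits yield a ratio of 1 rather than an
amplified quotient of rounding noise. The Hill fit is reported but never
preferred: with its extra shape freedom it tracks biphasic data about as
well as the two-site model while answering a different question.

## ICx and the dose reduction index

`estimate_icx()` offers two routes to the concentration producing $x$
inhibition. The default, log-linear interpolation of replicate-mean
inhibition between the bracketing measured doses, is the reproducible
analogue of reading the value off a plotted curve; `from_fit` inverts the
best biphasic fit analytically (the quadratic obtained by clearing
denominators, solved in the cancellation-safe form). On noiseless model
data at 2× grid density the two agree within a few percent; the
interpolation route is preferred for reporting because it makes no model
commitment. Levels the curve never reaches within the tested range are
flagged unattainable (`NC` in reports) rather than extrapolated.

The dose reduction index at level $x$ for a 1:1 combination is the
aggregate form

$$\mathrm{DRI}_x = \frac{IC_{x,1} \cdot IC_{x,2}}
{IC_{x,1+2}\,(IC_{x,1} + IC_{x,2})},$$

where $IC_{x,1+2}$ is the *total* combined dose. It is symmetric in the
two drugs and unit-invariant. Note the calibration of this aggregate
statistic: a combination identical in effect to dose-sharing between two
equally potent drugs gives DRI = 1, and a "combination" that is literally
the same curve as both single agents gives DRI = 0.5 — values well above
1 indicate genuine synergy. This printed aggregate form is implemented
as-is; it is not the classical per-drug Chou–Talalay DRI pair, which
answers a related but different question and does not reproduce the
reference worked example (500 nM × 790 nM / (28 nM × 1290 nM) ≈ 10.9,
i.e. an 11-fold reduction at 50% inhibition).

## Screen normalization, QC and classification

Raw readings are normalized per cell line × drug as raw/control, with one
amendment: when any drug-treated reading exceeds the control (a common
low-dose growth uptick), the highest reading becomes the control, so
relative viability is 1 at that dose and ≤ 1 there by construction. The
procedure is scale-free.

"Obvious scattering" is operationalized as two configurable rules:
a single-step *increase* in per-dose mean viability larger than 0.25
along increasing dose, or a best-of-three-models RMSE above 0.15. Each
rejection carries its reason code. These thresholds are this package's
choices — descriptions, not published constants — so retention counts on
real screens will depend on them.

Classification applies, in order:

1. **LV** — mean per-dose viability < 0.35 with range < 0.2: the cells
   are dead or dying regardless of dose, no signal to fit.
2. **NI** — maximum inhibition < 0.20 across the tested range.
3. **MP** vs **BP** — by the fitted target-specific fraction:
   $F_1 \ge 0.85$ is monophasic, below is biphasic.

The 0.85 boundary is the field's published convention for this split; the
LV/NI thresholds (0.35/0.2/0.20) are package defaults, config-exposed
(`--lv-threshold`, `--ni-threshold`, `--f1-mp-threshold` on the CLI).
Classification operates on normalized viability (whether the original
low-viability calls used raw or normalized readings is not specified in
the source material; normalized is the self-consistent choice here).

**Identifiability guards.** A globally RMSE-optimal biphasic fit of a
noisy single-phase curve often parks a spurious phase where the data
cannot constrain it: a small phase with $K_{d}$ far below the lowest dose
(saturated everywhere — indistinguishable from an intercept soaking up
the mean of the noise), or two phases closer than the dose spacing can
resolve. Both artifacts would flip the MP/BP call while changing the
fitted curve negligibly. `classify_response()` therefore derives an
*effective* $F_1$ first: a phase with $K_{d1}$ under half the lowest dose
and $F_1 <$ `blip_f1_max` (0.15) is treated as an intercept artifact and
the dose-dependent phase is taken as the target phase; phases closer than
`phase_sep_factor` (10-fold) in affinity are merged into one effective
phase at the fraction-weighted log-affinity. The fitter itself is left
untouched — it remains a pure RMSE minimizer, which is what the
brute-force-lattice equivalence test checks. Relatedly, the fitted
$K_{d2}$ is flagged unreliable when the top tested dose does not reach it
(the off-target phase is then essentially unsampled, as in screens capped
at low-micromolar doses).

## The synthetic-data generators

`simulate_curve()` adds independent Gaussian noise (sd in viability
units, default 0.05 — the scale of a careful triplicate MTT assay) to the
model viability on one of two standard grids: the 16-point 2× series from
0.6 nM to 20 µM used for full dose-response work, and the 9-point 2×
series from 5 nM to 1.28 µM typical of high-throughput screens. Values
are truncated at a −0.05 floor; values above 1 are kept (normalization
upstream handles upticks). Generators take an explicit seed, restore the
caller's RNG state, and are bit-reproducible.

`simulate_combination()` is a deliberately simple generative testbed for
the synergy pipeline: four independent subpopulations (A-only, B-only,
shared, resistant), hyperbolic kill per mechanism, multiplicative
survival within a subpopulation, and 1:1 dosing by total drug. It
produces the qualitative phenotype of interest — single agents plateau
near their target fraction, the combination kills the union — but it is a
construction for testing, not a claim about any cell line's biology.

`fixture_panel()` builds labeled LV/NI/MP/BP/scattered curves on the
9-point grid (generating parameters drawn away from the classification
thresholds: monophasic IC50s of 20–80 nM, biphasic $F_1$ of 0.40–0.60,
flat panels at ~0.2 and ~1.0, scatter with sd 0.30 against the 0.03 of
the clean categories) for classifier round-trip tests.

What passing these tests shows — and does not. The generators share the
analysis models' functional form plus i.i.d. Gaussian noise, so
round-trip results demonstrate correctness of the estimation machinery,
not robustness to the structured artifacts of real screens (edge effects,
dose-correlated errors, heteroscedastic readouts, carryover). The QC
rules catch gross scatter, not subtle bias.

## Numerical choices

* Biphasic ICx is the positive root of
  $(1-x)D^2 + [F_1 K_{d2} + (1-F_1)K_{d1} - x(K_{d1}+K_{d2})]D
  - x K_{d1} K_{d2} = 0$, computed via the $q = -(b + \mathrm{sign}(b)
  \sqrt{b^2-4ac})/2$ form to avoid cancellation; it agrees with bisection
  on the forward model to $10^{-9}$ relative.
* Unattainable ICx levels raise an explicit error in the closed-form
  layer and a flagged estimate (never an exception) in the curve-level
  estimator.
* Optimizer tolerances are `nlminb` defaults with 500 iterations; the
  coarse lattice is 21 $F_1$ × 20 log-spaced $K_d$ values per axis.
  Against a 50-points-per-axis brute-force lattice on 9-point curves the
  refined optimum is equal or better to well within $10^{-4}$ RMSE.
* Test and acceptance problem sizes — 500 random curves for the nesting
  property, 50 for lattice equivalence and for noisy parameter recovery,
  5×5 panels for classification — were chosen to bound each property's
  sampling error while keeping the full suite around a minute on a
  laptop-class single core.

## Known limitations

* No confidence intervals on fitted parameters; bootstrap support is
  future work.
* The four-parameter logistic with floating bottom is intentionally out
  of scope (inhibition is zero at zero dose by assumption); stimulation
  above baseline is clipped by normalization, not modeled.
* $K_{d2}$ from screens whose top dose is far below the off-target range
  is reported but flagged; treat it as a bound, not an estimate.
* The wide-table reader targets one documented header dialect
  (`cell_line`, `control*`, dose columns like `5nM`/`1.28uM`); other
  screen export dialects need a mapping step.
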