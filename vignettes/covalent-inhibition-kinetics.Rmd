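---
title: "Progress-curve kinetics of covalent serine protease inhibitors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Progress-curve kinetics of covalent serine protease inhibitors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(covkin)
```

## The inference problem

Covalent active-site inhibitors of the neutrophil serine proteases (human
neutrophil elastase, proteinase 3, cathepsin G) are ranked by the
second-order inactivation constant $k_\mathrm{inact}/K_I$
(M$^{-1}$s$^{-1}$). In a continuous assay the enzyme cleaves a fluorogenic
substrate while the inhibitor inactivates it, so the accumulated signal in
one well follows, under pseudo-first-order conditions,

$$P(t) = \frac{v_i}{k_\mathrm{obs}}\left(1 - e^{-k_\mathrm{obs} t}\right),$$

rising with initial velocity $v_i$ and flattening to the plateau
$v_i/k_\mathrm{obs}$ as the enzyme dies. The substrate competes with the
inhibitor for the active site, which attenuates the apparent rate:

$$k_\mathrm{obs} = \frac{(k_\mathrm{inact}/K_I)\,[I]}{1 + [S]/K_M}.$$

The pipeline estimates $(v_i, k_\mathrm{obs})$ per well, regresses the
$k_\mathrm{obs}$ ladder on $[I]$ through the origin, and multiplies the
slope by the competition factor $1 + [S]/K_M$.

**Assumptions.** (i) Inhibitor in large excess over enzyme, so inactivation
is exponential with a constant rate; (ii) $[I] \ll K_I$, so $k_\mathrm{obs}$
is proportional to $[I]$ (departures are flagged, not fitted); (iii)
negligible substrate depletion over the read window, so uninhibited
controls are linear; (iv) no slow-binding hysteresis, enzyme autolysis, or
inner-filter effects.

## Per-curve fitting

`fit_kobs()` adds a free baseline to the exponential model: plate readers
have offsets, and whether historical campaigns baseline-subtracted their
traces is generally unknowable, so the free term covers both conventions.
Estimation is least squares via `minpack.lm::nlsLM`, initialized from a
40-point log-spaced grid over $k_\mathrm{obs} \in [0.05, 50]/t_\max$ in
which, for each candidate rate, baseline and amplitude are solved in closed
form. Ties in the grid go to the smallest $k_\mathrm{obs}$ (the
conservative estimate). Three numerical choices matter:

* **Normalization.** Signals are shift/scale-normalized before fitting, so
  adding a constant changes only the baseline and rescaling changes only
  $v_i$ — exactly, not approximately.
* **Polish.** The Levenberg–Marquardt solution is refined by Gauss–Newton
  iterations until the step falls below $10^{-13}$ relative, which makes
  noiseless curves recover their parameters to machine precision and makes
  the fit invariant to representation details.
* **Model selection.** The exponential must beat the straight line by a
  margin of 2 on the small-sample corrected information criterion,
  otherwise the curve is declared `linear_unresolvable` and only the upper
  bound $k_\mathrm{obs} < 0.1/t_\max$ is reported. This prevents spurious
  tiny rate constants on control-like curves. Residual sums of squares are
  floored at $n \cdot 10^{-18}$ (normalized units) so numerically perfect
  fits compare by parameter count alone.

Standard errors come from the Gauss–Newton covariance at the optimum;
$v_i = A\,k_\mathrm{obs}$ inherits its error by first-order (delta-method)
propagation. Residuals are unweighted by default — the generator's noise is
approximately homoscedastic — with a weighting hook for real data.
Control-curve linearity (`check_control_linearity()`) compares a straight
line against a quadratic and calls a curve nonlinear when the quadratic
term is significant at $\alpha = 0.01$ *and* its peak deviation exceeds
$10^{-6}$ of the signal range; the magnitude guard prevents
vanishing-residual degeneracies from producing false alarms on noiseless
lines.

## Ladder regression

`second_order_constant()` fits $k_\mathrm{obs} = m\,[I]$ through the origin
— the relation has zero intercept by construction — weighting by
$1/\mathrm{SE}^2$ where per-curve errors are available, and reports
$m(1+[S]/K_M)$ with the delta-method standard error. A free-intercept fit
is attached as a diagnostic, and a through-origin $R^2$ below 0.9 flags
saturation (hyperbolic $k_\mathrm{obs}$); saturating ladders are flagged
but never refitted with the two-parameter hyperbola, which the linear
protocol cannot support. Ladders in which no curve resolved a positive rate
return a *bounded* result object rather than a number. Whether ladders
should instead be averaged as $k_\mathrm{obs}/[I]$ is not derivable from
the historical protocols; the slope fit was chosen because it
inverse-variance-weights the informative high-concentration curves, and the
ratio average is a one-line alternative on the returned fit table.

$K_M$ **is a required input.** The Michaelis constants of the canonical
substrates (MeO-Suc-AAPV-AFC on elastase and proteinase 3, Suc-AAPF-AFC on
cathepsin G) are not published for the standard assay conditions, so the
correction factor cannot be reproduced for the real campaigns without a
measured value. The shipped defaults (80, 125, 125 µM) are explicit
placeholders chosen so the three default enzymes exercise competition
factors 1.5, 2 and 3; every function that needs $K_M$ fails loudly when it
is absent rather than assuming one.

## Screening triage

The screen measures inhibition at 25 µM after 15 min of substrate-free
preincubation. `triage()` applies the standard decision tree verbatim:
below 5% ⇒ no inhibition; 5–40% (closed interval) ⇒
$k_\mathrm{inact}/K_I < 50$ M$^{-1}$s$^{-1}$, carried downstream as a
censored bound; above 40% ⇒ quantify. The simulator models the
preincubation without a competition term (substrate is absent before the
read) at rate $k_\mathrm{inact}[I]/(K_I + [I])$, then reads either initial
velocities (`"rate"`) or accumulated product (`"endpoint"`) against an
uninhibited control — both readouts are exposed because the historical
protocols do not pin one down.

The convention is internally tense: in the linear regime a compound at
exactly 50 M$^{-1}$s$^{-1}$ shows $1 - e^{-50 \cdot 25\mu\mathrm{M} \cdot
900\,\mathrm{s}} \approx 67.5\%$ inhibition — above the 40% band edge —
while 40% inhibition corresponds to about 22.7 M$^{-1}$s$^{-1}$. The
mapping may reflect competition during a different effective window or an
endpoint readout; `screen_boundary_note()` logs the discrepancy, and the
triage rule itself is left exactly as stated.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes:
signals $b + g\,[P](t)$ on a regular read grid (default 10 s for 600 s),
seven-concentration ladders in triplicate with one control per replicate,
and per-point Gaussian noise with a relative component (default 5%)
proportional to the signal above baseline. Defaults mirror the canonical
assay where stated — substrate concentrations 40/125/250 µM, 25 µM / 900 s
screening, triplicates — and make explicit choices where nothing is stated:

* **Enzyme concentration**: elastase is sold by activity (1.25 mU/mL), so a
  nominal 1 nM stands in; proteinase 3 and cathepsin G use their stated 7
  and 20 nM.
* **Microscopic split**: published potencies are lumped constants, so the
  simulator splits them with $K_I = 100$ µM by default — far enough above
  the 25 µM screen that the linear regime holds — and a turnover number
  $k_\mathrm{cat} = 20$ s$^{-1}$, typical of serine protease reporter
  substrates. Dissociation rates are set `equilibration_factor` (default
  100) times the chemical step, approximating rapid equilibrium.
* **Detector**: gain $10^9$ signal units per M product and baseline 50,
  arbitrary but fixed and recorded in every dataset header so fits are
  unit-consistent.
* **Ladder design**: concentrations are chosen so the noiseless
  $k_\mathrm{obs} \cdot t_\max$ spans $[0.5, 5]$ log-spaced — low enough
  that the initial slope is measurable, high enough that curvature is
  resolvable against a straight line.

Curves are generated from the closed form by default (exactly linear in
$[I]$, so noiseless datasets round-trip the true constant exactly, a
property the test suite asserts at 0.1%) or from the mass-action mechanism
(`method = "ode"`, integrated with `deSolve::lsoda` at `rtol = 1e-10`),
which exhibits inhibitor saturation, enzyme–inhibitor sequestration and
substrate depletion when the conditions impose them. The integrator solves
the reduced system (complexes and product) and reconstructs free species
from the conservation laws, so mass balances hold exactly at every grid
point. Reproducibility is by explicit integer seeds; determinations derive
per-curve child seeds as $(s + 1009\,i) \bmod (2^{31}-1)$ so a dataset is a
pure function of its seed.

What the generator does **not** emulate: inner-filter effects,
photobleaching, evaporation, enzyme autolysis, pipetting bias between
wells, or heteroscedastic detector noise. Passing tests therefore
demonstrate that the inference machinery inverts the assumed data model and
respects its stated scatter, not that it is robust to every artifact of
real plates.

## Selectivity profiling

Profiles collect per-enzyme entries that are either numeric constants or
censored bounds ("< 50"); bounds propagate as inequalities and are never
used in arithmetic — a property the tests enforce on randomized libraries.
Fold changes against the reference compound are computed at full precision
and *reported* rounded half-up to one decimal, the convention of printed
potency comparisons. A compound numeric on both elastase and proteinase 3
within 10-fold of each other, with cathepsin G quiet, is labeled a dual
HNE/PR3 inhibitor; 10-fold is the conventional selectivity cliff and is a
configurable window (compounds with ~2-fold proteinase 3 preference are
conventionally described as dual inhibitors, so the window must be
generous). Ranking sorts numeric entries descending, censored entries last,
ties lexicographically — a stable order independent of input permutation.

The bundled library transcribes the published constants of fourteen
phosphonic tripeptide inhibitors (elastase for all; proteinase 3 where
quoted; cathepsin G censored at the inactivity bound for the
selectivity-panel members). It is knowingly incomplete relative to the full
published tables, which are not reproduced here; randomized synthetic
compounds spanning 50–9×10⁶ M$^{-1}$s$^{-1}$ can be appended for stress
tests.

## Problem sizes and runtime choices

The test suite and the acceptance script use 61-point curves (600 s at
10 s), 7-concentration ladders in triplicate, 200-trial noise-calibration
ensembles, and 9-combination round-trip grids (three constants spanning
5×10³–2×10⁶ M$^{-1}$s$^{-1}$ × three competition factors). These sizes were
chosen to match the designed assay itself — a real determination is 24
wells — while keeping Monte-Carlo summaries (pass rates, SE calibration
within 30%) stable across seeds.

## Known limitations

* Only the linear (non-saturating) ladder model is fitted; strongly
  saturating data are flagged for a different experimental design, not
  analysed.
* The full $(k_\mathrm{inact}, K_I)$ decomposition and reversible IC$_{50}$
  analyses are out of scope.
* Global multi-curve fitting of microscopic constants is deliberately
  absent: the protocol fits wells one at a time, and the package follows
  it.
* With $K_M$ unpublished for the canonical assays, absolute constants for
  real campaign data depend on a user-supplied $K_M$; all package defaults
  are placeholders and marked as such.
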