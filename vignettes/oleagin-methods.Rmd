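---
title: "Methods: growth kinetics, FAME quantification and lipid-pattern classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: growth kinetics, FAME quantification and lipid-pattern classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oleagin)
```

`oleagin` implements the quantitative core of a comparative-physiology
workflow for oleaginous yeasts: batch growth kinetics from OD600 time
series, gas-chromatography (GC-FID) quantification of fatty-acid methyl
esters (FAMEs) by internal standard, lipid content expressed as percent
of cell dry weight (CDW), and categorical classification of
lipid-accumulation behaviour and substrate-assimilation phenotypes. This
vignette records the models, the tunable parameters, and the design
choices behind each stage, including the ones that were genuinely open.

## Growth parameter estimation

### Model-free fitting

`growth_fit()` deliberately avoids fitting a parametric growth law.
Batch cultures of *Yarrowia*-clade yeasts on oleic acid or glucose are
not guaranteed to follow a logistic or Gompertz curve (filamentation,
substrate emulsions and oxygen transfer all distort the late phase), so
the three classical parameters are estimated directly from the shape of
ln(OD) versus time:

* **Maximum specific growth rate** `mu_max` (h^-1^): the largest
  least-squares slope of ln(OD) over all sliding windows of `window`
  consecutive points. The window default is 5 points; at the typical
  2-3 h sampling interval of a flask experiment that spans roughly one
  generation at the fast end and stays local enough not to average over
  curvature. Ties are broken by the earliest window (relevant for a
  perfectly exponential series, where every window has the same slope).
* **Lag phase** `lag` (h): the intersection of the winning tangent line
  with the baseline, taken as the mean ln(OD) of the pre-growth plateau.
  The plateau is every point collected before the smoothed curve first
  exceeds the initial OD by `lag_threshold` (default 0.10, i.e. a 10 %
  rise — comfortably above replicate-level OD noise but below the first
  doubling). This is the classical tangent construction for lag
  determination. A lag is reported *absent* rather than zero when the
  tangent intersects at or before time zero or when the plateau is
  shorter than one sampling interval; cultures transferred onto a medium
  they are already adapted to genuinely have no measurable lag, and an
  optional field represents that more honestly than a sentinel value.
* **Maximum cell density** `od_max`: the maximum of the series after a
  centred rolling median of window 3. The median kills single-point
  spikes (a washing artefact in oleic-acid cultures) without flattening
  the plateau.
* **Generation time**: `ln(2) / mu_max`. Printed generation-time tables
  derived from rounded `mu_max` values can disagree with this identity
  in the second decimal; the identity is the definition used here.

A series that never rises `lag_threshold` above its initial density is
flagged `no_growth`; lag and generation time are then unset and
downstream time-point selection refuses to run.

`growth_fit()` returns a classed model object with the usual verbs
(`print`, `summary`, `coef`, `predict`, `fitted`, `residuals`, `plot`,
`simulate`). `predict()` exposes the fitted *envelope* — baseline, then
tangent, then saturation at `od_max` — which is exactly the information
the estimator extracts, no more; `simulate()` is the parametric
bootstrap companion, drawing new series from a delayed-logistic
generator at the estimates.

### Sampling time points

Lipid measurements are compared across strains at equivalent
*physiological states*, not equal clock times: the times at which the
smoothed curve first reaches one fifth of `od_max`, half of `od_max`,
and `od_max` itself. `select_timepoints()` finds the earliest crossings
by linear interpolation. The "at maximum" target is `(1 - delta) *
od_max` with `delta = 0.02`, because a noiseless asymptotic curve only
touches its maximum at the final sample and a 2 % shortfall marks the
plateau robustly. Targets never reached are returned as `NA` with a
warning rather than extrapolated.

## Synthetic data generation

The package is verified end to end against its own seeded generator;
every default below is therefore part of the study conditions the tests
assume.

### Growth curves

Two lag models are available. The default, `delayed_logistic`, holds the
culture at `od0` for exactly `lag_true` hours and then grows
logistically; because the configured lag is sharp, lag recovery can be
tested tightly. The `baranyi` option uses the Baranyi-Roberts adjustment
function (`h0 = r * lag`) for a smooth, more physiological transition.
In both models the internal logistic rate is `r = mu_true / (1 -
od0/od_max_true)`, so that the *realised* maximum of d ln(OD)/dt equals
`mu_true` exactly — the generator's `mu_true` and the estimator's
`mu_max` then refer to the same quantity.

Defaults mirror the flask experiments the generator emulates:
inoculation at OD 0.5, sampling every 0.5 h, 30-48 h duration.
Measurement noise is multiplicative log-normal (`noise_sd` is the sd on
the log scale, default 0.02, i.e. ~2 % CV) — OD errors scale with the
reading and the simulated OD must stay positive. No within-replicate
variance was available to calibrate against, so 2 % is a conventional
spectrophotometer figure; it is a free parameter.

### Chromatograms

A simulated GC-FID trace is a sum of Gaussian peaks on a drifting
baseline. Each fatty acid of mass *m* µg contributes area `k * RF * m`
(pA min) at its library retention time, with a single global detector
constant `k = 1000` pA min µg^-1^ — arbitrary but fixed, since the
internal-standard method uses only area *ratios*. The C17:0 internal
standard is always present at `is_mass_ug` (default 75 µg, the routine
spike). The default library spaces C14:0 through C18:2(n-6) at 1-minute
intervals with peak width sd 0.04 min, so neighbouring compounds are
~25 peak widths apart: the generator emulates a well-resolved run and
deliberately does **not** model co-elution, detector saturation or
retention-time drift across runs. Baseline level 10 pA, drift
0.5 pA min^-1^ and white noise sd 2 pA are of the order of a low-bleed
column specification. Configurations whose retention times fall within
3 peak widths record an overlap warning in the metadata.

### Scenarios

A `scenario_config` ties a growth simulation to a ground-truth lipid
trajectory: percent CDW and FA composition at the three sampling states.
Per-FA masses are set so that total FA mass equals `pct_cdw / 100 *
aliquot CDW`, with `aliquot CDW = cdw_per_od * aliquot_od_units`
(defaults 0.5 mg per OD unit and 10 OD units — the fixed-aliquot harvest
convention; ~0.5 mg dry weight per OD600 unit is typical of yeast).

`clade_scenarios()` encodes the nine study strains on both media. Growth
parameters come from the study's printed table (no lag on oleic acid;
lags of 1.26-8.77 h on glucose). Trajectory anchors printed in the text
are used verbatim: maxima of 67.1 % CDW (*C. hispaniensis*), 52.2 %
(*Y. lipolytica*), 29.4 % (*C. oslonensis*), the 34.4 → 15.2 % decline
(*Y. deformans*), and on glucose 5.1 → 7.2 % (*C. hispaniensis*),
4.0 → 4.5 % (*C. alimentaria*), 6 → 4.7 % (*Y. yakushimensis*).
Unprinted trajectory points were fixed once to values consistent with
the reported three-way pattern grouping (rise-then-fall for
*Y. lipolytica*, *C. galli*, *C. alimentaria*, *C. hispaniensis*;
continuous increase for *C. oslonensis*, *C. phangngensis*; decline for
*Y. deformans*, *Y. yakushimensis*, *C. hollandica* on oleic acid) and
are not revisited; they are defaults of the generator, not measurements.
Compositions reflect the reported majors: C18:1(n-9) dominant on oleic
acid with C16:1(n-7) second; on glucose C18:1(n-9) dominant except
C18:2(n-6) in *C. alimentaria* and *Y. yakushimensis* and a C16:0 /
C18:1(n-9) tie in *C. hispaniensis*.

Passing tests on these scenarios show that the estimators recover what
the generator encodes under realistic noise; they cannot show
robustness to features the generator omits (co-elution, asymmetric
peaks, diauxic growth, CDW measurement error).

## Peak detection and quantification

The baseline is a centred rolling minimum of width `baseline_window`
(default 1 min — an order of magnitude wider than a peak, so it tracks
drift without eating into peaks) smoothed by a rolling mean of the same
width, then subtracted. Peaks are local maxima of the corrected signal
with topographic prominence at least `min_prominence` (default 20 pA).
The default is set an order of magnitude above the detector noise floor:
white noise of sd 2 pA produces spurious *prominences* of up to ~14 pA
over long baseline stretches (prominence is measured against the lowest
valley toward the nearest higher point, which can be far away), while
the smallest real FAME peaks in a routine run are thousands of pA tall.
Two equal-height maxima with no dip between them are one clipped
plateau: they are merged and flagged saturated, not dropped, so a
saturated internal standard is visible rather than silently absent.

Integration bounds run outward from each apex to the first point where
the corrected signal falls below `max(0.1 % of apex height, 3 x robust
noise)`, but never past the valley shared with an adjacent detected
peak — overlapping peaks are split at the minimum between apexes. The
0.1 % relative floor truncates a Gaussian at ±3.7 sd (99.98 % of its
area), and because the internal standard is truncated at the same
relative height, the loss cancels in the area ratio. Areas are
trapezoidal integrals; at the default 100 points min^-1^ the grid error
is negligible against the 0.5-1 % tolerances used in tests.

Assignment matches apexes to library retention times greedily by
increasing distance within `rt_tolerance` (default 0.1 min, a tenth of
the library spacing): each library entry captures at most one peak and
each peak one entry, so a spurious shoulder cannot displace a true
assignment.

Quantification is the internal-standard rule `mass_i = area_i / area_IS
* is_mass_ug / RF_i`. Response factors default to 1 — FID response per
unit mass is nearly uniform across C14-C18 FAMEs and no RF correction
was part of the original workflow — but per-compound factors are
honoured when the library provides them. Endogenous C17:0 is assumed
negligible (the spike is added without correction); that is a documented
limitation of the method itself. Total lipid content counts identified
FAMEs only; `include_unassigned = TRUE` adds unidentified peak areas at
RF 1 for users who prefer the inclusive definition. `mg_per_g_cdw` is
`mass_ug / aliquot_cdw_mg` (µg/mg ≡ mg/g).

## Trajectory classification

With contents `c1, c2, c3` at the fifth/half/max states and relative
steps `d12`, `d23` (denominators floored at 10^-6^ to tolerate
zero-lipid samples), `classify_pattern()` uses a relative tolerance
`epsilon` (default 0.10):

* rise then fall → `accumulate_then_mobilize`;
* rise with no later fall and net gain, or flat start then rise →
  `continuous_increase`;
* net loss with no initial rise → `decline`;
* otherwise `stable`.

The study describes the three behaviours qualitatively; 10 % is the
smallest change treated as real, of the order of the replicate error
bars in such experiments, and the label is scale-invariant by
construction. A consequence worth knowing: a genuine but sub-10 %
drift (e.g. 4.0 → 4.5 % of CDW with a flat midpoint) classifies as
`stable` unless the midpoint splits the rise into a >10 % step.

`call_oleaginous()` uses a strict `> threshold` comparison with the
threshold at 20 % of CDW — the lower bound of the conventional
"20-25 % of biomass" definition, configurable for users who prefer 25.
`major_compound()` returns the argmax of the composition, with compounds
within 1 % relative returned together as a tie set (two compounds whose
masses differ by less than instrument repeatability should not be ranked).
The major compound is determined at the OD-max point, the state at which
storage capacity is assessed.

## Phenotype matrices

Scores are categorical: `growth`, `weak`, `none`, `untested`. The
original three-way "delayed, weak or slow" grading collapses to a single
`weak` level because drop-test timing is not reproduced here.
`summarize_substrates()` partitions substrates into universal / unused /
variable for one medium; `weak_counts_as_growth` defaults to `TRUE`
(weak growers count as users, the convention behind a 3/21/7-type
partition), and toggling it can only move substrates between universal
and variable — never into unused, which the test suite asserts as an
invariant. `toxicity_flags()` separates "toxic" (no growth on rich
medium plus substrate despite growth on rich medium alone) from
"non-metabolised" (no growth on minimal plus substrate, growth on rich
plus substrate), using rich-base-alone control rows encoded as substrate
`"none"`.

The packaged fixtures under `inst/extdata/` are **synthetic**
reconstructions (and are named accordingly): the constrained cells —
the universal set {fructose, glycerol, glucose}, the 3/21/7 partition,
the tributyrin halo strains, C6 toxicity, per-strain C18:1 and alkane
deficits — encode facts stated in the study text, while the remaining
cells are fixed plausible values. They exercise the code paths; they are
not the original supplementary tables, which ship as binary spreadsheets
and are not redistributed here.

## Problem sizes and reproducibility

All randomness flows through integer seeds carried in the config
objects; a scenario seeded twice is byte-identical, and `run_pipeline()`
re-seeds scenario *i* as `seed + 100 i` so an entire run is reproducible
from one integer. The test suite and the acceptance script run at the
study's own scale — 61-97 point growth curves, 1 101-point
chromatograms, nine strains by two media, 20 seeded replicates for the
stochastic checks — chosen to represent a realistic flask experiment and
instrument run.

## Known limitations

* No parametric growth model is fitted; confidence intervals on
  `mu_max` and `lag` are not produced (the `simulate()` bootstrap is the
  intended route if needed).
* The chromatogram model omits co-elution, asymmetric (tailing) peaks,
  retention drift and detector saturation below the clipping level;
  deconvolution is out of scope.
* Endogenous C17:0 biases the internal-standard method low by its own
  (small) amount; lipid classes (TAG vs free fatty acids) are not
  separated.
* Two-replicate designs support no inter-strain hypothesis testing, and
  none is implemented.
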