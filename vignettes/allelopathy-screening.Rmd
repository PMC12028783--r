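---
title: "Screening donor species for allelopathic effects on seed germination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening donor species for allelopathic effects on seed germination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alleloscreen)
```

## The problem

Allelopathy screens ask which donor species' root exudates stimulate or
inhibit the germination and early growth of a receiver species. The raw
material is a Petri-dish bioassay: a control (distilled water) and several
exudate treatments, each applied to replicate dishes of seeds, with
germination counted at day 3 and day 7 and seedling morphometrics (radicle
length, germ length, seedling height) measured at the end. A second,
physiological layer measures oxidative-stress and antioxidant indicators on
treated seedlings. `alleloscreen` turns these tables into comparable
effect scores and a defensible ranking of the donors.

## Germination parameters and the allelopathy index

Per dish with $n_{total}$ seeds, $n_3$ germinated by day 3 and $n_7$ by
day 7:

* germination percentage $= n_7 / n_{total}$,
* germination potential $= n_3 / n_{total}$ (early vigor; never exceeds
  the percentage because a day-3 germinant is also a day-7 germinant),
* simple vigor index $SVI = \text{germination percentage} \times
  \text{seedling height} \times 100$ (percent points × cm).

The package keeps fractions internally and renders percents only for
display. Metrics are computed per dish and averaged with equal dish
weights, so the replication unit carried into ANOVA is the dish (four per
treatment in the default design), not the individual seed. Dishes with no
germinated seed contribute an SVI of 0 and are excluded from morphometric
means, which avoids 0/0 without biasing the counts.

For each parameter the allelopathy response index compares a treatment
value $T$ to the control $C$:

$$RI = \begin{cases}(T-C)/T & T \ge C\\ (T-C)/C & T < C\end{cases}$$

$RI$ is positive for stimulation, negative for inhibition, bounded in
$(-1, 1]$, and invariant to rescaling both values by the same constant —
so the unit convention chosen for SVI cancels. The comprehensive effect
$SE$ is the arithmetic mean of a treatment's $RI$ over the six germination
parameters (the set is an argument; six is the default). $RI$ is computed
on treatment-level means by default because the index is defined on one
$(T, C)$ pair; a per-dish variant (`ri_level = "dish"`) is available and
flagged in the output, since the raw-data convention behind published
screens is usually unstated. Cells with $T = C = 0$ are undefined; they
become `NA` with a warning and are dropped from $SE$ rather than aborting
a whole run.

## Entropy-weighted TOPSIS

Ranking donors on six correlated criteria is a multi-criteria decision
problem. The package uses TOPSIS with entropy weights. For criterion $j$
over $m$ alternatives, with column proportions $p_{ij}$, the normalized
entropy is $e_j = -\frac{1}{\ln m}\sum_i p_{ij}\ln p_{ij}$, the divergence
$d_j = 1 - e_j$, and the weight $w_j = d_j / \sum_k d_k$ — a criterion that
does not vary across alternatives gets weight exactly zero. Alternatives
are then scored by relative closeness
$c_i = d^-_i / (d^+_i + d^-_i)$ to the per-criterion ideal point in the
weighted, normalized criteria space.

Two choices here were genuinely open and are therefore configurable:

* **Normalization.** Classical vector normalization (each column divided
  by its Euclidean norm) is the default; min-max scaling is available via
  `normalization = "minmax"`. Both routes are covered by the brute-force
  oracle tests, and vector normalization makes the ranking invariant to
  rescaling any single criterion column.
* **Positivity.** Entropy needs strictly positive proportions. Columns
  with non-positive cells are shifted by $|\min| + 10^{-6}\times$ range,
  with a warning; germination criteria are positive in practice, so the
  rule exists for robustness, not as a modelling statement.

All six germination criteria are treated as benefit criteria (larger is
better) by default, matching the promotion framing of a germination
screen; per-criterion cost flags are available. Ties in closeness are
broken by input order and reported.

## Comparison layer

Group comparisons use classical one-way ANOVA (via `stats::aov`) followed
by Duncan's multiple range test, re-implemented from its definition: means
are sorted, and the least significant range for a span of $p$ means is the
studentized-range quantile at protection level $1-(1-\alpha)^{p-1}$ with
$(p, df_{error})$ degrees of freedom, scaled by $\sqrt{MSE/n}$ ($n$ the
harmonic mean of group sizes when unbalanced, flagged in the result). Two
means differ only if their gap exceeds the LSR for their span *and* no
enclosing span is itself non-significant; because non-significance is
closed under sub-spans, the homogeneous groups are intervals of the sorted
means, and the compact letter display assigns one letter per maximal
interval. The implementation is checked against an exhaustive
span-enumeration oracle on a thousand random instances in the test suite.

Percent change versus control, $(T - C)/C \times 100$, is provided for
reporting effect sizes on physiology and growth indicators.

Technical replicates are averaged into their biological replicate before
any inference, so the physiology ANOVA and PCA run on $n = 4$ biological
replicates per group, not $4 \times 3 = 12$ pseudo-replicates. No
multiple-testing correction is applied across indicators by default —
each indicator is reported marginally; users can apply `p.adjust` to the
returned p-values if they prefer.

## Variable importance and physiology profiling

Which germination parameter drives the composite $SE$? The package fits a
random-forest regressor (500 trees by default) and reports *permutation*
importance: the mean increase in held-out mean squared error when one
feature column is permuted, averaged over 50 permutation rounds. This is a
model-agnostic contract — it does not depend on a particular tree library's
impurity accounting — and it is validated by planted-predictor recovery
tests. A 30% holdout split estimates the loss; at least 8 observations are
required, so importance over a single screen uses the treatments as
observations, and simulation studies pool datasets.

PCA of the physiology indicators standardizes each indicator (they carry
heterogeneous units — rates, contents, activities), so the decomposition
is of the correlation matrix. Variance-explained fractions sum to one;
component signs follow a deterministic convention (the largest-magnitude
loading of each component is positive), so reruns are comparable.
Zero-variance indicators are dropped with a warning. Radar profiles use
per-indicator min-max scaling of treatment means to $[0, 1]$; a constant
indicator maps to 0.5 with a warning. Min-max is a declared display
convention, not an inference.

## The synthetic bioassay generator

No raw screen measurements are published alongside the design this package
emulates, so the generator is a first-class module: it draws data with the
statistical structure the analysis assumes, with planted treatment
effects, and every downstream stage is validated against it.

* Day-7 germination is Bernoulli per seed; day-3 status is Bernoulli
  *conditional on* day-7 germination, which enforces
  $n_3 \le n_7 \le n_{total}$ by construction. The operational criterion
  for a day-3 "germinated" call is treated as a latent label — field
  practice varies and the design being emulated does not pin it down.
* Morphometrics are lognormal with the treatment's mean and CV: published
  screens report only means and significance letters, and positivity is
  physical. The default CV of 0.15 is a calibration choice typical of
  seedling morphometrics, not a published value.
* Physiology draws a latent biological-replicate value (control mean ×
  multiplier × biological noise) and adds technical noise (CV half the
  biological CV of 0.08-0.10) around it, truncated at zero.
* Each (group, dish) pair uses its own counter-derived RNG substream, so
  a dataset is reproducible from one seed and unchanged by the order in
  which groups are generated — dropping a treatment does not perturb the
  others.

The `demo_effects()` preset plants the qualitative structure of a
10-donor screen: T1 the strongest promoter on all six parameters, T10 the
weakest (just above control), T2 inhibiting germination percentage while
mildly promoting growth, and graded intermediates; T1 additionally lowers
reactive-oxygen and MDA levels and raises the ascorbate pool while T10
mainly raises osmolytes. What passing tests on these data show is that the
pipeline *recovers planted structure at realistic noise*; they cannot show
that any particular real screen's numbers are reproduced, because the
generator's effect sizes are phenomenological multipliers, not a
dose-response model, and real bioassays add dish-position and batch
effects the generator omits.

## Orchestration and reproducibility

`run_pipeline(config, outdir)` drives the whole screen from a JSON or YAML
configuration (see `inst/extdata/demo_config.json`): simulate or read the
input CSVs, then metrics → allelopathy scores → TOPSIS → comparisons →
physiology profiles, writing one tidy CSV per stage plus a `manifest.json`
with the package version, config hash, seed, per-stage row counts and any
warnings raised (shift rules, dropped indicators, undefined RI cells).
Outputs are staged and moved only on success, so a failed run leaves no
partial output directory; failure modes carry distinct condition classes
(`alleloscreen_config_error`, `alleloscreen_missing_control`,
`alleloscreen_degenerate_weights`). All randomness flows from the single
config seed. The package is driven from R — `run_pipeline()` plus the
stage functions are the scripting interface; no shell wrapper is shipped.

Problem sizes in the shipped validation suite: 1,000 regenerated datasets
for generator calibration, 100 random matrices against the TOPSIS oracle,
1,000 instances against the Duncan oracle, 10,000 null datasets for ANOVA
calibration, 200 screens for planted-ranking recovery and 100 runs for
importance recovery — sizes at which the Monte-Carlo standard errors are
small relative to the margins being checked.

## A short example

```{r example}
design <- allelo_design(seed = 20240601)
effects <- demo_effects(design)
sim <- simulate_germination(design, effects)
physio <- simulate_physiology(design, effects)

scr <- allelo_screen(sim$dishes, sim$seedlings, physiology = physio,
                     control = "CK", seed = 20240601)
print(scr)
head(scr$allelopathy$se[order(scr$allelopathy$se$rank), ])
```

## Known limitations

* Effects are phenomenological multipliers; no allelochemical
  concentration-response model is attempted.
* The day-3/day-7 snapshots do not support germination time-course
  modelling.
* TOPSIS rank-reversal mitigation and other MCDA methods (VIKOR, AHP) are
  out of scope.
* The comparison layer is fixed-effects only; randomized-block or
  repeated-measures structure is not modelled.
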