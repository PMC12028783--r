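# alleloscreen

Tools for allelopathy screening bioassays: given a Petri-dish germination
experiment (a control plus several donor-species root-exudate treatments)
and optional physiological assays, `alleloscreen` computes the standard
germination parameters, scores each treatment's allelopathic effect, ranks
the donors by a multi-criteria method, and runs the comparison statistics a
screening paper reports. A built-in synthetic bioassay generator with
planted treatment effects makes the whole pipeline testable end to end.

It is written for plant ecologists and agronomists running
seed-germination allelopathy screens (e.g., candidate companion or cover
crops against a receiver species such as alfalfa), and for anyone who
wants those analyses reproducible from tidy CSVs.

## What it computes

For each dish with `n_total` seeds, `n3` germinated by day 3 and `n7` by
day 7:

- germination percentage `n7 / n_total`, germination potential
  `n3 / n_total`, and the simple vigor index
  `SVI = germination percentage × seedling height × 100`;
- the allelopathy response index comparing a treatment value `T` to the
  control `C`:

  `RI = (T − C)/T` if `T ≥ C`, else `(T − C)/C`

  (positive = stimulation, negative = inhibition, bounded in (−1, 1]);
- the comprehensive effect `SE` = arithmetic mean of `RI` over the six
  germination parameters, with treatments ranked by `SE`;
- an entropy-weighted TOPSIS ranking: criterion weights
  `w_j = (1 − e_j) / Σ(1 − e_k)` from the normalized Shannon entropy `e_j`
  of each criterion column, and relative closeness
  `c_i = d⁻_i / (d⁺_i + d⁻_i)` to the ideal solution;
- one-way ANOVA with Duncan's multiple range test (least significant
  ranges from the studentized range at protection level
  `1 − (1 − α)^(p−1)`) and compact letter displays;
- permutation variable importance of the germination parameters for `SE`
  (random-forest regressor, held-out MSE increase under column
  permutation);
- PCA of standardized physiological indicators (ROS, antioxidant enzymes,
  ascorbate pool, osmolytes) and min-max radar profiles;
- percent change vs control for any indicator.

## Worked example

```r
library(alleloscreen)

design  <- allelo_design(seed = 20240601)        # CK + T1..T10, 4 x 30 seeds
effects <- demo_effects(design)                  # planted promoter gradient
sim     <- simulate_germination(design, effects)
physio  <- simulate_physiology(design, effects)

scr <- allelo_screen(sim$dishes, sim$seedlings, physiology = physio,
                     control = "CK", seed = 20240601)
print(scr)
#> Allelopathy screen: 10 treatments vs control CK
#>   strongest composite effect: T1 (SE = 0.3348)
#>   TOPSIS ranking: T1 > T5 > T7 > T6 > T3 > T4 > T2 > T8 > T9 > T10

head(scr$allelopathy$se[order(scr$allelopathy$se$rank), ], 3)
#>   treatment        se rank
#> 1        T1 0.3348498    1
#> 5        T5 0.2923593    2
#> 6        T6 0.2327356    3

print(scr$pca)
#> PCA of physiological profiles: 12 samples, 14 indicators
#> Dim.1 + Dim.2 explain 77.6% (59.7% + 17.9%)
```

The `SE` column is each treatment's mean allelopathy index over the six
germination parameters: T1's 0.33 means its exudate improved the
parameters by roughly a third of their attainable relative range, while
T10's 0.089 (rank 10) marks the weakest net stimulation — exactly the
gradient the demo generator plants. The TOPSIS ranking weighs the same six
criteria by their information content instead of averaging, and agrees on
the extremes. The PCA line says the first two components carry 77.6% of
the variance in the 14 physiological indicators across the 12 biological
replicates (control, T1, T10 × 4).

The same run, driven by a config file and writing tidy CSVs plus a
manifest:

```r
run_pipeline(system.file("extdata", "demo_config.json",
                         package = "alleloscreen"), outdir = "demo_out")
```

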