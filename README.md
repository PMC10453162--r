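# cicquant

Quantification of cell-in-cell (CIC) structures — dead cells engulfed by
viable tumour cells through non-professional phagocytosis — in two-colour
co-incubation fluorescence images and immunostained tissue-microarray
cores.

The package is aimed at groups running engulfment assays (green-stained
viable cells co-incubated with red-stained dead cells, DAPI nuclei) or
scoring CIC events and membranous E-cadherin on TMA slides, and at anyone
who wants those counts to come from criteria that are explicit, parameterised
and testable rather than buried in interactive software.

## The method

A candidate event is a (dead, viable) object pair with pixel overlap. Three
scores decide it:

* **containment** — |P_dead ∩ P_host| / |P_dead| ≥ 0.90 ("swallowed");
* **circularity** — 4πA/P² of the dead cell ≥ 0.70 (an engulfed cell rounds
  up because it cannot adhere inside the host);
* **crescent score** — solidity deficit 1 − A/A_hull of the host nucleus
  ≥ 0.10, with the indentation adjacent to the engulfed cell (the
  semicircular nuclear imprint of a genuine engulfment).

Each dead cell is assigned to at most one host (highest containment, ties
to the larger host, then lower label); rejected candidates are kept for
audit. Per sample the package reports the **CIC rate**
100·n_CIC/n_viable (%), per tissue core the **CIC density** n_CIC/area
(events/mm², nominal core area π/4 mm² for a 1-mm spot), plus group tables
(mean ± SD density, fraction of cores with ≥ 1 event) with the rule that
groups under 5 samples never enter significance testing.

A synthetic-data module generates co-incubation scenes and TMA cores with
fully known planted truth, so segmentation, detection, and every summary
statistic are tested by recovery rather than by eyeballing.

## A worked example

```r
library(cicquant)

sc <- generate_coincubation_scene(scene_spec(seed = 7))
an <- analyze_scene(sc$image)
an$events
#>   host_id engulfed_id containment_fraction circularity crescent_score accepted
#> 1       1           1                    1           1      0.1493124     TRUE
#> 2       2           2                    1           1      0.1491935     TRUE

summarize_scene("scene7", an)[, 1:6]
#>   sample_id         mode n_viable n_dead n_cic cic_rate_percent
#> 1    scene7 coincubation        6      5     2         33.33333

evaluate_recovery(an, sc$truth)[c("precision", "recall")]
#> $precision
#> [1] 1
#> $recall
#> [1] 1
```

The scene planted 4 free viable cells, 2 hosts, 3 free dead cells and 2
engulfed cells; both planted pairs are accepted (containment 1, circular
engulfed cells, nuclear imprint scores ≈ 0.15 above the 0.10 criterion) and
nothing else is, so the rate is 2/6 viable cells = 33.3 %.

Correlating per-line E-cadherin intensity (gray levels) with CIC rates:

```r
correlate(c(12.9, 5.7, 2.8, 1.1, 0.5), c(9.9, 6.0, 13.0, 3.8, 2.2))
#> Pearson r = 0.480, p = 0.414, n = 5
```

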