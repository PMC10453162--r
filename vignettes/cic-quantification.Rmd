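---
title: "Quantifying cell-in-cell structures: models, criteria, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cell-in-cell structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cicquant)
```

## The biological question

Living tumour cells can engulf dead neighbours by non-professional
phagocytosis, producing cell-in-cell (CIC) structures: a whole dead cell
enclosed in the cytoplasm of a viable host. In two-colour co-incubation
assays the viable population carries a green cytoplasmic stain
(CellTracker-type), the dead population a red stain (CyTRAK-type), and DAPI
marks nuclei. A genuine engulfment has a characteristic morphology: the
dead cell rounds up into a near-circle (it has nothing to adhere to inside
the host), sits fully inside the host's footprint, and compresses the host
nucleus into a crescent. In tissue microarrays the same events are counted
per core and related to membranous E-cadherin, the adhesion molecule
engulfment depends on.

`cicquant` turns those criteria into an auditable pipeline: synthetic
scenes with planted truth, channel segmentation, pairwise morphology
scoring, and the rate/density/group statistics used to report such
experiments.

## Detection model

For every dead object $d$ and viable object $v$ with nonzero pixel overlap,
three scores are computed:

* **Containment** $|P_d \cap P_v| / |P_d|$ on the segmented pixel sets. The
  acceptance cutoff is 0.90, not 1.0: segmentation boundary jitter of one or
  two pixels would otherwise reject true engulfments. The cutoff is a
  parameter (`cic_params()$containment_min`).
* **Circularity** $4\pi A / P^2$ of the dead cell, cutoff 0.70. The
  perimeter $P$ is a chain-code estimate from the traced object contour with
  Vossepoel-Smeulders step weights (0.980 axial, 1.406 diagonal). A raw
  boundary-pixel count was rejected: it behaves like a Manhattan perimeter,
  deflating disk circularity to about 0.6 while inflating thin bars, so a
  single threshold could not separate the two shapes the criterion is meant
  to separate. The same estimator is used everywhere circularity or
  perimeter appears, including its own tests.
* **Crescent score** of the host nucleus: the solidity deficit
  $1 - A_{\text{nucleus}} / A_{\text{convex hull}}$, cutoff 0.10. Solidity
  deficit was chosen over a local curvature fit because it is monotone in the
  imprint depth, cheap, and checkable against brute-force hull enumeration.
  Because any lobulated nucleus has a deficit, the indentation must
  additionally be *adjacent* to the engulfed cell: the nearest hull-defect
  component centroid must lie within twice the engulfed cell's equivalent
  radius of its centroid.

A dead cell is assigned to at most one host: highest containment wins, ties
go to the larger host, then the lower label, so runs are bit-reproducible.
Rejected candidates are kept with `accepted = FALSE`, mirroring the manual
verification step such counts normally receive. Hosts touching the image
border are excluded (`exclude_border_hosts`): a partial host cannot
demonstrate complete engulfment. Setting `require_crescent = FALSE`
reproduces a pure overlap count.

## Summary statistics

The **CIC rate** of a co-incubation sample is
$100 \cdot n_{\text{CIC}} / n_{\text{viable}}$, with all viable cells
(hosts included) in the denominator; it is undefined (`NA`), not zero, when
no viable cells were counted. The **CIC density** of a tissue core is
$n_{\text{CIC}} / \text{area}$; the default denominator is the nominal core
area ($\pi/4$ mm^2 for the standard 1-mm spot) because reports of CIC/mm^2
rarely state a segmented-tissue normalisation and the nominal area is the
reproducible choice - callers can pass a measured area instead. Group
tables report mean and sample SD of density plus the fraction of cores with
at least one event, and carry a `significance_eligible` flag: groups with
fewer than 5 samples are never entered into significance testing
(`gate_significance()` marks those pairs "not calculated").

Cell-line condition summaries report **both** the unweighted mean ± SD of
per-line rates and the pooled totals with the pooled rate. The two answer
different questions and disagree under unbalanced line sizes; published
co-incubation counts show exactly this divergence, so the package always
prints both rather than reconciling them.

`compare_conditions()` defaults to a paired two-sided t test on per-line
rates - pairing by line is the natural design when each line is measured
adherent and in suspension - with a Wilcoxon signed-rank alternative. Lines
missing one condition are dropped with a message. No multiple-testing
correction is applied, matching the reporting style of such studies; the
report states the number of comparisons made. `correlate()` is Pearson's r
with the two-sided t-based p-value, returning an explicit "undefined"
marker for zero-variance input.

## What the synthetic data emulate - and what they do not

`generate_coincubation_scene()` renders hard-edged disks at 0.5 um/px,
8-bit: host cells 21-27 px radius (21-27 um diameter), nuclei 12-16 px,
engulfed cells 6-8 px, free cells of the same populations, background 10
and additive Gaussian noise of SD 8 grey levels clipped to range. Host
nuclei are disks carved by the engulfed disk at an overlap depth of
`crescent_depth` (default 0.75) times the nucleus radius. That depth renders
a pronounced semicircular imprint whose rasterised solidity deficit is
0.13-0.19 across the radius ranges - planted events are unambiguous under
the 0.10 criterion, which a recovery benchmark requires of its ground
truth; at shallower depths the deficit straddles the criterion and "truth"
becomes a coin flip. Placement is rejection sampling with a 10,000-attempt
cap per object; exhausting it raises an error naming the crowding, never a
silent truncation, because silently dropping an object would corrupt the
planted truth. Coordinates are 0-based (row, col) with pixel centres at
integers; bounding boxes are half-open.

Deliberately **not** simulated: point-spread blur and optics, intensity
gradients, stain bleed-through, 3-D structure, ellipsoidal or lobulated
cells, and real segmentation ambiguity. Perfect recovery on these scenes
therefore validates the criteria's logic and the pipeline's bookkeeping,
not performance on real micrographs, where thresholds would need
calibration against manually verified fields.

`generate_tissue_core()` renders a circular 1-mm core (nominal TMA spot) of
membrane rings; ring intensity increases strictly with the 0-3 E-cadherin
level (amplitudes 8, 70, 140, 210 grey levels over background 15 - level 0
keeps a faint nonspecific rim). CIC figures are ring-in-ring motifs.
`generate_cohort()` draws per-core CIC counts Poisson with mean density x
area, the simplest defensible model for counts of rare spatial events.

## Numerical and scoring conventions

* Components are labelled with `EBImage::bwlabel` (4-connectivity); for the
  filled, non-touching shapes segmented here this is equivalent to
  8-connectivity, and touching blobs are handled by the distance-transform
  watershed (`split_touching`), not by connectivity.
* Otsu's threshold per channel is the default; `min_area_px = 30` removes
  noise specks and is a scale-dependent choice.
* Convex hulls use base `chull()` on pixel centres, rasterised inclusively
  (boundary pixels count as inside); the tests check this against an
  independent gift-wrapping hull with triangle-decomposition membership.
* E-cadherin score cutpoints default to midpoints between the generator's
  level amplitudes, giving exact recovery on synthetic cores. For real
  images the cutpoints are a calibration input the user must supply:
  absolute grey levels are instrument-specific, so only orderings transfer.
* A mean grey value exactly at a cutpoint falls in the lower bin.
* p-values print to 3 decimals, as "p < 0.001" below that.

## Problem sizes used in the checks

The bundled verification uses 200 zero-noise plus 50 noisy scenes of 4-9
objects at 256^2 px for detection recovery, 500 cores per group for Poisson
density recovery at densities {0, 0.76, 1.64}/mm^2, 16 rendered cores for
score recovery, and 2,000 replicates of an 11-pair null for the paired
test's type-I error. These sizes give standard errors a few times smaller
than the tolerances they are checked against.

## Known limitations

Real micrographs will break the hard-edge assumptions first: Otsu on dim or
uneven staining, watershed over-splitting of clumped nuclei, and crescent
scoring on lobulated tumour nuclei (partly mitigated by the adjacency
requirement). The pipeline does not distinguish entosis, emperipolesis and
cannibalism - that needs markers beyond a live/dead pair - and deliberately
does no survival modelling.

## A minimal run

```{r example, eval = FALSE}
sc <- generate_coincubation_scene(scene_spec(seed = 7))
an <- analyze_scene(sc$image)
summarize_scene("scene7", an)
evaluate_recovery(an, sc$truth)
```
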