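---
title: "Growth-zone morphometrics: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-zone morphometrics: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The biological problem

Anostracan crustaceans such as fairy shrimp develop *anamorphically*: they
hatch with a head and a few specified trunk segments, and add the rest one
at a time from a posterior **growth zone** (GZ). Each newly specified
segment is marked by a transverse stripe of Engrailed (En) expressing
cells at its posterior; the stripe count is therefore the natural
developmental staging variable. Whether the posterior really is a "growth"
zone — a region of concentrated proliferation — or merely a segment
*addition* region is a quantitative question: it requires measuring how
the GZ's size and cell content change as segments are added, how much
mitosis occurs there, and whether that mitosis can account for the tissue
in the segments produced.

`gzmorph` implements that quantitative programme as a reusable, fully
tested pipeline, driven by a synthetic larva generator so that every
analysis runs end-to-end without micrograph-derived data.

```{r}
library(gzmorph)
gz_config()
```

## The synthetic larva model

`generate_larva(t, config, seed)` produces a 2D ventral nucleus field for
one larva at `t` hours post hatch.

**Stage clock.** Segments are specified at a constant rate: the stripe
count is `initial_stripes + floor(t / interval_h)`, capped at
`max_stripes`. Defaults are 3 stripes at hatch and 1.4 h per segment. Note
a deliberate non-reconciliation: with a 1.4 h interval, adding 14 segments
takes 19.6 h, slightly more than the nominal 18 h observation window over
which roughly 14 segments are reported for this kind of larva. The clock
follows the interval; users who prefer the 18 h reading can override
`interval_h`. The package does not silently split the difference.

**Geometry.** Nuclei sit on a jittered rectangular lattice with spacing
`cell_diameter_um` (default 6 µm; epithelial nucleus spacing is not a
published constant, so it is a config parameter and *every*
count-to-length conversion goes through it). Jitter is uniform within
±0.2 spacing. We use a rectangular rather than hexagonally offset lattice,
and give every transverse row an odd cell count, so that one nucleus
column lies exactly on the midline: with the corridor-based cell counting
described below (corridor half-width = half a cell diameter), hex-offset
rows would place nuclei exactly on the corridor boundary and make
count-versus-length identities fragile to jitter. The rectangular packing
keeps every count↔length oracle exact while remaining a reasonable
approximation of an epithelial sheet at the 10%-level accuracy the
area/count consistency checks demand.

Axially the field is: a head region, the specified segments (each
`seg_length_cells_by_order` cells long between stripes, plus its En stripe
row), the GZ, and the telson. Hatchling segments are 4 cells long; late
segments shrink to 2, matching the observation that newly added posterior
segments are 2–3 cells long versus about 4 early.

**Growth-zone kinetics.** The GZ starts `gz_length0_cells` long (default
13) with widths `widthA_cells` (at the last En stripe, default 23) and
`widthB_cells` (at the GZ/telson boundary, default 27), both held constant
through development. Length shrinks by `gz_shrink_per_segment` cells
(default 0.75) per added segment and gains `molt_gz_gain_cells` (default
2.5) at the first molt (`molt_time_h`, default 3.7 h) — the molt is
modeled as an instantaneous length gain because only its average timing
and cell-count effect are known, not its mechanism. The defaults were
chosen once so that the hatchling GZ cell-field area is
`13 × (23 + 27)/2 = 325` cells and its ventral area `325 × 36 µm² =
0.0117 mm²`, the canonical hatchling values for this system; widths are
odd for the midline-column reason above. `constant_gz_mode = TRUE`
switches to an *Artemia*-like condition in which GZ length is maintained
as segments are added.

**Cell-cycle labels.** Per region, nuclei are flagged S-phase (EdU-like)
and M-phase under two independent markers: `m_hoechst` (morphological
metaphase–telophase scoring) and `m_ph3` (phospho-histone H3,
prophase/metaphase). The two are drawn independently — in this system the
pH3-detectable window fades before anaphase, so neither marker's set is a
subset of the other; `ph3_ratio` (default 2.4) sets the expected
pH3:Hoechst count ratio. GZ mitotic fraction defaults to 0.025, the
midpoint of the 1–4% band typical of this system. S-phase fractions
implement the tri-domain pattern: near-1 (`band_sync_frac = 0.95`) in the
newest segment (the synchronous band), near-0 (`edu_clear_frac = 0.02`)
in the anterior GZ, intermediate (`edu_scatter_frac = 0.4`) in the
posterior GZ. `band_lateral_ext_prob` (default 0) optionally lets the
band spill into the lateral edges of the penultimate segment, as is
sometimes seen. Mitotic nuclei carry a spindle angle to the AP axis:
GZ mitoses are AP-oriented (angle < 45°) with probability
`ap_orientation_prob = 0.8`, segmental mitoses are transverse-biased
(`seg_ap_prob = 0.2`).

**Cohorts.** `generate_cohort()` emulates the staged-collection design:
hatchlings pooled over a collection interval (`hatch_jitter_min = 15`, so
true age is nominal age plus Uniform(0, 15) minutes) and stripe counts
scored with integer observation noise, uniform on {−1, 0, +1} by default
(`stage_noise_stripes`); the field shows stage-to-stage scoring
variability without a published error distribution, and a symmetric
single-stripe error is the minimal model of it. All randomness flows from
one top-level seed through `derive_seed(seed, stage_name)`.

**What the generator does *not* emulate.** No pixel-level images, no 3D
curvature (ventral projection only — dorsal and ventral GZ measures are
equivalent in these larvae), no cell movement or lineage tracking, no
post-specification segment growth (real segments grow substantially after
they form, so synthetic body lengths rise more slowly than real ones), no
stereotyped anterior-segment S-phase progression, and the three observed
sub-patterns of posterior scattered EdU incorporation are collapsed into
one `scattered` class. Passing tests therefore validate the estimators
and the bookkeeping on fields with known truth; they do not certify
performance on micrographs.

## Measurement definitions

`measure_larva()` computes the eight standard measures — body length, GZ
length, GZ widths A and B, trunk area, last-segment area, GZ area,
last-segment length — plus cell-count analogues and GZ mitosis counts
under both markers. Linear measures are polyline arclengths; areas are
shoelace polygon areas over landmark-bounded polygons (trunk area runs
from just posterior of the second maxillary stripe to the width-B line;
last-segment length lies *between*, and excludes, the final two stripe
rows). Cell counts use `count_cells_along()`: nuclei whose centre falls
within a corridor of half-width `cell_diameter_um / 2` around the measured
path — the scoring protocol counts nuclei "along" a line without defining
a corridor, so the half-cell corridor (exactly one lattice row) is our
operationalization, exposed as an argument. For length counts the path is
inset by one corridor half-width at each end so the corridor's end caps
cannot leak across the bounding landmark into the neighbouring row.
`score_en_stripes()` implements the stripe-completeness rule: a stripe
counts only if its nuclei form a chain with inter-nucleus gaps at most
1.5 cell diameters reaching both lateral margins.

With fewer than two stripes the last-segment measures are flagged absent
(`NA`), and a degenerate GZ (coincident width lines) yields zero area
rather than an error.

## EdU domain detection

`detect_edu_domains()` profiles the S-phase fraction in sliding windows
(width 2 cell diameters, step one half diameter — wide enough to average
over a row's nuclei, narrow enough to localize boundaries to about one
cell) from just behind the penultimate stripe to the GZ/telson boundary.
Windows classify as `synchronous_band` (fraction ≥ 0.8), `clear` (≤ 0.1)
or `scattered`; both thresholds are arguments since the underlying
pattern is reported qualitatively. Adjacent same-class windows merge, and
any resulting domain narrower than one window is absorbed into its
anterior neighbour: a window straddling a true boundary sees a mixed
fraction and would otherwise insert a spurious sliver domain between band
and clear zones. Boundaries are therefore accurate to about one window
width, which is the tolerance the recovery tests assert. The canonical
anterior-to-posterior result is `synchronous_band > clear > scattered`,
and `boundary_concordance()` compares those boundaries against posterior
expression territories (*WntA* ↔ clear, *Wnt4* ↔ scattered, band
posterior edge ↔ *cad*/*WntA* anterior border) as signed offsets in µm.

Spindle angles classify as AP when < 45°, with the exactly-45° tie going
to AP — the angular cutoff is not part of the published protocol, so the
midpoint with a documented tie rule is used.

## The division budget

`gz_cell_area()` (trapezoid: length × mean width, in cells),
`segment_cell_area()` (rectangle: last-segment length × width A) and
`divisions_required()` implement the cell-count bookkeeping that converts
GZ and new-segment cell-field areas into the average number of doublings
the initial GZ pool must undergo. Two lineage models are provided:

* **depletion** (default): all new segmental tissue descends from the
  initial pool, which is itself consumed — `d = log2(N / G0)`, floored at
  0. This is the package default because the GZ demonstrably shrinks in
  the default condition.
* **persistence**: the pool survives alongside its output —
  `d = log2(1 + N / G0)`.

On the canonical fixture (G0 = 325 cells; 14 segments of width 22 cells
and lengths 5×4 + 4×3 + 5×2, totalling 924 cells) the depletion model
gives 1.51 ≈ 1.5 doublings. The published account of this calculation
does not print the underlying cell dimensions or state which lineage
model it used; the fixture is a consistent reconstruction, and neither
model is asserted to be the original computation.
`area_bookkeeping()` performs the companion mm² bookkeeping (initial GZ
area as a percentage of the summed newest-segment areas), and
`report_about()` reproduces round-to-nearest-ten "about N%" reporting.

## Cohort statistics

`segment_addition_rate()` fits stripe count on nominal age by ordinary
least squares (`stats::lm`). Because the underlying clock is a floor
staircase observed over a finite window, the fitted slope carries a small
deterministic quantization bias relative to `1/interval_h` (about −0.005
segments/h under the default design); recovery tests therefore compare
the mean fitted slope across seeds to the truth at three estimator
standard errors and check 95% CI coverage, rather than demanding exact
equality.

`assign_tagma()` maps stripe counts to axial regions (3–6 thoracic
pre-molt, 7–11 thoracic post-molt, 12–13 genital, 14–17 abdominal;
outside that range the record is flagged and excluded from tagma
analyses with a warning). `pca_morphometrics()` standardizes the eight
measures and eigendecomposes their correlation matrix
(`stats::prcomp`), with each component's largest-magnitude loading made
positive for sign stability. Group separation uses a **permutation**
pseudo-F over PC1–PC3 (`tagma_separation()`) rather than a parametric
MANOVA: the generator's output gives no grounds for the parametric
distributional assumptions, and the permutation test is exact under label
exchangeability, with `p = (1 + #(perm ≥ obs)) / (1 + n_permutations)`.
Reproducing the published real-data magnitudes (PCA variance percentages,
MANOVA F, adjusted R²) requires the authors' deposited measurement data
and is an optional external validation, deliberately outside the test
suite. `regress_pc1_on_group()` codes tagmata 1–4 in axial order (the
original coding is unstated; an ordered integer coding is the simplest
monotone choice), and `tagma_group_compare()` is Tukey's HSD via
`stats::TukeyHSD` (studentized-range distribution).

## Problem sizes and numerical choices

The test suite and acceptance script run the default cohort design (25
larvae per hourly timepoint, 0–18 h) for rate estimation, 100 seeds for
the rate-recovery distribution, 50 seeds of pooled hatchling fields for
orientation/mitotic-fraction recovery, 20 seeds for domain-boundary
recovery, and 200 shuffled-label simulations at 99 permutations for the
group-test size check — sizes chosen so every Monte-Carlo band
(3 standard errors) is decisively wider than the generator's sampling
noise while the whole suite stays quick on a laptop. Measured-cohort
fixtures use 8 larvae per timepoint; the statistics are insensitive to
this choice beyond standard-error scaling.

Degenerate inputs are handled explicitly rather than by convention:
negative ages, invalid probabilities, empty timepoint lists and empty
paths raise typed errors; empty regions yield `NA` fractions; a missing
synchronous band yields an `absent` flag from `ph3_band_exclusion()`;
constant measure columns make the PCA stop with the offending column
named (and `run_pipeline()` records, rather than propagates, that
degeneracy, since it is the expected outcome in constant-GZ mode where GZ
length has zero variance).

## Known limitations

Synthetic body-length growth underestimates real growth (no
post-specification segment expansion), so absolute body-length
percent-change values from the generator are not comparable to published
ones — the worked percent-change numbers in the README use the published
endpoint values as direct inputs instead. Stripe-count observation noise
is symmetric and single-stripe; real mis-scoring may be asymmetric.
Domain detection assumes a single synchronous band; fields with multiple
high-S regions keep only the first for band-specific statistics. The
permutation pseudo-F tests location differences over the first three
components and is not sensitive to pure dispersion differences.
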