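# gzmorph

Quantitative analysis of posterior elongation in sequentially segmenting
arthropod larvae, built around the anostracan crustacean (fairy shrimp)
case: larvae hatch with three specified trunk segments and add the rest,
one at a time, from a posterior **growth zone** (GZ). Whether that region
truly *grows* — or merely patterns segments while the tissue budget is
paid elsewhere — is a measurement question. `gzmorph` answers it with a
tested pipeline covering:

* a **synthetic staged-larva generator**: 2D ventral nucleus fields on a
  jittered lattice with Engrailed (En) stripe, S-phase (EdU-like) and
  M-phase (Hoechst / phospho-histone H3) labels, plus staged cohorts with
  hatch-time jitter and stripe-scoring noise;
* **morphometry**: the eight standard measures (body length, GZ length,
  GZ widths A and B, trunk area, last-segment area, GZ area, last-segment
  length) and their cell-count analogues, with the stripe-completeness
  scoring rule;
* **cell-cycle dynamics**: mitotic indices per region and marker, spindle
  orientation classification (AP iff angle < 45°, tie to AP), sliding-
  window S-phase domain detection (synchronous band / clear / scattered),
  pH3 exclusion from the band, and boundary concordance with posterior
  *Wnt*/*caudal* expression territories;
* the **division budget**: GZ cell-field area by the trapezoid rule
  `L × (wA + wB)/2`, per-segment new-cell areas `l × wA`, and the average
  doublings required of the initial pool, `d = log2(N/G0)` under the
  default depletion lineage model (a persistence variant
  `d = log2(1 + N/G0)` is available);
* **cohort statistics**: segment-addition rate by OLS, tagma assignment
  (En 3–6 / 7–11 / 12–13 / 14–17), PCA of the eight standardized
  measures, a permutation pseudo-F test of tagma separation, PC1-on-tagma
  regression, and Tukey HSD group comparisons.

## Worked example

```r
library(gzmorph)

# one larva, 2 h post hatch
f <- generate_larva(2, gz_config(), seed = 1)
f
#> <cell_field> 1656 nuclei, 4 En stripes, stage 2.00 h, seed 1
#>   regions: growth_zone=300, segmented=1196, telson=160

measure_larva(f)[c("gz_length_cells", "gz_area_mm2", "mitoses_gz_hoechst")]
#>   gz_length_cells gz_area_mm2 mitoses_gz_hoechst
#> 1              12      0.0108                  8

detect_edu_domains(f)
#> <edu_domain_profile> window 12.0 um, span 282.0-384.0 um
#>             class x_start x_end
#>  synchronous_band   282.0 316.5
#>             clear   316.5 343.5
#>         scattered   343.5 384.0
```

The domain profile is the tri-domain S-phase signature: every cell of the
newest segment in S phase (the synchronous band), an anterior growth zone
almost devoid of S phase, and scattered cycling in the posterior growth
zone.

```r
# division budget on the canonical hatchling fixture:
# G0 = 13 x (22+28)/2 = 325 cells; 14 added segments, width 22 cells,
# lengths 5x4 + 4x3 + 5x2
division_budget(gz_cell_area(13, 22, 28), c(rep(4, 5), rep(3, 4), rep(2, 5)) * 22)
#> <division_budget> G0 = 325 cells; 14 segments totalling 924 new cells
#>   divisions required (depletion model): 1.51

# segment-addition rate from a noisy staged cohort
coh <- generate_cohort(gz_config(), 25, 0:18, seed = 0, measure = FALSE)
segment_addition_rate(coh)
#> <rate_fit> 0.703 segments/h (SE 0.0073), intercept 2.68, R2 0.952, n = 475
#>   implied interval: 1.42 h per segment
```

So the initial growth-zone pool needs only ~1.5 average doublings to
supply all 14 segments' worth of new tissue — consistent with the low
(1–4%) mitotic fraction the generator places in the GZ — and a staged
cohort of 475 noisy larvae recovers the segment-addition rate of 0.7
segments/h (1.4 h per segment). Worked percentage bookkeeping uses the
published endpoint values directly, e.g.
`report_about(percent_change(0.41, 0.98))` → `140` (percent body-length
increase) and `report_about(area_bookkeeping(0.0118, rep(0.029/14, 14))$fraction_pct)`
→ `40` (initial GZ area as a percentage of all new-segment area).

`run_pipeline(config, seed)` chains cohort simulation, measurement,
dynamics, budget and statistics into a single `analysis_report`
(serialized by `write_report()` as JSON + CSV), and
`inst/cli/gzmorph.R` exposes `simulate`, `measure`, `dynamics`, `budget`,
`analyze` and `report` subcommands over files.

## Package layout

* `R/config.R` — generator configuration, validation, YAML IO, seed
  derivation
* `R/generate.R` — stage clock, larva and cohort generators, expression
  truth
* `R/geometry.R`, `R/morphometry.R` — shoelace areas, corridor cell
  counts, stripe scoring, the eight measures
* `R/dynamics.R` — mitosis, orientation, EdU domains, concordance
* `R/budget.R` — division-budget model and bookkeeping
* `R/stats.R` — rate fit, tagma statistics, PCA, permutation test
* `R/io.R`, `R/pipeline.R` — cell-field CSV/JSON IO, end-to-end pipeline
  and report
* `vignettes/growth-zone-morphometrics.Rmd` — model assumptions,
  parameter rationale, numerical choices, limitations
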