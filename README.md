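# optophos

Downstream analysis of optogenetic phosphoproteomic time courses, with a
mechanistic synthetic-data generator for verifying every stage against
planted ground truth.

## The problem

Optogenetic constructs let a kinase such as Akt1 be switched on with light:
illumination recruits the kinase to the plasma membrane, where it is
activated; darkness lets phosphatases reverse the signal within minutes. By
crossing light **intensity** (three levels: `005`, `010`, `025`),
**pattern** (sustained `Su`, periodic `Pe` with 5-min on/off cycles, pulsed
`Pu` with a single 5-min exposure) and **duration** (10/20/30 min sampling),
a DIA-MS phosphoproteomics experiment can ask how tens of thousands of
phosphosites decode the strength, stability and duration of a kinase signal.

`optophos` implements the statistical pipeline such a study needs, for
anyone analysing a phosphosite quantification matrix (sites x samples, log2
intensities) with a factorial stimulation design:

* **Trait attribution** — per-site OLS F-tests with one of
  intensity/pattern/duration as the major factor and the other two as
  covariates (`anova_traits()`).
* **Intensity contrasts** — paired t-tests across intensity groups over the
  nine matched (pattern, time) cells, fold-change gating, and hierarchical
  clustering of regulated profiles (`paired_intensity_tests()`,
  `intensity_regulated_sites()`, `cluster_intensity_profiles()`).
* **Temporal classes** — an activation filter (>1.5-fold versus dark at
  every periodic timepoint) followed by fuzzy c-means clustering of
  first-timepoint-normalised profiles (`akt_activated_sites()`,
  `normalize_profiles()`, `fuzzy_cmeans()`, `assign_clusters()`).
* **Sequence and kinase enrichment** — positional motif matching on ±7
  flanks (strict basophilic motif `R-x-R-x-x-S/T`, generic `R-x-x-S/T`,
  MAPK and CK2 motifs) and one-sided Fisher enrichment with the standard
  gates EF > 1, ≥ 4 sites, p < 0.05 (`match_motif()`, `motif_enrichment()`,
  `kinase_site_enrichment()`).
* **Covariation discovery** — Pearson correlation of every site's
  condition-level profile to a reference activation site (the pT308
  analogue), thresholded at R > 0.85, benchmarked against candidate
  substrate lists with rank-sum tests and mutual-support arithmetic
  (`correlate_to_reference()`, `benchmark_lists()`, `mutual_support()`).
* **Two-series time-course testing** — per-site quadratic time polynomial
  with a series indicator, F-test of all series-difference terms, BH
  adjustment, an R² ≥ 0.8 gate and k-means partitioning of the fitted
  difference curves (`fit_two_series()`, `partition_profiles()`).

## The kinetic model behind the generator

The simulator (`simulate_phospho_experiment()`) drives everything from a
first-order activation balance for the light-controlled kinase,

```
dA/dt = a(I) L(t) (1 - A) - d A,        A(0) = 0,
```

with `L(t)` the on/off illumination indicator. On piecewise-constant light
this has the exact solution used throughout: on-segments relax towards
`A* = a/(a+d)` at rate `a + d`, off-segments decay at `d = 0.16 /min`
(so 5 min of darkness retains `exp(-0.8) ≈ 45%` of the signal). The three
activation rates are calibrated so the sustained steady states stand in the
ratios 1 : 3.4 : 7.1 with the top level at `A* = 0.85`
(`calibrate_intensity_rates()`).

Downstream sites belong to planted classes (`substrate_classes()`) coupled
to `A(t)` through `dS/dt = k_s A (1 - S) - k_d S`: rapidly tracking
(`direct_fast`), delayed (`direct_slow`), persistent, cascade-integrating
(`integrator`), suppressed, and unresponsive (`null`) sites. Measurements
are `log2(baseline · (1 + β S)) + ε` with i.i.d. Gaussian log2 noise and
missing-completely-at-random dropout; flanking sequences, kinase
annotations and benchmark-list memberships are planted per class. See the
methods vignette (`vignettes/optophos-methods.Rmd`) for every parameter and
its rationale.

## Worked example

```r
library(optophos)
res <- run_pipeline(pipeline_config(), seed = 1)
res$summary
```

```
   stage       metric                        value
 1 input       n_sites                      501
 2 input       n_samples                     62
 3 anova       duration_significant          49
 4 anova       intensity_significant        283
 5 anova       pattern_significant          230
 6 intensity   n_regulated                  248
 ...
12 fcm         n_activated                  255
17 enrich      fC1_strict_motif_pct           1.64
20 enrich      fC4_strict_motif_pct          20.9
22 covariation core_set_size                143
23 timecourse  n_significant                 20
```

Reading the funnel: of 501 simulated sites across 62 samples (27 light
conditions + dark control + a growth-factor-like series, duplicates), 283
are significantly associated with stimulation *intensity* but only 49 with
*duration* — intensity dominates, as expected when most responsive sites
equilibrate within the first sampling interval. 248 sites clear the paired
intensity gate, 255 the periodic activation filter; fuzzy c-means splits the
activated sites into four temporal classes, and the cluster dominated by
direct substrates carries the strict `R-x-R-x-x-S/T` motif at ~21% versus
~2% in the fastest-decaying bystander cluster. 143 sites covary with the
reference activation site at R > 0.85 — the candidate direct-substrate set —
and 20 sites differ significantly between the sustained-light and
growth-factor series.

Because the generator plants ground truth, every one of these numbers is
checkable: `res$truth` holds each site's class, motif status and planted
kinase.

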