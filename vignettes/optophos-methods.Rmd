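---
title: "Models and methods behind optophos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind optophos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optophos)
```

This vignette is the package's own account of its models: what is assumed,
which parameters matter, why each default has the value it has, and what
the tests do and do not demonstrate.

## 1. The activation model

Light-controlled kinase activation is modelled as a two-state first-order
balance between recruitment-driven phosphorylation and constitutive
dephosphorylation:

$$\frac{dA}{dt} = a(I)\,L(t)\,(1 - A) \;-\; d\,A, \qquad A(0) = 0,$$

where $A \in [0,1]$ is the fraction of activated kinase, $L(t) \in \{0,1\}$
the illumination indicator and $I$ the intensity level. The assumptions are
deliberately minimal: recruitment saturates (the $1-A$ factor), turn-off is
first order, and there is no adaptation, depletion or spatial structure.
Three observations pin the model down:

* activation is essentially complete within ~5 min of continuous light —
  satisfied because $a + d \gtrsim 1\,\mathrm{min}^{-1}$ at the top
  intensity;
* ~40–50% of the signal survives 5 min of darkness — this fixes
  $d = 0.16\,\mathrm{min}^{-1}$, since $e^{-5d} \approx 0.45$;
* sustained steady states across the three intensities stand in the ratios
  $1 : 3.4 : 7.1$ — with the top steady state set to $A^{*} = 0.85$,
  `calibrate_intensity_rates()` solves $A^{*}(I) = a/(a+d)$ for
  $a \approx (0.022, 0.110, 0.907)\,\mathrm{min}^{-1}$.

Dose–response is a per-level lookup, not a fitted Hill curve: only three
intensities ever occur, so a parametric light-to-rate curve would add
parameters without adding testability.

On piecewise-constant light the model is piecewise exponential and
`pakt_activity()` evaluates it in closed form; `pakt_activity_rk4()` is an
independent fixed-step RK4 discretisation kept solely as a cross-check (the
test suite requires agreement below $10^{-6}$ at step $10^{-3}$ min on all
27 schedules).

## 2. Substrate classes

Downstream phosphosites couple to $A(t)$ through

$$\frac{dS}{dt} = k_s\,A(t)\,(1 - S) - k_d\,S,$$

integrated by RK4 on a 0.01-min grid because $A(t)$ is time-varying. The
planted classes in `substrate_classes()` differ only in rates and
amplitude:

| class | $k_s$ | $k_d$ | $\beta$ | role |
|---|---|---|---|---|
| `direct_fast` | 0.9 | 0.60 | 20 | tracks $A$ closely, decays within minutes of a pulse |
| `direct_slow` | 0.4 | 0.12 | 16 | delayed rise and decay (half-life ≈ 6 min) |
| `persistent`  | 0.8 | 0.02 | 8  | switches on fast, barely decays within 30 min |
| `integrator`  | 0.03 | 0   | 8  | accumulates through a persistent intermediate |
| `suppressed`  | 0.5 | 0.05 | −0.85 | loses signal as activation accumulates |
| `null`        | 0   | 0    | 0  | unresponsive background |

Two modelling notes. The **integrator** is a two-step cascade: a persistent
intermediate $P$ (rates 0.8/0.02) feeds $dS/dt = k_s P$, capped at 1. A
plain integrator of $A(t)$ would plateau as soon as a light pulse ends and
become indistinguishable from the persistent class under pulsed light; the
cascade keeps the class rising across the whole 30-min window, which is the
defining "graded accumulation" phenotype. The **suppressed** class uses the
standard kinetics but a negative amplitude, so occupancy stays in $[0,1]$
while the measured abundance falls (up to ~1.8 log2 units); amplitudes must
satisfy $\beta > -1$ for positivity of the abundance model.

Rates and amplitudes were chosen once, at design time, so that the classes
express their intended phenomenology under the study conditions: direct
substrates clear the 1.5-fold gates and covary with the reference site,
suppressed sites pass the two-sided fold gate downward, and the four
temporal classes are mutually distinguishable in pulsed-regime profiles.
They were not revisited afterwards.

## 3. The measurement model

A site $i$ in condition $c$ is observed as

$$y_{ic} = b_i + \log_2\!\bigl(1 + \beta_i S_{ic}\bigr) + \varepsilon_{ic},
\qquad \varepsilon_{ic} \sim \mathcal N(0, \sigma^2),$$

with per-site baselines $b_i \sim \mathcal N(20, 1.3^2)$ (log2 scale),
i.i.d. additive noise and missing values inserted completely at random
(default rate 0.03; the reference site is exempt, matching its complete
quantification in practice). Replicate agreement is an emergent quantity:
the correlation between replicate columns across sites is (shared
between-site variance)/(shared + noise). With the default
$\sigma = 0.44$ log2 units the mean cross-replicate Pearson correlation
lands at ≈ 0.94, the reproducibility level of a good phosphoproteomics-DIA
replicate pair; $\sigma$ was tuned by simulation to hit that anchor and
then frozen.

The optional growth-factor-like series drives the kinase at an intermediate
sustained level ($A^{*} = 0.63$, between the `010` and `025` steady states)
and adds an independent second-pathway activity $E(t)$ (rates 0.3/0.1). A
random 25% of sites respond to the second pathway with a log2 shift
$\gamma\,E(t)$, $|\gamma| \in [0.5, 2]$, signs balanced — the minimal
structure needed for "common versus pathway-preferring" sites to exist.

**What the generator does not emulate:** between-run normalisation drift,
intensity-dependent missingness, peptide-level quantification artefacts
(shared peptides, localisation ambiguity), correlated noise between sites
on the same protein, and any proteome-level change. Passing recovery tests
therefore demonstrates that the statistics do what they claim under clean
factorial conditions — not that they are robust to every real-data
pathology.

## 4. Statistical stages and their conventions

**Trait ANOVA.** Per site, OLS with main effects of intensity, pattern and
duration on the 54 replicate-level light observations; the major-trait F is
the nested full-vs-reduced comparison, $p$ two-sided and unadjusted
($\alpha = 0.01$). Plain OLS is used rather than moderated (empirical
Bayes) statistics — a deliberate simplification: with 54 observations per
site, variance moderation changes little, and the plain fit keeps the
module free of heavy dependencies. Interactions are excluded by design;
covariate adjustment is the point of the procedure. Factors with a single
observed level are dropped from the model (so the no-covariate limit *is*
one-way ANOVA, a tested identity); a site missing observations in more than
20% of conditions is skipped and reported — the matrix rule is ours, as no
standard exists.

**Paired intensity contrasts.** The nine (pattern, time) cells are exactly
matched across intensity groups, so contrasts are paired t-tests on
condition means (df = 8). The gate is read as: $p < 0.01$ in **both**
`010vs005` and `025vs005` (the two comparisons that also carry the
1.5-fold gates), with `025vs010` reported but ungated; a stricter
`all-three` variant is available (`gate = "all-three"`) because the
published phrasing is ambiguous. The fold gate is two-sided so that
dephosphorylated sites pass. A zero-spread difference vector is guarded
with $\epsilon = 10^{-8}$ on the standard deviation: an exactly constant
non-zero shift yields $p \to 0$, an all-zero difference yields $p = 1$.

**Hierarchical clustering.** Row-centred profiles, correlation distance
$1 - r$, average linkage, cut at $k = 5$ — shape-based clustering matching
how heatmaps of such profiles are read. `hclust` merges equal-height pairs
by lowest index, so results are deterministic given input order.

**Activation filter and fuzzy c-means.** The filter requires fold > 1.5
versus dark at *all three* timepoints of the periodic high-intensity group
(all-of semantics; any missing timepoint excludes the site).
"Normalisation to timepoint 1" is implemented as shift-to-first-timepoint
followed by per-row standardisation (population SD, denominator $n$); both
steps are explicit, and zero-variance rows are dropped and reported. The
clusterer is Bezdek alternating optimisation with Euclidean distances,
fuzzifier $m = 1.25$ (the conventional setting for standardised temporal
profiles), convergence on $\max|\Delta U| < 10^{-6}$, exact-zero distances
assigning membership 1, and — because FCM is initialisation-sensitive —
ten seeded random restarts keeping the best objective. The objective is
asserted non-increasing at every iteration. For the cross-regime
12-cluster analysis the feature vector concatenates the three regimes'
time series at one intensity.

**Enrichment.** Motifs are positional constraint sets on the ±7 window;
the padding character `_` never satisfies a constraint. The enrichment
universe is the measured phosphoproteome (all quantified sites), not a
proteome-wide model — the comparison of interest is against "the entire
dataset". Fisher tests are one-sided (enrichment direction), computed as
hypergeometric upper tails, with the gate EF > 1, ≥ 4 annotated sites in
the group, $p < 0.05$; a kinase passing in several clusters is assigned
its predominant cluster by lowest $p$.

**Covariation.** Pearson correlation on condition means (replicates
averaged) across *all* conditions including the growth-factor series,
pairwise-complete over missing cells with a minimum of 10 complete pairs
(the missing-value policy is ours; the threshold R > 0.85 is a config
default, not hard-coded). A replicate-level switch is unnecessary because
`condition_means()` is the only aggregation step and callers may pass any
column set.

**Two-series time course.** Per site,
$y = \beta_0 + \beta_1 t + \beta_2 t^2 + z(\gamma_0 + \gamma_1 t + \gamma_2 t^2)$
with $z$ the series indicator, an F-test of $\gamma = 0$, BH adjustment
across sites, and the gates $q < 0.05$, $R^2 \ge 0.8$, $K = 4$ clusters on
the fitted difference curves. This replaces a stepwise-selection procedure
with a single nested F-test — a documented simplification that preserves
the published gates. Degree 2 is the natural choice for four timepoints.
The dark control supplies the 0-min observations and is carried by the
reference series only; the second series' 0-min level is identified
through its polynomial. The alternative — duplicating the dark samples
into both series — reuses observations and makes the null F statistic
anticonservative, which the type-I tests would catch. Partitioning uses
the fitted difference curves (not raw data), seeded k-means with ten
restarts; with exactly $K$ significant sites the partition is forced to
one site per cluster.

## 5. Numerical choices and degenerate inputs

* RK4 steps: $10^{-3}$ min for the kinetics cross-check, 0.01 min for
  substrate occupancies (both far below the fastest timescale,
  $1/(a+d) \approx 0.9$ min).
* Constant sites in any F-test: residual and attributable sums of squares
  below $10^{-12}n$ report $F = 0$, $p = 1$ rather than 0/0.
* FCM ties in hard assignment resolve to the lowest cluster index;
  `max.col(ties.method = "first")`.
* Correlation of zero-variance profiles is undefined; such rows carry no
  shape information and are treated as distance-neutral in hierarchical
  clustering and dropped in normalisation.
* All randomness flows from one seeded generator per entry point, in a
  documented draw order (classes, baselines, flanks, annotations,
  growth-factor responsiveness, noise, missingness); pipeline stages that
  need their own seeds derive them as fixed offsets of the run seed.

## 6. Problem sizes used by the tests

The default study is 501 sites × 62 samples (27 light conditions + dark +
three growth-factor timepoints, duplicates) — small enough that the full
pipeline runs in seconds while every class keeps enough members for rate
estimates. Type-I checks use 10,000 pure-noise sites; motif-fraction
checks use 5,000-site classes (binomial SE ≈ 0.5% at 16%); recovery and
sensitivity checks average over 5–20 generator seeds. These sizes are the
package's choices for stable Monte-Carlo estimates at interactive
runtimes.

## 7. Known limitations

* The kinetic model is deterministic and population-level; single-cell
  stochasticity, phototoxicity and spatial (membrane/cytosol/nucleus)
  structure are out of scope.
* Substrate classes are caricatures: real sites mix kinetics continuously,
  and class recovery rates on simulated data bound what clustering can do
  under the model, not on real data.
* The trait ANOVA treats replicates as independent observations (no block
  effect); with duplicates and balanced designs the effect on F is minor,
  but it is a convention, not a theorem.
* Motif matching is exact and positional; it does not model degenerate
  specificities or score matrices.
* The two-series test is a fixed-degree polynomial contrast; it will miss
  differences orthogonal to the quadratic basis and is not a reimplementation
  of stepwise time-course selection procedures.
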