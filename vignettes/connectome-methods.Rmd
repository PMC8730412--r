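---
title: "Methods: neonatal connectome analysis with neonconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neonatal connectome analysis with neonconn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neonconn)
```

## The problem

Hypoxic-ischemic encephalopathy (HIE) and critical congenital heart
disease (CHD) injure the term neonatal brain through very different
mechanisms and on very different timescales: an acute or subacute
peripartum insult in HIE, versus chronically reduced fetal oxygen
delivery across the third trimester in CHD. `neonconn` implements an
analysis workflow for comparing the structural brain networks of two
such cohorts and relating network organization to toddler
neurodevelopmental outcomes (Bayley-III composite scores, population
mean 100, SD 15; expressive/receptive subscores, mean 10, SD 3).

The central object is the **connectome**: a symmetric 90 x 90 matrix over
a bilateral infant parcellation (AAL-style descriptive names, 45 regions
per hemisphere), with each off-diagonal entry the mean fractional
anisotropy (FA, dimensionless, in [0, 1]) along the tractography
streamlines connecting the two regions, and 0 meaning no observed
connection. Tractography itself, registration and motion rejection are
upstream of this package: input is either a dense labelled CSV matrix or
a streamline summary table (`roi_i`, `roi_j`, `fa`), averaged by
`build_connectome()` with an unweighted arithmetic mean per unordered
region pair.

## Graph metrics

Four whole-brain metrics are computed on the weighted, undirected graph
(`metric_set()`):

* **Global efficiency** — the mean over unordered node pairs of the
  inverse shortest-path distance. Edge length is `1/weight` (higher FA
  means a stronger, "shorter" connection); disconnected pairs contribute
  zero. This is the harmonic-mean convention: it keeps the metric finite
  on fragmented graphs.
* **Weighted transitivity** — weights are scaled by their maximum, each
  triangle contributes the geometric mean of its three scaled weights,
  and the summed triangle intensity at each node is divided by
  `sum(k(k-1))` over binary degrees `k`. This is the standard weighted
  generalization of the triangle/triple ratio.
* **Modularity** — Newman weighted modularity `Q` of the best partition
  found by Louvain greedy optimization, 20 randomized restarts, maximum
  `Q` kept, deterministic given a seed. Resolution defaults to 1. Each
  restart randomizes vertex order (Louvain's passes are order-dependent)
  and refines both the Louvain output and a random initial partition
  with single-node moves until no move improves `Q` — plain
  agglomeration can never split a community and measurably underestimates
  `Q` on weakly structured graphs.
* **Small-worldness** — `sigma = (C/C_null) / (L/L_null)`, with `C` the
  weighted transitivity and `L` the characteristic path length (mean
  finite shortest-path distance). Null statistics are means over
  Erdos-Renyi G(n, m) graphs with the observed node and edge counts and
  the observed weight multiset permuted onto random edges. We follow the
  "same number of nodes and connections" null rather than
  degree-preserving rewiring because the whole-network edge count, not
  the degree sequence, is the quantity held fixed in the comparison this
  reproduces; a degree-preserving null would additionally condition on
  hub structure, which is part of what small-worldness is meant to
  detect. Values above 1 indicate clustering in excess of a comparably
  dense random network.

Metrics are natural-log-transformed before regression
(`log_metrics()`); only monotonicity matters for the linear models, so
the base is a free choice.

Numerical choices: path lengths use exact Dijkstra; unreachable pairs
are excluded from `L` but contribute zero to efficiency; Louvain ties
are resolved by keeping the first maximal-`Q` restart, making results
reproducible; the permutation of null-model weights uses a sorted
canonical weight order so all metrics are invariant to node relabeling
at a fixed seed.

## Language tracts

Five left-hemisphere association pathways implicated in language are
encoded as explicit region-pair sets on the parcellation: SLF 1 (3
pairs), SLF 2 (2), SLF 3 (7), ILF (12) and arcuate (6 = 2 temporal x 3
frontal targets). `tract_connectivity()` aggregates the FA weights of
the listed pairs. The default aggregation is the **mean** for all five
tracts, even though one tradition reports "total FA" for the ILF: the
mean is comparable across tracts of different pair counts, and the sum
is exposed as an option (`aggregation = "sum"`). Absent edges count as
zeros rather than being dropped — a missing connection is informative
hypoconnectivity, and dropping it would inflate the mean. Whether the
arcuate's temporal origin includes the temporal poles is anatomically
ambiguous; we restrict it to the superior and middle temporal gyri.

## Edge-wise group comparison

`edgewise_compare()` tests every included edge for a cohort difference,
adjusted for corrected gestational age at MRI:

1. **Inclusion**: an edge enters the analysis only if nonzero in at
   least 50% of subjects *within each* cohort (threshold configurable).
   This avoids testing edges dominated by absence.
2. **Statistic**: OLS of edge weight on group + covariates; the group
   coefficient's t value, sign-oriented so positive means the first
   group is stronger.
3. **Permutation**: the Freedman-Lane scheme — residuals of the
   covariate-only model are permuted (5000 times by default) with group
   labels fixed, preserving exchangeability under covariate adjustment.
   Two-sided p-values use the add-one convention
   `p = (1 + #{|t*| >= |t|}) / (1 + n_perm)`, so `p >= 1/(n_perm+1)`.
4. **Link-based FDR**: Benjamini-Hochberg step-up at `alpha = 0.05`
   across all included edges; selected edges are split by sign into
   hypoconnected-in-A versus hypoconnected-in-B, and region involvement
   counts incident significant edges (ties broken in atlas order).

A resolution caveat worth stating explicitly: with the add-one
convention, BH can only ever select `k` edges if
`1/(n_perm+1) <= alpha * k / m`. At `m ~ 1400` included edges and
`alpha = 0.05`, detecting a set of 18 edges requires
`n_perm + 1 >= m / (alpha * 18) ~ 1556`. Permutation counts in the few
hundreds are therefore structurally unable to yield discoveries at this
scale regardless of effect size — which is why the default follows the
5000-permutation convention, and why our calibration experiments (which
only need the null distribution) may use fewer.

## The synthetic cohort generator

No subject-level data are distributable, so `simulate_cohort()`
generates cohorts with the statistical structure the analysis assumes,
plus ground truth for recovery testing. Defaults
(`default_scenario()`): 60 HIE and 35 CHD subjects; male fractions
0.517 and 0.80; gestational age at birth 39.9 vs 39.1 weeks (SD 1.0);
MRI at a lag of ~5 days (HIE) vs ~3.5 days (CHD, preoperative), chosen
to reproduce the observed one-week gap in age at scan; follow-up
42/60 and 14/35 at 12-18 months, 31/60 and 8/35 at 30 months.

Connectomes share one random sparsity template (density 0.35; edges
exist or not population-wide, so inclusion masks are well defined), with
the five language tracts and the planted edge set forced present —
major association pathways exist in every subject. Edge weights are

```
weight = edge mean + 0.005 * (GA_MRI - 40) + subject offset + noise
```

with population edge means ~ N(0.25, 0.05) (clamped to [0.05, 0.7]),
a per-subject global FA offset ~ N(0, 0.012) representing
inter-individual variability, maturation slope 0.005 FA/week, and
per-edge noise SD 0.03; weights are truncated to [0, 1] (truncation
rather than resampling preserves seed determinism).

The offset's scale deserves a note, because two requirements pull it in
opposite directions. Outcome-coefficient recovery needs inter-subject
variation in global efficiency that is not collinear with age at scan —
without a global offset the residual log-efficiency SD collapses to
~0.003 and no realistic cohort size can estimate a coefficient on it.
But a global offset is a rank-one nuisance shared by every edge: in an
edge-wise comparison, a cohort whose mean offsets happen to draw a few
SD apart shifts *all* ~1400 edge statistics together, and
Benjamini-Hochberg — whose step-up threshold rises as discoveries
accumulate — can then cascade, selecting hundreds of edges in a single
unlucky cohort even though expected FDP remains controlled under
positive dependence. At SD 0.012 a cascade requires roughly a 3.5-SD
draw of the cohort-offset gap (per-run probability on the order of
1e-3), while the coefficient-recovery experiment retains about a
2.5-SD margin on its 10% accuracy band. Larger offsets (e.g. 0.02)
measurably trigger such cascades; this rank-one sensitivity is a real
and underappreciated property of link-based FDR on connectome data. CHD subjects have
0.08 FA subtracted on a fixed set of 18 left occipito-temporal edges
spanning 22 regions (including the calcarine-to-middle-occipital
pathway); the full pathway list is an artifact choice guided by the
regions implicated in the source cohorts, since only a partial list is
printed there.

Outcomes are linear in the log global efficiency computed from each
generated connectome, cohort and sex, with noise SD 12 — chosen so
simulated score spreads resemble the published interquartile ranges
(a calibration choice, not a published value). Intercepts are
back-computed so HIE domain means sit at the published HIE medians given
a typical log global efficiency of about -1.69. The 30-month motor
domain carries the log-efficiency coefficient 43.7; cohort and sex
coefficients come from the published univariate tables. Expressive
language carries a planted SLF2 effect of -5.2 points per FA unit plus
a direct cohort effect of -3 points.

Two properties of the generator worth knowing when reading test
results:

* Because CHD subjects are scanned about a week earlier and FA matures,
  unadjusted tract-outcome regressions are **confounded**: the direct
  cohort effect on expressive language biases the marginal SLF2
  coefficient upward by roughly +5.3, nearly cancelling the planted
  -5.2. This mirrors real observational data. Direction-recovery tests
  therefore isolate the planted mechanism by zeroing the direct cohort
  effect in their scenario.
* The per-edge Gaussian model with a shared sparsity template is a
  stand-in: real FA distributions are right-skewed, edge presence varies
  across subjects, and noise is spatially correlated along tracts. A
  passing recovery test shows the statistics behave as designed under
  this structure; it does not certify performance on real tractography
  output.

## Outcome regression protocol

Cohort tables use rank-sum tests (exact enumeration when both groups
have at most 8 untied observations, normal approximation with tie
correction otherwise; interquartile ranges use the type-7 quantile
convention) and Fisher's exact test for 2 x 2 or sparse tables, Pearson
chi-squared otherwise. For each Bayley-III domain and timepoint, every
clinical factor and each log graph metric is screened by simple linear
regression; predictors with p < 0.1 enter multivariate models — one
model per metric, since the four metrics are mathematically
interdependent. Corrected gestational age at MRI is always included a
priori; gestational age at birth is always excluded as collinear with
it. Delivery pH, base deficit and Apgar scores are excluded from the
screens by default because they define HIE cohort entry; reference
levels are male sex, HIE cohort, white race and graduate-school maternal
education. Analyses are complete-case per model; no imputation.

## Problem sizes used in the test suite

Simulation-backed checks run at deliberately chosen sizes: metric
oracles on 100 graphs of up to 6 nodes and exhaustive modularity on up
to 8 nodes (4140 partitions); small-worldness calibration on 50 random
graphs of 60 nodes with 20 nulls each; edge-wise null calibration on 20
matched 30 + 30 cohorts at 500 permutations; planted-deficit recovery on
10 default cohorts at 5000 permutations; coefficient recovery on 100
cohorts of 200 subjects; direction recovery of the SLF2 effect on 10
scaled-up cohorts of 2000 subjects. These sizes give the binomial and
sampling margins the assertions rely on while keeping the suite
reasonably quick.

## Known limitations

* The streamline-count matrix is carried but unused by the metrics; no
  single-streamline filter is applied (none is defined upstream).
* Only cohort-level cross-sectional analysis is supported — no
  longitudinal modeling across the two outcome timepoints.
* Cost- or strength-controlled network comparisons and cluster-extent
  network statistics are out of scope; FDR control is link-based only.
* The generator makes no attempt at biophysical realism (see above);
  its role is statistical, not anatomical.
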