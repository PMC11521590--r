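---
title: "Clustering mixed-type clinical cohorts and stratifying pregnancy risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering mixed-type clinical cohorts and stratifying pregnancy risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Pregnancy in systemic lupus erythematosus (SLE) carries simultaneous
maternal risks (flares, preeclampsia, nephritis) and fetal risks
(miscarriage, stillbirth, preterm birth, low birth weight). Rather than
modelling single risk factors, `somrisk` groups whole patient records —
obstetric history, serology, routine laboratory labels, and clinical
manifestations — into clusters of similar patients and then reads the risk
off each cluster's observed perinatal outcomes. The package implements the
full pipeline for a cohort of 119 pregnant SLE patients whose per-cluster
summary statistics are built in as reference tables, plus a synthetic
cohort generator so that every stage is testable without patient-level
data (none are publicly available).

The pipeline is: **validate → impute → quantify categorical labels →
assemble features → normalize → batch SOM → two-level merge → profile →
tier → chart export**, with one seed governing all randomness.

## Quantifying categorical labels by co-occurrence

Clinical tables mix numeric attributes (age, disease duration, gestational
age, newborn weight, urinary protein, G/P/A/L counts) with categorical
ones (13 lab variables labelled low/normal/high; delivery type CS/FD/ND).
To cluster them jointly, each categorical label is converted to a number
through its co-occurrence with the 15 binary *base* manifestations
y1–y15 (gestational hypertension, oligohydramnios, preeclampsia, lupus
nephritis, …, "no manifestations"):

* `O(i,j)` counts the occurrences of nonbase label *i* in patients with
  manifestation *j*. The L/N/H labels are pooled across all 13 lab
  variables, so one patient contributes up to 13 occurrences of a label
  (the pooled totals are 13·n); delivery labels count once per patient.
* the similarity is the Jaccard-style ratio
  `S(i,j) = O(i,j) / (O(i) + O(j) − O(i,j))`;
* the quantified score of label *c* is
  `F(c) = Σ_j S(c,j) · ȳ_j`, where `ȳ_j` is the cohort prevalence of
  manifestation *j*.

Two conventions are ours, because the printed method leaves them open.
First, `ȳ_j` is read as the *prevalence* of the binary indicator — the
only cohort-level mean of y_j that exists. Second, a zero denominator
(a label and a manifestation that never occur) defines `S = 0`: no
evidence of association. `F(c)` then lies in `[0, Σ_j ȳ_j]`, and because
this cohort averages about one recorded manifestation per patient, that
upper bound is ≈ 1, i.e. the F scores live on the same unit scale as the
min-max-normalized numerics.

The within-group sum of squares `SSw` over the 9 numeric attributes and
its variance `Vw = SSw/(n − g)` (g = 9) are computed and logged as scale
diagnostics of the numeric block; they do not rescale features, since the
normalization below already equalizes ranges.

## Feature assembly and normalization

The default feature matrix has 23 columns: the 9 numeric attributes
(urinary protein entered in mg/dl via the dipstick map negative→0,
trace→5, 1+→30, 2+→100, 3+→300, 4+→1000) and the 14 categorical columns
with each label replaced by `F(label)`. A config switch drops the
outcome-adjacent columns (gestational age, newborn weight, delivery type)
for strictly pre-outcome clustering.

Normalization is deliberately two-tier (`normalize_features()`):

* **raw numeric columns** are min-max mapped to [0, 1] per column —
  their units (years, days, grams, mg/dl) are arbitrary and must not
  dominate distances;
* **quantified columns** are left on their common F scale. They are
  already commensurable by construction, and per-column min-max would
  stretch the few-distinct-value label columns (whose pooled L/N/H
  scores differ only in the third decimal) into full-range noise,
  drowning the numeric signal. The pure per-column map remains available
  as `minmax_normalize()`, which is idempotent and affine-invariant.

Constant columns map to 0 and are flagged rather than dropped, keeping
column counts stable. Mode imputation fills categorical gaps with the
variable's modal label (ties broken by the fixed order L < N < H, logged),
numeric gaps with the variable's observed mean; "each variable" is read
globally because clusters do not exist before imputation. Outlier
screening (median ± 3×IQR per numeric variable, zero-IQR guarded) is
flag-only by default since the original analysis does not state which
observations it removed.

## The batch SOM and two-level clustering

The self-organizing map is a 12 × 12 hexagonal lattice of 144 codebook
vectors ("miniclusters"), matching the published topology; the grid is
configurable (e.g. 5, 9, or 15 nodes reproduce the published architecture
comparison). Training is batch mode: per epoch each node is set to the
Gaussian-neighborhood-weighted mean of all data points,
`h = exp(−d_lattice² / 2σ²)`, with σ decaying linearly from
`max(rows, cols)/2` to 1 over 200 epochs. These schedule constants follow
standard SOM practice — the source names its toolbox but not its
schedule — and are all exposed in `som_grid()`. Nodes receiving zero
total weight keep their previous vector, which stabilizes the later
merge. Performance is the mean squared distance of patients to their
best-matching unit (BMU); ties in BMU lookup break to the lowest node
index for determinism.

Initialization is linear by default: the codebook spans the plane of the
top two principal components. With 144 nodes for 119 patients,
sampled-row initialization (available as `method = "sample"`) starts with
essentially zero quantization error, which makes "training improves the
map" meaningless; linear initialization is also the default of the
toolbox family the original analysis used.

The second level merges miniclusters into patient clusters
(`merge_nodes()`): hit-weighted Ward agglomeration of the non-empty
codebook vectors (squared Euclidean dissimilarities with hit counts as
member weights), zero-hit nodes inheriting the nearest non-empty node's
cluster so the whole lattice is colorable. A hit-weighted k-means on the
codebook is provided as an alternative strategy. The default k = 5
mirrors the published five clusters; `select_k()` offers a hit-weighted
Davies–Bouldin selection over k = 2..10 (ties to the smallest k) for the
"auto" path. Patients inherit their BMU's cluster, and clusters are
relabelled by decreasing size, so cluster 1 is always the largest.

## Profiles, risk tiers, chart export

`profile_clusters()` reproduces the published table layouts per cluster:
manifestation counts and percentages, numeric attributes as mean ± SD
(sample SD, n − 1; single-patient clusters report SD 0 with a degeneracy
flag), lab-label and delivery-type counts, and the perinatal summary
(live births + fetal losses = cluster size; term + preterm = live
births).

The published risk tiers are narrative; the package distils them into
explicit, config-exposed rules (`risk_thresholds()`), with precedence
high > low > moderate and the firing rule recorded per cluster:

* **high**: fetal-loss proportion ≥ 0.10, or mean 1-min Apgar < 7, or
  mean newborn weight < 1500 g;
* **low**: loss proportion < 0.10 and mean Apgar ≥ 9.8 and preterm
  proportion (among live births) ≤ 0.45;
* **moderate** otherwise.

On the built-in reference per-cluster statistics these rules tier
cluster 1 high, clusters 2–3 moderate, and clusters 4–5 low — the
published grouping. Percentages use two-decimal round-half-up for cohort
shares and truncation for the outcome percentages, matching the rounding
conventions the printed numbers imply; both modes are available in
`percent_of()`. The chart export (`export_chart_data()`) serializes the
tier blocks (red/yellow/green), manifestations ranked by pooled
frequency, per-tier perinatal expectations, and a patient → cluster →
tier placement record, so a patient's position can be compared across
visits.

## The synthetic cohort generator

`generate_cohort()` plants a five-cluster structure (sizes 33/27/16/19/24)
and draws, per cluster: numeric attributes from truncated normals
(disease duration ≥ 0; maternal age 18–45 y; gestational age 35–300 d,
the upper bound chosen so that truncation bias stays an order of
magnitude below sampling error at the tested scales); G/P/A/L rounded to
non-negative integers with gravid ≥ 1 and para ≤ gravid enforced by
resampling; lab labels, delivery types and dipstick grades from the
per-cluster count proportions of the reference tables; manifestations as
independent Bernoulli draws at the per-cluster reference frequencies; and
perinatal outcomes from the reference parameters, with all 21 fetal
losses in cluster 1 (the reference delivery-type table disagrees slightly
— 20/1/1/0/0 — and is available via `fetal_loss_source = "delivery"`).
Fetal losses receive Apgar 0 and a weight drawn from their cluster's
weight distribution, since the recorded values for losses are not stated.
`inject_missingness()` then masks the documented registry pattern:
dsDNA/ANA 5 patients each, APL 7, SSA/SSB 4 each.

What the generator does *not* emulate: within-patient correlation between
attributes given the cluster (draws are conditionally independent),
correlation between gestational age and the term/preterm flag,
longitudinal disease activity, and treatment effects. Passing tests
therefore demonstrate that the pipeline recovers structure of this
conditional-independence form — not that it would perform identically on
real registry data, where correlated severity patterns should, if
anything, sharpen cluster boundaries. A few reference count columns are
internally inconsistent in the source (one lab column sums to 26 in a
16-patient cluster); counts are used as proportions, so these typos
shift label frequencies only.

`sd_scale` multiplies every numeric SD (including newborn weight and
Apgar) and is the lever for recovery experiments: at `sd_scale = 0.25`
the planted clusters are sharply separated in most attributes. One honest
caveat from our own experiments: even at that separation, the urinary
protein grades (spanning 0–1000 mg/dl within the high-risk cluster), the
integer rounding of obstetric counts at means near 0.5, and the
near-identical disease-duration means leave the high-risk cluster with
more internal variance than the gap between the two low-risk clusters.
In a substantial fraction of seeds the partition with the lowest
within-cluster sum of squares *splits the high-risk cluster and merges
the two low-risk ones*, and any distance-based method — the SOM two-level
merge, direct Ward, k-means with many restarts — correctly finds that
optimum rather than the planted labels. Recovery quality is therefore
reported honestly by the acceptance script (adjusted Rand index per seed)
rather than guaranteed.

## Problem sizes and numerical choices

The test-suite and acceptance problem sizes are the study's natural ones:
cohorts of n = 119 (scale ×100 for parameter-recovery checks), 12 × 12
maps trained for 200 epochs, 20 seeded SOM runs, 10 seeded end-to-end
recovery runs, and 100 small-cohort (n ≤ 20) oracle recounts. Exact
oracles (co-occurrence recount, exhaustive two-partition Ward optimum on
≤ 10 nodes, two-pass SSw summation) are kept deliberately naive and
independent of the implementation paths they check.

Degenerate inputs are defined, not rejected: empty cohorts round-trip as
header-only CSV; constant features normalize to 0 with a flag; a 1 × 1
grid is a single centroid; all-equal codebooks give a zero U-matrix;
single-patient clusters profile with SD 0 and a flag. Determinism is
end-to-end: a pipeline run writes no timestamps, and a rerun with the
same configuration and seed is byte-identical.

## Limitations

Global mode/mean imputation biases label frequencies when missingness is
informative; the method produces cluster-level tiers, not per-patient
prospective predictions, and no disease-activity score (SLEDAI/BILAG)
can be derived from it. The tier thresholds are reverse-engineered from
the published cluster outcomes and should be re-calibrated before use on
any other cohort.
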