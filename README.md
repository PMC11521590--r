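# somrisk

Cluster analysis and pregnancy-outcome risk stratification for cohorts of
pregnant systemic lupus erythematosus (SLE) patients — or any clinical
cohort mixing numeric attributes with categorical laboratory labels.

Pregnancy in SLE combines maternal risks (flares, preeclampsia, lupus
nephritis) with fetal risks (miscarriage, stillbirth, preterm birth, low
birth weight). Instead of modelling individual risk factors, `somrisk`
groups whole patient records into clusters of similar patients with a
batch-trained self-organizing map (SOM) and reads the risk of each cluster
off its observed perinatal outcomes. The package is written for
biostatisticians and clinical data scientists who want the complete,
reproducible pipeline: mixed-type feature quantification, SOM clustering,
two-level minicluster merging, cluster profiling, and high/moderate/low
risk tiers with an exportable risk-assessment chart.

## The method in brief

Mixed-type records are made numeric by **co-occurrence quantification**.
With 15 binary base manifestations y1..y15 (preeclampsia, lupus
nephritis, PROM, ..., "no manifestations") and the nonbase labels
L/N/H (13 lab variables, pooled) and CS/FD/ND (delivery type):

    S(i, j) = O(i, j) / ( O(i) + O(j) − O(i, j) )        (Jaccard similarity)
    F(c)    = Σ_j  S(c, j) · ȳ_j                          (label score)

where `O(i, j)` counts co-occurrences, `O(i)`, `O(j)` are totals, and
`ȳ_j` is the prevalence of manifestation j. Every categorical cell is
replaced by `F(label)`, giving a 23-column numeric matrix (9 numeric
attributes + 14 quantified columns) that is min-max normalized
(`x' = (x − x_min)/(x_max − x_min)` per numeric column) and fed to a
12 × 12 hexagonal batch SOM (144 miniclusters, Gaussian neighborhood,
linearly decaying radius, 200 epochs). Miniclusters are merged into k = 5
patient clusters by hit-weighted Ward agglomeration of the codebook
vectors, and each cluster is tiered:

* **high** — fetal-loss proportion ≥ 0.10, or mean 1-min Apgar < 7, or
  mean newborn weight < 1500 g;
* **low** — no high trigger, mean Apgar ≥ 9.8, preterm proportion ≤ 0.45;
* **moderate** — otherwise.

A synthetic cohort generator reproduces the reference 119-patient cohort
(five clusters of 33/27/16/19/24 patients, per-cluster lab/delivery/
manifestation frequencies, perinatal outcomes, and the documented
missingness pattern), so the whole pipeline is testable end to end.

## Worked example

A seeded run on a sharpened synthetic cohort (numeric SDs scaled ×0.25 so
the planted structure is cleanly separated):

```r
library(somrisk)
res <- run_pipeline(pipeline_config(out_dir = "demo", seed = 11,
                    params = cohort_parameters(sd_scale = 0.25)))
#> [simulate] generated 119 patients
#> [validate] 0 warnings, 25 missing cells
#> [impute] 5 variables imputed
#> [quantify] F: L=0.0937 N=0.1014 H=0.0960 CS=0.0891 FD=0.0535 ND=0.0293
#> [features] SSw = 8.782e+07, Vw = 7.984e+05 (n=119, g=9)
#> [som] quantization error 0.033296 after 200 epochs
#> [merge] k = 5, cluster sizes 33/27/24/19/16

res$tiers[, c("cluster", "tier", "loss_prop", "apgar_mean", "weight_mean")]
#>   cluster     tier loss_prop apgar_mean weight_mean
#> 1       1     high 0.6363636   1.181818    947.6667
#> 2       2 moderate 0.0000000   9.555556   2785.8519
#> 3       3      low 0.0000000  10.000000   2989.0833
#> 4       4 moderate 0.0000000  10.000000   2768.2105
#> 5       5 moderate 0.0000000   9.812500   2423.7500

cluster_share(res$assignment$counts)
#> [1] 27.73 22.69 20.17 15.97 13.45
```

Reading the output: the pipeline recovered the five planted clusters
exactly (cluster 1 is the 33-patient high-risk group carrying all 21
fetal losses — 63.6 % loss rate, mean Apgar 1.2, mean weight 948 g — and
is tiered *high*; the remaining clusters have no losses and Apgar ≥ 9.5
and split between *low* and *moderate* on Apgar and preterm rates). The
quantified label scores `F` place fetal-death delivery (FD = 0.054) well
below cesarean (CS = 0.089), reflecting FD's weaker co-occurrence with
the common manifestations. `SSw`/`Vw` are the within-group
sum-of-squares diagnostics of the raw numeric block before
normalization. The run directory `demo/` contains the seven artifacts
(cohort, similarity table, features, SOM model, assignment, profiles,
chart) plus the effective config; rerunning with the same seed is
byte-identical.

On the built-in reference statistics of the original cohort, the tier
rules reproduce the published grouping — cluster 1 high, clusters 2–3
moderate, clusters 4–5 low:

```r
assign_risk_tiers(profiles_from_summary(reference_perinatal_summary()))$tier
#> [1] "high"     "moderate" "moderate" "low"      "low"
```

A thin shell wrapper is installed at
`inst/scripts/run-pipeline.R` (`Rscript run-pipeline.R --out DIR --seed N`).

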