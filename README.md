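# swnet

Graph-theory analysis of resting-state functional connectomes, built to
quantify treatment-related change in brain network topology and to test
whether pre-treatment network organization predicts later symptom
change. The motivating use case is longitudinal psychiatric imaging —
for example a cohort of adults with OCD scanned before and after an
intensive course of cognitive-behavioral therapy and followed up
clinically — but every stage takes generic node x time BOLD matrices and
a clinical table, so any two-session design with follow-up scores fits.

## What it computes

For each scan, nodes are brain regions and edges are **partial
correlations** between regional BOLD time series (conditioned on all
other nodes, via a shrinkage-regularized precision matrix; Pearson full
correlation is available as a mode). The weighted, undirected matrix is
thresholded proportionally across the small-world sparsity regime
`0.10 <= S <= 0.50`, and at each sparsity the package computes weighted
global metrics — mean clustering coefficient `C` (Onnela), characteristic
path length `L`, global and local efficiency, Louvain modularity `Q` —
plus node-level degree, clustering, local efficiency and (edge)
betweenness. Small-world attributes are normalized against 100
degree-preserving random networks:

```
gamma = C / <C_rand>,   lambda = L / <L_rand>,   sigma = gamma / lambda
```

with `sigma > 1` indicating small-world organization. Each metric's
curve over the sparsity grid is collapsed to its trapezoidal AUC, giving
one threshold-free number per subject, session and metric. Statistics
then follow the field's conventions: AUCs are residualized on DVARS
(head motion) before testing; pre/post change uses a paired t-test or an
exhaustive sign-flip permutation test depending on Shapiro–Wilk
normality of the differences; follow-up symptom worsening is regressed
on a pre-treatment metric AUC controlling for months to follow-up,
medication months, CBT sessions and pre-treatment DVARS (overall F on
(5, n-6) df, adjusted R²); Bonferroni (0.05/3 = 0.017, 0.05/6 = 0.0083,
0.05/12 = 0.004) and within-metric FDR (q = 0.0125) control multiple
comparisons.

Because subject-level fMRI of this kind is rarely shareable, the package
ships a first-class **synthetic cohort generator**: factor-model time
series with planted modular correlation structure (stronger within-module
correlation after treatment), motion spikes visible to DVARS, clinical
scores calibrated to treated-OCD distributions, and a planted linear
association between each subject's *realized* pre-treatment
small-worldness AUC and their follow-up symptom change. Every inference
stage is validated end-to-end against this generator and against
brute-force metric oracles.

## Worked example

```r
library(swnet)

spec <- cohort_spec(n_subjects = 17, effect_beta = 4,
                    post_within_r_delta = 0.05,
                    graph_grid = c(0.1, 0.3, 0.5), n_rand = 20, seed = 42)
cohort <- generate_cohort(spec)

cm  <- cohort_metrics(cohort, grid = c(0.1, 0.3, 0.5), n_rand = 20,
                      metrics = c("C", "sigma"), seed = 7)
adj <- residualize_on_motion(cm$auc, cm$dvars)

s    <- adj[adj$metric == "sigma", ]
pre  <- s$auc[s$session == "pre"][order(s$subject_id[s$session == "pre"])]
post <- s$auc[s$session == "post"][order(s$subject_id[s$session == "post"])]
paired_change_test(pre, post, seed = 1)
#> <stat_result> paired t: stat = 2.539, df = 16, p = 0.02189, mean difference = 0.004143 (n = 17)

clin <- cohort$clinical[order(cohort$clinical$subject_id), ]
fit_followup_regression(clin, pre, "smallworldness")
#> <followup_fit> delta-YBOCS ~ smallworldness + 4 covariates
#>   adjusted R^2 = 0.694, F(5,11) = 8.25, p = 0.001863 (n = 17)
#>   smallworldness coefficient = 400.3

round(classify_outcomes(clin)$rates, 1)
#>  response remission worsening
#>      52.9      52.9      41.2
```

Reading the output: small-worldness AUC rose significantly from pre to
post treatment (the generator planted a within-module correlation
increase); higher pre-treatment small-worldness predicts follow-up YBOCS
worsening with adjusted R² = 0.69 (the generator planted a 4-points-per-SD
effect with residual SD 3, i.e. a population R² of 0.64); and about half
the synthetic cohort meets the response/remission definitions while 41%
worsen by 5+ YBOCS points during follow-up.

`run_pipeline()` drives the same stages from a single YAML config with
checksummed, cacheable stage outputs and a reproducibility manifest; a
thin command-line wrapper lives at `inst/cli/swnet-cli.R`
(`simulate | preprocess | connectivity | metrics | stats | run`).

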