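---
title: "Small-world connectome analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-world connectome analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

swnet measures treatment-related change in the topology of resting-state
functional brain networks and asks whether pre-treatment network
organization predicts later symptom change. This vignette describes the
models and procedures the package implements, the parameters that matter,
and the choices made where the methodological literature leaves the
design open.

## The analysis model

Each scan session is summarized as a node x time matrix of BOLD signal
(regions of interest x volumes). The pipeline is:

1. **Temporal cleaning** — drop the first volumes (magnetization
   equilibrium), band-pass filter 0.009–0.08 Hz, regress out nuisance
   signals (six motion parameters, white matter, CSF, and their temporal
   derivatives), and compute DVARS, the root-mean-square volume-to-volume
   signal change used as a motion index.
2. **Connectivity** — all pairwise *partial* correlations between nodes,
   i.e. the correlation of each node pair conditioned on every other
   node, taken from the inverse of a shrinkage-regularized correlation
   matrix. Partial correlations suppress indirect paths and are less
   motion-sensitive than full correlations; a Pearson full-correlation
   mode is retained for sensitivity analyses.
3. **Graph construction** — proportional thresholding at sparsity `S`
   keeps the `round(S * n(n-1)/2)` strongest positive edges with their
   weights. The analysis sweeps the small-world regime
   `0.10 <= S <= 0.50` in steps of 0.05 (the regime boundary is
   conventional; the step is this package's choice).
4. **Graph metrics** — weighted mean clustering coefficient (Onnela
   geometric-mean-of-triangles, weights normalized by the network
   maximum), characteristic path length and global efficiency on edge
   lengths `1/weight`, mean local efficiency, and Louvain modularity
   `Q`. Clustering, path length and efficiency are normalized against
   100 degree-preserving random networks per sparsity:
   `gamma = C / <C_rand>`, `lambda = L / <L_rand>`, and small-worldness
   `sigma = gamma / lambda`.
5. **AUC aggregation** — each metric's curve over the sparsity grid is
   collapsed to its trapezoidal area under the curve (AUC), a
   threshold-free per-subject summary.
6. **Statistics** — AUCs are first residualized on scan-level DVARS
   (removing motion confounding), then compared pre vs post treatment
   with a paired t-test when the paired differences pass Shapiro–Wilk
   normality at alpha = 0.05, and with a two-sided sign-flip permutation
   test otherwise (exhaustive over all `2^n` sign patterns whenever
   `2^n <= 65536`, so always at small cohort sizes; Monte-Carlo with the
   add-one correction beyond that). Follow-up symptom change
   (`YBOCS_followup - YBOCS_post`; positive = worsening) is regressed on
   a pre-treatment metric AUC plus four covariates of no interest:
   months to follow-up, months of medication and CBT sessions during
   follow-up, and pre-treatment DVARS. The overall F has (5, n - 6)
   degrees of freedom and adjusted R^2 is
   `1 - (1 - R^2)(n - 1)/(n - p - 1)`. Bonferroni thresholds follow the
   instrument conventions (0.05/3 = 0.017 for the three independent
   global metrics, 0.05/6 = 0.0083 for secondary clinical predictors,
   0.05/12 = 0.004 for exploratory metric x instrument scans) and
   node-level tests control FDR within metric at q = 0.05/4 = 0.0125.

## Key parameters

| parameter | default | meaning |
|---|---|---|
| `low_hz`, `high_hz` | 0.009, 0.08 Hz | resting-state BOLD passband |
| `k_discard` | 2 volumes | pre-equilibrium discard |
| DVARS threshold | 25 (%) | scan exclusion flag on mean DVARS |
| `shrinkage` | `"auto"` | Schäfer–Strimmer analytic intensity toward the identity |
| sparsity grid | 0.10–0.50 by 0.05 | small-world regime |
| `n_rand` | 100 | null networks per sparsity |
| `n_swaps_per_edge` | 10 | double-edge-swap attempts per edge |
| Louvain `n_restarts` | 20 | randomized restarts, best Q kept |
| permutation `n_perm` | 10000 | Monte-Carlo size when not exhaustive |

With 160 nodes and roughly 208 usable volumes the sample correlation
matrix is close to singular, so conditioning on 158 nodes is not
feasible without regularization. The package defaults to analytic
Ledoit–Wolf/Schäfer–Strimmer shrinkage toward the identity because it is
deterministic, parameter-free and guarantees a well-conditioned inverse;
the intensity actually used is recorded on every connectivity matrix and
in the run manifest. A fixed intensity can be supplied instead. This
regularization choice is the package's own: pipelines differ here, and
partial-correlation magnitudes (hence thresholded topologies) depend on
it, which is one reason all group inference runs on within-study
contrasts rather than absolute metric values.

DVARS is computed, by default, on the raw post-discard series rather
than after filtering and nuisance regression: the conventional
percent-of-grand-mean-signal scale (and the 25% exclusion rule) is only
meaningful while the signal retains its baseline, which band-pass
filtering removes. `dvars_stage = "cleaned"` restores the alternative
order, falling back to raw units with a warning when the baseline is
gone. The package flags exclusions rather than silently dropping scans.

Other conventions: self-connections are exactly 0 so thresholding can
never select the diagonal; negative edges are discarded at thresholding
(rank by signed weight) because path metrics are undefined on negative
lengths, with magnitude ranking available; ties at the threshold cutoff
break by lexicographic node-pair order so runs are reproducible;
characteristic path length averages over connected pairs only (the
disconnected-pair count is reported) while global efficiency handles
disconnection natively via `1/Inf = 0`; null networks preserve the
degree sequence exactly (double edge swaps) and reassign the original
weight multiset in random order; nulls with zero clustering are dropped
from the clustering null mean and counted. Whether to null-normalize the
efficiency metrics is ambiguous in the literature, so gamma/lambda/sigma
always use nulls, a normalized global efficiency is also returned, and
normalized local efficiency is optional (it requires an induced-subgraph
sweep per null and is rarely reported).

## The synthetic cohort generator

No subject-level scan or clinical data are available to this package, so
`generate_cohort()` plants known structure and effects to make every
downstream stage testable:

* **Time series** follow a factor model: node `i` in module `m` is
  `sqrt(b) g_t + sqrt(w - b) f_mt + sqrt(1 - w) e_it`, a global latent
  plus a module latent plus idiosyncratic noise, giving expected
  correlation `w` within and `b` between modules with a
  positive-definite covariance by construction (a Cholesky of the full
  160 x 160 target covariance would cost more and gain nothing).
  Defaults `w = 0.35`, `b = 0.10` sit in the range of empirical
  within-/between-system resting-state correlations; the post-treatment
  session uses `w + 0.05`, which raises clustering and small-worldness.
* **Motion** is emulated as global additive spikes (default rate 0.01
  per volume, amplitude 5 signal units) on a baseline of 15, which puts
  clean-scan DVARS near 9.5% — the scale reported for compliant adult
  cohorts. Spiked volumes are recorded so QC can be validated against
  ground truth.
* **Clinical scores** are Gaussian draws calibrated to the treated-OCD
  distributions the package targets (YBOCS 23.12 +/- 3.04 pre,
  13.76 +/- 4.25 post, follow-up drift +1.71; HAMA, MADRS, GAS, Stroop
  analogous), rounded to integers and clamped to instrument ranges
  (instruments are integer-valued), with a warning when clamping occurs.
  Follow-up covariates (months to follow-up ~ 7 +/- 4.5 clamped to
  1–12, medication months, CBT sessions) are independent of outcome
  unless configured otherwise.
* **The planted effect**: when `effect_beta != 0` the generator runs the
  real connectivity + metric pipeline on each subject's pre-treatment
  scan, standardizes the realized small-worldness AUC within the cohort,
  and adds `effect_beta * z(AUC)` to the follow-up symptom change. The
  defaults `effect_beta = 4` YBOCS points per SD with residual SD 3 give
  a population R^2 of 16/25 = 0.64, matching the strength of association
  the method is meant to detect. Because the planted predictor is the
  *realized* (scan-derived) AUC, the pipeline's own recomputation
  correlates with it near 1 and recovery is a genuine end-to-end check.

What the generator does **not** emulate: hemodynamic autocorrelation
(series are temporally white), scanner drift and physiological noise
beyond Gaussian + spikes, heavy-tailed edge-weight distributions, and
any spatial embedding of nodes. Passing tests therefore demonstrate that
the estimators and inference machinery are correct and calibrated under
a clean generative model — not that the pipeline is robust to every
artifact of real BOLD data. The generator targets correlation *levels*,
not a fitted empirical weight distribution, because the latter is not
characterized in the literature the defaults are drawn from.

## Validation studies and their problem sizes

The test suite runs, with fixed seeds:

* **Metric-oracle equivalence** — every metric (clustering, path length,
  efficiencies, betweenness, edge betweenness) agrees to 1e-10 with
  naive brute-force oracles, and Louvain-with-restarts attains the
  exhaustively enumerated optimal modularity, on 50 random connected
  graphs of 4–8 nodes.
* **Small-world sanity** — Watts–Strogatz lattices (n = 60, k = 6,
  rewiring 0.1) give sigma > 1 and Erdős–Rényi graphs give sigma within
  [0.8, 1.2], 20 seeds each, 100 nulls.
* **Type-I calibration** — 500 null cohorts (17 subjects, 160 nodes, 208
  volumes, no pre/post delta, no planted effect) run through the full
  pipeline at a reduced sparsity grid {0.10, 0.20} on the raw clustering
  AUC; the motion-residualized paired test and the follow-up regression
  reject at most at the nominal 5% rate within binomial Monte-Carlo
  error.
* **Parameter recovery** — with the planted effect, the fitted
  coefficient is positive in more than 80% of 40 replicate 17-subject
  cohorts (grid {0.10, 0.20}, 2 nulls), and at n = 100 the standardized
  coefficient recovers `effect_beta = 4` within two standard errors.
* **Determinism** — identical configurations and seeds produce
  byte-identical result files, including a cached-stage rerun.

The reduced grids and null counts in the simulation studies are
computational choices for the replicated designs; single-cohort analyses
(and `scripts/acceptance.R`) use the full 9-point grid with 100 nulls.

## Known limitations

* Pairwise-conditioned partial correlations under heavy shrinkage
  compress edge-weight contrast; absolute metric values are not
  comparable across shrinkage intensities or cohort sizes.
* Louvain restarts make the *returned partition* deterministic given a
  seed, but modularity optima of near-degenerate partitions can differ
  between platforms' floating-point orderings at the 1e-15 level.
* The repeated-measures ANOVA sometimes reported across three clinical
  timepoints is reproduced descriptively (means/SDs) only; the package's
  inference rests on the paired tests and the covariate-adjusted
  regression.
* Image-space preprocessing (slice timing, realignment, registration,
  resampling) is out of scope: node extraction assumes registered input
  volumes, and accepts any node coordinate table in world (RAS) mm.
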