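# cytobench

Synthetic flow cytometry benchmarks for automated cell population
identification tools.

Clustering software is increasingly used to replace manual gating in flow
cytometry — including in cell and gene therapy manufacturing, where cell
counts feed release decisions — but real data carry no ground truth, so the
accuracy of a clustering tool can only be judged against another operator's
subjective gates. cytobench generates two-dimensional synthetic event data
in which the two properties that most stress clustering algorithms are
controlled one factor at a time:

* **separation** — cluster centers placed so the projection separation
  index between neighbouring clusters hits an exact target, from merged
  (−0.3) to well separated (+0.3);
* **skew** — multivariate skew-normal populations with shape
  α ∈ {2.5, 5, 7.5, 10}, paired tail-to-tail, head-to-tail or head-to-head
  and shifted until their measured separation index lies in [−0.25, −0.15].

Every event keeps its generating label, so accuracy is explicit. Datasets
are written as FCS 3.1 files (float32 list mode) with a ground-truth CSV
sidecar, so any cytometry tool can consume them unchanged.

## The statistics

**Separation index.** For clusters with means μ₁, μ₂ and covariances
Σ₁, Σ₂ projected on a unit vector *a*, with Δ = |aᵀ(μ₂−μ₁)|,
σᵢ = √(aᵀΣᵢa) and z the normal upper α/2 quantile (α = 0.05):

    J = (Δ − z(σ₁+σ₂)) / (Δ + z(σ₁+σ₂)),  maximised over a.

J = 0 means the central 95% bodies just touch; J < 0 means overlap. An
empirical form on sample quantiles measures J for arbitrary point clouds.

**Difference to reference.** With A the ground-truth cluster-1 count and B
the count of the output cluster matched to it (optimal assignment;
majority-overlap merging first if the tool over-clusters):

    difference % = |A − B| / total events × 100,

summarised per condition by mean, sample SD and CV across replicates.

## Worked example

```r
library(cytobench)
cfg <- run_config(list(
  si_targets = c(-0.2, 0, 0.2), replicates = 3, alpha_grid = 10,
  orientations = "tail_tail", base_seed = 42,
  sources = c("kmeans", "gmm_em"), out_dir = "bench_out", log_level = "quiet"))
cmd_generate(cfg)                       # writes FCS + sidecars + manifest.csv
res <- cmd_evaluate(cfg)                # runs both baselines, writes CSVs
res$summary[, c(1:2, 4:5, 7:9)]
```

```
      family target_si source n_replicates mean_difference_pct sd_difference_pct cv_pct
1 separation      -0.2 gmm_em            3              1.1833            1.3531  114.3
2 separation      -0.2 kmeans            3              3.0833            2.2008   71.4
3 separation       0.0 gmm_em            3              0.6167            0.4072   66.0
4 separation       0.0 kmeans            3              1.9000            0.6538   34.4
5 separation       0.2 gmm_em            3              0.0333            0.0289   86.6
6 separation       0.2 kmeans            3              0.2667            0.0764   28.6
7       skew      -0.2 gmm_em            3             10.7333            6.1027   56.9
8       skew      -0.2 kmeans            3              9.7333            6.0857   62.5
```

Reading the table: at SI +0.2 both baselines recover cluster 1 almost
exactly (mean difference ≤ 0.27% of events); once the clusters overlap at
SI −0.2 the error grows more than tenfold, and on heavily skewed
tail-to-tail pairs (α = 10, measured SI ≈ −0.2) the Gaussian-model
baselines misassign ~10% of events — the characteristic failure mode the
benchmark is designed to expose.

Single datasets are just as direct:

```r
ds <- build_separation_dataset(cfg$spec, 0.2, 1)
ds
#> labeled_dataset: 2000 events x 2 channels, k = 2 [separation]
#>   target SI 0.20, measured SI 0.211, replicate 1
separation_index_empirical(ds$events[ds$labels == 1, ],
                           ds$events[ds$labels == 2, ])
#> Separation index J = 0.2112 (coverage alpha = 0.05)
#> direction: 0.4659 -0.8849
```

External tools are scored from per-dataset `event_index,label` CSVs via
`load_external_assignments()` or an `external_dir` in the configuration.

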