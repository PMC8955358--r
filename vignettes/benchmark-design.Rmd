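---
title: "Design of the cytobench synthetic benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design of the cytobench synthetic benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytobench)
```

## Why synthetic cytometry data

Automated cell population identification tools (density-based, k-means,
self-organising-map, graph-community and mixture-model clusterers) are
increasingly used to replace manual gating of flow cytometry data, but real
data provide no ground truth against which their accuracy can be stated
absolutely. cytobench generates two-dimensional synthetic event data in
which two properties known to stress clustering algorithms are controlled
one at a time — the separation between neighbouring clusters, and the
asymmetry (skew) of each population — and every event carries a known
generating label. Accuracy and repeatability of any clustering tool can
then be measured explicitly, event by event.

## The separation index

For two clusters projected on a unit vector $a$, write
$\Delta = |a^\top(\mu_2-\mu_1)|$ and $\sigma_i = \sqrt{a^\top\Sigma_i a}$.
With $z$ the standard-normal upper $\alpha/2$ quantile
($z \approx 1.96$ at the default tail level $\alpha = 0.05$), the index is

$$J = \frac{\Delta - z(\sigma_1+\sigma_2)}{\Delta + z(\sigma_1+\sigma_2)},$$

maximised over $a$. $J = 0$ means the central 95% bodies of the two
clusters just touch; negative values mean overlap; values near 1 mean far
separation. The maximising direction satisfies the fixed point
$a \propto (\Sigma_1/\sigma_1 + \Sigma_2/\sigma_2)^{-1}(\mu_2-\mu_1)$,
which `optimal_direction()` iterates to $10^{-10}$ (at most 500 steps,
with a 3600-point angle-grid fallback in two dimensions). Unit tests hold
this solver to the grid optimum within $10^{-6}$ on random instances.

The empirical form replaces Gaussian quantiles with linear-interpolation
sample quantiles of the projected events: with the clouds ordered by
projected mean, $J = (L_{hi}-U_{lo})/(U_{hi}-L_{lo})$, where $U$/$L$ are
the $1-\alpha/2$ / $\alpha/2$ quantiles. The direction starts at the
moment-based optimum and is refined by a local angle search; arguments are
canonically ordered first, so the result is exactly symmetric under
swapping the clouds. At 1000 events per cluster the empirical index
carries a small positive bias (tail quantiles shrink toward the centre and
the direction search maximises on the sample), of the order of a few
hundredths — the unit tests hold measured-versus-target deviations to
absolute bands of 0.03–0.06 at this sample size; it
converges to the theoretical value as the sample grows, which the test
suite checks at $n = 10^3, 10^4, 10^5$.

The tail level $\alpha = 0.05$ is fixed as the package default because it
reproduces the separation scale on which the benchmark grids are defined.
`solve_center_distance()` inverts $J$ by bisection (the index is strictly
increasing in the center distance) to a default tolerance of 0.005 on $J$,
an order of magnitude below the 0.1 grid spacing of the separation series.

## The dataset families

**Separation family.** Per dataset, `k` (2 or 3) covariance matrices are
drawn as $Q\Lambda Q^\top$ with eigenvalues uniform in $[1, 5]$ and a
uniformly random rotation — giving cluster diameters and shapes in the
range seen in well-compensated two-channel data — and centers are placed
so the theoretical optimal-direction index between each cluster and its
nearest neighbour equals the target; the grid runs from $-0.3$ to $+0.3$
in steps of 0.1, with 1000 normal events per cluster and nine replicates
per level. For three clusters, all three pairwise center distances are
solved for the target and the triangle is rebuilt from those edge lengths
(iterated because edge directions feed back into the required lengths);
every pair, and hence every nearest neighbour, then sits at the target
index, matching the nearest-neighbour-separation semantics of established
cluster-generation software. A final random rotation is applied jointly to
centers and covariances, which leaves every pairwise index unchanged.

**Skew family.** Individual clusters follow the multivariate skew-normal
with shape $(\alpha, 0)$, sampled by the conditioning representation: draw
$(X_0, X)$ jointly Gaussian with $\mathrm{cor}(X_0, X_j) = \delta_j$,
$\delta = \bar\Omega\alpha/\sqrt{1+\alpha^\top\bar\Omega\alpha}$, and flip
the sign of $X$ when $X_0 \le 0$. The shape grid is
$\alpha \in \{2.5, 5, 7.5, 10\}$ ($\alpha = 0$ gives the symmetric
control), and events are location-shifted so the theoretical (not sample)
mean sits at the origin, since the mean vector is a generation parameter.
Left-skewed clusters are mirrored copies of right-skewed draws, never
negative-$\alpha$ samples, so the two directions are exactly
distribution-symmetric.

Skewing contracts the x marginal by the factor $\sqrt{1-2\delta^2/\pi}$
($\delta = \alpha/\sqrt{1+\alpha^2}$). `rescale_to_preskew_width()`
restores the pre-skew width by multiplying centered x coordinates by the
inverse of that factor. This is deliberately a *theoretical variance*
restoration rather than a sample min–max range match: range matching
depends on the extremes of the particular draw, while variance matching is
deterministic in the model and preserves the moment-ratio skewness
$g_1 = m_3/m_2^{3/2}$ exactly — the invariance the generation procedure is
required to satisfy. The manifest records the choice so a range-based
rescale could be swapped in.

A skew pair always combines two clusters of the same $\alpha$. With
cluster A at lower x and B at higher x, the orientations are: tail-to-tail
(A left-skewed, B right-skewed), head-to-head (the reverse — the dense
mode sides face each other, maximising interface density), and
head-to-tail (both skewed the same way). B is then shifted along x by
bisection until the *empirical* index of the sampled events falls in the
acceptance band $[-0.25, -0.15]$; the accepted value is recorded as
`measured_si`. The empirical index is used here because the skew-normal
index has no closed form, mirroring a measure-then-select workflow; both
the target and the measured value are kept in the manifest since either
convention ("set theoretically" vs "verified empirically") could be wanted
downstream.

## Files and ground truth

Datasets are written as single-dataset FCS 3.1 files: 58-byte header,
`/`-delimited primary TEXT segment (delimiter characters in values escaped
by doubling), little-endian float32 list-mode DATA. Float32 is the
cytometer convention and loses nothing at the O(10) intensity scale used
here. Ground truth lives in a CSV sidecar (`event_index,label`,
`event_index` 0-based in binary row order) so clustering tools see only
the event data; a validator rejects sidecars whose index set is not the
contiguous 0-based sequence. The reader handles big-endian files and
float64 data for interoperability, and refuses truncated DATA segments
rather than silently shortening them.

## Scoring

With $A$ the event count of ground-truth cluster 1 and $B$ the count of
the output cluster matched to it,

$$\text{difference to reference (\%)} = \frac{|A-B|}{\text{total events}}
\times 100 .$$

"Cluster 1" is fixed deterministically as the first generated cluster, and
the matched output cluster is found by optimal one-to-one assignment on
the contingency table (Hungarian algorithm; ties broken toward the
smallest reference label). Tools that over-cluster are first reduced by
majority-overlap merging: each sub-cluster joins the reference cluster
holding most of its events, with the merge map retained for audit — an
automated, reproducible surrogate for the manual merging such tools
otherwise require. Outputs with *fewer* clusters than designed are scored
rather than rejected (reference cluster 1 is matched by maximal overlap
and the record flagged), because failing to return the requested number of
clusters is itself a benchmark finding. Replicate summaries report the
mean, the sample standard deviation ($n-1$ denominator; a single replicate
reports a missing SD, never 0) and CV $= 100\,\mathrm{SD}/\mathrm{mean}$.

## Baselines

Two in-package clusterers make the harness runnable end-to-end without
external software: k-means (k-means++ seeding, Lloyd iterations, empty
clusters re-seeded from the farthest point, best of 5 restarts by
within-cluster sum of squares) and a full-covariance Gaussian mixture
fitted by EM (initialised from k-means, covariances regularised by
$10^{-6}I$, stopping when the log-likelihood gain falls below $10^{-6}$,
hard labels by maximum posterior because the statistic needs integer
counts). They are explicitly stand-ins for the k-means-family and
model-based families of cytometry tools, not re-implementations of any
published package; external tools plug in through per-dataset assignment
CSVs instead. The test suite cross-checks both against independent
implementations and asserts EM's per-iteration log-likelihood monotonicity.

## What the generator does and does not emulate

It emulates: controlled inter-cluster separation on a measurable scale,
realistic spread in cluster diameter and orientation, graded asymmetry
with all three skew-pair orientations, fixed equal cluster sizes, and
exactly reproducible replication (every dataset's seed derives from the
base seed, family, condition and replicate, so any single dataset can be
rebuilt in isolation). It deliberately omits: debris/noise events,
unequal or rare populations, more than three clusters, more than two
channels, mixed-$\alpha$ pairs, and instrument effects (spillover,
autofluorescence, acquisition drift). Passing benchmarks here therefore
demonstrate algorithmic behaviour under controlled low-dimensional
conditions; they do not certify performance on high-dimensional panels or
noisy real samples.

## Numerical choices and degenerate inputs

Quantiles use the linear-interpolation estimator throughout, fixed for
reproducibility. Non-positive-definite covariances, coincident means,
rank-deficient clouds, constant skewness inputs, unreachable bisection
targets and truncated files all raise typed errors rather than warnings.
Direction-solver ties are broken by the first grid index; assignment ties
by the smallest reference label. Library generation records per-condition
failures in the manifest and continues.

## Problem sizes in the shipped checks

The test suite and the acceptance script run the study conditions at
desk scale: 1000 events per cluster and nine replicates where replicate
statistics are asserted; the skew library build uses the full
$\alpha$ × orientation grid with three replicates per cell; sampling-
distribution checks (skewness, moments, empirical-index convergence) use
$10^5$ events, where the closed-form comparisons are sharp to about
$\pm 0.03$. These sizes were chosen so the whole suite exercises every
code path in a few minutes on a single core while keeping each assertion
statistically meaningful.
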