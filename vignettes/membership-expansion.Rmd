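---
title: "Expanding cytometry feature spaces with GMM membership functions"
author: "CytoMembership"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expanding cytometry feature spaces with GMM membership functions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CytoMembership)
```

## The model

Mass cytometry measures tens of protein markers on up to millions of single
cells.  After the standard variance-stabilizing transform
$y = \operatorname{asinh}(x / c)$ (cofactor $c = 5$), each marker's marginal
intensity distribution is treated as a univariate Gaussian mixture

$$p(y) = \sum_{k=1}^{K} w_k\, \varphi(y;\, m_k, s_k),
\qquad \sum_k w_k = 1,$$

fitted by EM with the number of components selected by BIC,
$\mathrm{BIC}(K) = -2\log L + (3K - 1)\log n$, under a floor
$s_k \ge s_{\min}$ that prevents components from collapsing onto single
values.  Each mixture component is interpreted as one expression mode of the
marker (negative, low, intermediate, high, ...), and the posterior
probability

$$P(k \mid y) = \frac{w_k \varphi(y; m_k, s_k)}
                     {\sum_j w_j \varphi(y; m_j, s_j)}$$

scores how strongly a cell's value belongs to each mode.  Plotted over the
marker's range these posteriors form *conditional probability lines*, and
projecting every cell through every marker's curves replaces the
$n \times M$ marker matrix by an $n \times \sum_m K_m$ matrix of values in
$[0, 1]$ — the *expanded feature space*.  Because membership saturates near
0 and 1 away from the component boundaries, well-fitting components become
nearly binary features, which both sharpens cluster boundaries and acts as a
normalization for downstream clustering.  A population whose defining marker
value lies in the *middle* of a marker's range — the classic hard case for
rare-population detection — becomes a dedicated feature of its own as soon
as the mixture resolves that intermediate component.

## Posterior artifacts and their correction

Raw posterior curves exhibit three artifact families that make them
unsuitable as features:

* **multi-peak dominance** — a broad component beats a narrower one on
  *both* sides of the narrow component's range, so one curve dominates two
  disjoint intervals and cells with very different values are scored alike;
* **order violations** — the sequence of dominance intervals along the
  marker axis disagrees with the ascending-mean order of the components;
* **inactive components** — components (typically of very low weight) that
  are never the largest posterior anywhere; they contribute nothing and are
  removed, after which the remaining weights are renormalized to sum to 1
  (no re-fit: the location/scale estimates are kept).

`detectArtifacts()` formalizes dominance as the columnwise argmax on a dense
grid (ties toward the lower-mean component) and additionally flags curves
whose peak is not located near the component mean (farther than $3 s_k$).
`correctLines()` then re-models each retained curve into a *membership
function*:

1. each component keeps exactly one dominance interval — the argmax run
   containing its mean, otherwise the run nearest to it;
2. anchor points are sampled from the original posterior inside
   $m_k \pm 3 s_k$ restricted to that interval (11 per side of the peak),
   always including the peak summit and the grid points flanking the
   intersections with the neighbouring curves — intersections are preserved
   because they are used as gating cut-offs;
3. the first curve is pinned at membership 1 at the grid minimum and the
   last at the grid maximum (the extremes of the range are closest to the
   first/last component); every other curve endpoint is pinned at 0;
4. the curve is rebuilt through the anchors with monotone piecewise-cubic
   Hermite (pchip) interpolation, which cannot overshoot or introduce new
   extrema between anchors.

The corrected curves no longer sum to 1 across components — they are
memberships, not probabilities — and no cross-curve renormalization is
applied.

### Numerical choices

* **Grid**: 1024 equally spaced points spanning the observed data range
  (configurable, minimum 64).  This resolves 2–13-component structures and
  keeps curve storage trivial.  The boundary anchor "start at probability 1"
  is attached to the *observed minimum*, not to zero, because
  arcsinh-transformed values are routinely negative.
* **Peak detection**: strict discrete local maxima merged by persistence
  with tolerance $10^{-4}$, so floating-point ripples never count as peaks.
* **Selective correction**: a curve set that already satisfies every
  membership invariant (single peaks, boundary values within $10^{-6}$,
  contiguous mean-ordered dominance, peaks near means) passes through
  unchanged apart from exact boundary snapping.  This makes the correction
  an exact fixed point — correcting a corrected set changes nothing — and
  avoids perturbing curves that need no repair.
* **Anchor monotonization**: anchor values are forced non-decreasing into
  the peak and non-increasing after it (cumulative min/max), so a single
  peak is guaranteed even for pathological posterior shapes.
* **EM**: each candidate $K$ runs `nInit` restarts — quantile-spaced means,
  range-equispaced means, then seeded random draws from the data.  The
  range-equispaced restart matters: quantile spacing never places a
  component inside a sparse intermediate region, which is exactly where
  rare intermediate populations live.  Restarts run briefly at a loose
  tolerance (relative $10^{-5}$, 100 iterations) and only the best is
  refined at relative $10^{-8}$ (up to 500 iterations).  The refinement
  tolerance is deliberately tight: with $n$ in the tens of thousands, a
  $10^{-6}$ relative change still allows absolute drifts of order 0.1
  log-likelihood per iteration, and EM can be stopped on the long plateau
  that precedes the growth of a low-weight component, leaving it broad and
  overweighted.  All restart seeds are derived deterministically from
  (user seed, marker index, $K$, restart), so a fit is reproducible from
  one integer.
* **Ties and degenerate input**: components are relabeled by ascending
  mean, ties broken by ascending sigma then ascending weight, making
  relabeling total and deterministic.  Inputs with fewer than
  $10\,k_{\max}$ observations or with all values identical are rejected.
  A marker whose fit selects $K = 1$ still contributes one (constant)
  feature, with a warning-level note in the pipeline report; dropping
  markers is left to downstream feature selection.

### Decisions where the design was open

* After removing an inactive component only the weights are renormalized
  (no EM re-fit); posterior curves are recomputed from the reduced model.
  Removal can expose a newly never-dominant component, so the
  detect-remove loop iterates until the report is clean.
* If the *first* (lowest-mean) component is itself removed as inactive, the
  lowest-mean retained component inherits the membership-1 anchor at the
  grid minimum.
* The comparison report can compute validity indices either in the space
  that was clustered (default) or always in the regular space
  (`evaluationSpace` flag), since either convention is defensible for
  cross-space comparisons.

## What the synthetic generator emulates — and what it does not

`benchmarkSpec()` / `simulateCytof()` generate labeled cytometry-like data
directly in arcsinh space: populations are defined by abundances and by the
mixture component they draw from on every marker, so each marker's marginal
is *exactly* a Gaussian mixture whose component weights are the abundance
totals.  Three presets are provided:

* **easy** — 3 populations, 4 markers, component means 4 sigma apart;
* **overlap** — 3 populations, 4 markers, adjacent means 1.5 sigma apart;
* **rare_intermediate** — a 1% population expressed only through an
  intermediate component of one defining marker (means 0/3/6, sigma 0.5).

The defining-marker geometry of `rare_intermediate` was chosen so that the
*Bayes-optimal* argmax assignment recovers the rare population: with gap
$g$ between adjacent means, the 1% weight moves each dominance boundary
inward by $s^2 \ln(w_{\text{neighbour}}/w_{\text{rare}})/g$, which at
$g = 6s$ leaves oracle recall near 0.98 but at $g = 4s$ would cap it near
0.69 regardless of the estimator.  A recovery benchmark must keep the
target recoverable in principle; this constraint is derived from the
generative model alone.

The generator deliberately does **not** simulate raw-count acquisition,
doublets, bead or batch effects, non-Gaussian marginals, or between-marker
correlation beyond shared population structure.  Passing tests on these
data therefore demonstrate the correctness of the decomposition, correction
and expansion machinery and the direction of its effect under the assumed
mixture family — not robustness to instrument artifacts in real panels.

## Benchmark study sizes

The package's end-to-end checks simulate 50,000 cells per dataset across 20
seeds per preset and run the pipeline with `kMax = 3`, `nInit = 2` (the two
deterministic initializations) and `gridSize = 512` — sizes chosen to match
the presets' known ≤3-component structure.  Parameter-recovery checks use
20,000 observations with `kMax = 5` and the default five restarts.  The
acceptance script (`scripts/acceptance.R`) re-runs one seed of each preset
at the same sizes.

## Known limitations

* **The expansion is only as good as the mixture fit.**  When components
  are closer than roughly 2 sigma, BIC *correctly* prefers a merged fit at
  realistic sample sizes — the merged populations then share expanded
  features and cannot be separated downstream.  On the `overlap` preset
  (1.5 sigma spacing) the expanded space improves cluster compactness
  (higher Calinski–Harabasz) in every seed, but forcing k-means to the true
  population count splits a merged feature-space blob arbitrarily and the
  Davies–Bouldin index degrades.  Uniform improvement of both indices
  should only be expected when the population structure is
  mixture-resolvable per marker, as in well-characterized CyTOF panels.
* Expanded features are strongly bimodal (values near 0 and 1), which
  violates the distributional assumptions of some clustering algorithms;
  algorithms should be chosen or adapted accordingly.
* The expanded dimension is $\sum_m K_m$, an order of magnitude larger than
  the marker count; distance-based methods inherit the usual
  high-dimensional caveats.
* Correction preserves curve shape at peak summits and intersections but is
  not intended to preserve the full posterior geometry elsewhere; the
  membership values between anchors are an interpolation model.
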