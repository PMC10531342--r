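# CytoMembership

Cell-subpopulation identification in mass cytometry (CyTOF) struggles with
rare populations: cells whose defining marker values sit in the *middle* of
a marker's range are easily absorbed into neighbouring clusters, and
algorithms that downsample lose them entirely.  **CytoMembership**
implements a feature-space *expansion* that addresses this: every marker's
arcsinh-transformed intensity distribution is decomposed into a univariate
Gaussian mixture, and each mixture component becomes its own feature.  It
is aimed at cytometry analysts and methods developers who want to run their
favourite clustering algorithm in a sharper feature space rather than adopt
a new clusterer.

## The method

For each marker, the marginal density is modeled as

    p(y) = sum_k w_k * N(y; m_k, s_k),    k = 1..K

fitted by EM with K selected by BIC = −2 log L + (3K − 1) log n, under a
minimal-sigma constraint.  The component posteriors
P(k | y) = w_k N(y; m_k, s_k) / p(y) — the *conditional probability lines* —
are then corrected into single-peaked *membership functions*: components
that are never dominant are removed (weights renormalized), curves with two
dominance peaks or out-of-order dominance are re-modeled through anchor
points by monotone piecewise-cubic (pchip) interpolation, the first/last
curves are pinned at membership 1 at the range extremes, and intersection
points between neighbouring curves (the natural gating cut-offs) are
preserved.  Projecting every cell through every marker's membership
functions turns an n × M marker matrix into an n × Σ K_m matrix of values
in [0, 1], where downstream clustering separates populations — including
rare intermediate ones — better than in the raw space.  Cluster quality is
compared with the Calinski–Harabasz (CHI, higher is better) and
Davies–Bouldin (DBI, lower is better) indices.

## Worked example

Simulate a 20,000-cell benchmark with a 1% rare population expressed only
through an intermediate component of marker M1, expand, and compare spaces:

```r
library(CytoMembership)

spec <- benchmarkSpec("rare_intermediate", nCells = 20000, seed = 1)
m <- simulateCytof(spec)
res <- fitExpandPipeline(m, expansionConfig(kMax = 3, nInit = 2,
                                            gridSize = 512, seed = 1),
                         verbose = TRUE)
#> marker M1: K = 3 selected, 3 component(s) retained
#> marker M2: K = 2 selected, 2 component(s) retained
#> marker M3: K = 2 selected, 2 component(s) retained
#> marker M4: K = 2 selected, 2 component(s) retained

res$models[["M1"]]
#> GMMModel for 'M1': K = 3 (n = 20000)
#>   weight    mean  sigma
#> 1 0.5515 -0.0018 0.5013
#> 2 0.0091  3.0059 0.5252
#> 3 0.4394  6.0039 0.4977
#> BIC trace: K=1: 100880.1; K=2: 60744.5; K=3: 58349.2
```

BIC isolates the 1% intermediate component (weight 0.0091, mean 3.01) on
the defining marker; the other markers fit their true two components, so
the four markers expand into 3 + 2 + 2 + 2 = 9 features.  Clustering both
spaces with the built-in k-means baseline at the true K = 3:

```r
lab  <- kmeansBaseline(intensityValues(m), 3, seed = 1)
labE <- kmeansBaseline(intensityValues(res$expanded), 3, seed = 1)
compareSpaces(m, res$expanded, list(kmeans_regular = lab,
                                    kmeans_expanded = labE))
#>         algorithm    space n_clusters     chi     dbi
#> 1  kmeans_regular  regular          3  154285 0.42400
#> 2  kmeans_regular expanded          3 3114439 0.04758
#> 3 kmeans_expanded  regular          3  154285 0.42400
#> 4 kmeans_expanded expanded          3 3114439 0.04758

rarePopulationRecall(m, res$membership[["M1"]], "M1", "rare",
                     rareMean = 3, rareSigma = 0.5)$recall
#> [1] 0.973
```

In the expanded space CHI rises (154,285 → 3,114,439) and DBI falls
(0.424 → 0.048) — memberships saturate near 0/1, so clusters become tight
and well separated — and assigning each cell to its argmax membership
column on the defining marker recovers 97.3% of the rare population.

A command-line front end wrapping the same functions ships at
`inst/scripts/cytoexpand.R` (subcommands `simulate`, `expand`, `evaluate`,
`plot-lines`).

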