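# healthccd

Coupling coordination analysis of regional health systems.

Regional health policy increasingly asks not just how developed a region's
healthcare delivery, medical insurance and pharmaceutical sectors are, but
how *balanced* their joint development is. `healthccd` is an R package for
that question on provincial-style panels: it builds composite subsystem
indices from indicator batteries, scores the coupling coordination of the
three subsystems, and explains its distribution dynamics and spatial
structure with the standard toolkit of regional economics — kernel
densities, traditional and spatially conditioned Markov chains, Moran/LISA
statistics, panel spatial Durbin models, and Hansen-style panel threshold
regressions. A synthetic-panel generator with known ground truth makes the
whole chain testable.

## The model

Indicators are min–max standardized with direction handling
(`(x−min)/(max−min)` for positive, `(max−x)/(max−min)` for negative
indicators), then combined with CRITIC objective weights
`W_j ∝ σ_j · Σ_l (1−r_lj)` (contrast intensity times conflict) into
subsystem indices `U1, U2, U3 ∈ [0,1]`. From these,

    C = 3 (U1·U2·U3)^(1/3) / (U1+U2+U3)     coupling degree
    T = αU1 + βU2 + λU3                     coordination index (α=β=λ=1/3)
    D = sqrt(C·T)                           coupling coordination degree

and `D` is classified into ten named levels from "Extreme imbalance"
(`0 ≤ D < 0.1`) to "Excellent coordination" (`0.9 ≤ D ≤ 1`).

Downstream, `D` panels feed Gaussian kernel densities, quartile-tier Markov
transition matrices (optionally conditioned on the tier of each unit's
spatial lag), global/local Moran statistics with randomization or
permutation inference, a panel spatial Durbin model
`y = ρWy + Xβ + WXθ + u` estimated by concentrated maximum likelihood
(pooled, fixed or random effects) with the full specification battery
(VIF, LM/robust LM, LR, Wald, Hausman), and a fixed-effects panel threshold
regression with bootstrap F-tests for one and two thresholds.

## Worked example

```r
library(healthccd)

cfg    <- sim_config(n_units = 31, n_years = 11, seed = 2024)
sim    <- generate_indicator_panel(cfg)
std    <- standardize(sim$panel, sim$schema)
scores <- composite_scores(std, sim$schema)     # CRITIC weights
ccd    <- ccd_table(scores)
head(ccd, 3)
#>   unit year        U1        U2        U3         C         T         D
#> 1  U01    1 0.1361620 0.1074970 0.1486653 0.9909004 0.1307748 0.3599788
#> 2  U01    2 0.2604642 0.2780621 0.2114089 0.9933491 0.2499784 0.4983129
#> 3  U01    3 0.2651446 0.2449757 0.1877893 0.9894966 0.2326366 0.4797844
#>                  level
#> 1       Mild imbalance
#> 2 Borderline imbalance
#> 3 Borderline imbalance
```

Unit U01 starts mildly imbalanced (`D = 0.36`) and improves; its coupling
degree `C ≈ 0.99` says the three subsystems are balanced with each other,
so its low `D` reflects low overall level `T`, not imbalance. By the final
year the 31 units spread across the upper classification levels:

```r
table(classify_level(ccd$D[ccd$year == 11]))
#>        Basic coordination    Excellent coordination         Good coordination
#>                         7                         5                        12
#> Intermediate coordination
#>                         7
```

Spatial structure and spillovers:

```r
w <- build_weights(adjacency = sim$geography$adjacency,
                   centroids = sim$geography$centroids,
                   units     = sim$geography$centroids$unit)
y <- ccd$D[ccd$year == 11][match(w$units, ccd$unit[ccd$year == 11])]
global_moran(y, w)
#> Moran's I = 0.6464  E(I) = -0.0333  SD(I) = 0.0999  z = 6.805  p = 1.012e-11 (randomization)
```

The synthetic panel is generated with positive spatial autocorrelation and
east > central > west level offsets, and the Moran statistic recovers that:
`I = 0.65` against a null expectation of `−1/30 ≈ −0.033`.

```r
fit <- fit_sdm(ccd, sim$covariates, w, effects = "random")
fit$coefficients[fit$coefficients$term == "rho", ]
#>    term estimate     se    z p
#> 12  rho    0.905 0.0159 57.1 0
```

The spatial autoregressive coefficient is strongly positive: a unit's CCD
co-moves with its neighbours', as built into the generating process.

The whole chain — simulate, weights, CCD, kernel density, Markov, Moran,
LISA, SDM, threshold — runs as one configured pipeline writing CSV tables
with provenance headers:

```r
report <- run_pipeline(run_config(out_dir = "ccd_run", seed = 1))
```

or from a shell via the thin wrapper `inst/scripts/ccd-pipeline.R`.

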