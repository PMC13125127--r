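---
title: "Measuring coupling coordination of regional health systems: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring coupling coordination of regional health systems: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(healthccd)
```

# The problem

Regional health systems are usually described through three interacting
subsystems: healthcare delivery, medical insurance, and the pharmaceutical
sector. Each can be summarized by a composite development index built from a
battery of indicators, and the *coupling coordination degree* (CCD) asks how
balanced and how developed the three are jointly, per region and year.
`healthccd` implements the full analytical chain — objective weighting,
composite indices, CCD scoring and classification, distribution dynamics,
spatial autocorrelation, spatial Durbin regression, and panel threshold
regression — together with a synthetic-panel generator with known ground
truth, so every stage can be validated end to end.

# Composite indices

## Standardization

Indicators carry a direction: for a positive indicator (e.g. physicians per
thousand people) more is better, for a negative one (e.g. disease mortality)
less is better. Min–max standardization maps each indicator onto $[0,1]$:

$$X'_{ij} = \frac{x_{ij} - x_{\min}}{x_{\max} - x_{\min}} \quad (+), \qquad
  X'_{ij} = \frac{x_{\max} - x_{ij}}{x_{\max} - x_{\min}} \quad (-).$$

The pool over which $x_{\min}, x_{\max}$ are taken defaults to the whole
panel (all units and years jointly) so that scores are comparable over time;
a per-year pool is available by configuration. A constant indicator within
its pool is an error, not a silent `NaN`: surfacing degenerate data beats
hidden propagation.

## CRITIC weights

CRITIC weighting scores each indicator by its *contrast intensity* — the
sample standard deviation $\sigma_j$ of its standardized column — times its
*conflict* with the other indicators in its block,
$c_j = \sum_l (1 - r_{lj})$ with $r$ the Pearson correlation matrix of the
standardized columns. The information capacity is $I_j = \sigma_j c_j$ and
weights are $W_j = I_j / \sum_j I_j$, computed once per subsystem block over
the whole panel. Two conventions deserve a note:

* the conflict sum includes the self term, which contributes exactly zero,
  so the choice is inconsequential but is made explicit here;
* correlations are computed on standardized values; because min–max
  standardization is affine, Pearson correlations are unchanged whether raw
  or standardized values are used (up to the sign flip for negative
  indicators, which the direction handling makes deliberate).

An entropy-weight alternative (shares, entropy
$e_j = -\tfrac{1}{\ln m}\sum_i p_{ij} \ln p_{ij}$, weight $\propto 1-e_j$)
is provided for robustness analyses only.

## Subsystem scores

The composite index of a subsystem is the weighted sum
$U = \sum_j W_j X'_{ij}$ over that subsystem's indicators. Since weights are
convex and standardized values lie in $[0,1]$, so does every $U$.

# Coupling coordination

For subsystem scores $U_1, U_2, U_3$:

$$C = \frac{3\,(U_1 U_2 U_3)^{1/3}}{U_1 + U_2 + U_3}, \qquad
  T = \alpha U_1 + \beta U_2 + \lambda U_3, \qquad
  D = \sqrt{C \cdot T}.$$

$C$ is the ratio of geometric to arithmetic mean: by AM–GM it lies in
$[0,1]$, equals 1 exactly when the three scores coincide, and equals 0 when
any score is 0. The weights default to $\alpha=\beta=\lambda=1/3$, treating
the subsystems as equally important. $D$ is classified into ten named
levels on left-closed tenth-intervals from "Extreme imbalance" to
"Excellent coordination"; the top interval is closed at 1 because $D = 1$
is attainable and must classify.

Growth summaries use the geometric compound annual growth rate
$100\,[(\text{last}/\text{first})^{1/k} - 1]$ over $k$ year-intervals.
Alternative conventions (e.g. the arithmetic mean of year-on-year growth
rates) give slightly different numbers; the geometric form is used
consistently here.

Trajectory grouping labels units Leading / Advantageous / CatchingUp /
Lagging by quartiles of final-year $D$ (ties broken by unit id). Published
analyses of this kind rarely state a quantitative membership rule, so the
rule is a pluggable function, with quartiles as a transparent default.

# Distribution dynamics

**Kernel density.** $f(x) = \frac{1}{Nh}\sum_i K\!\left(\frac{X_i - x}{h}\right)$
with a standard normal kernel, evaluated on a grid extending four
bandwidths beyond the data range (so the trapezoid mass is $\approx 1$).
The automatic bandwidth is Silverman's rule
$0.9 \min(s, \mathrm{IQR}/1.34)\, n^{-1/5}$.

**Markov chains.** Pooled unit-year CCD values are cut at their 25/50/75
percentiles (linear interpolation; boundary ties go to the lower tier) into
tiers I–IV; the pooled scheme makes tier row totals near-equal, and a
per-year scheme is available by flag. Transition matrices are
maximum-likelihood row-normalized counts of year-over-year moves. The
spatial variant conditions each transition on the tier of the unit's
spatial lag $\mathrm{Lag}_i = \sum_j W_{ij} Y_j$ at the start year, using
the same quartile scheme for lag tiers; the four conditioned count matrices
partition the unconditional counts by construction, and the same weight
matrix is used as for the autocorrelation analyses unless overridden.

# Spatial autocorrelation

Global Moran's I with $z$-scores from the standard randomization-moments
formula (expectation $-1/(n-1)$; the variance involves the sample
kurtosis), plus seeded permutation inference as a cross-check. Local Moran
statistics use $I_i = z_i \sum_j W_{ij} z_j / m_2$ with $m_2 = \sum z^2/n$,
so that with a row-standardized $W$ the local values sum to $n$ times the
global statistic. LISA pseudo $p$-values come from conditional permutations
(unit $i$ held fixed, the rest shuffled), with quadrant classes HH/LL/HL/LH
and $\alpha = 0.05$, 999 permutations, and no multiple-testing correction
by default — mirroring common LISA practice; an adjustment option exists.

Weight matrices come from binary contiguity (adjacency list), inverse
distance (centroids), or symmetrized k-nearest neighbours. Isolated units
are linked to their nearest neighbour with a warning. The default for
Moran/LISA/Markov analyses is row-standardized contiguity; the spatial
Durbin model defaults to row-standardized inverse distance, reflecting the
distance-based interaction that spillover regressions usually assume. Both
are overridable, and every result records which matrix produced it.

# Spatial Durbin model

The panel SDM is
$$y_t = \rho W y_t + X_t\beta + W X_t\theta + u_t,$$
estimated by maximum likelihood with the log-determinant
$\log|I - \rho W|$ evaluated from the precomputed eigenvalues of $W$ —
exact and fast at regional panel sizes ($n \approx 31$), where sparse or
Chebyshev approximations would add nothing.

* **Pooled / fixed effects.** The within transformation (unit demeaning) is
  applied before the spatial step; it commutes with $W$ because the weight
  matrix acts cross-sectionally and demeaning acts over time. The
  concentrated residual sum of squares is exactly quadratic in $\rho$, so
  after a bracketing search the maximizer is polished on the analytic score
  equation, making estimates invariant to unit reordering at machine
  precision.
* **Random effects.** The error-component transformation quasi-demeans by
  $\psi = 1 - 1/\sqrt{1 + T\phi}$ with $\phi = \sigma_\mu^2/\sigma_e^2$,
  and the likelihood is maximized jointly over $(\rho, \phi)$. The
  spatial-error model under random effects applies $(I - \lambda W)$ first
  and quasi-demeans after — the two transformations commute — which
  corresponds to the error-component spatial model in which the unit
  effects share the spatial process. Unit-only random effects are the
  default; time effects can be absorbed by adding year dummies to the
  regressors.
* **Inference.** Standard errors come from the numerical observed
  information at the optimum; a pseudo-$R^2$ (squared correlation of
  transformed outcome and fit) and the log-likelihood are reported.

The specification battery mirrors standard practice: VIFs from auxiliary
regressions; Anselin LM and robust LM statistics for lag and error
dependence from pooled OLS residuals with the block-diagonal panel weight
matrix; LR tests of the SDM against its SAR ($\theta = 0$) and SEM
(common-factor) simplifications; Wald tests of $\theta = 0$ and of the
common-factor restriction $\theta + \rho\beta = 0$ by the delta method; and
a Hausman contrast of fixed- vs random-effects slope vectors. Regressors
enter in the units supplied — no log transforms are applied silently;
rescale covariates (e.g. per-capita GDP) before fitting if coefficient
magnitudes matter for presentation.

Robustness variants re-fit the model with an alternative outcome (e.g. the
entropy-weighted CCD) and on a subsample excluding flagged units, with the
weight matrix rebuilt (and re-standardized) on the subset, reporting
coefficient-sign agreement with the baseline.

# Panel threshold regression

A fixed-effects regression whose slope on the threshold variable $q$
switches at $\gamma$:
$$y_{it} = \mu_i + x_{it}'\delta + \beta_1 q_{it} 1(q_{it} \le \gamma)
  + \beta_2 q_{it} 1(q_{it} > \gamma) + e_{it}.$$
Candidate thresholds are the observed values of $q$ with 5% trimmed from
each tail of its support; $\hat\gamma$ minimizes the within-regression RSS
over the grid (the search uses a Frisch–Waugh projection of the regime
columns off the demeaned controls, so the grid and the bootstrap below stay
cheap). The threshold-existence statistic
$F = (\mathrm{RSS}_{\text{linear}} - \mathrm{RSS}_{\text{threshold}})/\mathrm{MSE}_{\text{threshold}}$
has a nonstandard null distribution, approximated by a residual bootstrap
under the no-threshold model: residual blocks are resampled by unit
(preserving within-unit dependence), the outcome regenerated from the
linear fit, and the threshold re-estimated each replicate; 300 seeded
replicates by default. A second threshold is searched conditional on the
first, the first refined conditional on the second, and the 2-vs-1 test
uses the same bootstrap under the single-threshold model. Fixed effects are
used throughout this module even when the SDM prefers random effects — the
two models are estimated independently, as is conventional.

# The synthetic panel

The generator emulates the structure the analysis assumes, with defaults
chosen once as the study conditions:

* **31 units, 11 years**, matching a provincial panel observed over a
  decade, in three longitudinal bands (east / central / west) laid out on a
  grid; queen contiguity and centroid distances come from the grid, so
  contiguity and distance matrices exist without shapefiles.
* **Latent subsystem qualities** per unit-year: base level 0.5, region
  offsets $+0.15 / 0 / -0.15$ (east above central above west), positive
  annual drifts (0.02–0.03 per year, the pharmaceutical subsystem fastest
  from the lowest base), and a spatially smoothed disturbance
  $(I - \rho W)^{-1}\varepsilon$ with $\rho = 0.4$ and
  $\sigma = $ `noise_sd` $= 0.05$. Indicators are noisy affine transforms
  of the latent quality; negative-direction indicators get a sign flip
  before noise, so direction handling is genuinely exercised.
* **Covariates** (per-capita GDP, government health expenditure share,
  urbanization, education human capital, old-age dependency) are drawn
  uniformly within realistic provincial min–max ranges and given mild AR(1)
  persistence (0.8) around unit baselines, clipped to the range.
* **Ground-truth generating processes** for the SDM
  ($y = (I-\rho W)^{-1}(X\beta + WX\theta + \varepsilon)$ per period) and
  the threshold model (regime-switching slope with unit fixed effects)
  record their parameters exactly for recovery testing.

The Gaussian noise family is a modelling convenience, not a claim about
real indicator distributions. The generator reproduces level ordering,
trends, direction mixing and positive spatial autocorrelation, but not
heavy tails, measurement artefacts, policy breaks, or missingness — so
passing tests demonstrate correctness of the estimators under clean
conditions, not robustness to real-data pathologies.

# Numerical choices

* Quartiles use linear interpolation (type 7); values equal to a cut point
  fall to the lower tier — deterministic, documented tie-breaking.
* The ten-level classification treats intervals as left-closed and the top
  interval as closed at 1.
* The spatial parameter is restricted to the interval defined by the
  reciprocal extreme eigenvalues of $W$, with a small margin; estimates at
  the boundary trigger a warning.
* The pooled/fixed spatial-lag optimizer polishes the bracketed optimum on
  the analytic score equation (tolerance $10^{-14}$); random-effects
  models use Nelder–Mead on $(\rho, \log\phi)$ with a tight relative
  tolerance.
* All stochastic components flow through one run seed, fanned out to
  stages by a stable string hash, so enabling or disabling one stage never
  perturbs another's draws, and derived seeds stay below $2^{31}$.
* Test and validation problem sizes are deliberately modest — panels of
  10–31 units over 6–11 years, 100 Monte-Carlo replicates for coefficient
  recovery, 500 for test size, 100–300 bootstrap replicates — sizes at
  which the checked properties are already sharp.

# Known limitations

* Direct/indirect (impact) decompositions of SDM coefficients are not
  computed; reported quantities are coefficients, spatially lagged
  coefficients and $\rho$.
* The random-effects spatial-error model uses the error-component form in
  which unit effects share the spatial transformation; the variant with
  spatially uncorrelated effects has a different likelihood and is not
  implemented.
* Ergodic distributions and mobility indices for the Markov chains, and
  threshold models with spatial lags, are out of scope.
* The ten-level classification and the quartile trajectory rule are
  conventions; both are exposed as data/configuration rather than
  hard-coded behaviour.
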