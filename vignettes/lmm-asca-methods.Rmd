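---
title: "LMM-ASCA for nested factorial quality-control data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{LMM-ASCA for nested factorial quality-control data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lmmasca)
```

## The problem

A consortium of 15 artisanal dairies produces an extra-hard PDO cheese under
a common protocol. Quality control samples whole cheese wheels every two
months over two years — one to three wheels per dairy per session, in
proportion to production volume — and cuts 24 blocks from each wheel in six
annular sampling positions (`RND`, `RNDs`, `RNDp1`, `Int`, `RNDp2`, `CNT`,
ordered by decreasing distance from the wheel centre). On every block six
physical responses are measured: the CIELAB colour coordinates `L`, `a`,
`b` and three texture parameters from uniaxial compression (`Fmax`, N;
`Ac`, N·mm; `El`, N/mm).

The questions are multivariate: which factors — dairy, period of the year,
position in the wheel — move the physical profile of the cheese, by how
much, and which dairies or periods resemble each other? Blocks cut from
the same wheel are correlated, so observations are not independent and a
plain ANOVA is wrong; the wheel must enter the model as a random grouping
unit.

## The per-variable linear mixed model

For each standardized response, the package fits

$$x_{iklgt} = \mu + \alpha_k + \beta_l + \gamma_g + (\alpha\beta)_{kl} +
(\alpha\gamma)_{kg} + (\beta\gamma)_{lg} + \delta_t + \varepsilon_{iklgt},$$

with fixed factors position ($k = 1..6$), time period ($l = 1..6$, the
couple-of-months level derived from the bi-monthly session) and dairy
($g = 1..15$), their three two-way interactions, a wheel random intercept
$\delta_t \sim N(0, \sigma^2_w)$ and residual
$\varepsilon \sim N(0, \sigma^2_\epsilon)$. The wheel is nested inside the
crossed fixed factors (each wheel belongs to one dairy and one session), so
no interaction involves it, and no three-way fixed interaction is included.
All fixed factors use sum-to-zero contrasts, so every level effect is a
deviation from the grand mean and effects sum to zero over the levels of
each factor. With the printed level counts the fixed-effect matrix has
$1 + 5 + 5 + 14 + 25 + 70 + 70 = 190$ columns on the full design.

### REML by one-dimensional profiling

With a single random intercept the covariance is
$V = \sigma^2_\epsilon (I + \lambda Z Z^\top)$ with
$\lambda = \sigma^2_w/\sigma^2_\epsilon$, and both $\sigma^2_\epsilon$ and
the fixed effects profile out of the restricted likelihood in closed form.
Estimation therefore reduces to a one-dimensional minimisation of the
profiled REML criterion over $\log\lambda$. The implementation (C++, via
group-sum identities from the Woodbury decomposition) uses Brent's method —
golden section with successive parabolic interpolation — on
$\log\lambda \in [\log 10^{-8}, \log 10^{8}]$ with tolerance $10^{-10}$
and an iteration cap of 200; Brent reaches the same optimum as a pure
golden-section search in roughly a third of the criterion evaluations,
which matters because the permutation test refits the model hundreds of
thousands of times. A minimiser driven to the lower end of the interval is
clamped to the boundary solution $\sigma^2_w = 0$ (ordinary least
squares). The fixed effects are the generalized-least-squares solution at
the optimum. The engine agrees with `lme4::lmer` (REML criterion, variance
components, fixed effects) to near machine precision on identifiable
designs; `lme4` serves as an independent oracle in the test suite, never
as the implementation.

One identifiability caveat is worth knowing: when every dairy-by-time cell
holds exactly one wheel, the wheel intercept is confounded with the
dairy-by-time interaction and the REML profile is flat in $\lambda$ — the
variance split is then arbitrary (different optimisers return different
ratios at the same criterion value), while the fixed effects, and
everything downstream of them, are unique. The default campaign allocates
up to three wheels per cell, which separates the components.

## Permutation significance with restricted exchangeability

Each term's test statistic is its observation-expanded sum of squares: the
squared norm of the term's estimated effect expanded to the rows it
applies to. The model's SS decomposition is not uniquely defined for
mixed, unbalanced designs; the effect-expansion convention is the standard
ASCA choice and is well defined under imbalance, so it is used both for
reporting and as the permutation statistic.

The permutation null must respect the nesting of blocks in wheels:

* **wheel-level terms** (`time`, `dairy`, `time:dairy`): the
  `(dairy, time)` label pair is reassigned by a uniform permutation of
  whole wheels, so blocks keep their wheel-mates;
* **position terms** (`position`, `position:time`, `position:dairy`):
  position labels are shuffled uniformly among the blocks within each
  wheel, independently per wheel.

The full REML model is refitted on every permuted dataset — no residual
shortcut. Internally the engine exploits an exact identity: with rows in
canonical order and the balanced within-wheel layout of the design,
relabeling wheels equals permuting whole-wheel response blocks, and
relabeling positions within a wheel equals permuting responses within the
wheel, so the design matrix is built once and each refit is a pure numeric
operation. A test asserts the identity against the explicit label-level
permutation.

The one-sided Monte-Carlo p value uses the +1 correction,
$p = (1 + \#\{SS_{perm} \ge SS_{obs}\})/(n_{perm} + 1)$, so the smallest
attainable p at $n_{perm} = 1000$ is $1/1001$ — the resolution floor of
the test, not the significance level. The rejection rule is the
conventional one: adjusted $p < 0.05$. Bonferroni correction is applied
across the six response variables within each term (the per-factor family;
a `multiplicity = "all"` option corrects across all 36 tests instead,
since the family choice is a judgment call). Testing each variable
univariately and correcting afterwards avoids distorting the tests by the
strong cross-variable correlation of colour and texture measurements.

## ASCA: decomposing the effect matrices

For each main factor the reconstructed level effects of the six variables
are assembled into a levels × variables **effect matrix** (15×6 for dairy,
6×6 for time and position), columns centered per variable. Rows are
levels, weighted equally — one point per level, as in the score plots —
not observation-expanded rows. With sum-to-zero coding the columns already
sum to zero up to estimation error on balanced data, so centering is a
numerical no-op there. No column re-scaling is applied before the
decomposition: unit-variance scaling already happened once, up front, on
the raw responses; re-scaling effect columns would double-count it.

The thin SVD $X = U S V^\top$ gives scores $US$, loadings $V$ and
explained-variance fractions $S_c^2 / \sum S^2$. Because $X$ contains
model effects, not raw data, these fractions quantify exactly how the
factor's effect variance distributes over components. The retained
component count is the smallest one reaching 85% cumulative explained
variance. The contribution of variable $j$ to component $c$ is
$100\, v_{jc}^2 / \sum_j v_{jc}^2$; multi-component contributions weight
the per-component ones by explained variance. SVD signs are arbitrary, so
a deterministic convention is imposed: the largest-magnitude loading entry
of each component is made positive.

Only the three main-effect matrices are decomposed by default (interaction
effect matrices are computable through the same functions). By default the
ASCA stage runs only for factors found significant for at least one
variable; `force_all = TRUE` decomposes all three regardless, which is
useful when a factor is significant for part of the profile only.
Residuals are not added back to the effect matrices before projection (a
known ASCA variant): the package decomposes pure effect matrices.

## Clustering factor levels

Dairies (many levels, structured effects) are grouped by Hartigan–Wong
k-means — `stats::kmeans`, best of 25 random restarts by total
within-cluster SS — on the score matrix over the components retained at
the 85% threshold. Euclidean distance on unscaled scores is used: scores
already carry the singular-value weighting, and re-weighting would count
the variance twice. The number of clusters is chosen by the average
silhouette width over k = 2..8 by default; the elbow rule (largest second
difference of the WSS curve) is implemented as an alternative, and both
diagnostic curves are always computed, because the two rules are both in
common use and need not agree. Cluster labels are canonicalized (cluster 1
contains the first level) so output is deterministic and invariant to row
order. A fixed band on scores (the package exposes it as a plain report
threshold, ±0.55 by convention in this application, with no inferential
meaning) can be used to describe levels "near the overall mean" in
biplots.

## The synthetic-data generator

The real quality-control dataset is confidential, so the package carries a
generator that emulates the campaign design and the generative model
above; every downstream stage is developed and tested against it.

* **Allocation.** 15 dairies × 12 bi-monthly sessions, 1–3 wheels per
  cell, 317 wheels in total. Per-dairy production volumes are not public,
  so the default is a fixed documented table: dairies 1–6 one wheel per
  session, 7–12 two, 13–15 three, except dairy 15 delivering two wheels in
  sessions 1–7. 317 is not divisible by 12, so no constant-per-dairy table
  can reach it; a single dairy with a volume dip is the smallest
  deviation. The default reproduces every printed count: 317 wheels, 7608
  block records, 24 blocks per wheel, all dairies in all sessions.
* **Blocks.** 6 positions × 4 replicates per wheel — the only equal split
  of 24 blocks over six positions.
* **Effects.** Main-effect and interaction arrays in sum-to-zero form,
  built from fixed orthogonal-polynomial level patterns (cycled over at
  most cubic degree so variables share level structure, as colour and
  texture do in real cheese) scaled by per-variable amplitudes in
  residual-SD units. The default amplitudes plant the qualitative pattern
  the campaign is designed to detect: position (0.8) and dairy (0.6)
  effects on all six variables; a time effect (0.4) on `L`, `b`, `Fmax`,
  `El` but not `a`, `Ac`; a position:time interaction (0.15) on the colour
  variables only; a position:dairy interaction (0.15) on all but `El`; no
  time:dairy interaction. The shorter ripening of the final period of a
  campaign can only be represented as a larger configured time effect for
  that level — the model has no ripening covariate.
* **Noise.** Wheel intercepts are drawn once per wheel per variable,
  independent across variables; residuals per block, optionally correlated
  across variables through a user-supplied correlation matrix (residuals
  only — the univariate model motivates keeping the random intercepts
  independent). Grand means and noise scales default to plausible raw
  magnitudes for hard cheese (e.g. `L` ≈ 80, `Fmax` ≈ 260 N), which the
  standardization step then removes.

What the generator does **not** emulate: instrument noise signatures,
spatial continuity inside a wheel beyond the six discrete zones,
season-specific milk chemistry, or the real data's unknown effect sizes
and correlation structure. Passing tests therefore demonstrate that the
machinery is correct under the stated generative model — not that the
confidential dataset's published percentages would be reproduced.

## Numerical choices and degenerate inputs

* Standardization uses the (n−1) sample SD, computed once over the whole
  table; constant variables are an error, as are missing or non-finite
  responses (the design is complete; no imputation).
* Rows are put in a canonical order before fitting, so results are
  invariant to input row order to 1e-10 or better.
* Variance ratio search interval $[10^{-8}, 10^{8}]$, tolerance
  $10^{-10}$, cap 200 iterations; boundary solutions clamp
  $\sigma^2_w = 0$.
* Factors with a single observed level are dropped from the model
  (degenerate sub-designs reduce to the remaining factors); a design with
  fewer than two wheels or no residual degrees of freedom is an error.
* An all-zero effect matrix is flagged degenerate: explained variance is
  undefined there, and dependent quantities raise typed errors rather
  than returning NaN.
* k-means ties and label arbitrariness are resolved by best-of-restarts on
  total WSS under a caller-supplied seed plus canonical relabeling.

## Problem sizes used in the shipped checks

The test-suite simulations are sized for a desk machine: oracle
equivalence uses 100 random toy effect matrices; parameter recovery uses
the full 7608-block design with 50 replicate simulations for the variance
ratio; permutation calibration uses 500 null datasets on a reduced
5-dairy × 4-session × 1-wheel design with 200 permutations each; the
acceptance script runs the full pipeline on the complete 317-wheel design
with 200 permutations per test. These sizes are the package's choices for
routine verification; all of them scale up through function arguments.

## Known limitations

* One random intercept only — the engine is specialised, by design, to
  the single-grouping-unit model; it is not a general mixed-model fitter.
* No degrees-of-freedom approximations (Satterthwaite, Kenward–Roger):
  significance is by permutation only.
* The SS decomposition convention matters in unbalanced designs; other
  conventions (sequential, marginal F-based) would give different
  statistics. The permutation reference distribution is computed under
  the same convention, so the test remains valid, but SS values are not
  comparable across conventions.
* Bootstrap confidence regions on scores and residual back-projection are
  out of scope.
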