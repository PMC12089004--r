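---
title: "From Boolean networks to epigenetic landscapes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From Boolean networks to epigenetic landscapes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grnlandscape)
```

## The problem

A gene regulatory network (GRN) constrains which combinations of gene
activities a cell can sustain.  In the dynamical-systems reading of
Waddington's epigenetic landscape, the attractors of the protein-concentration
dynamics are cell states, and the quasi-potential `U(p) = -log P_ss(p)` --
with `P_ss` the stationary probability density of the stochastic dynamics --
is the landscape whose valleys those states occupy.  For realistic networks
the state space has one dimension per gene, so the stationary Fokker-Planck
equation (FPE) cannot be solved on a grid; this package approximates its
solution with a parametric gamma-mixture ansatz fitted by Monte Carlo
weighted-residual collocation, and then confronts the fitted density with
gene-coexpression data.

The worked system is the 12-gene *Arabidopsis thaliana* flower-morphogenesis
network (genes EMF1, TFL1, LFY, AP1, CAL, LUG, UFO, BFU, AG, AP3, PI, SUP),
shipped as `at_flower_network()` together with the published 4-component
stationary-density fit (`at_table2_mixture()`).

## Model chain

**Boolean layer.**  The network is given as an integer weight matrix `W`
(`W[i, j]` = signed influence of gene `j` on gene `i`) and integer thresholds
`theta`.  Synchronous dynamics `x_i' = H(sum_j W_ij x_j - theta_i)` with
`H(0) = 0` (ties never activate).  `boolean_fixed_points()` enumerates all
`2^N` states; for the packaged network this yields exactly four fixed
points, matching the four floral developmental stages.

**Continuous layer.**  `continuous_model()` translates the Boolean rules
into Hill-type ODEs for protein concentrations:

\[
\frac{dp_i}{dt} = \frac{N_i(p)}{D_i(p)} + \alpha_{i,0} - \delta_i p_i,
\qquad
D_i = 1 + |\theta_i| + \sum_j |w_{ij}|\, p_j^{n},
\]

with the numerator summing the activator terms and, for genes with
`theta_i <= 0`, an additive basal term `1 + |theta_i|`.  The sign of
`w_ij` routes a regulator to the activator or repressor list; `|theta_i|`
enters the half-saturation constant because the Boolean threshold measures
how hard the gene is to switch on.  All unstated rates default to 1
(the Boolean model carries no rate information; introducing fictitious
values would be worse than a parsimonious convention), each overridable
per gene.

**Stochastic layer.**  `fpe_model()` attaches the chemical Langevin
equation: drift `a_j = B_j - delta_j p_j` (with `B_j` the synthesis part)
and diagonal diffusion `Gamma_j = (B_j + delta_j p_j)/Omega` at system size
`Omega`.  Synthesis and degradation are independent Poisson-like event
streams, so their rates *add* in the noise variance.  The diffusion is
treated as diagonal throughout (the single-index noise form); cross-diffusion
is not modeled.  `simulate_langevin()` integrates the SDE by Euler-Maruyama
(Ito), reflecting at 0 to preserve nonnegativity.

`Omega` controls fluctuation size and is not fixed by the network; the
package default is 1, and all shipped low-dimensional examples use
`Omega = 50`, a moderate-noise regime in which wells are well separated yet
clearly smeared.

## The stationary-density fit

The ansatz is a mixture of `n` products of independent gamma densities (one
factor per gene), `n` defaulting to the number of Boolean fixed points.
Gamma factors respect the positive support and the skewness of concentration
distributions; the published fit for the packaged network is exactly of this
form.  The fit minimizes the Monte Carlo estimate of
`integral over D of |R(p)|`, where `R` is the stationary-FPE residual and
`D = [0, p_max]^d` (default `p_max = 10`, above every attractor; the drift
is strongly negative beyond `(1 + alpha0)/delta`).  Mixture derivatives in
`R` are analytic; drift/diffusion fields are differentiated by central
differences.  Collocation points are redrawn at every optimization step; a
fixed validation set drives stopping and best-iterate selection.

Three stages: (1) a Monte Carlo candidate search over Gaussian proxies;
(2) Adam refinement of the proxy (central-difference gradients on an
incremental fast path -- the gradient of each parameter touches only one
gene-column of one component); (3) moment-matched initialization of the
gamma mixture (`mode = proxy mean`, `variance = proxy variance`, which the
pair `beta = (m + sqrt(m^2 + 4v))/(2v)`, `alpha = 1 + m beta` solves
exactly) and Adam fine-tuning.  Stopping: no relative improvement beyond
`tol` for `patience` validation evaluations, or a target residual level.

### Degeneracies of the residual objective, and how the fit handles them

The stationary operator is *linear* in the density.  Three consequences,
each observed directly during development, shape the implementation:

1. **Mass escape.**  A normalized density displaced outside the collocation
   box has near-zero residual on it, so the bare objective rewards pushing
   all mass away.  The fitted objective therefore adds a domain-confinement
   penalty `lambda (1 - mass inside D)` (`box_penalty`, default 1).  It is
   zero for any genuinely contained solution and never enters reported
   residuals.

2. **Basin allocation.**  Any convex combination of per-basin
   quasi-stationary densities is near-stationary, so the residual cannot
   identify the mixture weights; freely fitted weights drift to degenerate
   corners.  By default the weights stay at their initialized (uniform)
   values (`fit_weights = FALSE`).  This matches the packaged published fit,
   which reports no weights.  Relative well depths of the returned
   landscape are therefore determined by component shapes, not by an
   estimated basin mass -- a genuine limitation of the residual-collocation
   approach, inherited from the method itself.

3. **Well evacuation.**  A Gaussian proxy can never match a skewed gamma
   well, so at a sharp well its residual exceeds that of a proxy parked in
   flat low-density "limbo"; gradient refinement will happily drag
   components there.  The fit therefore locates the deterministic attractors
   first (`fpe_attractors()`: multi-start ODE integration of the drift,
   seeded with the Boolean fixed points mapped through
   `boolean_to_concentration()`), anchors one component per attractor, and
   confines the proxy stages to a trust region around the anchors
   (`anchor_radius`, default 5% of the domain span), with proxy variances
   windowed around the small-noise estimate
   `Gamma_j(p*) / (2 |da_j/dp_j|(p*))`.  Stage-3 modes respect the same
   trust region; shapes and spreads are free.

With these in place, refitting a *known* two-gene, two-component gamma
mixture from its own Fokker-Planck equation (constant diffusion, gradient
drift `a = (Gamma/2) d log P*/dp`, for which `P*` is exactly stationary)
recovers both modes to better than 0.01 and the density to `L1 ~ 0.01`
against the grid oracle, across seeds.

### What "mean |R| per collocation point" means -- and does not

The per-point average of `|R|` is the convergence figure the fit reports.
It is strongly scale-, dimension- and normalization-dependent: for the
12-gene model, almost every uniform point in `[0,10]^12` carries vanishing
density, so the scaled 12-gene fit reaches per-point levels below 1e-50
"for free", while on the 1-gene toy at `Omega = 50` the best *normalized*
single gamma cannot go below ~8e-3 (the exact stationary law is a shifted
gamma in `1 + p`, outside the ansatz family; the floor shrinks only like
`Omega^{-1/2}`).  Comparisons of this figure are meaningful only at fixed
dimension, domain and normalization convention.  Density-level accuracy is
better judged by the `L1` distance to a grid solution (1-D/2-D) or by
held-out simulation checks.

## The grid oracle

`grid_stationary()` is an independent low-dimensional solver used only for
verification: a flux-conservative Chang-Cooper finite-volume discretization
(exponential upwind weights, unconditionally positivity-preserving,
zero-flux boundaries) whose generator's null vector is solved sparsely.
It reproduces the Ornstein-Uhlenbeck stationary law to `L1 ~ 1e-8` and the
1-gene model's closed-form stationary density to `L1 < 5e-3`, and
cross-validates `simulate_langevin()` (long-run histograms agree to total
variation < 0.05).  It shares no derivative code with the residual module.

## Coexpression validation

`mixture_sample()` draws expression profiles from the fitted density
(default `1e5`), `pearson_matrix()` forms the model coexpression matrix
`M_m`, and `matrix_distance()` computes the Euclidean (Frobenius) distance
to an experimental matrix `M_e` over all `t^2` entries.  Significance is
judged against two sampled nulls (`null_distance_distributions()`):
distances between pairs of random correlation matrices, and distances
between `M_e` and random matrices.  Random correlation matrices are sample
correlations of `m_eff` i.i.d. standard-normal vectors (symmetric, PSD,
unit diagonal by construction); `m_eff` (default 100) tunes the null's
spread.  `validate_model()` reports `(r+1)/(n+1)` percentiles and a
three-way verdict at tail probability `q = 0.05`: below the lower quantile
of the experimental-vs-random null, "discriminated from random"; within,
"cannot be discarded"; beyond the upper quantile, "discard".  The quantile
policy is this package's explicit choice; the underlying comparison only
supports qualitative conclusions.

A useful structural fact (and test): with `M_e` the identity, random-vs-
random distances are `sqrt(2)` larger in mean than identity-vs-random ones,
because entrywise differences of two fluctuating matrices have twice the
variance of one.

Reproducing the published model-vs-experiment distance for the flower
network requires the external coexpression resource (ATTED-II); the package
never downloads data.  `read_coexpression_csv()` ingests such a matrix
(missing cells set to 0, asymmetry averaged, diagonal forced to 1), and the
whole comparison runs synthetically end-to-end via
`synthetic_coexpression()`.

## Choices made where the design was open

* **Monostability of the parsimonious translation.**  With every rate set
  to 1 and Hill exponent 1, the continuous 12-gene model is monostable:
  every multi-start ODE run converges to a single interior fixed point
  (regulator-free genes must sit at `alpha0/delta = 1` in any steady
  state).  The four components of the published fit persist because the
  protocol initializes one component per Boolean attractor and refines each
  locally -- the multimodal landscape reflects the Boolean structure through
  the initialization, not deterministic multistability of the translated
  ODEs.  The same holds for the two-gene mutual-repression toy, which is
  monostable at defaults; the package's bistable demonstrations use
  `alpha0 = 0, delta = 0.5, hill_n = 3` (attractors near (1.92, 0.44) and
  (0.44, 1.92)).
* **Factorized components cannot represent correlated wells.**  The
  bistable toggle's wells have within-well correlation about -0.7, placing
  a representational floor of `L1 ~ 0.5` on any diagonal gamma mixture.
  Per-component full covariance is out of scope; low-dimensional grid
  comparisons that probe *fitting* accuracy therefore use targets inside
  the ansatz family.
* **Sampling.**  Collocation is uniform over the box by default (unbiased
  for the residual integral); importance sampling from the current proxy is
  available (`sampling = "proxy"`).
* **Gradients** are central differences in the unconstrained
  parameterization (log shapes/rates, logit weights), exact for the
  incremental objective to ~1e-12 against brute-force differencing; no
  autodiff dependency.
* **Problem sizes.**  Shipped examples and tests run desk-scale: `1e4`
  collocation points and a few hundred optimizer steps (the full-scale
  protocol is `1e6` points), grids of 801 (1-D) / 101^2 (2-D) cells,
  `1e5`-sample coexpression matrices.  A full-scale 12-gene fit is a
  long-running job left to the user.
* **Numerical guards.**  Gamma parameters are clamped to `[1e-3, 1e4]`,
  Gaussian means to the domain box, proposal reflection at 0 in the SDE,
  `H(0) = 0` ties, modes of components with `alpha <= 1` reported as 0,
  zero-density landscape values as `+Inf`.

## What the synthetic tests do and do not show

The generators emulate multimodal, positively supported, factorized
expression densities with optional truncated Gaussian measurement noise.
They do not emulate mRNA/protein bursting (the Langevin white-noise
approximation is known to miss it), within-state regulatory correlation,
batch structure, or the condition-dependence of real coexpression
compendia.  Passing tests therefore certify the numerics and the internal
consistency of the pipeline -- not that the white-noise gamma-mixture model
is an adequate description of any particular organism's expression data.
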