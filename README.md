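# grnlandscape

Epigenetic landscapes of gene regulatory networks via the Fokker-Planck
equation.

## What it does, and for whom

For systems biologists who have a *qualitative* gene regulatory network
(GRN) — which genes activate or repress which — and want to connect it to
*quantitative* expression data, this package implements the full chain:

1. **Boolean layer** — synchronous threshold dynamics
   `x_i(t+1) = H(Σ_j w_ij x_j(t) − θ_i)` over an integer weight matrix `W`
   and thresholds `θ`; exhaustive fixed-point (attractor) enumeration.
2. **Continuous layer** — a parsimonious Hill-type ODE translation for
   protein concentrations,
   `dp_i/dt = N_i(p)/D_i(p) + α_{i,0} − δ_i p_i` with
   `D_i = 1 + |θ_i| + Σ_j |w_ij| p_j^n`, activators in the numerator and a
   basal term `1 + |θ_i|` for genes with `θ_i ≤ 0`; all unstated rates 1.
3. **Stochastic layer** — the chemical Langevin equation with diagonal
   diffusion `Γ_j = (B_j + δ_j p_j)/Ω` at system size `Ω`, its
   Euler–Maruyama simulator, and the associated stationary Fokker-Planck
   equation (FPE).
4. **Landscape fit** — the stationary density is approximated by a gamma
   mixture `P̂(p) = Σ_i A_i Π_j Gamma(p_j; α_ij, β_ij)` fitted by Monte
   Carlo weighted-residual collocation (minimize `∫_D |R(p)| dp` for the
   stationary-FPE residual `R`), in three stages: Gaussian-proxy global
   search, gradient refinement, gamma fine-tuning.  The epigenetic
   landscape is `U(p) = −log P̂(p)`; its minima are the cell states.
5. **Validation** — coexpression matrices from fitted-density samples
   (Pearson `ρ = σ_xy/(σ_x σ_y)`), the Euclidean matrix distance
   `d(M, N) = sqrt(Σ_s (m_s − n_s)²)` to an experimental matrix, and
   significance against two random-correlation-matrix null distributions.

The 12-gene *Arabidopsis thaliana* flower-morphogenesis network ships as a
fixture (`at_flower_network()`), together with its published 4-component
stationary-density fit (`at_table2_mixture()`).  Low-dimensional grid
solvers (`grid_stationary()`, Chang–Cooper scheme) serve as independent
oracles for everything.

## Worked example

```r
library(grnlandscape)
net <- at_flower_network()
nrow(boolean_fixed_points(net))        # 4 Boolean attractors

fpe <- fpe_model(continuous_model(net), omega = 50)
im  <- t(apply(boolean_fixed_points(net), 1,
               boolean_to_concentration, model = fpe$model))
fit <- fit_stationary(fpe, n_components = 4, init_means = im,
  control = fit_control(n_points = 1e4, stage1_trials = 20,
                        stage2_steps = 40, stage3_steps = 60,
                        val_points = 5000, seed = 1))
summary(fit)
```

```
4-component stationary density fit (12.1 s)
  mean |R| per point: 1.86e-54; residual norm: 1.86e-42
  component weights: 0.25 0.25 0.25 0.25
  modes:
      EMF1  TFL1   LFY   AP1   CAL   LUG   UFO   BFU    AG   AP3    PI   SUP
[1,] 0.189 0.188 0.501 0.501 0.421 0.501 0.501 0.501 1.696 0.188 0.191 0.190
[2,] 0.197 0.193 0.501 0.501 0.501 0.194 0.230 2.501 2.021 2.501 1.674 0.501
[3,] 0.449 0.289 0.501 2.490 0.501 0.345 0.230 0.501 0.501 0.375 0.501 0.193
[4,] 0.501 0.195 0.501 1.579 0.474 0.501 0.446 2.501 0.195 2.058 2.501 0.501
  mean concentration of active genes per attractor: 0.46 0.96 0.57 1
  landscape depth U at each mode: -5.961 -4.428 -6.099 -4.519
```

Each row of `modes` is one attractor of the fitted landscape: e.g.
component 2 has BFU, AG, AP3 and PI switched on — an organ-identity
expression state — while component 1 is the AG-dominated state.  The mean
`|R|` per collocation point is the fit's convergence figure (in 12
dimensions it is tiny because most uniform collocation points carry
vanishing density; see the methods vignette for why this number is only
comparable at fixed dimension).  `predict(fit, p, type = "landscape")`
evaluates `U`, `simulate(fit, 1e5)` draws expression profiles, and

```r
M_m <- pearson_matrix(simulate(fit, 1e5, seed = 1))
# validate_model(M_m, M_e)   # M_e: experimental coexpression CSV
```

compares them against experimental coexpression data; with a synthetic
`M_e` drawn from a known mixture the verdict is "cannot be discarded", and
`M_m = M_e` gives distance 0 and "discriminated from random".

The published flower-morphogenesis fit can be inspected without refitting:

```r
active_gene_summary(at_table2_mixture())
#> 1.935760 2.557274 1.816883 1.932290      # printed: 1.9 2.5 1.8 1.9
```

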