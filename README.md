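# patchsde

Stochastic population dynamics in patchy environments: persistence,
extinction, and the stochastic growth rate.

## The problem

A population lives on `n` habitat patches coupled by dispersal. Each
patch has its own mean per-capita growth rate, its own intraspecific
competition, and its own environmental fluctuations — which may be
correlated across patches, up to the fully degenerate case where a
single environmental driver (one Brownian motion) hits every patch at
once. The abundances follow the coupled SDE system

    dX_i = ( X_i (a_i − b_i(X_i)) + Σ_j D_ji X_j ) dt + X_i dE_i(t)

with `D` a dispersal matrix (nonnegative off-diagonal per-capita
movement rates, zero row sums, irreducible), `b_i` competition functions
vanishing at 0, and noise `E = Γᵀ B` with covariance `Σ = ΓᵀΓ`.

Whether such a population persists or goes extinct is decided by a
single number: the **stochastic growth rate**

    r = ∫_Δ ( aᵀy − ½ yᵀΣy ) ν*(dy),

the Lyapunov exponent of the total population in the absence of
competition, where `ν*` is the stationary law of the proportion process
`Ỹ` on the simplex. If `r > 0` the abundances converge to a unique
invariant distribution on the open orthant; if `r < 0` every patch goes
extinct exponentially fast at rate `r`. For one patch this reduces to
the classical trichotomy in `a − σ²/2`.

The package is aimed at theoretical ecologists studying source–sink and
metapopulation dynamics under environmental stochasticity, and provides:

* model constructors with the admissibility checks the theory requires
  (dispersal irreducibility, competition growth bounds, noise rank);
* seeded Euler–Maruyama integrators for the abundance system, its
  proportion/log-total decomposition `(Y, ln S)`, the competition-free
  simplex process, and the linearized system;
* four routes to `r`: the single-patch formula, Monte Carlo time
  averaging, quadrature against the explicit two-patch stationary
  density (built from the scale/speed construction, covering
  independent, partially correlated and perfectly correlated noise),
  and closed forms for the noiseless-proportion case, including the
  large-dispersal approximation `r ≈ (a1+a2)/2 − σ²/2 + (a1−a2)²/(8α)`;
* diagnostics that make the theory executable: persistence
  classification, occupation of the extinction boundary, extinction-rate
  recovery from log-abundance slopes, synchronization on the degenerate
  diagonal manifold, the infinite-dispersal (eigenweight) limit, and
  robustness under bounded (`θ`) model perturbations.

A central scientific point the package reproduces: under perfectly
correlated noise, dispersal *decreases* `r` (mixing reduces growth — the
reduction principle), so coupling two sink patches can never rescue the
population; with independent noise, dispersal can increase `r`.

## Worked example

Two patches with growth rates `a = (3, 4)`, equal noise intensities
`σ² = 7` and symmetric dispersal `α = 1`. Each patch alone is a sink
(`a_i − σ²/2 < 0`). Under one shared Brownian motion (`ρ = 1`) the
proportion process is noiseless and `r` has a closed form:

```r
library(patchsde)
spec <- two_patch_spec(a1 = 3, a2 = 4, d12 = 1, d21 = 1,
                       sigma1 = sqrt(7), sigma2 = sqrt(7), rho = 1)
model <- make_two_patch(spec)
model
#> Patch population model (2 patches)
#>   growth rates a:  3, 4
#>   competition:     linear, kappa = 1, 1
#>   noise:          rank(Sigma) = 1  [degenerate]

res <- stochastic_growth_rate(model)
res
#> r = 0.118034  [closedform_equal_sigma]
classify_persistence(res)
#> PERSISTENT (r = 0.118, band +/- 0.001)
```

`r = (a1+a2−2α+√((a1−a2)²+4α²))/2 − σ²/2 = (5+√5)/2 − 7/2 ≈ 0.118 > 0`:
two sinks coupled by weak dispersal persist here because the growth
heterogeneity (`a1 ≠ a2`) keeps the proportion equilibrium
(`y* = (3−√5)/2 ≈ 0.382`) weighted toward the better patch. Raising `α`
pulls `r` down toward `(a1+a2)/2 − σ²/2 = 0`: strong mixing destroys the
advantage.

With independent noise (`ρ = 0`) the quadrature route applies, and the
Monte Carlo time average over the simplex process confirms it:

```r
m0 <- generate_fixture("two_patch_het", rho = 0)
stochastic_growth_rate(m0)
#> r = 1.31872  [quadrature_2p]
r_mc_timeaverage(m0, T = 1000, burn_in = 100, replicates = 16,
                 dt = 1e-3, seed = 1)
#> r = 1.31675 (se 0.00189)  [mc_timeaverage]
```

Independent fluctuations are much kinder to the population than a
shared driver: averaging over patches cancels noise (`r = 1.32` versus
`0.12`).

A thin command-line wrapper ships in `inst/cli/patchsde`:

```sh
patchsde growth-rate --fixture two_patch_het --rho 1 --alpha 1
patchsde scan --fixture two_patch_het --alpha-grid 0.5:16:6:log \
              --rho-grid 0,0.5,1 --out scan.csv
```

## The methods vignette

`vignettes/patch-persistence.Rmd` documents the model and its
assumptions, the derivation of the two-patch stationary density by the
scale/speed construction (with the exponent constants used here), the
numerical choices (schemes, step sizes, tolerances, degenerate-case
thresholds) and the known limitations.
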