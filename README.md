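# nmsis — non-Markovian SIS epidemics on networks

Real spreading processes rarely have exponentially distributed waiting
times: infection attempts and recovery events cluster, age, and carry
memory. `nmsis` is an R toolkit for
susceptible–infected–susceptible (SIS) dynamics on static networks where
the infection and recovery times follow arbitrary laws (Weibull,
Beta(1, γ), exponential). It is written for computational
epidemiologists and network scientists who want to ask: *when does a
non-Markovian epidemic behave exactly like a Markovian one, and how wrong
is the Markovian surrogate when it doesn't?*

The package provides four coordinated pieces:

1. **Waiting-time laws** — density ψ, survival Ψ, hazard ω = ψ/Ψ,
   inverse-survival samplers and Laplace transforms
   (`wt_weibull()`, `wt_beta()`, `wt_exponential()`).
2. **An exact event-driven simulator** (`sis_simulate()`,
   `sis_ensemble()`; C++ core) — a min-heap of absolute event times, no
   time discretization, supporting two edge-activation mechanisms:
   *type-I*, where a directed edge i←j carries a transmission clock only
   while j is infected **and** i is susceptible, and *type-II*, where the
   clock runs whenever j is infected and re-arms after each firing.
3. **An age-structured mean-field integrator** (`mean_field_sis()`) for
   the transient dynamics: per-node densities I_i(τ; t), S_i(τ; t) over
   the state age τ evolve by transport in age with recovery-hazard decay
   and an infection pressure Φ_{i←j} built from the neighbors' infection-age
   profiles — ω_inf[min(τ, τ′)] under type-I, the renewal intensity η(τ′)
   under type-II.
4. **Steady-state theory** — the effective recovery rate
   δ_eff = 1/∫Ψ_rec, the effective infection rate
   λ_eff = ∫η(τ)Ψ_rec(τ)dτ (expected transmissions per infectious period
   along one edge), the quenched mean-field fixed point
   Ĩ_i = λ_eff(1−Ĩ_i)Σ_j a_ij Ĩ_j with outbreak threshold
   λ_c = 1/Λ_max, and, for type-I, the asymptotic series in the inverse
   neighborhood pressure whose coefficients ϑ⁽ⁿ⁾(0) come from power-series
   reversion of Ω(τ) (`omega_theta()`, `type1_fixed_point()`).

Under type-II activation the stationary state of the non-Markovian
process maps onto a Markovian SIS with rates
(λ_eff·δ_eff, δ_eff) — an exact statement at the first-order mean-field
level. Under type-I the map is only approximate, improving with the
neighborhood infection pressure; `markovian_reference()` builds the
surrogate process for either case.

Results come back as tibbles (`time`/`infected`, sweep tables), fitted
steady states have `tidy()`/`glance()` methods, and `autoplot()` gives
quick ggplot2 views.

## Worked example

Weibull recovery with shape 2 and scale 0.5 (mean infectious period
0.443), Weibull infection with shape 2 and scale 1, on an
Erdős–Rényi graph with N = 1000 and mean degree 10:

```r
library(nmsis)

g   <- generate_network("er", n = 1000, mean_degree = 10, seed = 1)
rec <- wt_weibull(2, 0.5)
inf <- wt_weibull(2, 1)

epidemic_threshold(g)
#> [1] 0.08949284

effective_rates(inf, rec)
#> <effective rates>
#>   delta_eff      : 2.256758
#>   lambda_eff     : 0.2165745
#>   lambda_eff_star: NA

ens <- sis_ensemble(g, "type2", inf, rec, rho0 = 0.1, t_max = 40,
                    n_realizations = 10, seed = 42)
ensemble_stationary(ens, burn_in = 20)
#> # A tibble: 1 × 3
#>    mean       se n_realizations
#>   <dbl>    <dbl>          <int>
#> 1 0.547 0.000958             10

qmf_fixed_point(g, lambda_eff_type2(inf, rec))
#> <quenched mean-field stationary state>
#>   lambda: 0.2165745  threshold: 0.08949284
#>   network density: 0.5361256 (converged)
```

Reading the numbers: the spectral outbreak threshold of this graph is
λ_c ≈ 0.089; the chosen laws give an effective infection rate
λ_eff ≈ 0.217 ≈ 2.4 λ_c, i.e. a clearly supercritical epidemic. The
simulated stationary infected density (0.547 ± 0.001) sits close to the
Markovian mean-field solution at the same effective rate (0.536); the
residual ~2% is the combination of first-order closure bias and the
infection-age correlations that the effective-rate map ignores.
(`lambda_eff_star` is `NA` here because the shape-2 Weibull hazard
vanishes at age 0, so the type-I inverse series does not exist; with a
Beta(1, γ) infection law `effective_rates()` also reports
λ*_eff = γ/δ_eff and the ϑ⁽ⁿ⁾(0) sequence.)

`mean_field_sis(g, "type1", inf, rec, rho0 = 0.01, t_max = 12)` produces
the matching theoretical transient for either mechanism, and
`run_experiment()` drives the full comparison designs (transient
agreement, the type-II equivalence sweep, the type-I approximate
equivalence sweep, threshold checks) with seeded, reproducible output
tables.

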