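---
title: "Methods: non-Markovian SIS dynamics, mean-field theory and Markovian equivalence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: non-Markovian SIS dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models it implements,
the numerical choices behind them, and what the test suite does and does
not establish.

## The model

SIS dynamics on a simple undirected graph with adjacency matrix
$a_{ij}$. Each node is susceptible (S) or infected (I). Waiting times
are general: an infected node recovers after a random time drawn from a
recovery law $\psi_{\mathrm{rec}}$, and an *active* directed edge
$i \leftarrow j$ transmits after a random time drawn from an infection
law $\psi_{\mathrm{inf}}$. The corresponding survival functions
$\Psi(x)$ and hazards $\omega(x) = \psi(x)/\Psi(x)$ carry the memory:
for the exponential law the hazard is constant and the process is
Markovian; for a Weibull law with shape $\alpha \ne 1$ or a
Beta$(1,\gamma)$ law the hazard ages.

Two activation mechanisms decide when an edge carries a transmission
clock:

* **type-I** — $i \leftarrow j$ is active iff $j$ is infected *and* $i$
  is susceptible. Any state change at either end resets or removes the
  clock: susceptible-side state changes matter.
* **type-II** — $i \leftarrow j$ is active iff $j$ is infected,
  regardless of $i$; after each firing the clock re-arms at age zero.
  Transmissions toward an already-infected target are wasted.

With exponential infection times the two mechanisms define the same
process in law. Otherwise they differ, and the difference is exactly
what decides whether a Markovian surrogate exists.

### Age-structured mean field

The transient theory tracks, per node, densities $I_i(\tau;t)$ and
$S_i(\tau;t)$ over the *state age* $\tau$ (time since the node entered
its current state), assuming ages of adjacent nodes are independent
(first-order closure; no pair correlations). Infected mass is advected
in age and decays with the recovery hazard; susceptible mass decays with
the neighborhood infection pressure
$\sum_j a_{ij} \Phi_{i \leftarrow j}(\tau;t)$, where

* type-I: $\Phi_{i \leftarrow j}(\tau;t) = \int_0^\infty
  \omega_{\mathrm{inf}}[\min(\tau,\tau')] \, I_j(\tau';t)\,d\tau'$ — the
  active edge is as old as the younger endpoint;
* type-II: $\Phi_{i \leftarrow j}(t) = \int_0^\infty \eta(\tau')
  I_j(\tau';t)\,d\tau'$ — $\eta$ is the renewal intensity of the
  infection law (the expected firing rate of an edge whose source has
  been infected for time $\tau'$), the solution of the Volterra equation
  $\eta(\tau) = \psi_{\mathrm{inf}}(\tau) + \int_0^\tau
  \eta(\tau')\psi_{\mathrm{inf}}(\tau-\tau')\,d\tau'$.

All recovered and newly infected mass re-enters at age zero, so per-node
total probability is conserved.

### Steady state and effective rates

At stationarity the age profiles factorize
($\tilde I_i(\tau) \propto \Psi_{\mathrm{rec}}(\tau)$) and the theory
collapses to scalar fixed points. Two numbers summarize the laws:

* $\delta_{\mathrm{eff}} = 1/\int_0^\infty \Psi_{\mathrm{rec}}$, the
  reciprocal mean infectious period;
* $\lambda_{\mathrm{eff}} = \int_0^\infty \eta(\tau)
  \Psi_{\mathrm{rec}}(\tau)\,d\tau$, the expected number of transmission
  attempts per infectious period along one edge.

Under type-II the stationary equations become exactly the quenched
mean-field (QMF) equations of a Markovian SIS with rates
$(\lambda_{\mathrm{eff}}\delta_{\mathrm{eff}}, \delta_{\mathrm{eff}})$:
$\tilde I_i = \lambda_{\mathrm{eff}} \tilde S_i \sum_j a_{ij} \tilde
I_j$, with outbreak threshold $\lambda_c = 1/\Lambda_{\max}$.

Under type-I the stationary relation is a series in the inverse
neighborhood pressure $1/\sum_j a_{ij}\tilde I_j$ with coefficients
$\delta_{\mathrm{eff}} \vartheta^{(n)}(0)$, where $\vartheta$ is the
inverse function of
$\Omega(\tau) = \delta_{\mathrm{eff}} \int_0^\tau \int_0^{+\infty}
\omega_{\mathrm{inf}}[\min(\tau',\tau'')]\Psi_{\mathrm{rec}}(\tau')
\,d\tau'\,d\tau''$. The leading coefficient defines
$\lambda^*_{\mathrm{eff}} = 1/[\delta_{\mathrm{eff}}\vartheta^{(1)}(0)]
= \omega_{\mathrm{inf}}(0)/\delta_{\mathrm{eff}}$; with constant
infection hazard all higher coefficients vanish and
$\lambda_{\mathrm{eff}} = \lambda^*_{\mathrm{eff}}$ exactly. Scaling a
Beta$(1,\gamma)$ hazard by $\theta$ scales $\Omega$ pointwise by
$\theta$ and each $\vartheta^{(n)}(0)$ by $\theta^{-n}$, which shifts
the series along the $\lambda_{\mathrm{eff}}$ axis without changing its
shape — the reason the approximate equivalence improves as $\gamma$ (and
with it the infected density) grows.

## Parameters that matter

| Parameter | Meaning | Default / typical |
|---|---|---|
| $\alpha_I, \beta_I$ | Weibull infection shape (dimensionless) and scale (time) | sweeps use $\alpha_I \in \{0.5, 1, 2, 4\}$, $\beta_I = 1$ or solved from a target $\lambda_{\mathrm{eff}}$ |
| $\alpha_R, \beta_R$ | Weibull recovery shape and scale | $\alpha_R = 2$, $\beta_R = 0.5$ (mean 0.443, $\delta_{\mathrm{eff}} = 2.257$) |
| $\gamma$ | Beta$(1,\gamma)$ infection shape; hazard $\gamma/(1-\kappa)$, support $[0,1)$ | type-I sweeps |
| `rho0` | initial infected fraction, ages zero | 0.01 for transients; 0.1 for stationary sweeps (see below) |
| `delta` | age/time step of the mean-field grid | 0.02 |
| `t_max`, burn-in | horizon and discarded prefix for stationary averages | 60 / 30 |

## Numerical choices

* **Event-driven simulator (C++).** A binary min-heap over absolute
  event times with lazy invalidation: every node/edge keeps a version
  counter, bumped on each state change; stale heap entries are skipped
  on pop. Ties break by (time, recovery-before-transmission, entity id),
  making runs bit-reproducible given the seed. Waiting times are sampled
  by inverting the survival function in closed form
  ($\kappa = \beta(\ln 1/u)^{1/\alpha}$ for Weibull,
  $\kappa = 1 - u^{1/\gamma}$ for Beta). An optional audit pass
  re-derives the active-edge predicate from the node states every 1000
  events and aborts on any inconsistency.
* **Ensembles** average unconditionally: realizations that go extinct
  keep contributing zeros. Survival conditioning is deliberately not the
  default, so decay to extinction is visible in subcritical ensembles.
* **Renewal equation.** Rather than discretizing the Volterra equation
  on the density (which diverges at age 0 for Weibull shape < 1 — a case
  the standard experiment grid includes), the equivalent
  renewal-function equation $M(t) = F(t) + \int_0^t M(t-s)\,dF(s)$ is
  solved in midpoint Riemann–Stieltjes form using only the cdf; the
  intensity is recovered as cell averages of $dM$. The scheme is
  second order for smooth laws, and $\lambda_{\mathrm{eff}}$ adds one
  Richardson extrapolation in the step, reaching ~1e-7 relative accuracy
  in closed-form cases (doubly exponential, $\eta \equiv 1$).
* **Mean-field grid.** Cell-centered ages with step `delta` (= the time
  step; ages and time advance together). Center evaluation keeps all
  hazards finite: Weibull shape < 1 diverges only at exactly 0, the Beta
  hazard only at exactly 1 (where the argument of
  $\omega_{\mathrm{inf}}[\min(\cdot)]$ is capped half a cell inside the
  support). The grid extends to where
  $\Psi_{\mathrm{rec}} < 10^{-8}$; mass aging past the end pools in the
  terminal cell.
* **Transport.** Infected mass decays by the *exact* survival ratio
  $\Psi_{\mathrm{rec}}(\tau + \Delta)/\Psi_{\mathrm{rec}}(\tau)$ rather
  than a first-order hazard factor (unconditionally stable, exact for
  pure decay); susceptible mass by $\exp(-\Phi\Delta)$. Boundary inflows
  equal the outflows, so conservation is exact to rounding. Two
  second-order refinements matter in practice: a Heun step (pressure
  re-evaluated on a predictor field and averaged), and a *newborn
  half-step exposure* — mass that changes state mid-step is decayed by
  the opposite hazard over half a step before entering the age-0 cell,
  with the complement routed back. Without the latter the stationary
  state carries an $O(\Delta)$ bias of order (pressure × Δ/2), clearly
  visible at step 0.02; with it the integrator converges at second order
  onto the QMF fixed point in the Markovian limit.
* **Type-I pressure cost.** The $\min(\tau,\tau')$ kernel is evaluated
  with prefix/suffix cumulative sums of the aggregated neighbor field
  ($O(E \cdot \text{bins})$ per step); a brute-force double loop backs
  it as a test oracle.
* **$\Omega$ and $\vartheta^{(n)}(0)$.** The Taylor coefficients of
  $\Omega$ at 0 are computed analytically — writing $\Omega' =
  \delta_{\mathrm{eff}} g$ with $g'(u) = \omega_{\mathrm{inf}}'(u)
  \int_u^\infty \Psi_{\mathrm{rec}}$, every derivative at 0 reduces to
  closed-form hazard derivatives of the infection law and density
  derivatives of the recovery law — and $\vartheta^{(n)}(0)$ follows by
  exact power-series reversion. Finite differences were rejected: at
  order 10–12 they are numerically meaningless in double precision.
  The construction requires laws smooth at age 0 (Beta, exponential,
  integer-shape Weibull); others raise an error rather than returning a
  silently wrong expansion. A hazard vanishing at 0 (Weibull shape ≥ 2)
  makes $\Omega'(0) = 0$ and the inverse series does not exist; this is
  reported, not worked around.
* **The type-I series is asymptotic**, not convergent: the
  $\vartheta^{(n)}(0)$ grow factorially. The fixed-point solver
  therefore sums each node's series to its smallest term (optimal
  asymptotic truncation, capped at `n_max = 10`) and flags nodes whose
  smallest term still exceeds 1% of the sum — the low-pressure /
  small-degree regime where the expansion is known to break down. If
  every node is flagged the solver refuses with an error. This flagging
  policy is the package's own choice; the theory itself gives no
  prescription for the divergent regime.
* **Scale inversion.** Sweeps are parameterized by
  $\lambda_{\mathrm{eff}}$ and solve for $\beta_I$ by monotone root
  bracketing around the mean-matched guess, to 1e-12.
* **Eigenvalue.** Power iteration on $A + I$ (the shift removes the
  $\pm\Lambda_{\max}$ degeneracy of bipartite graphs such as stars) with
  a Rayleigh-quotient stop at 1e-8 relative tolerance.

## What the generators emulate — and what they do not

Study networks are generated internally: Erdős–Rényi $G(N, p)$ with
$p = \langle k\rangle/(N-1)$, Barabási–Albert with $m$ attachments,
power-law configuration-model graphs with a structural cutoff, random
regular graphs; arbitrary real networks enter as whitespace edge lists.
Transient comparisons run at $N = 1000$, 50 realizations, 1% seeds with
zero initial age; stationary sweeps at $N = 1000$ (ER) or $N = 500$
(10-regular), 8–10 realizations of horizon 60 with burn-in 30. These
sizes keep the full suite at desk scale; the generators accept larger
$N$ and realization counts to restore a full-size study. Stationary
sweeps start at `rho0 = 0.1` rather than 1%: the stationary estimate is
independent of the initial condition, and the larger seed fraction
avoids spurious early extinctions near threshold at these sizes — a
property of the estimator, not of the dynamics.

Synthetic networks are static, simple and uncorrelated; the simulator
does not model degree–degree correlation, clustering beyond what the
generators produce, temporal networks, or SIR/SEIR compartments. Tests
passing on these graphs say nothing about adaptive or weighted contact
structures.

## Known limitations, honestly measured

The test suite distinguishes three levels of agreement, and it is worth
being explicit about them:

* **Theory-internal identities** (renewal limits, closed-form
  $\lambda_{\mathrm{eff}}$, QMF fixed points, conservation, series
  scaling) hold to 1e-5 or better and are asserted at those tolerances.
* **Theory vs simulation, Markovian case**: the two mechanisms are
  equivalent in law and their ensembles are statistically
  indistinguishable; the integrator matches an independent ODE solution
  of the QMF equations to its discretization order.
* **Theory vs simulation, non-Markovian case**: the first-order closure
  carries a genuine bias. The mean-field transient tracks the
  50-realization ensemble mean everywhere within the realization spread
  (3 standard deviations), but *not* within 3 standard errors of the
  mean at late times — no first-order theory can, once the Monte-Carlo
  error is pushed below the closure bias (~1e-2 in density). Likewise,
  the type-II "exact equivalence" is exact at the mean-field level only:
  measured stationary densities at $N = 1000$ sit a few times $10^{-2}$
  below (heavy-tailed $\alpha_I = 0.5$) or above ($\alpha_I = 2$) the
  Markovian surrogate — infection attempts cluster just after edge
  resets, when the local neighborhood is atypically infected, an
  age–age correlation outside the theory. At $\alpha_I = 1$ the laws
  coincide microscopically and the gap vanishes within noise. The
  acceptance tests assert the strict statistical bands and therefore
  record these closure effects as failures by design; the module tests
  assert the scientifically meaningful bands.

A second-order (pairwise) closure would capture the missing
correlations; it is outside this package's scope.
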