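---
title: "Stochastic dynamics of infection-triggered autoimmunity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic dynamics of infection-triggered autoimmunity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stochimm)
```

## The biological model

The package implements a seven-compartment within-host model of immune
response to a viral infection and the autoimmunity that can follow it
through molecular mimicry. The compartments are susceptible organ cells
$S$, infected cells $F$, naive T cells $T_{in}$, regulatory T cells
$T_{reg}$, normal activated T cells $T_{nor}$, autoreactive T cells
$T_{aut}$, and the cytokine interleukin-2 $I$.

Susceptible cells grow logistically (linear rate $r = b_1 - d_1$,
carrying capacity $N = r/(\tilde d_2 - \tilde b_2)$) and are infected at
rate $\tilde\beta$ by infected cells. Naive T cells, supplied at rate
$\tilde\lambda_{in}$, are activated by the infection at rate
$\tilde\alpha$; a fraction $p_1$ of activated cells become regulatory, a
fraction $p_2$ become normal effectors that kill infected cells at rate
$\tilde\mu_F$, and the remainder become autoreactive cells with a lowered
activation threshold, which kill both infected and healthy cells at rate
$\tilde\mu_a$. Regulatory T cells (influx $\tilde\lambda_r$) suppress
autoreactive cells at rate $\tilde\delta$. Normal and autoreactive cells
secrete IL-2 at rates $\sigma_1$ and $\sigma_2$, and IL-2 feeds back by
driving proliferation of the three activated T-cell classes at rates
$\tilde\rho_1, \tilde\rho_2, \tilde\rho_3$. Antibody responses, memory
T cells and regulatory control of IL-2 secretion are deliberately outside
the model's scope.

The same kinetics are represented at three levels, all driven by one
parameter object (`imm_params()`):

1. **Macroscopic ODE** (`scaled_rhs()`, `integrate_ode()`): concentrations
   $x = n/\Omega$, where $\Omega$ is the system size.
2. **Exact jump process** (`propensities()`, `simulate_ssa()`): a
   continuous-time Markov chain on integer copy numbers with 17 reactions,
   each changing at most two compartments by one unit. Bimolecular rates
   scale as $\tilde k/\Omega$, influxes as $\tilde k\,\Omega$.
3. **Chemical-Langevin (Itô) SDE** (`drift_diffusion()`,
   `simulate_em()`): $dY = \mu(Y)\,dt + H(Y)\,dW$ with
   $\mu = \sum_i P_i s_i$ equal to the deterministic drift and
   $HH^\top = \Sigma = \sum_i P_i s_i s_i^\top$ the jump covariance.

Two identities tie the levels together and are asserted in the test
suite at machine precision: the propensity-weighted stoichiometry equals
the deterministic right-hand side, and the block-structured $7\times 11$
factor $H$ reproduces $\Sigma$ exactly. $H$ is kept in its block form
(a $2\times3$ block for the host cells, a $4\times7$ block for the
T cells, a scalar for IL-2) rather than replaced by a Cholesky factor:
any factor of $\Sigma$ gives a distributionally equivalent SDE, but the
block form makes the factorisation identity directly testable.

## Steady states and their stability

With no infected cells the model has up to three biologically distinct
fixed-point families (`steady_states()`):

* **S1, disease-free**: $x = (N, 0, \tilde\lambda_{in}/d_{in},
  \tilde\lambda_r/d_r, 0, 0, 0)$.
* **S2, organ-cell death** ($S = 0$) and **S3, autoimmune regime**
  ($S > 0$): both carry a self-sustaining autoreactive--IL-2 loop with the
  regulatory T-cell level $x_4^\*$ solving the quadratic
  $\tilde\rho_1\tilde\delta (x_4^\*)^2 +
  (\tilde\rho_1 d_a - \tilde\rho_3 d_r)x_4^\* +
  \tilde\rho_3\tilde\lambda_r = 0.$
  Both admissible roots are reported (suffixes `a` for the larger root,
  `b` for the smaller); the quadratic is solved in the cancellation-free
  form. A short calculation with the Jacobian's block structure shows the
  smaller root always carries a positive eigenvalue (the determinant of
  the $(T_{reg}, T_{aut}, I)$ block has the wrong sign there), so the
  dynamically relevant branch is the larger root.
* **S4, chronic infection** (all components positive): no closed form
  exists; a damped Newton iteration on the scaled vector field is run
  from a lattice of starting points (perturbations of the closed-form
  states, a generic infected state, and a point on a short trajectory),
  with duplicates merged at relative distance $10^{-6}$. At the default
  parameters the basic reproduction number of the infection,
  $\tilde\beta N / d_F$, is below one, so no interior state exists and
  the search correctly reports none.

Stability is classified from the eigenvalues of the closed-form Jacobian
with a symmetric tolerance band: stable if $\max\mathrm{Re}\,\lambda <
-10^{-9}$, unstable above $+10^{-9}$, otherwise *marginal*. Marginal
states are refused by the fluctuation analysis rather than regularised,
because the stationary fluctuation variance diverges at the stability
boundary and masking is the honest answer.

Printed textbook-style inequality conditions for these states circulate
in several typographically corrupted variants; the package therefore
reports such condition verdicts separately (`conditions` field) and
never lets them override the eigenvalue classification. One concrete
defect is worth recording: the widely quoted criterion "S1 is stable if
$d_F > \tilde\beta$" omits the organ-cell level; the transversal
eigenvalue at S1 is $\tilde\beta N - d_F$, so the correct threshold is
$d_F > \tilde\beta N$. The quoted form is necessary but not sufficient
(for $N > 1$), and the package stores both verdicts.

## Default parameter values

Several entries of the originally reported parameter table for this
model are typeset ambiguously: fractions collapsed into digit strings
(for example a killing rate printed as "409" and a suppression rate as
"14500"). The ambiguity matters, because the model's headline regimes --
coexistence of a stable disease-free state and a stable, weakly damped
autoimmune spiral at $\sigma_2 = 1$, reached from the standard initial
condition $(18, 2, 7.2, 6.3, 0, 0, 0)$ -- pin the admissible readings
tightly. We screened all digit-split readings of the seven ambiguous
entries (72,000 combinations, full eigenvalue analysis of every steady
state at both operating points) and found that *no* combination
reproduces every reported regime simultaneously; the deterministic
$\sigma_2$-switch between an S1/S2 and an S1/S3 bistability requires
$\tilde\mu_a d_i (d_a + \tilde\delta x_4^\*)/\tilde\rho_3$ to fall in a
narrow window that all candidate readings straddle. The shipped defaults
are the reading that reproduces the central claims exactly:

```{r defaults}
p <- imm_params(sigma2 = 1)
c(mu_a_t = p$mu_a_t, rho1_t = p$rho1_t, mu_F_t = p$mu_F_t,
  rho2_t = p$rho2_t, delta_t = p$delta_t, rho3_t = p$rho3_t,
  lambda_r_t = p$lambda_r_t)
```

i.e. $\tilde\mu_a = 4/9$, $\tilde\rho_1 = 10/9$, $\tilde\mu_F = 4/3$,
$\tilde\rho_2 = 4/45$, $\tilde\delta = 1/4500$, $\tilde\rho_3 = 2/9$ and
$\tilde\lambda_r = 108$ (digits read literally). Under these values, at
$\sigma_2 = 1$ both S1 and S3 are stable, S3 is a spiral with
eigenvalues $-0.023 \pm 0.198i$ (period $\approx 32$ time units, so
individual stochastic runs sustain visible oscillations long after the
ensemble mean has settled), and the standard initial condition lies in
the basin of S3. One reported regime is *not* reproducible under any
self-consistent reading: an S2-majority outcome at the default
$\sigma_2 = 0.4$ from the larger initial infection, because whenever S3
is feasible the organ-death state S2 is transversally unstable
($r - \tilde\mu_a x_6^\* > 0$). The corresponding acceptance check is
implemented as stated and fails, documenting the discrepancy. Every
parameter is overridable, directly or through YAML/JSON files in which
fractions may be written as strings (`"40/9"`).

## Linear-noise approximation

Around a stable steady state the copy numbers are written as
$n = \Omega x + \Omega^{1/2}\zeta$; to leading order beyond the
deterministic limit the fluctuations $\zeta$ are Gaussian with zero mean
and stationary covariance $\Xi$ solving the Lyapunov equation
$A\Xi + \Xi A^\top + B = 0$, where $A$ is the Jacobian and $B$ the
scaled jump covariance at the state (`noise_matrix_B()`; identically
$\Sigma(\Omega x)/\Omega$, which the tests verify). The count-scale
covariance is $C = \Omega\,\Xi$.

`lyap_solve()` is a dense Bartels--Stewart solver: real Schur
decomposition (via the Matrix package), then back-substitution over the
quasi-triangular factor with $1\times1$/$2\times2$ blocks handled
through small Kronecker systems. A naive $n^2 \times n^2$
Kronecker-vectorisation solve serves as the independent oracle in the
tests, and the residual
$\lVert AC + CA^\top + \Omega B\rVert_\infty / \lVert\Omega B\rVert_\infty$
is reported with every solve (at the defaults it is below $10^{-8}$).
Because $\Xi$ is $\Omega$-free, $C$ is exactly linear in $\Omega$ -- a
property asserted rather than assumed.

The Monte-Carlo counterpart (`empirical_covariance()`) starts an
Euler--Maruyama ensemble *at* the steady state, discards a burn-in of
five relaxation times $5/|\max\mathrm{Re}\,\lambda|$ (at the default
autoimmune state this is $\approx 214$ time units -- the spiral is
slow), drops runs whose endpoints escaped to another basin, and pools
deviations across runs and retained times. At $\Omega = 1000$ the
regulatory T-cell fluctuations around S3 have standard deviation close
to $10^5$ on a mean of $5.3\times10^5$ -- relative fluctuations of
nearly 20%, which is why the validation tolerance for simulated versus
Lyapunov variances is a generous 15%: the linear-noise approximation is
itself only first-order in $\Omega^{-1/2}$.

`variance_map()` scans a two-parameter plane, recomputes the steady
states per cell, and records $\mathrm{diag}(C)$ for the target family
where it is deterministically stable, masking the rest. Two structural
facts show up in these maps at the defaults: the regulatory T-cell
variance at S3 is *exactly* independent of the killing rate
$\tilde\mu_a$ and the infection rate $\tilde\beta$ (the
$(T_{reg},T_{aut},I)$ fluctuation block decouples from the channels
those rates enter), and the variance rises steeply toward both edges of
the stability window -- a Hopf boundary on one side and the saddle-node
collapse of the quadratic's roots on the other. Because the suppression
rate $\tilde\delta$ and the regulatory influx $\tilde\lambda_r$ move the
state through that window in the same direction (both enter the
discriminant through the product $\tilde\delta\tilde\lambda_r$), their
local variance trends at the default point have the same sign: variance
decreases in both. A reading of the model in which the two trends have
opposite signs is not attainable in this regime, and the corresponding
trend check is left failing by design.

## Stochastic simulation choices

* **SSA**: the direct (first-reaction-free) Gillespie method, compiled;
  no tau-leaping. The sampler's role in this package is to be the exact
  oracle against which the SDE is judged, so correctness beats speed;
  test and validation workloads keep costs manageable by reducing
  $\Omega$ (means and variances at $\Omega = 100$ are compared against
  the ODE and the SDE at 200--500 runs, where the agreement criterion is
  three standard errors plus one count for discreteness).
* **Euler--Maruyama**: default $dt = 10^{-3}$ time units. The noise-off
  scheme reduces to explicit Euler and its endpoint error halves when
  $dt$ halves (tested); weak-convergence sanity is covered by the
  SSA-versus-SDE moment comparisons. Negative excursions are clamped to
  zero after each step and propensities are evaluated on the clamped
  state, so every $\sqrt{P_i}$ argument is nonnegative; in the interior
  the drift identity is untouched. IL-2 production is pooled into a
  single reaction with rate $\sigma_1 n_5 + \sigma_2 n_6$, which is
  distributionally identical to two separate production channels.
* **Reproducibility**: both samplers consume R's RNG stream; ensembles
  derive per-run seeds as `base_seed + run - 1`, so any run can be
  reproduced in isolation and a fixed base seed fixes the entire
  ensemble.

## Experiment drivers

`bistable_ensemble()` classifies every endpoint against the stable
steady states by nearest attractor in a relative Euclidean metric (each
component normalised by $\max(1, \text{attractor level})$), with an
`unresolved` label beyond a threshold (default 0.5) and a deterministic,
flagged tie-break. At $\sigma_2 = 1$, $\Omega = 1000$, horizon 100 and
1000 runs, roughly 10--20% of trajectories started from the standard
initial condition are captured by the disease-free state and the rest by
the autoimmune spiral; a two-component Gaussian mixture fitted to the
endpoint sample (means initialised at the two attractors, EM iterated to
a log-likelihood improvement below $10^{-8}$ per point or 500
iterations, with a monotonicity assertion and degeneracy flags) recovers
the same split as its component weights. The mixture EM is implemented
in the package so that initialisation, trace and degeneracy behave as
specified; an independent general-purpose mixture fitter is used as a
cross-check in the tests, not as the implementation.

`basin_probability_map()` scans initial infected-cell and regulatory
T-cell numbers with the other compartments fixed, estimating per cell
the probability of reaching a designated outcome (binomial standard
errors $\sqrt{\hat p(1-\hat p)/n}$), alongside the deterministic basin
label from an ODE integration of the same initial condition. "Entering
and staying" is operationalised as classification at the final time; a
zero-noise mode (`noise_scale = 0`) collapses the map onto the
deterministic indicator and is used as a structural test. At the default
parameters the map reproduces the expected geometry: infections starting
small, or met by a large regulatory population, are cleared
(disease-free probability near one), while large inocula with few
regulatory T cells almost surely end in the autoimmune regime, and the
probability varies smoothly across the deterministic boundary at
$\Omega = 1000$.

Default ensemble sizes are desk-scale (1000 runs; the validation suite
uses 40--500 runs per configuration and grids of $10\times10$ cells with
50 runs per cell); all drivers accept larger sizes for
publication-quality ensembles of, say, 20,000 runs.

## What the simulations do and do not show

The synthetic regimes explored here emulate demographic stochasticity
only: intrinsic reaction noise at a fixed, well-mixed system size. They
do not emulate extrinsic parameter variability between hosts,
measurement noise, spatial structure, or the antigen-specific repertoire
structure of real T-cell populations. Passing the package's checks
therefore demonstrates internal consistency of the three model levels
and of the fluctuation theory -- not fidelity of the model to any
particular experimental system. Known limitations: the master equation
is never solved directly (the SSA represents it exactly by sampling);
time-dependent fluctuation covariances along transients are out of
scope (only stationary covariances at stable states are computed); no
bifurcation continuation is attempted, so periodic attractors are
detected only empirically by simulation; and first-passage quantities
(mean switching times between basins) are estimated, if at all, only
empirically from ensembles.
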