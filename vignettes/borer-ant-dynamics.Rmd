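---
title: "Borer-ant dynamics: model, thresholds, and pest-management analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Borer-ant dynamics: model, thresholds, and pest-management analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antborer)
library(ggplot2)
```

## The model

The coffee berry borer (*Hypothenemus hampei*) develops inside the coffee
bean, which shields its immature stages from most control measures. Several
ant species prey on the borer in both its adult and immature stages, making
them candidates for biological control. `antborer` implements and analyses a
three-compartment predator-prey model of this interaction: `A(t)` adult
borers, `I(t)` immature borers, and `H(t)` ants, all continuous "average
number of individuals" state variables on a daily timescale,

$$
\begin{aligned}
\dot A &= \omega I - \mu A - \alpha A H,\\
\dot I &= \phi A\left(1 - \frac{I}{q}\right) - \omega I - \theta I - \delta I H,\\
\dot H &= \left(r + \epsilon\alpha A + \epsilon\delta I\right) H \left(1 - \frac{H}{k}\right).
\end{aligned}
$$

Adults are recruited by maturation of immatures (rate $\omega$), die from
causes other than predation at rate $\mu$ (natural death plus traps and
insecticide — the management lever), and are eaten by ants by mass action at
rate $\alpha$. Oviposition ($\phi$ eggs per adult per day) is regulated by
the logistic factor $1 - I/q$, because immatures develop inside beans and the
plantation supports at most $q$ of them; immatures additionally die naturally
($\theta$) and are preyed upon ($\delta$). The ants grow logistically towards
their own carrying capacity $k$ — they persist on other food when the borer
is absent — with the intrinsic rate $r$ boosted by converted prey biomass
(conversion efficiency $\epsilon \in (0,1]$).

Model assumptions worth keeping in mind: generations overlap; the populations
are well mixed (no spatial structure); there is no migration and no
seasonality; a single predator species acts. `mu = 0` is rejected at
construction because adults always die of natural causes and the adult bound
of the invariant region, $\omega q/\mu$, would be undefined.

The baseline illustrative parameter set used throughout the package
(`cbb_baseline_params()`) is $q = 700$, $k = q/20 = 35$, $r = 0.01$,
$\alpha = \delta = 0.01$, $\epsilon = 0.2$, $\theta = 0.23$, $\phi = 2$,
$\omega = 0.17$, with $\mu$ variable. These values are illustrative, not
field estimates; a realistic $q$ would be orders of magnitude larger, which
scales the equilibria but not the thresholds below ($q$ cancels from both).

## Invariant region

Trajectories that start in the box
$\Omega = [0, \omega q/\mu] \times [0, q] \times [0, k]$ never leave it: on
each face the field points inward or along the face (on $I = q$, for
instance, $\dot I = -(\omega + \theta + \delta H)q < 0$), and the planes
$H = 0$ and $H = k$ are themselves invariant since $\dot H$ vanishes there.
`omega_region()` exposes the box, `check_invariance()` audits an integrated
trajectory against it, and `planar_portrait()` integrates on the two
invariant ant planes.

## Thresholds and equilibria

Two dimensionless net reproductive rates organise the entire qualitative
picture:

$$
B_0 = \frac{\phi\omega}{\mu(\theta+\omega)}, \qquad
\Psi_0 = \frac{\phi\omega}{(k\alpha+\mu)(k\delta+\theta+\omega)},
$$

the borer's offspring-per-individual without the predator and with the
predator at capacity, respectively; $\Psi_0 < B_0$ whenever predation is
active. Solving each `= 1` for $\mu$ gives the bifurcation values
$\mu^* = \phi\omega/(k\delta+\theta+\omega) - k\alpha$ and
$\mu^{**} = \phi\omega/(\theta+\omega)$, with $\mu^* < \mu^{**}$.

There are four equilibria: total extinction `E1 = (0,0,0)`, borer-only
`E2` (admissible when $B_0 \ge 1$), borer-free `E3 = (0,0,k)`, and
coexistence `E4` on the plane $H = k$ (admissible when $\Psi_0 \ge 1$).
`cbb_classify()` implements the five-regime classification in $\mu$:

```{r}
p <- cbb_baseline_params(mu = 0.03)
cbb_thresholds(p)
cbb_classify(p)[, c("label", "A", "I", "H", "verdict", "case")]
```

All Jacobian eigenvalues are real (every radicand in the closed forms is a
sum of a square and positive terms), so no oscillatory attractors arise;
the package does not search for limit cycles for this reason.
`cbb_eigen_closed_form()` returns the printed-form eigenvalues and
`cbb_eigen_numeric()` the eigenvalues of the analytic Jacobian, matched to
the same labels by nearest value rather than by magnitude sorting, so the
two routes stay comparable term by term.

## Bifurcations

At $\mu = \mu^*$ the coexistence equilibrium E4 passes through E3 and the
two exchange stability (a transcritical bifurcation); at $\mu = \mu^{**}$
the same happens between the borer-only equilibrium and extinction in the
ant-free planar system. `sotomayor_check()` certifies both by Sotomayor's
three scalar conditions, computing each scalar twice: from its closed form
and by nested central differences of the vector field. The field is a
polynomial of degree three, so central differences are exact up to
roundoff; the step `h = 1e-4 * (1 + |x|)` balances truncation (zero here)
against cancellation. Null eigenvectors keep the normalization with second
component 1 — unit-normalizing them would rescale the scalars and break
comparability with the closed forms.

```{r}
tidy(sotomayor_check("E3", cbb_baseline_params()))
```

At $\mu = \mu^{**}$ the origin of the full system is nonhyperbolic (its
linearization has a zero eigenvalue), yet it is still unstable: the scalar
function $V = H$ increases strictly along any trajectory with $H > 0$
inside the ball of radius $\rho/2$, where
$\rho = \min\!\big(r/(\epsilon\sqrt{\alpha^2+\delta^2}),\, k\big)$ is the
distance from the origin to the plane $r + \epsilon\alpha A + \epsilon\delta I = 0$
capped by the ant capacity. `lyapunov_instability_demo()` turns this
argument into a numerical experiment: seeded starts in the half-ball, a
check that $H$ is monotone, and the first exit time from the ball. The
default seed (20230675) is fixed so the demonstration is reproducible.

`bifurcation_diagram()` sweeps $\mu$ and always injects the exact
bifurcation values into the grid, so collisions appear on the diagram
rather than between grid points.

## Numerical integration choices

* Solver: `lsoda` with `rtol = 1e-8`, `atol = 1e-10`, `maxsteps = 1e5`.
  For extreme synthetic parameter corners (predation rates near 3 per
  ant-day with thousands of individuals) `lsoda`'s step-size control can
  give up; the integrator then falls back to the fully implicit `bdf`
  method. The solver actually used is recorded in the trajectory's
  attributes.
* No non-negativity clipping: invariance is asserted with an additive slack
  (`1e-6` by default) instead, so integrator defects fail loudly. When a
  test needs the slack to be meaningful, solver tolerances are tightened to
  `rtol = 1e-10` so that integration error sits two orders below the slack.
* Convergence detection uses the maximum distance over the trailing 10% of
  the time span, not the final point, with a default absolute tolerance of
  `1e-3` (populations here are of order $10$–$10^3$).
* Horizons: `t_end = 5000` days suffices for every hyperbolic regime of the
  baseline set (slowest eigenvalue magnitudes are of order $10^{-2}$/day).
  Exactly at $\mu = \mu^*$ the approach to the collided equilibrium is
  algebraic ($\sim 1/t$, the signature of a transcritical center
  direction), not exponential; reaching the `1e-3` convergence tolerance
  there takes horizons of order $10^6$–$10^7$ days. The tests use
  `t_end = 8e6` for that single regime; wall-clock cost is negligible
  because the integrator's steps grow with the dynamics' timescale.
* Equality of a threshold with 1 (equilibrium collision) is declared at
  relative tolerance `1e-9`: thresholds are closed-form, so only rounding
  noise needs absorbing.

## Management sweep

`predation_sweep()` converts $\mu^*$ into an operational figure: the number
of adult borers that must die daily from causes other than predation for
eradication, $\lceil A_{\max}\,\mu^* \rceil$ with
$A_{\max} = \omega q/\mu_{\mathrm{ref}}$ and $\mu_{\mathrm{ref}} = 0.03$
(the smallest adult mortality considered in the baseline scenarios).
The ceiling matches the "at least" reading of the threshold; all quantities
are computed from the exact closed forms, never from rounded intermediate
values — rounding $\mu^*$ to four decimals before multiplying would already
shift the count. With predation disabled the requirement rises from 410 to
`no_predation_requirement(p)` = 3372 adult deaths per day, the quantitative
argument for integrating biological control with other measures rather than
relying on insecticide-driven mortality alone. When $k\alpha$ exceeds
$\phi\omega/(k\delta+\theta+\omega)$, $\mu^*$ is negative; it is reported
verbatim (no clamping) and the required count is 0 — predation alone
eradicates the pest.

```{r}
predation_sweep(
  expand.grid(alpha = c(0.01, 0.011), delta = c(0.01, 0.011)),
  cbb_baseline_params()
)
```

## Synthetic parameter generator

All property tests draw inputs from `sample_params()` /
`sample_states_in_omega()`; no external data is involved anywhere. Draw
ranges centre on the baseline values: $q \in [100, 5000]$ and
$\epsilon \in [0.05, 1]$ uniform; all rate parameters log-uniform on
$[10^{-3}, 3]$ per day so that both sides of each threshold are exercised;
$k$ a uniform fraction $[1/50, 1/5]$ of $q$, reflecting the premise that
predatory ants are far fewer than borers. A master seed fans out to one
substream per draw, so extending a batch never reshuffles earlier draws.
The generator emulates the *structure* the analysis assumes — positive
rates, bounded conversion efficiency, states inside $\Omega$ — and nothing
more: draws are independent across parameters (no allometric or ecological
correlations), and nothing is calibrated to field data. Green property
tests therefore certify the mathematics of the model across a broad
parameter box, not the behaviour of any real plantation.

## Interface notes and limitations

The package is function-first: parameter construction (`cbb_params()`,
`read_cbb_params()` for JSON or flat `key = value` configs), analysis
functions returning tibbles, `autoplot()` methods for trajectories,
bifurcation diagrams and sweeps, and `tidy()`/`glance()` for the non-tabular
result objects. There is deliberately no shell entry point: the natural unit
of use is an R session or script.

Known limitations: the model has no stage structure finer than
adult/immature, no spatial refuges, no seasonality, and a single predator
species; the coexistence analysis says nothing about transient outbreak
sizes; and parameter values are illustrative. The decoupled case
$\alpha = \delta = 0$ is permitted (the ant equation then reduces to pure
logistic growth) and reproduces the planar analysis on $H = 0$.
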