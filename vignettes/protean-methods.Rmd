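---
title: "Methods: state-dependent mortality and the selection of behavioral unpredictability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: state-dependent mortality and the selection of behavioral unpredictability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protean)
```

## The question

Individual animals observed repeatedly rarely behave the same way twice.
After environmental gradients and plastic responses are accounted for, a
residual within-individual variability remains — behavioral
unpredictability. `protean` asks under what conditions such
unpredictability is *adaptive*, using the logic of the expected-utility
hypothesis: if unpredictable behavior makes the distribution of
behavioral *outcomes* wider, then selection on unpredictability is
governed by the curvature of the map from outcome to fitness. Where that
map is convex, outcome variance raises expected fitness (Jensen's
inequality); where concave, it lowers it; where linear, it is neutral.

The package implements two linked pieces: a patch-foraging Monte Carlo
showing that unpredictability in behavior does widen the distribution of
outcomes over short horizons, and a dynamic state variable model showing
that ordinary state-dependent mortality is enough to put curvature — of
both signs — into the state–fitness map, and therefore to select for
unpredictability at some states and against it at others.

## The dynamic state variable model

A forager's discrete state $y \in \{y_{\min}, \ldots, y_{\max}\}$
(default $0, \ldots, 50$) changes stochastically over $T = 50$ foraging
steps; reproduction occurs at $t = T + 1$ with linear terminal fitness
$\Phi_0(y) = y / y_{\max}$. The linearity is deliberate: any curvature
in the fitness surface at $\tau > 0$ steps before reproduction is then
attributable to the dynamics, not to the boundary condition.

### Mortality

Each step the forager dies with state-dependent probability $d(y)$.
The headline form combines starvation, $e^{-\alpha y}$, and
mass-dependent predation, $\beta y^2$, acting independently:

$$d(y) = 1 - (1 - e^{-\alpha y})(1 - \beta y^2).$$

Defaults are $\alpha = 0.5$ and $\beta = 0.2 / y_{\max}^2$, so the
predation term reaches at most 0.2 on the grid. These are per-step
probabilities: the time step is an abstract foraging bout, and halving
the step size would roughly halve both terms without changing the
qualitative results (a lower $d$ simply needs a larger $\tau$ to bend
the surface equally). At $y = 0$ the starvation term forces
$d(0) = 1$ — zero state is deterministic death. Three further
parameterizations isolate the mechanism: constant $d(y) = 0.05$,
decreasing $d(y) = 0.1 - 0.002y$, increasing $d(y) = 0.002y$
(`mortality_preset()`). Validity of $d(y) \in [0, 1]$ over the whole
grid is enforced at construction, never per call.

### Behavioral unpredictability as a transition kernel

Unpredictability is not modeled as a behavior but as its signature: the
spread of the one-step outcome distribution. At level
$q \in \{0, 1, 2, 3\}$ the next state lies in
$\{y - q, \ldots, y + q\}$ with binomial probabilities of size
$N = 2q$, the binomial outcome $k$ mapped to state $y - q + k$. The
expected outcome is $E(Y_{t+1}) = y + uq$, where $u \le 0$ is the cost
of unpredictability for the expectation (the analyses use $u = 0$ and
$u = -0.1$); this is achieved through the success probability

$$p = \frac{E(Y_{t+1}) - (y - q)}{N} = \frac{1 + u}{2},$$

so at $u = 0$ the kernel is symmetric with variance $q/2$, and at
$q = 1, u = -0.1$ the row is $0.3025 / 0.4950 / 0.2025$ (a binomial
with $Np = 0.9$, $N = 2$). Realizing the expectation shift through $p$
on the *integer* support — rather than shifting and rounding the
support itself — is the construction consistent with those
probabilities, and is the design adopted throughout. $q = 0$ is a point
mass: environmental stochasticity at zero unpredictability is
deliberately excluded so that $q$ is the only source of outcome
variance.

Mass falling outside the grid is accumulated onto the nearest boundary
state rather than renormalized across the row; this conserves
probability while implementing the hard state bounds, at the cost of
boundary rows whose means are pulled inward (the "boundary effects"
that motivate the frozen-dynamics analysis below). An integer `drift`
parameter shifts the kernel's center to represent systematically
positive or negative foraging returns; non-integer drift is rejected
rather than silently rounded, since only $-1, 0, +1$ are meaningful on
the integer grid.

A numerical note: the binomial probabilities are computed directly as
$\binom{N}{k} p^k (1-p)^{N-k}$. For $N \le 6$ this is exact for dyadic
$p$ (all $u = 0$ kernels are then exact binary fractions), which keeps
row sums exactly 1 and makes exact tie comparisons in the optimization
meaningful.

### Backward iteration

Expected fitness satisfies

$$F_q(y, t) = (1 - d(y)) \sum_z P_q(z \mid y)\, F(z, t + 1), \qquad
  F(y, t) = \max_q F_q(y, t),$$

solved backward from $F(y, T + 1) = \Phi_0(y)$. The kernels are
time-homogeneous, so each $P_q$ is built once and reused. The optimal
level $q^*(y, t)$ is the *smallest* maximizer, with equality tested
exactly (tolerance 0 by default, configurable via `tie_tol`): after the
exact-pmf choice above, genuine ties — e.g. under zero mortality and
flat terminal fitness, where every level is equivalent — resolve to
$q^* = 0$ rather than an arbitrary floating-point winner. Surfaces are
re-indexed by time-to-reproduction $\tau = T + 1 - t$
(`phi_surface()`); the policy table masks $\tau = 0$ (no decision at
reproduction) and any state with $d(y) = 1$ (deterministic death).

The full default run (51 states × 50 steps × 4 levels) is three dense
51×51 matrix–vector products per step and completes in well under a
second.

### The frozen-dynamics oracle

With the identity kernel only ($q = 0$, no drift) the recursion
collapses to a closed form,

$$\Phi_\tau(y) = s_\tau(y)\, \Phi_0(y), \qquad
  s_\tau(y) = (1 - d(y))^\tau,$$

implemented independently in `closed_form_phi()` /
`isolated_effects_surface()`. The test suite asserts agreement with the
frozen-dynamics DP to $10^{-12}$ absolute over the full grid for all
four mortality presets — the package's core cross-validation. The
closed form also explains the science: nonlinearity in $\Phi_\tau$
emerges purely from the multiplicative survival process whenever
$d(y)$ depends on $y$ at all. Constant mortality scales the linear
terminal fitness and preserves linearity exactly; increasing linear
mortality (and the combined curve) produce, at large $\tau$, a
unimodal surface — concave around its mode, convex in both tails —
which is precisely the geometry that selects predictability at
intermediate states and unpredictability at the extremes.

### Expectation costs and the selected region

When unpredictability costs expected gain ($u = -0.1$), two effects
compose. On the right tail of the unimodal surface the slope in $y$ is
*negative*, so an expected loss of state is itself beneficial there and
the region of states selecting $q^* > 0$ expands relative to $u = 0$;
on the left tail the positive slope makes the same cost harmful and the
selected region shrinks slightly. The tests assert the expansion
direction at high states (count of upper-grid states with $q^* > 0$
under $u = -0.1$ at least that under $u = 0$); the low-state shrinkage
is small and is not pinned to a quantitative threshold.

A related scoping choice: the claim that $\Phi_\tau(y)$ decays
monotonically in $\tau$ is a *zero-drift* statement. Under positive
drift the expected state gain can outweigh one step of survival risk
(with constant $d = 0.05$, $F(y, T) = 0.95 (y + 1)/50 > y/50$ for
$y < 19$), so the decay property is asserted across zero- and
negative-drift configurations only; positive drift is exercised without
that assertion.

## The patch-foraging Monte Carlo

The premise that unpredictability widens outcome distributions is
illustrated with a marginal-value-theorem forager. Patches yield
$g(t) = a t / (b + t)$ for residence time $t$; with encounter rate
$\lambda$ the rate-maximizing residence is
$t^* = \sqrt{\lambda b} / \lambda$. Search times are gamma with mean
$1/\lambda$ and variance $\sigma_s^2$; residence times are gamma with
mean $t^*$ and standard deviation $\sigma_t$ — the unpredictability
knob, with $\sigma_t = 0$ a degenerate point mass at $t^*$ (handled
explicitly, not as an invalid gamma). Gamma draws are parameterized by
shape $= \mu^2/\sigma^2$ and scale $= \sigma^2/\mu$; the conversion is
unit-tested against sample moments. Defaults follow the reference
configuration $\lambda = 0.01$, $a = 100$, $b = 25$,
$\sigma_s^2 = 5$, 1000 foragers per condition.

Each forager alternates search and residence bouts until the horizon is
spent. The horizon is accounted for exactly: ending mid-search earns
nothing further; ending mid-residence credits $g$ of the time actually
spent in the patch (the `"credit"` rule — chosen so gain remains a
function of realized residence time; the alternative of discarding the
unfinished patch is available as `partial_patch = "discard"`).

Over a short horizon (300 time units) the between-forager variance of
total gain at $\sigma_t = 25$ exceeds that at $\sigma_t = 0$ by two
orders of magnitude while the means differ modestly; over a long
horizon averaging across many patches attenuates the inflation and the
coefficient of variation collapses. The test suite checks the short-
horizon inflation with an F-test across 1000 foragers per cell and the
attenuation at a 20,000-unit horizon — long enough (~130 patch cycles
against 2) to show the averaging-out cleanly while keeping the full
suite fast; the direction, not a magnitude, is the claim, as the
underlying result is a boxplot comparison rather than a printed
statistic. The default $\sigma_t$ sweep is
$\{0, 5, 10, 15, 20, 25\}$ and is configurable.

What the generator does *not* emulate: patch depletion heterogeneity
(all patches identical), state feedback from gain to survival (the MVT
world and the DP world are deliberately separate illustrations), and
environmental stochasticity interacting with $q = 0$ in the DP model.
Passing tests therefore show the internal logic of the model, not a
calibration to any empirical system.

## Interfaces and reproducibility

All computations are exposed as plain functions; the
`inst/cli/protean.R` script adds `dp`, `isolated` and `mvt` subcommands
reading YAML/JSON configs with flag overrides (flags win; unknown keys
are errors naming the key). Outputs are long-format CSVs plus a
`metadata.json` echoing the fully resolved configuration, the seed and
the package version, so any run is reproducible from its metadata
alone. Stochastic components take explicit seeds; the $\sigma_t$ sweep
derives one seed per level from the global seed so a level's results do
not depend on its position in the grid.

## Known limitations

- The state grid is integer and the horizon finite; there is no
  continuous-state or infinite-horizon variant.
- Closed forms exist only for the frozen-dynamics case; the full model
  is validated structurally (policy banding, monotonicity, containment)
  rather than against independent numbers.
- Boundary clamping induces curvature near $y_{\min}$ and $y_{\max}$
  that is an artifact of the hard bounds; conclusions about
  state-dependent mortality rest on the interior of the grid.
- The MVT simulation treats residence-time variability as exogenous;
  it does not model *why* a forager is unpredictable.
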