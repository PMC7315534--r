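# protean

Tools for asking when *behavioral unpredictability* — the residual
within-individual variability in behavior left after plasticity and
environment are accounted for — is favored by natural selection in a
foraging animal.

The package is aimed at behavioral ecologists and theoreticians working
with dynamic state variable models. It implements a discrete-time model in
which a forager of state `y` (size, fat storage, satiation, ...) forages
for `T` steps and reproduces at `t = T + 1`:

- **State-dependent mortality.** Per-step death probability combines
  starvation and mass-dependent predation,
  `d(y) = 1 − (1 − e^(−αy))(1 − βy²)`, with linear and constant
  alternatives (`mortality_model()`, `mortality_preset()`).
- **Behavioral unpredictability as a transition kernel.** The one-step
  state change follows a binomial distribution of size `N = 2q` mapped
  onto the `2q + 1` states `{y − q, …, y + q}`, with success probability
  `p = (1 + u)/2` so the mean outcome is `y + uq`
  (`unpred_kernel()`). The level `q ∈ {0, 1, 2, 3}` is the
  unpredictability knob: larger `q` widens the outcome distribution
  (variance `q/2` at `u = 0`); `u` is the cost (or neutrality) of
  unpredictability for the expected outcome.
- **Backward iteration.** `backward_iterate()` solves
  `F_q(y, t) = (1 − d(y)) Σ_z P_q(z | y) F(z, t + 1)`,
  `F(y, t) = max_q F_q(y, t)` from the linear terminal fitness
  `Φ_0(y) = y / y_max`, returning the expected-fitness surface
  `Φ_τ(y)` (`phi_surface()`) and the optimal policy `q*(y, t)`
  (`policy_table()`), ties broken toward the smallest `q`.
- **Closed-form validation.** With no state dynamics the surface is
  `Φ_τ(y) = (1 − d(y))^τ · Φ_0(y)` (`closed_form_phi()`,
  `isolated_effects_surface()`), the independent oracle the DP engine is
  checked against.
- **Marginal-value-theorem Monte Carlo.** A patch forager with gain
  `g(t) = a t / (b + t)` and optimal residence `t* = √(λb)/λ` whose
  residence times have standard deviation `σ_t` shows how
  unpredictability inflates variance in total gain over short horizons
  (`mvt_config()`, `population_summary()`, `mvt_sweep()`).

## Worked example

```r
library(protean)

pol <- backward_iterate(dsv_config())   # defaults: y in 0..50, T = 50,
                                        # q in 0:3, u = 0, combined mortality
ps <- phi_surface(pol)
ps$matrix[c("10", "25", "40"), "50"]
#>          10          25          40
#> 0.095456558 0.042375216 0.001883767

pt <- policy_table(pol)
pt$q_star[pt$tau == 50]
#> NA 3 3 3 3 3 3 3 3 2 0 0 0 0 0 0 0 0 0 2 3 3 3 ... 3
```

Fifty steps before reproduction the fitness surface `Φ_50(y)` is unimodal:
starving foragers (low `y`) rarely survive, and heavy foragers (high `y`)
are killed by mass-dependent predation, so fitness peaks at intermediate
state. The policy row shows the consequence: maximal unpredictability
(`q* = 3`) is optimal at low and high states, where the surface is locally
convex and outcome variance pays, while complete predictability
(`q* = 0`) is optimal on the intermediate band (`y = 10–18`), where the
surface is concave. `y = 0` is deterministic death and carries no
decision (`NA`).

The patch-foraging simulation makes the premise concrete — unpredictable
residence times inflate the spread of foraging success over a short
horizon while barely moving its mean:

```r
mvt_sweep(c(0, 25), mvt_config(n_foragers = 1000), seed = 1)$summary
#>   sigma_t     mean        var      q25   median      q75
#> 1       0 132.7298   0.754607 132.2679 133.3018 133.3333
#> 2      25 117.5978 225.302047 109.7664 122.4419 129.6950
```

## Command-line interface

A thin executable wrapper over the same functions:

```sh
Rscript inst/cli/protean.R dp --out runs/dp --u -0.1
Rscript inst/cli/protean.R isolated --out runs/iso --mortality increasing
Rscript inst/cli/protean.R mvt --out runs/mvt --seed 1 --n_foragers 1000
```

Each run writes long-format CSVs plus a `metadata.json` from which the
run can be reproduced exactly. Exit codes: 0 success, 2 configuration
error, 1 runtime error.

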