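---
title: "A two-gene birth-death model of ageing: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-gene birth-death model of ageing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agebd)
```

## The model

Every individual is haploid and asexual and carries two heritable real
genes: `x_b`, the end of its fertility span, and `x_d`, the onset of its
intrinsic mortality risk. Both hazards are binary switches:

* **birth**: rate `i_b` while age `a < x_b` (and `x_b > 0`), 0 after;
* **death**: rate `i_d` once `a >= max(x_d, 0)`, plus a logistic
  competition term `c (N - 1)` felt identically by every living
  individual, which caps the population near `lambda / c`.

Time, ages and both genes share the same (arbitrary) time unit; `i_b`,
`i_d` and `c` are rates per that unit. There is no energy budget and no
trade-off term: every constraint that emerges (for instance the
negative association between fertility and longevity) emerges from the
demography alone.

At each birth the offspring copies the parental trait; with
probability `p` per gene (independently) it receives a Gaussian
increment of standard deviation `sigma`. Traits are unbounded: a
negative `x_b` means sterile, a negative `x_d` means at risk from
birth. Lineages labelled *Lansing* additionally apply a
transgenerational rule: if the parent satisfies `x_d < x_b` and
reproduces at an age past its own `x_d`, the offspring's (already
mutated) `x_d` is multiplied by `1 - magnitude`. At magnitude 1 the
offspring's onset is exactly 0; such zeros breed true, because every
reproducing parent with `x_d = 0` is itself past its onset. The label
is a fixed lineage property, inherited and never mutated, because the
experiments compete two fixed sub-populations.

## Fitness

The Malthusian parameter `lambda` of a fixed trait is the root of the
Euler-Lotka identity `i_b * int_0^{x_b} S(a) exp(-lambda a) da = 1`.
Survivorship is piecewise exponential, so the integral and all the
partial derivatives used by the gradients are closed-form
(`renewal_residual()`, `fitness_gradient()`); the `lambda -> 0` and
`lambda -> -i_d` singularities are series/limit expressions, never
numerical perturbations. The solver (`malthusian()`) runs Newton from
`lambda_0 = max(0, i_b (1 - 1/R_0))` — the residual is strictly
decreasing and convex in `lambda`, so Newton converges monotonically —
with a bisection fallback, to `|residual| < 1e-10` within 100
iterations. The root always satisfies `lambda <= i_b` and
`sign(lambda) = sign(R_0 - 1)`; positive growth requires
`i_b * x_b > 1` (`viability_threshold()`).

A Lansing genotype below the diagonal (`x_d < x_b`) founds a two-type
population: "normal" parents beget normal offspring only while
`a < x_d`, then beget `x_d = 0` offspring, and the `x_d = 0` subtree
feeds only itself. Both subsystems are autonomous renewal processes, so
the population growth rate is the dominant of the two branch roots:
`lambda_N` from the fertile window truncated at `x_d` (no hazard before
it) and `lambda_L` of trait `(x_b, 0)`. The `branch` field of the
result records which root won. For `x_d >= x_b` the rule never fires
and both genotypes have identical fitness — also for `x_d <= 0`, where
the clamp puts both under the hazard from birth.

## Adaptive dynamics and the gap

The canonical equation moves a monomorphic resident along
`d(x_b, x_d)/dt = k(t) * grad(lambda)`. Because both genes share the
same mutational variance, `k(t)` (which absorbs `p`, `sigma^2` and the
population size) rescales time without bending the trajectory.
`integrate_canonical()` therefore integrates the unit-speed field
`grad(lambda)/|grad(lambda)|` (classical fourth-order Runge-Kutta,
output step 0.25 in arc length, default horizon 60): the raw dynamics
slow exponentially as the traits grow, and the normalization turns an
astronomically long transient into a finite path while preserving the
limiting gap. The returned `speed` column is the raw gradient norm, so
the slowdown itself remains observable.

Along the flow both genes grow and `lambda` approaches its cap `i_b`;
equating the two gradient components in that limit gives
`(2 i_d + lambda) exp(-(i_d + lambda) gamma) = i_d` at
`lambda = i_b`, i.e.

```
gamma* = log((2 i_d + i_b) / i_d) / (i_b + i_d)
```

(`asymptotic_gap()`), `log(3)/2 ~ 0.549` at unit intensities and
`~ log 2` at `i_b = 0.01, i_d = 1`. Because this closed form was
re-derived rather than transcribed, the test suite cross-validates it
against the canonical integration to `1e-2` from two distant starting
traits; a disagreement fails the build. The gap depends only on the
intensities, is decreasing in both, and is far more sensitive to `i_d`
than to `i_b`: pointwise the `i_d`-slope dominates everywhere on
`[0.01, 1]^2`, and the gap's total variation along the `i_d` axis at
mid-range intensities exceeds that along the `i_b` axis by roughly
sixteen-fold. (A note on a related printed figure: the same source
quotes both `log(3)/2 ~ 0.549` and `1/sqrt(3) ~ 0.577` for the unit-
intensity limit; the former is consistent with the second anchor and
with our integration, so it is the one this package reproduces.)

## The simulator

`simulate_bd()` is an exact thinning (acceptance-rejection) simulator.
Each living individual is bounded by the constant rate
`i_b + i_d + c (N - 1)`, which dominates its true age-dependent rates;
proposal times are exponential in the aggregate bound, the candidate is
uniform among the living, and acceptance uses the true rates at the
proposed time. Because the true rates are piecewise constant in age,
this is exact — no discretization bias at the `x_b`/`x_d` crossings —
and the bound refreshes whenever `N` changes. The suite checks the
simulator against three independent yardsticks: the analytic lifespan
law `x_d + Exp(i_d)`, the mean-field logistic equilibrium
`(i_b - i_d)/c`, and a brute-force fine-time-step discretization on
small populations; and its realized growth rate against the renewal
root for both lineage types (measured over a window past the founder
cohort's age-structure transient, which otherwise inflates the rate).

Newborns have age exactly 0; founders are age 0 at `t = 0` unless
given earlier birth times. Stop criteria are an event budget (births
plus deaths accepted — thinning rejections do not count) and/or a time
horizon. Runs demand an explicit seed and are bit-identical under it;
the event log (CSV-exportable at full float precision) replays exactly,
which `snapshot_at()` and `population_trajectory()` exploit. For long
runs the log can be turned off and replaced by cheap in-run samples of
population summaries (`sample_times`).

## The experiments and their scale

The experiment drivers generate all of their own data; the generator's
defaults are the study conditions, not tuning knobs.

* **Gap convergence** (`run_gap_convergence()`): 1000 founders at
  `(1.2, 1.6)` — a viable, menopause-side start — with `c = 9e-4`,
  `p = 0.1`, `sigma = 0.05`. The population mean of `x_b - x_d` is
  sampled every 10 time units to a horizon of 1200 and averaged over
  the plateau window `[600, 1200]`, then over replicates (default 50).
  Two caveats the reader should expect: at any finite time the traits
  are finite, `lambda < i_b`, and the instantaneous optimum gap
  `log((2 i_d + lambda)/i_d)/(i_d + lambda)` sits somewhat above
  `gamma*`; and once selection on the gap has flattened, the
  population mean wanders slowly (single-run window averages have a
  standard deviation near 0.17), which is why the estimate averages
  replicates. Desk-scale estimates therefore sit a few hundredths
  above `log(3)/2`.
* **Competition** (`run_competition_cell()`): 500 Lansing founders at
  `(1.5, 1.3)` and 500 non-Lansing at `(1.5, 0.83)` — Malthusian-
  matched to 0.007, audited at run time — under a shared 2e5-event
  budget, replicated (100 replicates in the acceptance script; each
  replicate seeds as `seed + r`). "Collapse" is a lineage reaching 0
  living individuals before the stop criterion; the collapse index is
  the ratio of collapse counts (undefined, printed `-`, when neither
  side ever collapses), the progeny index pools birth events over all
  replicates, and the share is the mean final Lansing fraction among
  replicates with survivors. Per-replicate ratio averaging was
  considered and rejected: it is dominated by the near-infinite ratios
  of replicates where one lineage dies early.
* **Uniform start** (`run_uniform_start()`): both genes of every
  founder uniform on `[-10, 10]`, half the cohort per lineage, horizon
  1000, terminal window 10. The desk default of 500 founders per
  lineage matches the effective scale of a 5000-per-lineage start: at
  `c = 9e-4` the initial crowding death rate (~9 per unit) thins a
  10000-individual cohort almost uniformly at random to the same
  standing population (~1100) within a fraction of a time unit.
* **Magnitude sweep** (`run_magnitude_sweep()`): the competition cell
  repeated across Lansing magnitudes in `[0, 1]`, returning the final
  per-lineage gap distributions.
* **Decile curves** (`summarize_deciles()`): deciles 1/5/9 per lineage
  of the gap, of each individual's own lineage-specific `lambda`
  (cached per unique trait), or of realized lifespans among the dead,
  along a time grid; empty cross-sections produce `NA` rows.

## What the synthetic runs do and do not show

The generator emulates the model exactly — it *is* the model — so
passing tests certify internal consistency (simulator against renewal
theory, closed forms against integration oracles) and reproduce the
published anchor values at desk scale. They do not certify behaviour
of any real organism: the hazards are binary caricatures, there is no
environment, no space, no sex, no maturation delay. Two desk-scale
limits are worth naming. First, with a standing population near 1100,
lineage fixation by drift is common within a horizon of 1000 in the
uniform-start runs, whereas larger ensembles can report long
coexistence; per-run outcomes (which branch of trait space wins, the
final Lansing share) are bimodal, and only replicate averages are
meaningful. Second, above the `x_b = x_d` diagonal `x_d` is selectively
neutral (mortality after infertility has no individual cost), so
menopause-side branches persist for the whole horizon; the cross-run
pooled mode of the non-Lansing terminal gap lands near `log(3)/2`, but
an appreciable menopause-side mass remains, and the Lansing lineage's
position drifts (its fitness below the diagonal depends on `x_d`
alone, leaving `x_b` free to wander upward). Claims that depend on
coalescence of every branch onto the positive-side optimum need far
larger ensembles than a desk run.

## Numerical choices, in one place

* Fertility window half-open `[0, x_b)`; hazard onset clamped at 0;
  both conventions are measure-zero but fixed for reproducibility.
* Mutation before the Lansing override; the override replaces rather
  than perturbs, so magnitude-1 zeros are exact and breed true.
  Intermediate magnitudes interpolate linearly between the endpoints.
* Newton tolerance `1e-10`, max 100 iterations, bisection fallback;
  `lambda = 0` handled by the `R_0 - 1` limit, `lambda = -i_d` by the
  degenerate integral.
* Thinning bound `i_b + i_d + c (N - 1)` per individual, refreshed on
  every change of `N`; the event budget counts accepted events.
* Canonical integration: RK4 on the normalized field, step 0.25,
  horizon 60 (enough for the tail variation of the gap to drop under
  `1e-3` from the default starts); the tail gap is the mean over the
  last tenth of the path.
* Replicate `r` of any replicated experiment uses `seed + r`; the
  acceptance script derives all its seeds from `--seed`.
* All CSV output uses shortest-round-trip float formatting, so logs
  replay to the bit.

## Limitations

Beyond the desk-scale caveats above: the canonical-equation module
reports trait paths against arc length, not wall-clock evolutionary
time (absolute convergence times are not modelled); the two-type
Lansing growth rate assumes the `x_d = 0` subtree is demographically
autonomous, which holds in this model but would break if zeros could
mutate back (they cannot: the override re-applies to every descendant
born past its parent's onset, so back-mutation on `x_d` is masked); and
the competition indexes are sensitive to the unstated counting
conventions of any external tabulation one compares them to — the
package documents its own conventions precisely instead.
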