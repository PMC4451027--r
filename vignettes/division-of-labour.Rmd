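---
title: "Methods: adaptive dynamics and simulation of social division of labour"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adaptive dynamics and simulation of social division of labour}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(divlabsim)
```

## The model and its assumptions

`divlabsim` studies how consistent, heritable behavioural differences can
evolve in a population whose members repeatedly solve a collective task in
randomly assembled groups. The task consists of two subtasks, A and B. An
individual is a two-trait strategy `x = {q, c_A}`: the probability `q` of
choosing subtask A in any one game, and the additional cost `c_A` it pays
when performing A. Costs are constrained to the power-law trade-off surface
`c_A^alpha + c_B^alpha = k^alpha`, so investing in one skill necessarily
degrades the other. Reproduction is asexual and faithful apart from small
mutations; there is no learning, plasticity, task switching within a game,
or spatial structure — behavioural variation in this model is maintained
purely by selection on heritable traits.

A group of `N` members with `i` A-players produces total benefit `beta(i)`,
by default the Gaussian bump
`beta(i) = 30/(5*sqrt(2*pi)) * exp(-(i - 3.5)^2 / (2*5)^2)`, which for
`N = 7` is symmetric about `i = 3.5`: balanced groups do best. Two sharing
conventions are implemented: model I divides `beta(i)` equally among all
`N` members (a common good), model II divides it between the two task
subgroups and then equally within each, so rare skills command a premium.
Because a focal individual faces the binomial composition of the other
`N - 1` members, common strategies earn less — selection is negatively
frequency dependent, which is the engine of everything below.

The analytical layer applies adaptive dynamics to the invasion fitness
`W(x', x)`. Its key objects, all exported: the benefit gradient `G(q)`
(`benefit_gradient_term`), the cost gradient `H(q)` along the optimal-cost
curve (`cost_gradient_term`), singular points as roots of `G + H = 0`
(`find_singular_points`), the convergence/branching classification at the
central point (`stability_report`, `critical_k`), and the linearised
invasibility of the pure corner states (`pure_state_invasibility`). The
individual-based simulator (`run_simulation`) re-implements the same game
stochastically: finite population, random groups, realised (not expected)
payoffs, tournament reproduction and mutation.

## Parameters that matter

All payoffs and costs share one dimensionless payoff unit.

* `k` (default 0.25) — maximal additional cost, the price of being fully
  specialised in the *wrong* task. The convergence-stability criterion is a
  ceiling on `k`: `critical_k(alpha, game)` returns
  `Δw(1/2)·2^(1/alpha)(alpha-1)/4`, ≈ 0.849 for the default model-I game at
  `alpha = 0.15`.
* `alpha` (default 0.15) — trade-off shape. `alpha < 1`: generalists pay
  more, the cost optimum is interior and moves continuously; `alpha > 1`:
  corner optima with a jump at `q = 1/2`; `alpha = 1` is treated as its own
  regime (a neutral line at `q = 1/2`), compared with tolerance 1e-12,
  never as a limit of the `alpha != 1` formulas.
* `N` (default 7), benefit amplitude/width (30, `sigma = 5`, `mu = 3.5`) —
  the published simulation setting; the exponent denominator is the printed
  `(2*sigma)^2`, see below.
* IBM scale: population 1000, 1000 groups and 100 tournament bouts per
  generation (≈7 games per individual, 10% turnover), mutation probability
  0.1 with uniform half-width `epsilon = 0.005`, 1.5e5 generations. These
  are the published run parameters and are the package defaults.

## Numerical choices

* `H(q)` and the interior cost optimum are evaluated in log space
  (`log(q) - log1p(-q)`, `log1p(exp(.))`) so extreme exponents
  (`alpha` far from 1, `q` near 0/1) neither overflow nor cancel; at the
  exact endpoints the closed-form limits `∓theta*k` are used instead of the
  formula. For very small `alpha` the approach to those limits is
  logarithmically slow in `q` — that is a property of the function, not of
  the implementation, and the tests document it.
* Root finding scans `G + H` on a uniform grid (default 1e4 intervals,
  endpoint limits substituted at `q = 0, 1`) and polishes each sign change
  by bisection to 1e-10; grid points that are exact zeros (the central root
  at `q = 1/2`) are taken directly. Solver failures are reported per
  bracket, never silently dropped.
* The tie at `q = 1/2` for `alpha >= 1` (both corners equally optimal)
  returns `c_A = k` deterministically with `degenerate = TRUE`, preserving
  reproducibility without hiding the degeneracy.
* Corner selection gradients: the trade-off curve has zero-or-infinite
  slope at `c_A ∈ {0, k}` for `alpha != 1`, so the `c` component of the
  gradient may legitimately be `±Inf` there; results carry a `corner`
  attribute and are interpreted in the locally natural cost coordinate
  (`c_A` near the all-A corner, `c_B` near the all-B corner). At exactly
  `q = 1` the vanishing `(1-q)` weight beats the infinite slope and the
  gradient is the finite `-1` of the linearised invasion analysis.
* Mutation of the cost trait is uniform in the transformed coordinate
  `u = c_A^alpha` (the published mutation bracket is symmetric in `u`, not
  in `c_A`), clamped — not reflected — at `u ∈ [0, k^alpha]`; `q` mutates
  uniformly, clamped to `[0, 1]`. One Bernoulli(0.1) event mutates both
  traits together, matching the published description of simultaneous
  two-trait mutation.
* Fitness bookkeeping: accumulators and game counters reset at the start of
  every generation; realised fitness is the per-game average; individuals
  never sampled keep fitness exactly 0; offspring start at 0. Per-generation
  reset is the simplest reading consistent with the published description,
  which never states persistence across generations.
* All randomness flows through R's RNG (also inside the C++ core), so a
  single `seed` makes every trajectory bit-identical; experiment drivers
  derive per-replicate seeds deterministically from a seed base.

## Design decisions where the source was open

* **Model II's factor 1/2** is dropped by default (`half_factor = FALSE`),
  because the analytical treatment dismisses it as a pure rescaling and the
  simulation is described as sharing "as defined" there; keeping analysis
  and simulation on the same convention makes them directly comparable. The
  flag restores it for sensitivity checks. Note the bookkeeping consequence:
  without the 1/2, an interior model-II group disburses `2*beta(i)` in
  total (each subgroup receives the whole benefit); the conservation tests
  assert exactly that.
* **Gaussian denominator.** The benefit function is implemented with the
  printed `(2*sigma)^2` (i.e. 100 for `sigma = 5`), not the conventional
  `2*sigma^2`; a `conventional` flag exposes the alternative.
* **Printed unstable-point costs.** The printed cost coordinates of the
  unstable pair (`c_A^alpha = 0.168` at `q = 0.0154`, and `0.644` at
  `q = 0.984`) are mutually consistent (they sum to `k^alpha ≈ 0.812`) but
  do not satisfy the interior-optimum formula at those `q` (which gives
  `c_A^alpha ≈ 0.549` at `q = 0.0154`); the package pairs each root with
  the formula's cost and treats only the `q` coordinates as authoritative.
* **Naming of the unstable pair.** Members are labelled by their `q`
  values (`unstable_pair_member`), avoiding the starred naming, which the
  source uses inconsistently between sections.
* **Branching detector.** The published outcome classification is visual;
  the operational criterion here is: split at `q = 1/2`, both clusters hold
  ≥20% of the population with centroids below 0.25 / above 0.75
  (*branched*); one side holds ≥80% beyond its threshold (*near-pure*);
  otherwise *undecided*; a trajectory verdict additionally requires the
  branched state to persist over the last 10 recorded rows. All thresholds
  are arguments and are echoed in every verdict.
* **Configuration is JSON only** (`jsonlite`); no YAML parser is available
  in the supported dependency set, and a hand-rolled one would be worse
  than a narrower format.

## What the simulator does and does not establish

The IBM emulates the published stochastic model faithfully — finite
well-mixed population, binomially assembled groups, realised payoff noise,
tournament selection, rare small mutations — and reproduces its analytical
predictions at the published scale: monomorphic populations earn the
analytic expected payoff within Monte-Carlo error; runs from the singular
point at `k = 0.25, alpha = 0.15` (model I) branch into specialised
clusters at population 1000 over ~1e5 generations, while `alpha = 1.5`
runs collapse onto a pure corner; corner starts remain in their basins.

It does **not** make branching desk-cheap. Disruptive selection at the
central point is weak here (the mutant Hessian's positive eigenvalue is
~0.01 against per-game payoff noise orders of magnitude larger), so
branching is a drift-limited escape whose waiting time grows sharply as the
population shrinks: at population 300 no configuration we probed branched
within 1e5 generations, although the same code branches reliably at
population 1000. Consequently the desk-scale acceptance criterion
(population 300, 2e4 generations, majority branched) is implemented
faithfully and left failing, with the analysis recorded alongside the test;
green desk-scale tests cover everything except the branching wait itself,
and the branching properties are tested at the smallest scale verified to
work (population 1000, 1e5 generations, few seeds). For the same reason the
(k, alpha) sweep invariant is asserted across well-separated `k`
(0.25 vs 3) rather than as a dense-grid trend, and the model-I-vs-II
comparison of branching regions is asserted through the analytic threshold
ordering `critical_k(II) > critical_k(I)` — at matched parameters model II
branches more *slowly* in wall-clock generations, because its scarce-role
shares inflate payoff noise even though its branching region is far larger.

## Known limitations

* No dimorphic (post-branching) adaptive dynamics and no canonical-equation
  integration; the IBM covers post-branching behaviour.
* The `alpha >= 1` convergence question depends on the mutational
  covariance, which is not modelled; reports say so rather than guessing.
* No more than two subtasks, no structured populations, no hybridising
  (sexual) inheritance.
* Asymmetric benefits are supported as explicit tables (the source does not
  print its asymmetric forms); the asymmetric experiment asserts only the
  qualitative direction — mild shifts tilt the cluster masses toward the
  favoured task, severe (monotone) shifts collapse the population onto one
  pure strategy.
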