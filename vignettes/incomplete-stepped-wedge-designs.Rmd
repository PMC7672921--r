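---
title: "Hunting for efficient incomplete stepped wedge designs in continuous time"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hunting for efficient incomplete stepped wedge designs in continuous time}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The design problem

A stepped wedge cluster randomised trial recruits from `K` clusters that
each cross from the control to the intervention condition at a scheduled
time. `swhunt` addresses the continuous-recruitment version of this
design problem: one eligible participant presents at each cluster at each
of the regularly spaced times `1/M, 2/M, ..., 1` (the trial duration is
scaled to one unit, so `M` is the arrival rate), the investigator has fine
control over both *when each cluster crosses over* and *which presenting
participants are recruited*, and each recruited participant contributes a
single continuous outcome. When recruitment costs money, or participation
burden must be minimised, it pays to leave some slots unrecruited — an
*incomplete* design — provided precision is preserved. The package's job
is to quantify that trade-off exactly and to search for schedules that
make it well.

## Model and precision

The outcome of participant `i` in cluster `k`, recruited at time `t_ik`,
is modelled as

    Y_ik = T(t_ik) + theta * H(t_ik - t*_k) + e_ik,

where `T(t)` is a polynomial secular trend of degree `d` shared by all
clusters, `H` is the unit step (`H(t) = 1` for `t >= 0`, so a participant
presenting exactly at the cross-over time `t*_k` is under the
intervention), and `theta` is the treatment effect. Residuals have
variance `sigma2` and within-cluster correlation

    Corr(e_i1k, e_i2k) = rho * tau^|t_i1k - t_i2k|,

with independence across clusters. `rho` is the intracluster correlation
of two participants sampled at the same time; `tau` is the factor by
which that correlation has decayed across the whole trial duration, so
`tau = 1` recovers the classic exchangeable structure and smaller `tau`
means faster decay. Because neither the polynomial trend nor the decaying
correlation is piecewise-constant, outcomes cannot be collapsed to
cluster-period means; the model is kept at the individual level.

With fixed effects `[1, t, ..., t^d, treatment]` collected in `Z` and the
residual covariance in `V`, the GLS variance of the estimated treatment
effect is the `(treatment, treatment)` entry of `(Z' V^-1 Z)^-1`. `V` is
block-diagonal across clusters, so the information matrix is accumulated
cluster by cluster ([information_matrix()], [treatment_variance()]).
*Precision* is always the inverse of that variance computed at
`sigma2 = 1`; `sigma2` enters purely multiplicatively.

Two numerical choices matter here:

* **Basis.** The documented design matrix uses raw powers of `t`, but all
  variance computations reparameterize the trend columns to shifted
  Legendre polynomials on `[0, 1]`. The treatment coefficient is
  invariant to any invertible reparameterization of the trend space (a
  tested property), and the orthogonal basis keeps the information matrix
  well conditioned at `d = 6` and beyond.
* **Degenerate inputs.** Designs with fewer recruits than fixed-effect
  parameters, with all recruits under one condition, or with too few
  distinct recruitment times raise classed identifiability errors rather
  than returning infinite variances; the search treats such candidates as
  inadmissible.

## Reversal symmetry

Reversing the time scale *and* swapping the condition labels maps any
valid design to another valid design with identical precision, because
the correlation model is direction-blind. The search therefore works in
the space of designs invariant under this transformation: schedules are
chosen freely for clusters `1..K/2` and mirrored into the other half
([symmetrize()]). `K` must be even. On the slot grid the reversal maps
slot `s` to `M + 1 - s` (index reversal preserves the grid and all
inter-time gaps, which is all the correlation model sees) and the
cross-over slot `c` to `M + 2 - c`.

A convenient arithmetical fact: the diagonal boundary slot
`round(M (k - 1) / (K - 1))` can never be a half-integer when `K` is
even (`K - 1` is odd), so the half-up tie rule in the constructors never
actually fires in the symmetric design space.

## The search

Precision as a function of the design has no usable closed-form optimum,
and the design space is astronomically large (at `K = 30`, `M = 100`
there are `2^1500` half-schedules). The package uses an iterative greedy
algorithm:

1. start from the complete design with the straight diagonal cross-over
   boundary (`n = M K`);
2. improve the design at fixed sample size until no improving move
   remains;
3. remove the recruited participant (together with its mirror image)
   whose removal costs the least precision, found by exhaustive search
   over candidates;
4. repeat from 2.

This yields a solution at every even sample size. The same machinery run
in reverse — starting from a *staircase* design with window width
`j = round(M / (K - 1))` and greedily *adding* the most valuable pair —
guards against local optima from one direction; at a given power target
the two candidate solutions are compared and the smaller-`n` one kept
([hunt()]).

The sample-size-preserving improvement moves are this package's own
reconstruction (the move set is genuinely open design territory):

* **family A** — shift one half-cluster's cross-over by one slot (mirror
  applied);
* **family B** — relocate one recruited slot to any unrecruited slot of
  the same cluster, optionally compounded with a one-slot shift of that
  cluster's cross-over (mirror applied). The compound form matters:
  exhaustive enumeration of tiny design spaces shows per-sample-size
  optima that single-element moves cannot reach from the greedy path but
  a simultaneous relocate-and-shift can;
* **family C** (off by default) — relocate a recruited slot to another
  cluster. Cross-cluster transfer of recruitment effort already happens
  across iterations through the greedy remove/add steps, so family C
  mostly adds cost, not quality.

Sweeps are *best-improvement*: all candidates are evaluated, the single
best is applied, deterministically tie-broken by (family, cluster, slot).
A move counts as improving when its relative precision gain exceeds
`1e-10`, which guards the hill climb against floating-point noise; a
sweep-limit safeguard of `10 K M` moves guarantees termination. Working
with mirror pairs keeps every iterate inside the symmetric space; sample
size consequently moves in steps of two.

### Fast candidate evaluation

Each sweep evaluates tens of thousands of candidate designs, so
candidates are never re-solved from scratch. Per cluster the engine
caches the inverse correlation matrix `Rinv`, `G = Rinv Z` and
`W = Z' Rinv Z`. Removing observation `i` downdates the cluster
information by `g_i g_i' / u_i` (`g_i` the row of `G`, `u_i` the diagonal
entry of `Rinv`); adding an observation is the mirror-image rank-one
update; a within-cluster relocation composes the two exactly on the
post-removal state. The effect of a candidate on the treatment variance
is then a rank-2 to rank-4 Woodbury update of the cached `p x p` inverse
information, costing `O(p^2)` per candidate instead of `O(n^3)`.
*Committed* changes, by contrast, simply rebuild the affected cluster
from scratch — at `m <= 100` observations that costs microseconds and
leaves nothing to drift. The tests spot-check engine iterates against the
independent plain-R GLS path throughout.

On one CPU the full reference experiment (`K = 30`, `M = 100`, pruning
`n = 3000` down to `n = 40` with a compound-move sweep after every
removal) runs in well under ten minutes — fast enough that checkpointing
is unnecessary; a naive implementation re-solving each candidate would
need days.

## Power targets

Under the normal approximation, detecting a standardized effect
`delta = theta / sigma` with power `1 - beta` at two-sided level `alpha`
requires precision `((z_{1-alpha/2} + z_{1-beta}) / delta)^2`
([required_precision()]); conversely a design's power is
`Phi(|delta| sqrt(precision) - z_{1-alpha/2})` ([design_power()]), the
minor tail being ignored (`delta = 0` gives `alpha/2`). No small-sample
degrees-of-freedom correction is applied: the GLS framework treats the
variance components as known, which is the convention this design
machinery inherits. `design_power()` can re-evaluate a fixed design under
a different analysis polynomial degree than the scenario's; since the
models are nested, precision (hence power) is non-increasing in the
degree, and comparing design forms across degrees is how robustness to
trend misspecification is assessed. Staircase designs are strikingly
robust in this sense: their power is nearly flat across analysis degrees,
whereas phase-like designs collapse when the trend has more curvature
than the phases can absorb.

## Baselines and the generator

Two baselines put search solutions in context ([random_baseline()],
[staircase_sweep()]):

* **Random symmetric designs.** For each design, cross-over slots for the
  free half are drawn uniformly on `{1..M+1}` — the discretization of
  uniform cross-over times, deliberately including the two degenerate
  always-control / always-intervention schedules — and a recruitment
  probability `p ~ U[0, 1]` is drawn once per design, each slot then
  recruited independently with probability `p`. Drawing `p` per design
  (rather than fixing it) spreads the baseline across the whole
  sample-size axis.
* **Staircase designs.** Diagonal cross-overs with recruitment only in
  windows of width `j` on each side of the boundary, truncated at slots
  `1` and `M` (truncation is the only convention that keeps the design
  valid without shifting recruitment away from the boundary).

These generators are also the test fixtures. They emulate the structural
features that matter to the GLS calculation — symmetric schedules, all
sample sizes, degenerate conditions — but they do not emulate anything
about real data: no outcomes are ever simulated, arrival times are exactly
regular, cluster sizes are equal, and the correlation model is taken as
true. Passing tests therefore certify the design arithmetic and the
search behaviour, not robustness of any analysis to model
misspecification.

## Problem sizes used by the test suite

Exhaustive enumeration oracles run at `K = 2`, `M = 2..4`, where the
symmetric design space (up to 80 designs) can be scored completely and
the hunt's solutions compared with the global optimum. Property checks
(dense-matrix GLS oracle, reversal invariance, exchangeable closed form,
downdate correctness, monotonicity) run on hundreds of random designs at
`K = 2..6`, `M = 3..12`. The full-scale reference experiment
(`K = 30`, `M = 100`, `rho = 0.05`, `tau = 0.2`, degree 6) is run once in
the acceptance test and once by `scripts/acceptance.R`; these are the
sizes at which the headline precision trade-offs (about 93% of
complete-design precision at half the sample size; staircase designs
never more than about 5% below the algorithm's same-n solutions) are
reproduced.

## Known limitations

* Strict hill climbing can stop at local optima; at tiny design spaces
  the forward trajectory alone can sit a fraction of a percent below the
  global per-n optimum (the backward direction recovers it in the cases
  we enumerate, which is exactly why both directions are always run).
  There is no global-optimality guarantee at full scale.
* Transition periods between conditions, unequal cluster sizes, random
  (rather than regular) arrival processes, non-polynomial trends and
  outcome-data simulation / robust estimation are all out of scope.
* The search space is restricted to reversal-symmetric designs; removing
  a single participant (odd `n`) would leave that space and is not
  supported.
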