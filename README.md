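# swhunt

Design machinery for **stepped wedge cluster randomised trials with
continuous recruitment**. Participants present at each of `K` clusters at
regularly spaced times `1/M, ..., 1`; the investigator chooses when each
cluster crosses from control to intervention *and which presenting
participants to recruit*. Leaving slots unrecruited gives an
**incomplete design** that saves sample size — `swhunt` quantifies
exactly how much precision each schedule buys and searches for efficient
schedules at a target power.

## Who this is for

Trial statisticians planning stepped wedge (or more general cross-over)
studies where recruitment is continuous, each participant is measured
once, and recruitment effort is costly: the package answers "how few
participants, recruited when and where, still detect the effect of
interest?"

## Model

Outcomes follow a linear model with a polynomial secular trend and an
immediate treatment effect,

    Y_ik = T(t_ik) + θ · H(t_ik − t*_k) + ε_ik,

where `H` is the unit step and `t*_k` the cross-over time of cluster `k`.
Residuals have variance σ² and a within-cluster correlation that decays
with separation in time,

    Corr(ε_i1k, ε_i2k) = ρ · τ^|t_i1k − t_i2k|,

with independence between clusters (`τ = 1` is the classic exchangeable
structure). The treatment-effect precision of any schedule is the exact
GLS quantity: the inverse of the `(θ, θ)` entry of `(Z′V⁻¹Z)⁻¹`,
computed cluster-by-cluster from the block-diagonal covariance and
reported with σ² = 1.

The search works in the space of designs invariant under reversing time
and swapping condition labels (which leaves precision unchanged), and
alternates two steps: sample-size-preserving improvement moves
(cross-over shifts, recruitment relocations, applied to a half-cluster
and its mirror) and greedy removal — or, from a staircase start in the
backward direction, addition — of the mirror pair of participants that
matters least (most) to precision. Candidate changes are scored by
rank-one downdates of cached per-cluster inverse-correlation products,
so full-scale searches (`K = 30`, `M = 100`, 3000 participants) run in
minutes.

## Worked example

Six clusters, ten arrival slots each, intracluster correlation 0.05
decaying by a factor 0.2 across the trial, linear time trend. We want
90% power at the two-sided 5% level for a standardized effect
δ/σ = 1.2:

```r
library(swhunt)
sc <- sw_scenario(K = 6, M = 10, rho = 0.05, tau = 0.2, degree = 1)
attr(best_complete(sc), "precision")
#> [1] 12.06231
required_precision(power_spec(delta = 1.2))
#> [1] 7.296822
design <- hunt(sc, power_spec(delta = 1.2))
attr(design, "n"); attr(design, "precision"); attr(design, "power")
#> [1] 30
#> [1] 7.375074
#> [1] 0.9030086
print(design)
#> Stepped wedge design: K = 6, M = 10, n = 30 recruited
#>   1 |II..I.....|
#>   2 |ccIIII....|
#>   3 |ccIIII....|
#>   4 |....ccccII|
#>   5 |....ccccII|
#>   6 |.....c..cc|
#>   (c = recruited control, I = recruited intervention, . = skipped)
```

The complete design (60 participants) would have precision 12.06; the
target only needs 7.30, and the hunt finds a reversal-symmetric schedule
achieving it with 30 participants — recruitment hugging each cluster's
cross-over (with the middle clusters pairing up into phase-like groups),
plus a few slots in the off-diagonal corners. `write_design()`
saves the schedule as a plain CSV (`cluster,crossover_slot,s1,...,sM`);
`forward_search()` / `backward_search()` expose the full
precision-versus-n trajectories; `random_baseline()` and
`staircase_sweep()` provide the comparison envelopes.

A thin command-line wrapper is installed at `inst/cli/swhunt`:

```sh
Rscript inst/cli/swhunt hunt --K 6 --M 10 --rho 0.05 --tau 0.2 --degree 1 \
    --delta 1.2 --out design.csv
Rscript inst/cli/swhunt power --delta 0.3
```

Exit codes: 0 ok, 2 validation error, 3 identifiability error, 4 target
unachievable.

## Scope

No outcome data are ever simulated and no estimation from data is
performed; the package is design-time machinery. Transition periods,
unequal cluster sizes, random arrival processes, spline trends and
robust/GEE analysis are out of scope (see the vignette for the reasoning
and for numerical details of the search).
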