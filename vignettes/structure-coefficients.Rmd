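---
title: "Structure coefficients in group-structured populations: model, estimators, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure coefficients in group-structured populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(groupsigma)
```

## The model

A population of `N` individuals is fragmented into `M` groups arranged on a
circle. Each individual uses one of `S` strategies and plays a symmetric
matrix game `(a_ij)` with every other member of its own group, accumulating
payoff `p_k`; fitness is the linear map `f_k = 1 + delta * p_k`. Two update
rules are implemented:

* **Moran**: one individual reproduces (chosen with probability
  proportional to fitness across the whole population), then one of the `N`
  incumbents — possibly the parent, never the newborn — dies uniformly at
  random and the newborn fills the slot.
* **Wright–Fisher**: all `N` slots are refilled simultaneously by
  independent fitness-proportional offspring.

Each offspring independently mutates with probability `u` (adopting one of
the `S` strategies uniformly, the parental one included) and migrates with
probability `v`, displacing its group label by a draw from an isotropic
kernel `f(x)` on the circle (`f(x) = f(M - x)`). Both events can hit the
same offspring. Group sizes are unconstrained: groups drain and refill as
migration proceeds, which distinguishes this model from fixed-deme
stepping-stone models.

The one-parameter kernel family `range_kernel(M, r)` puts equal probability
on the signed displacements `{±1, ..., ±r}`. The two signed directions at
each magnitude are taken equiprobable — the choice forced by isotropy — so
`r = floor(M/2)` with odd `M` reproduces exactly the uniform
"global migration" pattern, and for even `M` with `r = M/2` the antipodal
group receives both directions' weight (`1/r`).

## The structure coefficients

Under weak selection (`delta -> 0`) the stationary mean frequency of
strategy `k` exceeds `1/S` exactly when

$$\sum_{q \ne k}\big[\sigma_1 a_{kk} + a_{kq} - a_{qk} - \sigma_1 a_{qq}\big]
  + \sigma_2\Big[\sum_q a_{kq} - \tfrac1S \sum_{p,q} a_{pq}\Big] > 0,$$

where the coefficients are neutral stationary expectations

$$\sigma_1 = \frac{E[x_1 I_{22} - x_1 I_{23}]}{E[x_1 I_{21} - x_1 I_{23}]},
  \qquad
  \sigma_2 = \frac{E[S\,x_1 I_{23}]}{E[x_1 I_{21} - x_1 I_{23}]},$$

with `x_1` the frequency of strategy 1 and `I_ij` the total number of
within-group games between `i`- and `j`-players (same-strategy games count
twice on the diagonal). We verified this condition by an independent
first-order perturbation argument: at stationarity the exact balance
`<x_k> = 1/S + delta (1-u)/u * E0[x_k(p_k_bar - p_bar)] + O(delta^2)` holds,
and expanding the payoff covariance over ordered individual pairs and
triples produces precisely the two-term condition above, including the
two-strategy reduction `sigma = (2 sigma1 + sigma2)/(2 + sigma2)`
implemented in `two_strategy_sigma()`. The coefficients depend on
`N, M, u, v`, the kernel and the update rule — never on the payoff matrix
(enforced by the interface: no sigma routine accepts payoffs) and never on
`S` (the label roles 1, 2, 3 are arbitrary under neutral exchangeability).

## Three independent routes

**Closed form** (`sigma_closed_form()`). The sigma expectations decompose
over ordered triples of distinct individuals into the joint law of
(a) the identity-by-descent pattern of three sampled lineages — which pairs
are separated by no mutation since their common ancestor — and (b) the
co-residence of two of them. Under neutrality reproduction is blind to
location and payoff, so the genealogy is independent of the mutation and
migration marks, and each needed probability satisfies a first-step
recursion backward in time. On the circle the displacement distribution
diagonalises over Fourier modes `lambda_j = sum_x f(x) cos(2 pi j x / M)`;
with `m_j = 1 - v + v lambda_j` and `w = 1 - u`, the two-lineage factor is
`H = z/(N - (N-1) z)` with `z = w m_j` (Moran: one lineage moves per event)
or `z = (w m_j)^2` (Wright–Fisher: both lineages move every generation).
Three-lineage pattern probabilities follow by conditioning on which pair
coalesces first (plus the simultaneous triple merger for Wright–Fisher) and
averaging over the `M` modes to impose co-residence. The result costs
`O(M)` arithmetic, is valid for any `N >= 3` and any `u in (0, 1]`, and all
`S`-dependence cancels in the two ratios — confirming the known
`S`-independence. Useful special values it reproduces: without migration
the Moran coefficients are exactly `sigma1 = (N-2)(1-u)/N` and
`sigma2 = (N-2)u`; the two-strategy `sigma` of the well-mixed population is
`(N-2)/N` for *every* `u`, for both update rules — the classic
arbitrary-mutation-rate result; as `u -> 0`, `sigma1 -> (N-2)/N`; at
`u = 1`, `sigma1 = 0`. In the large-population limit without migration the
Wright–Fisher `sigma2` is `(2 - u)` times the Moran value at equal `N` and
`u`; the familiar "factor two" (`Nu` versus `2Nu`) is the leading order of
this ratio in `u`.

**Exact enumeration** (`sigma_exact()`). The trusted oracle: all `(S M)^N`
states, the exact neutral transition matrix (Moran rows from uniform parent
and death choices; Wright–Fisher rows as products of per-slot offspring
laws), a dense stationary solve, and the exact stationary expectations. It
shares no code path and no formula with the closed form. Without migration
the location chain fixes in a single group; every closed class is
isomorphic to the `M = 1` chain, which is what gets built then.

**Monte Carlo** (`estimate_sigma_mc()`). The Methods-style accumulator: run
the neutral chain, add up the three statistics over recorded states, and
take the two ratios. The compiled driver maintains the count matrix and the
pairwise game sums incrementally (O(1) per Moran event). Optional label
symmetrisation averages the statistics over all ordered triples of distinct
strategy labels — a free variance reduction licensed by neutral label
exchangeability. Standard errors use 50 equal batch means with delta-method
propagation through each ratio; when `|sum(td)|/n` falls below
`1e-6 * N^2` the estimate is flagged `unreliable` instead of silently
returning a huge ratio.

The three routes agree to ~`1e-14` (closed form vs. exact) and to within
sampling error (Monte Carlo vs. both) on every enumerable instance in the
test suite; that three-way agreement is the package's central correctness
property.

## Tunable parameters

| parameter | meaning | constraint / default |
|---|---|---|
| `N` | population size | `>= 2` (`>= 3` for sigma) |
| `M` | groups on the circle | `>= 1` |
| `S` | strategies | `>= 2` (`>= 3` for sigma estimation) |
| `u` | mutation probability per offspring | `[0, 1]`; sigma needs `> 0` |
| `v` | migration probability per offspring | `[0, 1]` |
| `r` | migration range | `1..floor(M/2)` |
| `delta` | selection intensity | `>= 0`, small enough that `1 + delta p > 0` for every reachable payoff |
| `n_steps`, `burn_in` | chain length / discard | defaults `1e6` / `1e4`, desk scale; raise for production |

One Moran birth–death event counts as one recorded "generation", so Moran
and Wright–Fisher runs of equal `n_steps` see very different numbers of
birth events per capita; rescale accordingly when comparing mixing.

## Fixtures and what the tests do (and do not) show

`fixture_random_state()` and `fixture_random_kernel()` generate uniformly
random valid states and random isotropic kernels for property-style tests;
the chain initialiser (strategies i.i.d. uniform, everyone in group 1) is
irrelevant after burn-in and is used only for reproducibility. These
fixtures emulate the model's own state space, not any empirical data: a
passing suite certifies the mathematics and the implementation, not the
fit of the model to real populations.

Problem sizes in the tests are chosen for desk-scale runs: exact-oracle
comparisons at `N = 3, 4`, `M = 2`; Monte-Carlo consistency runs at
`N = 20` with `1e7` events; the weak-selection end-to-end check at `N = 50`,
`M = 7`, `delta = 0.01` with `1e7` events. Long production runs (e.g.
`1e9` generations at `N = 100`) are supported by the same compiled drivers
but are not exercised in the suite.

## Numerical choices

* **Stationary solves**: dense LAPACK solve of `(P^T - I)` with a
  normalisation row, residual checked below `1e-12`. Chains with a single
  closed class are accepted (transient states get mass zero); several
  closed classes are rejected with the class listing, since the stationary
  law is then ambiguous.
* **`u -> 0` limit**: all four ingredients of the sigma ratios vanish
  linearly in `u`, so `sigma_limit_small_u()` computes the ratio of
  derivatives at `u = 0` by complex-step differentiation (`h = 1e-80`) —
  exact to rounding for these rational functions, with no cancellation.
* **RNG**: the compiled drivers consume R's own RNG stream, so
  `set.seed()` makes every trajectory, estimate and sweep bit-reproducible;
  sweep row `i` derives its seed as `seed + i`.
* **Degenerate inputs**: `u = 0` is rejected by every sigma route (no
  mutation–selection balance); non-positive fitness aborts with the
  offending step; kernels are validated for symmetry, positivity and
  normalisation to `1e-12`.

## Design choices

* **Moran death rule**: the dying individual is drawn uniformly from the
  `N` incumbents; the newborn is exempt. The alternative (death among
  `N + 1`) shifts the coefficients only at `O(1/N)`.
* **Payoff aggregation**: payoffs accumulate over all co-residents (the
  game-count reading); a lone individual earns 0 and fitness 1. Under
  neutrality this choice cannot affect the sigma coefficients; it matters
  only for `delta > 0` validation runs.
* **Mutation and migration** are independent Bernoulli draws per offspring;
  order is irrelevant.
* **End-to-end sign test**: the direct-reciprocity check runs `m = 2`
  rounds at `delta = 0.01`. With `b = 1` this bounds the worst reachable
  payoff (a tit-for-tat player in a group full of defectors) well away from
  the `1 + delta p = 0` boundary, so the linear fitness map stays valid for
  every reachable state; larger `m` at this `delta` can crash into the
  boundary when a large group fills with defectors.
* **Critical cost-to-benefit ratio**: `(c/b)*` is found by solving the
  gradient's linear root in `c/b` from two evaluations of the simulated
  payoff automaton, not by transcribed algebra; a negative root is returned
  as is (it means cooperation is never favoured, as in one-shot games with
  `sigma1 < 1`).

## Known limitations

* The variant in which migration occurs *before* reproduction (one random
  incumbent in the Moran case, everyone in the Wright–Fisher case) is out
  of scope and not implemented.
* The exact oracle is deliberately brute force; it is a correctness anchor,
  not a production tool, and refuses state spaces beyond `2e5` states.
* Non-vertex-transitive migration graphs are rejected by design; only
  isotropic kernels are meaningful for these coefficients.
* Closed-form evaluation at extremely small `u` (below ~`1e-8`) loses
  digits to cancellation; use `sigma_limit_small_u()` there.
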