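---
title: "Stochastic multiclonal homeostasis of the naive T cell repertoire"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic multiclonal homeostasis of the naive T cell repertoire}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonedyn)
```

## The model

A T cell clonotype is the set of T cells carrying the same T cell receptor.
`clonedyn` models the naive repertoire as `N(t)` clonotypes with integer cell
counts `n_i(t)`, coupled through competition for division stimuli delivered
by `M` subsets of self peptide-MHC (pMHC). Recognition is a random bipartite
graph: clonotype `i` recognises pMHC subset `q` independently with
probability `p`, so cross-reactivities `phi_i` are Binomial(`M`, `p`)
draws (conditioned on `phi_i >= 1`; see below) with mean `pM`.

Three event types drive the continuous-time Markov chain:

* **death** — every cell dies at rate `mu`, independent of clonotype;
* **division** — pMHC subset `q` delivers stimulus at rate `gamma_q`,
  divided equally among all `c_q(t)` cells that recognise it, so clonotype
  `i` divides at rate
  `Lambda_i = n_i * sum_{q in Q_i, c_q > 0} gamma_q / c_q`;
* **thymic export** — new clonotypes arrive at rate `theta` with `n_theta`
  cells each and a freshly drawn recognition pattern. The thymus never adds
  cells to an existing clonotype, so extinction is irreversible.

Realisations are generated with the exact Gillespie algorithm: one of the
`2N+1` events is chosen with probability proportional to its rate and time
advances by an Exponential(mean `1/S`) increment, where
`S = sum_i (mu n_i + Lambda_i) + theta`.

Two exact bookkeeping identities hold at all times and are asserted
throughout the test suite: the counting identity `M*C_bar(t) =
N(t)*phi_bar(t)` (both sides count the live clonotype-pMHC connections), and
stimulus conservation `sum_i Lambda_i = sum_{q: c_q>0} gamma_q`, which makes
the mean total cell count relax on the timescale `1/mu` to

```
x* = (gamma*M + theta*n_theta) / mu.
```

## Parameters and their physiological values

| parameter | meaning | human | mouse |
|---|---|---|---|
| `mu` | per-cell death rate | 0.5 / yr | 1 / mo |
| `gamma` | divisions driven by one pMHC subset | 10 / yr | 1e-4 / mo |
| `theta` | new clonotypes from the thymus | 1e9 / yr | 2.5e6 / mo |
| `M` | self-pMHC subsets | 1e10 | 1e10 |
| `p` | recognition probability | 1e-6 | 1e-6 |
| `n_theta` | cells per exported clonotype | 4 | 4 |

The presets (available via `species_params()`) pin `gamma*M/mu` to the
measured naive CD4+ pool (`2e11` cells in an adult human) and the thymic
cell export (`theta*n_theta ~ 4e9`/yr). The time unit is set by `mu`: one
unit is the mean cell lifetime without division stimulus. Simulated scales
use the same dimensionless combinations (`pM`, `alpha`, `gamma*M/mu`) at
computable sizes; the scaling experiment (below) is the evidence that this
is legitimate.

The key dimensionless parameter is the thymic-to-peripheral production
ratio

```
alpha = n_theta * theta / (gamma * M),
```

about 0.04 in an adult human (peripheral division dominates) and about 10
in a mouse (thymic export dominates).

## Clonal lifetimes and clonotype numbers

The number of clonotypes equals the thymic production rate times the mean
clonal lifetime, `N* = theta * T(alpha, n_theta)`. `T` is obtained from a
diffusion approximation of the single-clone process: replacing competitor
sums by their homeostatic means gives the mean-field division rate
`Lambda_i = mu n_i / (1 + alpha)`, so increments of `n_i` have mean
`-mu*alpha/(1+alpha)*n_i*dt` and mean square `(2+alpha)/(1+alpha)*mu*n_i*dt`.
For `alpha << 1` the mean first-passage time to zero from `b` cells solves
`mu b T'' - alpha mu b T' = -1`, giving

```
T(alpha, b) = (gamma_E - e^(alpha b) Ei(-alpha b) + log(alpha b)) / (alpha mu)
```

with `Ei` the exponential integral and `gamma_E = 0.5772...` the
Euler-Mascheroni constant (`mean_extinction_time()`). As
`alpha*b -> 0` this reduces to `T -> (b/mu)(1 - gamma_E - log(alpha b))`,
the asymptotic mode of `clonotype_number()`. At `alpha = 0` the process is
critical: the mean lifetime diverges (the function returns `Inf`) and the
extinction-time distribution is `P[extinct by t] = exp(-b/(mu t))`
(`extinction_probability()`); at the repertoire level the appropriate
initial condition is the homeostatic share `b = gamma*M/(mu*N(0))`.

With the human numbers (`alpha = 0.04`, `n_theta = 4`, `mu = 0.5`/yr,
`theta = 1e9`/yr) the asymptotic form gives `N* ~ 1.8e10`, nine percent of
the `2e11` naive cells; the exact form gives `~2.0e10` (ten percent). Both
are reported by `theory_report()`; the asymptotic value is the headline
number. In the murine regime (`alpha ~ 10`) the diffusion derivation is
outside its validity (`alpha << 1`); there clonotypes decay essentially
independently from `n_theta` cells, the lifetime-averaged clone size is
`n_theta/2`, and `murine_clonotype_number()` applies:
`N* = 2x/n_theta ~ 5e6` for `x = 1e7` naive cells. Because a surviving
clone has at least one cell, the mean clone size is floored at 1
(`n_theta = 1` returns `N* = x` with a warning).

### Accuracy of the diffusion approximation

The package carries an independent Monte Carlo oracle
(`birth_death_extinction_oracle()`): direct Gillespie simulation of the
single-clone chain with birth rate `mu n/(1+alpha)` and death rate `mu n`.
The oracle is validated against the exact discrete closed form
`T_b = (1/lambda) sum_{n<=b} sum_{k>=0} rho^(k+1)/(n+k)` and then compared
with the diffusion formula. The gap is a few percent for
`alpha*n_theta <~ 0.5`, about 9% for single-cell emigrants
(`n_theta = 1`), and grows to ~19% at `alpha*n_theta = 2` — the
closed form is a small-`alpha` result and the tests record this honestly
rather than averaging it away.

Similarly, at the repertoire level the critical-diffusion extinction law
`exp(-b/(mu t))` with `b = gamma*M/(mu N(0))` describes the *late-time*
extinct fraction (`t >> b/mu`) well, but intermediate times deviate by up
to ~0.17 in the reference configuration: clones start at `n_i(0) = 25`
cells, below their homeostatic share `b = 50`, and the spread of `phi_i`
gives clonotype-dependent growth rates, both of which accelerate early
extinction relative to the homogeneous diffusion. The tests assert the law
in its regime of validity (`t >= 80` for the reference configuration) and
assert the faster-than-predicted direction elsewhere.

## The synthetic-data generator

All inputs are self-generated; the network generator *is* the study
design. Choices that matter:

* **Independent Bernoulli connections.** No degree correlations or
  structured cross-reactivity; `phi_i ~ Binomial(M, p)`.
* **Zero-degree redraws.** Clonotypes drawing an empty pattern are redrawn,
  mirroring thymic selection (every exported clonotype recognises some self
  pMHC). At the default `pM = 100` a redraw has probability `e^-100`; the
  policy only matters for deliberately sparse test networks, and
  `generate_network()` warns when `pM < 1`.
* **Monotone identifiers.** Clonotype ids are never reused, so extinction
  is irreversibly recorded, and replicate designs can share one network
  ("the same in-silico individual") while varying only the dynamics seed —
  the three named seed streams (`network`, `dynamics`, `thymus`) exist for
  exactly this.
* **Log-normal stimulus rates.** With dispersion `sigma` (= sd/mean), the
  log-space parameters are moment-matched: variance `log(1+sigma^2)`, mean
  `log(gamma) - log(1+sigma^2)/2`.

What the generator does *not* emulate about real repertoires: sequence-level
TCR structure (clonotypes are abstract pattern holders), cell-level
heterogeneity (IL-7R/CD5 expression), memory formation, foreign antigen,
age-dependent thymic output, or spatial circulation. Passing tests
therefore validate the competition mechanism and its analysis, not any
sequence-level prediction about real data.

## Numerical choices

* **Incremental rate caches.** An event in clonotype `i` changes `c_q` only
  for `q in Q_i`, and only clonotypes sharing those subsets have their
  stimulus-share sums updated (a delta of `gamma_q (1/c_new - 1/c_old)` per
  member). A pMHC subset whose last recognising cell dies contributes
  nothing until a recognising clonotype appears again. The total rate is
  re-summed from the cached shares every event, so selection and the time
  increment are always mutually consistent; scratch recomputation of every
  cache after `>1e4` events agrees to integer exactness for `c_q` and
  `<1e-9` relative error for `Lambda_i`.
* **Recording** happens on a fixed `record_dt` grid (state is constant
  between events, so a grid point inside a waiting interval records the
  pre-event state); fates are recorded at exact event times. Horizon
  comparison is a plain `t >= t_max`.
* **Exponential integral.** `Ei(-z) = -E1(z)` via pracma; for
  `alpha*b < 1e-8` the asymptotic lifetime form avoids catastrophic
  cancellation, and for `alpha*b > 50` the product `e^z E1(z)` is expanded
  asymptotically to avoid overflow. `gamma_E` is fixed at
  0.5772156649015329.
* **Plateau estimation.** Steady-state levels are time-averages over the
  final 25% of the horizon with a block-bootstrap standard error (blocks of
  10 recording intervals), since successive records are autocorrelated.
* **Event selection** uses a cumulative scan over the per-clonotype rates
  (theta first); ties are irrelevant in continuous time, and a terminal
  roundoff guard assigns the (probability-zero) leftover to the last live
  clonotype.

## Experiment drivers and the scales used in the tests

The drivers default to the published configurations: extinction
(`mu = 1, gamma = 10, M = 1000, p = 0.1, N(0) = 200, n_i(0) = 25`), degree
drift (`M = 2000, p = 0.05, N(0) = 1000, n_i(0) = 10`), selectivity
(`gamma = 10, M = 1000, p = 0.1`, ten replicates on one network, horizon
`1e4`; death rate and initial clone size are not stated for this
configuration and are adopted from the degree-drift one — the manifest
records this), scaling (`M in {1600, 3200, 6400}`, `pM = 100`,
`N(0) = M/4`), thymic input (`theta in {0.1, 1, 10, 100, 400}`/yr,
`M = 4000`, `pM = 100`, `n_theta = 4`) and log-normal rates
(`sigma in {0, 0.5, 1}`, `theta = 400`/yr). The thymic-input configuration
does not state an initial repertoire; the driver starts from an empty
periphery so the steady state is built entirely by thymic export, which is
the cleanest setting for comparing the plateau with `theta*T(alpha,
n_theta)`. One consequence worth knowing: the first clonotypes to arrive in
an empty periphery face no competition and balloon to a large share of
`x*`, and the extinction of these giant founders — not `T(alpha, n_theta)`
— sets the equilibration timescale, which is therefore much longer for
small `theta`. Horizons for plateau comparisons must cover it.

The test suite runs reduced versions chosen to finish in minutes while
keeping every scientific assertion meaningful: five replicates of the
extinction configuration to `t = 100` (stationary mean, extinction law,
counting identity), six selectivity replicates to `t = 60` (extinction
saturates early, so survival-count structure and the `phi`-survival rank
association are established long before the published horizon), scaling
with `M in {1600, 3200}` to `t = 15`, and thymic-input/log-normal checks at
`M in {100, 500}` with `pM` preserved. The theory-curve driver
(`theory_curves()`) regenerates the `N*(alpha)` family on a log grid for
`n_theta in {1, 4, 16}`; its tests assert the curve's shape (monotonicity,
asymptotic agreement at small `alpha`), not pointwise values.

## Known limitations

* The exact algorithm updates all affected division rates every event, so
  physiological cell numbers (`1e11`) are out of reach by design; the
  theory layer covers those scales, and the scaling property (`p*N(t)`
  invariant as `M` grows at fixed `pM`) justifies extrapolating the
  simulated behaviour.
* The diffusion lifetime is a small-`alpha` result (see accuracy notes
  above); in the murine regime use the weak-division estimate.
* Constant `mu`, `theta` and a well-mixed periphery: no lymphopenia,
  ageing, or tissue structure.
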