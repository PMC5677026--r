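---
title: "Half-lie search games: model, heuristics, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Half-lie search games: model, heuristics, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(halflie)
library(ggplot2)
```

## The problem

A confocal or multiphoton microscope looking for a single fluorescent
emitter is, formally, a player in a search game. Each acquisition
illuminates a controllable region of the sample and asks "is the target in
here?". The emitter produces at most one signal photon per query, and the
instrument loses that photon — through finite collection angle, fibre
attenuation, detector inefficiency — with probability $\alpha_0$, the
complement of the system collection efficiency. The resulting error
structure is *asymmetric*: a detected photon ($r = 1$) proves the target is
inside the illuminated region, but a null result ($r = 0$) is ambiguous —
the target may be elsewhere, or its photon may simply have been lost. In
the language of search games with lies, only "yes" states can be
misreported, and they are misreported at random with a fixed rate: a
*statistical half-lie* game. Typical confocal conditions sit near
$\alpha_0 \approx 0.99$, far beyond the error rates at which
worst-case-optimal strategies for games with bounded lie budgets exist, so
the natural objective is the *average* number of queries over random
target positions, under the hard constraint that the final answer must be
certain (100% fidelitous).

`halflie` implements this game in one dimension: a target at unknown
position $x_0$, uniform on $[0, L]$, to be localized to within a fraction
$\varepsilon$ of the domain using top-hat (sharp-edged, flat) illumination
profiles. Multi-dimensional searches factor into independent
one-dimensional games, one per axis.

## The measurement model

A query illuminates the half-open interval $[b, c)$. If the target is
outside, no photon is generated and $r = 0$ with certainty. If it is
inside, one photon is generated and survives with probability
$1 - \alpha_0$:

$$\mathbb{P}(r \mid n, \alpha_0)
  = \delta_{n,0}\,\delta_{r,0}
  + \delta_{n,1}\,[\alpha_0\,\delta_{r,0} + (1 - \alpha_0)\,\delta_{r,1}].$$

There are no dark counts: $r = 1$ is always truthful. Three representation
choices fix the simulation's determinism:

* **Half-open intervals.** A target belongs to exactly one of the $q$
  equal subdomains at every level of a sectioning search. Boundary
  membership is a measure-zero event under the uniform prior, so the
  choice is statistically irrelevant, but it must be pinned for exact
  reproducibility. The single exception is the domain's right edge $L$,
  which is treated as closed so that a target exactly at $L$ still has a
  home.
* **One random draw per illuminated query, none otherwise.** Queries that
  miss the target are deterministic and consume no randomness, so a
  trial's trace is exactly replayable from its seed and is invariant to
  how many misses occur.
* **Integer index tracking.** Inside a trial the current interval is a
  (level, index) pair; real coordinates are materialized only on output.
  Over the ~20–35 levels of a high-precision search this avoids cumulative
  floating-point drift entirely (indices stay below $2^{53}$ for every
  supported precision).

## Information per query and the optimal boundary

With a uniform prior, a query $[0, v)$ has mutual information between
position $X$ and result $R$ (natural logs, $L = 1$):

$$I(X\!:\!R) = -\big[(1-\alpha_0)\,v\log v
  + (1 - v + \alpha_0 v)\log(1 - v + \alpha_0 v)
  - \alpha_0 v \log \alpha_0\big].$$

`mutual_information()` evaluates this closed form with explicit
$0 \log 0 := 0$ guards; the unit is nats internally, with bits available
for the query-budget arithmetic (the two differ by $1/\log 2$). The test
suite checks it against an independent oracle that discretizes the joint
distribution on a fine grid and sums entropies directly.

Maximizing over $v$ gives the information-optimal boundary

$$v_0 = \frac{L\,\alpha_0^{\alpha_0/(1-\alpha_0)}}
  {1 + (1-\alpha_0)\,\alpha_0^{\alpha_0/(1-\alpha_0)}},$$

which is $L/2$ at zero loss (classical bisection) and tends to $L/e$ as
$\alpha_0 \to 1$: under loss one interrogates a *smaller* region, so a
surviving positive is worth more. At $\alpha_0 = 0$ the implementation
returns the analytic limit $L/2$ exactly rather than evaluating the
$0^0$-style expression; at $\alpha_0 = 1$ the boundary is undefined and
the input is rejected. Dividing the required $\log_2 \varepsilon^{-1}$
bits by the per-query maximum gives `estimated_optimal_queries()`, an
information-accounting estimate (not an achievable strategy): 34 perfect
queries for $\varepsilon^{-1} = 10^{10}$ at zero loss, 6240 at
$\alpha_0 = 0.99$.

```{r infomap, fig.width = 6, fig.height = 3.5}
autoplot(information_map(
  loss_grid = seq(0, 0.95, length.out = 40),
  boundary_grid = seq(0.01, 0.99, length.out = 99)
))
```

## q-sectioning with verification

A greedy strategy that re-optimizes $v$ after every query is hard to
update after null results and is not pursued here. Instead the package
implements a simple heuristic family: split the current interval into $q$
equal subdomains, query them cyclically left to right until a positive
detection *verifies* the target's subdomain, recurse into it, and repeat
for exactly $\lceil \log_q \varepsilon^{-1} \rceil$ levels (the final
split is still into $q$ subdomains even when fewer would reach
$\varepsilon$). Because the interval shrinks only on a truthful positive,
the final interval always contains the target, whatever the loss rate —
verification buys certainty at the price of ignoring the (weak) evidence
in null results.

Two engines produce the total query count:

* `run_qsectioning()` — the reference path: every individual query is
  simulated; per-level counts and the final interval are recorded.
* `sample_query_count_fast()` — the performance path: for a uniform
  random target the base-$q$ digits of the position are independent and
  uniform, so each level independently contributes $(k-1)q + l$ queries
  with $l \sim \mathrm{Unif}\{1..q\}$ and $k$ geometric with success
  probability $1-\alpha_0$. The two engines are distributionally
  identical; tests compare both to an exhaustive $(k, l)$ enumeration
  oracle and to each other.

The expected cost has a closed form. At zero loss the successful pass
costs $(q+1)/2$ on average, so
$\bar m_{q,\varepsilon,0} = \tfrac{q+1}{2}\lceil\log_q\varepsilon^{-1}\rceil$;
under loss, $1/(1-\alpha_0)$ passes must hit the correct subdomain before
a photon survives, each wasted pass also paying for the other $q - 1$
subdomains:

$$\bar m_{q,\varepsilon^{-1},\alpha_0}
  = \Big[q\Big(\tfrac{1}{1-\alpha_0} - 1\Big) + \tfrac{q+1}{2}\Big]
    \big\lceil \log_q \varepsilon^{-1} \big\rceil.$$

Rastering baselines (`rastering_verification_mean()`,
`conventional_raster_queries()`) and the comparison-question lower bound
with a bounded number of one-sided errors (`rivest_lower_bound()`) are
provided for context; both rasters scale linearly in $\varepsilon^{-1}$
and are uncompetitive at any appreciable precision.

## The level count, done exactly

Everything downstream multiplies a rational prefactor by
$\lceil \log_q \varepsilon^{-1} \rceil$, so this integer must be exact. A
naive `ceiling(log(n)/log(q))` misfires at exact powers of $q$ for some
$(q, n)$ pairs — in this R build, for example, at $n = 5^3$, $5^6$,
$6^3$, $6^6$ and $7^5$ — and each misfire silently shifts a whole step of
every cost curve. `sectioning_levels()` therefore finds the smallest $t$
with $q^t \ge n$ by exact integer power accumulation whenever $n$ is an
integer, and guards the float logarithm with explicit adjacent-power
checks otherwise. Level arithmetic is exact up to
$\varepsilon^{-1} = 2^{48}$, beyond which double-precision power tables
would fail; inputs beyond that are rejected rather than silently wrong.

## Optimality censuses and their sensitivity

`optimality_map()` and the streaming counter `count_optimal_q()` evaluate
the cost for every candidate $q$ over dense ranges of integer
$\varepsilon^{-1}$ and record the argmin set per cell. Ties matter: every
$q$ attaining the minimum is counted *optimal*, and a cell is *unique*
only when the argmin set is a singleton. Costs are half-integer-valued
multiples of level counts, with genuine gaps never below $0.5$, so a
guarded relative tolerance of $10^{-9}$ classifies ties exactly while
absorbing $\sim 10^{-14}$ float noise in the lossy prefactor.

Two census results are worth quoting (both recomputed by the test suite
and the acceptance script):

* **Zero loss, $\varepsilon^{-1} \in \{2,\dots,10^6\}$.** Among the four
  heuristics bi- through penta-sectioning, tetrasectioning is the most
  frequent winner: optimal in 611,612 of the 999,999 cells.
  Trisectioning and tetrasectioning jointly cover the overwhelming
  majority; with candidates extended to $q \in \{2,\dots,8\}$ the joint
  $\{3,4\}$ count is 987,354 and the tetrasectioning count 611,603
  (unique in 569,966) — orders above 8 never win a cell.
* **Heavy loss ($\alpha_0 = 0.99$), $\varepsilon^{-1} \in
  \{2,\dots,2^{24}\}$, $q \in \{2,\dots,5\}$.** Every cell has a unique
  winner; trisectioning takes 14,253,480 of the $2^{24}-1$ cells —
  85.0% — and sampling shows it is the unique winner for every
  $\varepsilon^{-1} > 2^{24}$ tested up to the $2^{48}$ numeric guard.

The census integers are *sensitive at the last few counts* to two
implementation choices that deserve flagging. First, the candidate
universe: adding candidates can only take cells away from a given $q$
(the $\{2..5\}$ versus $\{2..8\}$ tetrasectioning counts above differ by
nine cells). Second, the level computation: a float-log ceiling that errs
at a handful of exact powers of $q$ moves exactly those boundary cells
between neighbouring argmin sets — an error at $\varepsilon^{-1} = 3$
alone would hand bisectioning an extra win and change the joint
$\{3,4\}$ count by one. This package pins both choices (exact integer
levels; the universe as an explicit argument) so its counts are stable
and reproducible; analyses that used float logarithms can legitimately
differ from them by a few cells per million.

The cost is a step function of $\varepsilon^{-1}$, constant between
consecutive powers of any candidate $q$, so wide maps can be drawn from
the compressed grid `fig6_epsilon_grid()` — the points $q^i - 1$, $q^i$,
$q^i + 1$ straddle every step and classify entire intervals at once.

```{r optmap, fig.width = 6.5, fig.height = 3.5}
autoplot(optimality_map(
  fig6_epsilon_grid(2:5, 1e8),
  loss_rates = seq(0, 0.95, by = 0.05),
  q_candidates = 2:5
))
```

## Monte Carlo machinery

`run_trials()` draws uniform targets and summarizes total query counts;
`summarize_counts()` reports mean (with its standard error, so sampling
tolerances are self-documenting), median (even-length samples average
the central pair), mode (smallest count on ties — the distributions are
integer-supported, histogram bin width is 1), and the empirical CDF at
observed support points. At heavy loss the count distribution is strongly
right-skewed — the support is semi-infinite — so mean > median > mode, and
all three are reported rather than any single summary.

Reproducibility is bit-exact given `(config, n_trials, seed, engine)`.
The naive engine derives trial $i$'s seed as `seed + i`, so any single
trial can be replayed in isolation.

```{r mc, fig.width = 6, fig.height = 3.5}
mc <- run_trials(game_config(1e-6, 0.99, 3), 2e4, seed = 1)
glance(mc)
autoplot(mc)
```

## What the simulator does and does not emulate

The generator *is* the model: top-hat illumination with perfectly sharp,
instantly reconfigurable boundaries, exactly one signal photon per
illuminated query, loss i.i.d. at a known constant rate, no dark counts,
a single immobile emitter, uniform prior. Passing tests therefore
demonstrate internal correctness of the game, not instrument realism:
real point-spread functions roll off smoothly (so edge cells are
dimmer), reconfiguring spot size and position costs time, photobleaching
and photodamage penalize illumination unevenly, and detectors do fire
spuriously at some low rate, which breaks the guarantee that a positive
is truthful. Those effects are deliberately out of scope here.

## Problem sizes and default settings

Defaults mirror the study conditions this package models: headline Monte
Carlo runs use $10^6$ trials at $(q = 3, \varepsilon^{-1} = 10^{10},
\alpha_0 = 0.99)$ — about four seconds with the fast sampler — while
sweep-style checks use $10^3$–$10^5$ trials. Census defaults are
$q \in \{2..8\}$ for lossless scans and $q \in \{2..5\}$ at heavy loss,
both configurable as discussed above. The information-map default grid is
101 loss rates on $[0, 0.99]$ by 1001 interior boundaries, a resolution
choice (the ridge is analytic, so the grid only drives plotting). The
unit-tests' stochastic checks run at reduced scale ($10^3$–$10^4$ trials)
with seeds fixed in the test code, asserting agreement within 3–4
standard errors against closed forms or enumeration oracles.

## Known limitations

One spatial dimension only (higher dimensions factor, but no helper is
provided); loss rate assumed known and constant; no adaptive
re-optimization of the boundary between queries inside the heuristic; the
$E \log_2 E$ term of the comparison lower bound is taken as zero for
$E \le 1$ and the bound is not exercised beyond small $E$; censuses
beyond $\varepsilon^{-1} = 2^{48}$ are rejected rather than extended with
big-integer arithmetic.
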