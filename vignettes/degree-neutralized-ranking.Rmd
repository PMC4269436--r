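---
title: "Rating competitors with degree-neutralized random walks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rating competitors with degree-neutralized random walks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(walkrank)
library(dplyr)
```

## The model

A season of pairwise contests defines a weighted directed *competition
network*: competitors are nodes, and the edge weight $w_{ij}$ is the
cumulative number of points $i$ scored against $j$ (repeated fixtures are
summed into the same pair of weights). The rating question is how to turn
this asymmetric weight matrix into a single strength ordering.

`walkrank` answers it with a random walker that drifts along score
*gradients*. On the edge between $i$ and $j$ the walker's preference for
stepping toward $i$ is

$$g_{j \to i} = \frac{w_{ji} + \varepsilon}{w_{ij} + w_{ji} + 2\varepsilon},$$

the share of the pair's points scored *against* $i$, regularized by
$\varepsilon > 0$. The two directions are complementary
($g_{j\to i} + g_{i \to j} = 1$), strictly positive, and equal to $1/2$ on
any tie, including a scoreless one — that is what $\varepsilon$ is for.
Because both directions stay positive, the walker can move "uphill": an
upset is improbable, not impossible, and no node with a perfect record can
trap the walk.

Raw occupancy of such a walk is still biased by topology: a node with many
distinct opponents offers many pathways in, inflating its visit rate no
matter how it played. The canonical example is a three-team chain of draws,
A–B–C: transitivity says the three ought to be rated equal, yet the middle
team has twice the degree. The transition probability therefore discounts
the target's distinct-opponent degree $k_i$,

$$T_{ij} = \frac{1}{Z_j}\,\frac{g_{j\to i}}{k_i},
  \qquad Z_j = \sum_{i \sim j} \frac{g_{j\to i}}{k_i},$$

with $Z_j$ normalizing each column. $k$ counts *distinct opponents*, not
games: repeated fixtures are already merged into the cumulative weights, so
a double meeting widens an edge rather than adding a pathway.

The stationary occupancy $\mathbf{w}$ of the loser-seeking walk measures
*weakness*; reversing every gradient gives a winner-seeking walk whose
occupancy $\mathbf{s}$ measures *strength*. Neither picture is privileged,
so the final rating is the antisymmetric combination

$$\pi_i = s_i - w_i,$$

which is zero on perfectly balanced fixtures, flips sign when every score
is transposed, and by construction satisfies the duality
$\mathbf{s}(W) = \mathbf{w}(W^\top)$ exactly. Any symmetric monotone
combination of $\mathbf{s}$ and $-\mathbf{w}$ would preserve the package's
invariants; the difference is the simplest one and keeps ratings on an
interpretable occupancy scale.

## Parameters that matter

* `epsilon` (default **1**, dimensionless points): the gradient
  regularizer. It must only be positive; it sets how strongly a blowout is
  distinguished from a narrow win when few points have been scored. On a
  decisive fixture it does not reorder teams (the test suite asserts this
  on the transitive triangle for $\varepsilon \in \{0.5, 1, 2\}$); it
  mostly matters for early-season networks full of low totals.
* `normalization` (default **"column"**): $Z_j$ as a per-column
  normalizer. The alternative `"lazy"` mode uses one global normalizer and
  places the shortfall on self-loops. The two agree on orderings in
  practice but differ on the degenerate two-node network, where the bare
  walk is a deterministic 2-cycle whose occupancy is $(1/2, 1/2)$
  regardless of scores; only the lazy walk separates the teams there.
  Column normalization is the default because it is the direct reading of
  a per-target normalizing factor and keeps the chain maximally mixing.
* `teleport` (default **0**): disconnected early-season networks are rated
  per connected component, each component's occupancy scaled by its share
  of nodes. A PageRank-style random jump is available instead but is off
  by default: an indiscriminate jump equalizes nodes for reasons unrelated
  to performance, which is exactly the failure mode the gradient walk is
  designed to avoid.
* `eig_tol` (default 1e-12) and `max_iter` (1e6): the stationary vector is
  obtained from the balance equations by a dense linear solve up to 2000
  nodes — deterministic, no initialization effects — and checked against
  the residual $\lVert T v - v \rVert_\infty <$ `eig_tol`. Beyond that
  size, power iteration runs on the half-lazy operator $(I + T)/2$, which
  has the same stationary vector but converges geometrically even on
  periodic chains; the same residual check applies. (Iterate averaging
  would also handle periodicity, but only at a $1/t$ rate, far short of
  the residual tolerance.)

## Rating a season

```{r}
season <- simulate_season(n_teams = 8, r = 2, seed = 7)
fit <- walkrank(season, jackknife = TRUE)
tidy(fit)
glance(fit)
```

Ranks are averaged over exact rating ties (what the correlation statistics
expect); the display order breaks remaining ties by net points and then
team ID so output is reproducible.

The jackknife errors are delete-one-*game* errors: the combined rating is
recomputed on each of the $n$ networks with one game removed and the
spread is scaled by $\sqrt{(n-1)/n}$. Resampling whole rounds would be the
alternative reading; games are the independent observational unit here, so
the game-level jackknife is used throughout.

## The comparison raters

Four classical methods share the same rating-row interface
(`rate_teams()`): win–loss margin with a net-points tie breaker, Colley's
linear system, Park–Newman generalized wins–losses (a directional Katz
series on the win matrix, default attenuation $0.9/\lambda_{\max}$), and
PageRank on winner→loser edges read as weakness (damping 0.85, edges
weighted by points by default). The Park–Newman and PageRank parameter
defaults are package choices — standard values in their literatures —
not quantities estimated from data; both are configurable. Wins and losses
are always recomputed from individual games, because the cumulative weight
matrix cannot distinguish two 1:0 wins from one 2:0 win.

## Evaluating rankings over a season

```{r}
wa <- weekly_accuracy(season, methods = c("dnrw", "winloss", "colley"))
aggregate_accuracy(wa)

ss <- src_series(season, method = "dnrw")
convergence_round(ss, threshold = 0.9)
```

Prediction replays the season cumulatively: ratings through round $t-1$
pick the winner of each round-$t$ game; a drawn game is worth $1/2$
regardless of the pick, and a pick between equally rated or never-seen
teams is itself a draw, also worth $1/2$ — the same rule, applied to the
prediction side. Predictions start at round 2, since round 1 has no prior
data; aggregate accuracies are therefore totals over rounds
$2, \dots, R$.

Convergence is tracked two ways: the Spearman correlation of each round's
ranking with the final one (ties averaged; the final round is 1 by
construction), and the count of *line crossings* — strictly discordant
pairs — between consecutive rounds, with tied pairs excluded. Crossing
counts decay roughly exponentially as information accumulates, and
`fit_exponential()` fits $a e^{-bt}$ by nonlinear least squares on the raw
counts: late-season weeks with zero crossings make a log-linear fit
impossible, while the raw-count fit handles them and merely needs a
nudged starting rate when the series is exactly constant. An all-zero
series is reported as the degenerate fit $a = 0$.

## What the synthetic seasons emulate — and what they do not

`simulate_season()` exists so every stage is testable with known ground
truth. Each team carries a latent strength $\theta_i$ (default: evenly
spaced on $[-1, 1]$), and a scheduled game between $i$ and $j$ draws
independent Poisson scores with means
$\mu e^{\beta(\theta_i - \theta_j)/2}$ and the mirror term. Defaults are
$\mu = 1.4$ expected points (association-football-like totals, giving a
realistic draw rate) and $\beta = 1.5$, under which the strongest and
weakest teams differ in expected score by a factor of $e^3 \approx 20$ —
clearly separated — while mid-table games remain genuinely uncertain.
Schedules are either a round-robin repeated $r$ times (connectance exactly
$r$; the default double round-robin mirrors a 20-team European league) or
a division-based sparse schedule (intra-division round-robin plus
inter-division matchings at fixed games per team; 4 divisions of 5 at 9
games each gives connectance $\approx 0.47$, emulating a 32-team,
256-game gridiron season at the 20-team size used in the tests). Draws
are taken in deterministic schedule order from one seeded stream, so a
truncated season is a prefix of the full one.

The generator is deliberately simple: no home advantage, no within-season
strength drift, no injury shocks, and score distributions that are Poisson
rather than sport-specific (gridiron scores, in particular, are far from
Poisson). Passing the recovery tests therefore shows that the estimator
chain recovers a *stationary* latent order through the intended pipeline
at realistic sparsity — not that it conquers every pathology of real
leagues. Conversely, the protocol functions (`weekly_accuracy()`,
`src_series()`) take any game file, so real seasons drop straight in
through `read_games()` with a suitable dialect.

## Numerical and design notes

* Team indexing is lexicographic everywhere, making matrices and outputs
  reproducible regardless of input order.
* Scores are validated as non-negative; non-integer values are accepted
  with a warning to support pre-aggregated data.
* The recovery experiments in the acceptance script use 50 seasons per
  condition of a 20-team league (double round-robin, 380 games, vs a
  division schedule at 90 games); medians of Spearman recovery are stable
  at that replication and the whole script completes in well under a
  minute on one core.
* Known limitations: ratings from very sparse, barely connected rounds are
  dominated by the component-share scaling; the Park–Newman series is
  undefined at or above the spectral bound (the package refuses such
  `alpha`); and the two-node league is inherently degenerate for the bare
  walk (see `normalization = "lazy"` above).
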