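---
title: "Habit formation as structural change in a behavioral network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Habit formation as structural change in a behavioral network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habitnet)
```

## The model

An animal in a free-operant experiment does not emit the measured response in
isolation: it grooms, explores, rears, and the measured operant (a lever
press, a key peck) is one node in a web of transitions between responses.
habitnet implements a model in which that web is taken literally as a graph
and habit — responding that persists after the response's reward has been
devalued — is a property of the graph's shape rather than of a separate
habit system.

The pipeline has four stages.

1. **Transition learning.** An agent emits one response per time step. With
   the previous response playing the role of the state, it learns a tabular
   value `Q[previous, next]` for every transition by one-step
   temporal-difference learning,

   `Q[a, b] <- Q[a, b] + alpha * (R + gamma * max_c Q[b, c] - Q[a, b])`,

   choosing each next response by a softmax over the current Q row with
   inverse temperature `betaC`. An optional on-policy (SARSA) rule replaces
   the max by the value of the next response actually chosen. Rewards for
   the designated operant response are scheduled (below) with magnitude 1.0;
   every other response pays a token magnitude of 0.001 on every emission
   (a fixed-ratio-1 arrangement), so "doing something else" is never
   worthless but never competitive.

2. **Network generation.** After training, an unweighted simple graph over
   the N responses is generated: each node `i` samples `edgesPerNode`
   distinct targets without replacement with probability proportional to
   `exp(betaN * Q[i, j])` over `j != i`. Every node therefore has degree at
   least `edgesPerNode`. Self-loops are excluded; the self-transition value
   `Q[operant, operant]` is still learned and reported because it carries
   the response-rate signature of ratio schedules.

3. **Traversal.** In the baseline phase the agent starts on a uniformly
   random response and loops: choose a goal response with probability
   proportional to its reward value (`operant = 1.0`, others `0.001`), find
   a shortest path from the current response to the goal (ties between
   geodesics broken uniformly at random), and engage every response along
   the path. Neither Q nor the network changes during traversal.

4. **Devaluation assay.** The operant's reward value is set to 0.0 — with no
   further learning, mirroring devaluation by satiety or poisoning outside
   the chamber — and the traversal phase is repeated. **Resistance to
   devaluation** is summarized as the ratio of the operant's engagement
   proportion after devaluation to its proportion at baseline (the
   difference is reported alongside). A devalued response is never chosen
   as a goal, so any persistence comes from the operant lying on the
   shortest paths between *other* goals: habit, in this model, is literally
   a hub.

## Parameters

| Parameter | Default | Units / range | Role |
|---|---|---|---|
| `alpha` | 0.1 | [0, 1] | learning rate of the TD update |
| `gamma` | 0.5 | [0, 1) | discount of future transitions |
| `betaC` | 3.0 | > 0 | choice inverse temperature during training |
| `betaN` | 50 | > 0 | edge-sampling inverse temperature |
| `edgesPerNode` | 2 | ≥ 1 | targets sampled per node |
| `nResponses` | 50 | ≥ 3 | network size N (25–100 is a sensible sweep) |
| `nLoops` | 500 | ≥ 1 | goal choices per traversal phase |
| `nRewards` | 500 | ≥ 0 | training amount, counted in rewards, not steps |

Training stops on a *reward count*, not a step count, because the amount of
training is the experimentally meaningful quantity and schedules differ
wildly in steps per reward. With rewards in {0, 0.001, 1.0} and
`gamma = 0.5`, every Q entry initialized at zero stays in [0, 2]
(`R_max / (1 - gamma)`), which bounds all the softmax arguments.

## Reinforcement schedules

The schedule machinery runs on a discrete clock in which one agent response
is one time step; interval timers advance by one per step.

* **FR k / VR k** — ratio schedules: reward after k (fixed) or a
  geometrically distributed number (mean k) of operant responses.
* **VI t** — an interval with exponentially distributed duration (mean t
  steps) must elapse; the reward is then *armed* and held — single capacity,
  no stacking — until the next operant response collects it. The timer runs
  regardless of what the agent does.
* **VT t** — as VI, but delivery happens on elapse, independent of
  responding (used to match reward rates without response contingency).
* **tandem** — components completed in unsignalled succession; only the
  final component delivers. A zero-length time-based tail completes within
  the same step it is reached (a `VT 0` tail makes a tandem identical to its
  first component), whereas a `VI 0` tail arms instantly but still needs a
  collecting response.
* **concurrent** — independently armed schedules tied to distinct operant
  responses (or a response-free VT arm).

Variable requirements and intervals are not drawn i.i.d.: the unit interval
is divided into as many strata as rewards and the geometric / exponential
quantile function is evaluated at the stratum midpoints `(k - 0.5) / n`
(interior points, avoiding the infinite endpoint quantiles), then uniformly
permuted. Short sessions therefore see the nominal distribution almost
exactly; the 10,000-draw sample means recomputed by
`scripts/acceptance.R` sit within a fraction of a percent of the configured
values. Sequences are pre-generated with head-room; exhausting one raises a
typed session-end error rather than recycling.

A yoked VI is built with `yokeVIToVR()`: the mean of the successive
inter-reward intervals observed in a completed VR session becomes the VI
mean, matching reward rates across the response-based and time-based rules.

## The experiment drivers

`runSim1()` sweeps a *hypothetical* operant value: `hypotheticalQ(q)` builds
a value vector `(q, 0.001, ..., 0.001)` and expands it to a matrix by row
replication (`Q[i, j] = q_j`), so the attachment probability of a target is
source-independent. A literal outer-product expansion (`Q[i, j] = q_i q_j`)
is available for comparison, but with values at most 1 its off-operant
contrasts are of order `q_other * q_operant` — about 0.001 — and cannot
concentrate edges at `betaN = 50`; row replication is the expansion that
makes the sweep behave as intended, and it is the default.

`runSim2()` replaces the hypothetical matrix by training: variable ratio 15,
a VI yoked to each agent's own VR 15 session, a two-operant choice condition
(concurrent VI 60 VI 60, both worth 1.0, only the first devalued), and its
yoked no-choice control (concurrent VI 60 VT 60). `runSim3()` compares
simple and tandem orderings: VI 15, VR 15, tandem VI 15 VR 3, and
tandem VR 10 VI 5 (the simple-schedule values are chosen to match the
tandems' nominal components). Both return one tidy row per agent and metric;
`writeResults()` adds a CSV and JSON run manifest, and
`inst/scripts/run_simulation.R` wraps the drivers for shell use.

Determinism is end to end: every cell's seed is spawned from the master seed
by a counter (`deriveSeed()`), and an identical (configuration, seed) pair
reproduces the output CSV byte for byte.

## Numerical and design choices

* **Sign of the edge-sampling exponent.** The generator uses
  `exp(+betaN * Q)`, which concentrates edges on high-valued targets; the
  negated variant (under which high-valued targets become the *least*
  likely and no hub can form) is retained behind
  `networkParams(softmaxSign = "as_printed")` for auditability.
* **Undirected graph.** With two sampled out-edges per node, a directed
  reading would leave a fraction `~e^-2` of nodes without in-edges and
  unreachable as goals, deadlocking traversal; the edge set is therefore the
  undirected union of the per-node samples.
* **Weighted sampling without replacement** is done by sequential draws with
  renormalization between draws. Base R's one-shot
  `sample(prob =, replace = FALSE)` computes the residual mass after the
  first draw by subtraction, and when one probability is within machine
  epsilon of 1 the cancellation error dwarfs the true residual, which
  deterministically funnels second edges onto the last-scanned node. (At
  `betaN = 50` an operant value of 0.75 pushes the operant's probability to
  `1 - 3e-15`, squarely into this regime; the artifact shows up as a
  spurious second hub.)
* **Softmax stability.** All softmaxes subtract the row maximum first;
  results are invariant to adding a constant to a Q row.
* **Uniform geodesic tie-breaking.** All shortest paths are enumerated and
  one is sampled uniformly — exact uniformity, checked against a two-path
  cycle at 2000 draws.
* **Engagement counting.** The initial response counts once; each loop
  counts the path nodes after its start (goal included), so nothing is
  double-counted across loops and `sum(counts)` equals the number of logged
  engagements. A goal equal to the current response counts as a single
  re-engagement.
* **Non-contingent (VT) rewards during training** are credited to the
  transition the agent just completed; one-step TD needs a carrier
  transition and response-independent delivery does not name one.
* **Disconnected networks** are legal outputs; metrics flag them and the
  average path length is computed on the largest component. Traversal
  resamples unreachable goals (bounded, then errors).

## What the sweeps do and do not show

The hypothetical sweep (`runSim1`) is a clean existence proof: resistance to
devaluation, operant degree and betweenness rise together with the operant's
hypothetical value while the average path length falls, and a devalued hub
keeps being traversed purely because it lies on other goals' geodesics.

The learned conditions are more nuanced, and one regime deserves an honest
flag. The time-based schedules whose interval is short relative to the
agent's inter-operant time (VI 60 against a near-uniform 50-response
repertoire, VI 15, and the tandem with a terminal short VI) reward the
transition *into* the operant at a high per-visit rate, build strong hubs,
and show large resistance; ratio schedules concentrate value on the operant
self-transition instead, which is excluded from the graph — this
self-transition contrast (high under ratio-terminal schedules, low under
interval-terminal ones) is robust in the test suite. But when the VI is
*yoked* to a VR session of the same agent, yoking equalizes the per-visit
reward probability of the two schedules by construction, and with
`betaC = 3` over 50 responses and rewards of at most 1.0 the agent's
operant response never becomes frequent enough for response bursts to
differentiate which transitions collect rewards. In that regime the yoked
VI/VR contrast in hub structure and resistance is small and its sign is not
reliable at 20 agents — the acceptance suite runs the comparison at the
study conditions and reports it as it falls, rather than certifying a
direction the dynamics do not support. Separating the schedule effect from
the yoking constraint (for example by sweeping `betaC` or the reward
magnitude so that operant-dominant responding emerges) is the natural next
experiment the package supports.

The synthetic conditions emulate contingency structure, not biology: there
is no bout-and-pause microstructure (paths cannot revisit the operant
within a traversal), no within-test relearning or extinction, no stimulus
control over schedule components, and real time is response-counted rather
than clocked. Passing tests show that the network mechanism behaves as
designed under these idealizations, not that any particular animal's habit
is a graph hub.

## Problem sizes

The test suite and acceptance checks run the full study conditions: 50-node
networks, 20 agents per condition, 500 goal choices per phase and 500
training rewards (5/50/500 where the amount of training is swept), with the
training inner loop compiled (Rcpp) so a complete VR 15 session of ~300,000
steps takes well under a second. Oracle comparisons (hand-written BFS path
counting against the igraph-backed implementation) use graphs of up to 12
nodes, where brute force is exact.
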