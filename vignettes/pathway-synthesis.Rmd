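---
title: "Ant-colony synthesis of feasible metabolic pathways"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ant-colony synthesis of feasible metabolic pathways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antpath)
```

## The problem and the state-space model

Given a universe of biochemical reactions (each a directed transformation
between a substrate set $S(r)$ and a product set $P(r)$), the task is to find
an ordered sequence of reactions — a metabolic pathway — that relates a set of
target compounds $\mathcal{D}$, starting from one of a set of candidate
initial substrates $\mathcal{I} \subseteq \mathcal{D}$ and a set
$\mathcal{C}$ of freely available "pool" compounds (water, ATP, NAD and the
like, assumed present without synthesis).

Classical path finding on compound graphs has three well-known failure modes:
it scales poorly, it does not verify that the substrates of each step are
actually available when the step runs, and it can only produce linear routes.
`antpath` instead searches a *set-of-compounds* (SoC) state space: a state is
the set of currently available compounds plus the reactions applied so far,
and a transition applies a reaction whose substrates are *all* available,
adding its products. Availability only ever grows, so the model is monotone
and **every prefix of every pathway explored is substrate-feasible by
construction**. Because the goal test is set containment
($\mathcal{D} \subseteq$ available) rather than arrival at a single node,
solutions may be branched: one compound can feed several reactions.

A reversible reaction is represented as two independent directed reactions
with swapped substrate/product sets, sharing a `parent_id` (the reverse id
carries a `_rev` suffix). Stoichiometric coefficients are deliberately
discarded: every formula below is set-algebraic, and the package makes no
claims about flux, thermodynamics or atom conservation.

## The ant algorithm

The search maintains a pheromone matrix $\Omega$ with one row per reaction
plus a virtual start row. Initially every supported entry equals 1; the start
row's support is exactly $r_0$, the reactions consuming any candidate initial
substrate. Each iteration, $N_k$ ants walk independently:

1. The ant draws its first reaction $\pi_0$ from $r_0$ with probability
   proportional to the start row of $\Omega$. Its available set starts as
   $S(\pi_0) \cup P(\pi_0) \cup \mathcal{C}$ — only the substrates of the one
   chosen initial reaction are granted, so branching in a solution reflects
   the pathway's own topology rather than a padded initial set.
2. It repeatedly lists the feasible reactions not yet in its walk, draws one
   with probability proportional to the pheromone row of the last reaction
   taken, and applies it. The walk ends when all targets are available, no
   feasible reaction remains, or the step bound is hit.
3. The walk is *cleaned*: repeatedly, until a fixed point, any reaction whose
   non-free products contain no target and feed no retained later reaction is
   dropped. Cleaning preserves order, feasibility and goal attainment, and is
   idempotent.
4. The cleaned pathway $\hat\pi$ is costed (below). After all ants finish,
   every pheromone entry decays by the factor $1-\rho$, and each ant's
   cleaned pathway deposits $1/f(\hat\pi)$ on its start entry and on every
   consecutive-pair entry. Walks that clean to nothing deposit nothing — the
   connectivity penalty already down-weights partial solutions, and an empty
   pathway has no transitions.

The run stops at `max_iterations` or when the best cost has not strictly
improved for `stall_iterations` iterations. Ties never replace the incumbent
(first-found wins), which together with a seed makes runs exactly
reproducible. Depositing along *cleaned* pathways (so pheromone edges can
skip removed detours) is a deliberate reading of the update step; the
alternative (raw walks) reinforces detours the cost function is trying to
remove.

### The cost function

Four characteristics of a cleaned pathway are measured: its length
$L = |\hat\pi|$; the number $u$ of direction-agnostic unique reactions
(counted on `parent_id`, so using both directions of one reversible reaction
is penalized); the number $p$ of *productive* reactions, those producing at
least one compound not previously produced and not in $\mathcal{C}$; and the
connectivity $\kappa \in \{1, \alpha\}$. Connectivity is computed by a single
ordered sweep: a set $X$ starts as the first reaction's target substrates
plus its non-free products, and each later reaction consuming anything in $X$
contributes its non-free products; $\kappa = 1$ exactly when every target
lands in $X$. Note the seeding: had $X$ started as the first reaction's
target substrates *alone*, no products would ever enter it and every pathway
would score as partial — the seeded form is the only self-consistent reading,
and it reproduces the expected values on every hand-traceable example.

These are combined as

$$f(\hat\pi) = \kappa \,(3L - u - p).$$

No canonical algebraic combination of the four components exists, so the
package commits to this one and isolates it behind `pathway_cost()`: it
reduces to $\kappa L$ when every reaction is unique and productive (pure
shortest-path pressure), adds 2 per fully redundant step, and any strictly
monotone alternative would preserve the search's ordering behaviour. With
$\alpha \gg 1$ (default $10 N_k$) every complete solution costs less than any
partial one of length up to $\alpha/3$, so the colony is driven first to
completeness, then to brevity.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `n_ants` | 10 | walks per iteration; 10 handles three-target problems, 5 suffices for simple chains |
| `rho` | 0.1 | pheromone fraction evaporated per iteration |
| `alpha` | `10 * n_ants` | cost penalty for partial connectivity |
| `max_iterations` | 100 | hard cap |
| `stall_iterations` | 20 | stop after this many non-improving iterations; the stall window is a package choice — "best solution unchanged for a while" needs a concrete horizon |
| `max_steps` | number of reactions | per-walk bound (a reaction is used at most once, so walks are finite regardless) |

All randomness flows through R's global RNG; `aco_params(seed = )` pins a
run, and the generators take their own seeds.

## Baselines and their state-space behaviour

`bfs_search()` explores the SoC space level by level and returns a
shortest-in-reactions solution; `dfs_search()` is depth-limited and returns
the first solution found. BFS deduplicates visited states on the
available-compound set alone: in the monotone model two states with equal
compound sets can reach exactly the same compound sets (a reaction excluded
in one branch but not the other could only re-add compounds already
present), so the pruning is correctness-preserving. Whether the classical
baselines in the literature deduplicate is usually unstated; absolute effort
curves may therefore differ in level from published ones, and only the
*trend* — effort non-decreasing in the size of the initial available set — is
asserted by the tests.

`dfs_search(shuffle = TRUE)` draws one random operator order per run,
mirroring randomized-runs protocols. The benchmark driver uses the
deterministic universe order instead: with a depth bound of 10 and
distractor-heavy orderings, a depth-first searcher enumerates ordered
distractor sequences combinatorially, and desk-scale benchmarks are not the
place to reproduce multi-minute pathologies.

## What the synthetic generator emulates — and what it does not

`make_linear_network()` plants a chain $c_0 \to \dots \to c_L$ and targets
$\{c_0, c_L\}$; `make_branched_network()` grows several chains directly from
a common root, targeting the root and every tip, so the planted pathway's
branching factor exceeds 1 (the root is consumed once per branch) and its
length is exactly the sum of branch lengths. Around the planted pathway the
generator adds: pool compounds wired as substrates into several distractor
reactions (the high-connectivity currency-metabolite motif); "live"
distractors anchored on planted compounds (dead-end branches available
immediately); and "locked" distractors anchored on fresh compounds that
become feasible only when those compounds are handed to the search as extra
initial material. Distractor products are always fresh compounds, so no
distractor can shortcut the planted pathway — "planted = optimal" is a
construction invariant the tests rely on.

`grow_available_set()` reproduces the growing-initial-set protocol: a seeded
permutation of the non-producible, non-target, non-free compounds is
truncated at `n_extra`, so for a fixed seed the drawn sets are nested and
growing `n_extra` genuinely enlarges the same initial conditions. Compounds
already *producible* from the minimal set are excluded from the draw: adding
one would change the problem itself (shortcutting the planted chain) rather
than enlarging its initial conditions. For the classical searchers the
extras enter the initial available set; for the ant search they are passed
as `extra_available`, which seeds every walk but deliberately stays out of
$\mathcal{C}$ — the free-compound set is subtracted inside cleaning,
productivity and connectivity, and abusing it for extras silently turns
every solution into a "partial" one.

The generator does **not** mimic real metabolic networks beyond these
motifs: no KEGG-like degree distribution, no mass balance, no reaction
reversibility statistics, compound ids are synthetic (`X…`, `F…`, `P…`).
Passing the planted-recovery and scaling tests therefore demonstrates the
search mechanics — feasibility bookkeeping, pheromone learning, cost
ordering, the qualitative state-explosion trend — not performance on
genome-scale reconstructions.

`make_random_problem()` generates small random universes whose reactions all
consume at least one producible non-free compound, with targets drawn from
the true forward closure. Two consequences make it a sharp oracle: every
instance is solvable, and a shortest solution is automatically fully
connected, all-unique and all-productive, so its cleaned cost equals its
length. The test suite exploits this to demand that the colony match the
breadth-first optimum exactly on dozens of seeded instances.

## Numerical and degenerate-input choices

* Empty pathways: cleaning returns them silently; cost, connectivity and
  branching factor refuse them (the caller decides what a failed walk means).
* A reaction with substrates equal to products is rejected at load time; a
  substrate-set overlap (catalytic cycle) is allowed.
* Targets must be disjoint from the free compounds (a free compound needs no
  synthesis) and must each appear in some reaction.
* Branching factor is undefined when every substrate is free; this errors
  rather than returning a conventional value.
* Precision/recall denominators of zero yield 0, so disjoint comparisons
  score 0 rather than NaN.
* Best-cost ties keep the incumbent; improvement must be strict.

## Problem sizes used by the tests

The suite checks the oracle-equivalence property on 50 random universes of
6–12 reactions, planted recovery on 20 linear instances ($L=6$, 20
distractors, 2 pool compounds) and a branched instance, brute-force
shortest-length agreement on universes of up to 8 reactions, and the scaling
trend on a fixed $L=5$ instance with 30 distractors over extra-compound
grid $\{0, 4, 8, 12\}$ with medians of 5 runs. These sizes keep the full
suite within tens of seconds while leaving each property non-trivial (the
scaling instance's breadth-first effort grows several-fold across the grid).

## Known limitations

* The cost combination is one defensible choice among monotone alternatives;
  rankings between *ideal* pathways are insensitive to it, rankings among
  degenerate pathways are not.
* Connectivity is a single ordered sweep, not a fixed point: a reaction
  placed before the step that produces its trigger substrate contributes
  nothing, even if a reordering would connect it. For cleaned solutions the
  two notions coincide in practice, and the sweep is the documented
  semantics.
* Wall-clock comparisons between searchers are indicative only; states
  expanded is the stable effort measure and is what the tests assert on.
* Real-data workflows (KEGG extraction, direction assignment from reference
  maps) are out of scope; the reaction table with an explicit direction
  column is the interface.
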