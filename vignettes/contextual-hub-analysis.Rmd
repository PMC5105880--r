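---
title: "Contextual hub analysis: model, calibration and design choices"
author: "contexthubs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contextual hub analysis: model, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contexthubs)
```

## The problem

Molecular interaction networks have heavy-tailed connectivity: a few hub
proteins interact with very many partners. Ranking nodes by degree therefore
surfaces the same promiscuous, ubiquitously expressed or simply well-studied
proteins in every analysis, regardless of the experimental condition. When a
study supplies *contextual* information — say, the genes up-regulated during
a viral infection — the more relevant question is which nodes interact with
the contextual genes **more often than chance predicts**, not which nodes
have the most interactions overall. We call such nodes *contextual hubs*.

## The model

Let the filtered interaction database define the statistical universe:

* `N` — the number of genes with at least one qualifying interaction in the
  database (an [InteractionDb-class] stores only such genes, so
  `backgroundSize()` is exactly `N`);
* `K` — the number of contextual genes among those `N`
  (`contextK()`; contextual genes absent from the database cannot contribute
  and are reported separately).

For a node with `n` distinct interactors of which `k` are contextual, the
probability of observing `k` or more contextual interactors by chance is the
upper tail of the hypergeometric distribution,

$$
P(X \ge k) \;=\; \sum_{x=k}^{\min(n,K)}
  \frac{\binom{K}{x}\binom{N-K}{n-x}}{\binom{N}{n}},
$$

implemented in `hypergeomUpperTail()`. Three modelling commitments matter:

1. **`n` is the node's degree in the full filtered database**, not its degree
   inside the constructed network. The background `(N, K)` is database-wide,
   so the draw count must be too; it also makes the degree used by the
   conventional "degree hub" ranking identical to `n`.
2. **Self-interactions are disregarded** everywhere: a node is never its own
   interactor, and its own contextual label never enters its `k`.
3. **Only enrichment is tested** (one-sided upper tail); depletion of
   contextual interactors is not a hub signal.

P-values are corrected with the Benjamini–Hochberg step-up procedure
(`bhAdjust()`, delegating to `stats::p.adjust`). The BH family is the set of
nodes actually tested — the seed + first-neighbor network — not all database
nodes; `m` equals the network size and is recorded in the run metadata.
Bonferroni is deliberately not offered: with thousands of correlated
node-level tests it is far too conservative for a screening statistic.

## Network construction

Every uploaded gene found in the database seeds the network, whether or not
it satisfies the contextual predicate; the predicate controls contextual
*status* only. All first neighbors of the seeds are added. Edges touching at
least one seed are *display* edges; neighbor–neighbor edges are kept in the
analysis but flagged hidden (`exportGraphml()` writes a boolean `displayed`
edge attribute), mirroring the convention that first-neighbor interconnects
clutter a visualization without changing the statistics. Uploaded genes with
no qualifying database interaction are excluded from both network and
statistic and reported in the missing list — treating them as isolated
display-only nodes would create nodes the test cannot score.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `predicate` | `"all"` | which uploaded genes are contextual, e.g. `contextPredicate("logFC", "gt", 2)` (fold-change units are the user's) |
| `species`, `interactionTypes`, `idNamespace` | unset | database filters; species must match **both** interactors |
| `top` | 20 | hub-list size used for display and ranking comparison |
| `minDbEdges` | 10,000 | below this interaction count the run carries a warning: background frequencies `K/N` from small databases are unstable. It is a warning, not an error, because the rule governs which public databases are worth querying, not the mathematics |

Identifier normalization is intentionally conservative: strip one `db:`
prefix, strip parenthetical annotations and whitespace, upper-case. No
cross-namespace mapping service is consulted — the user chooses one ID type
for both inputs. Records whose namespace differs from a requested
`idNamespace` are dropped and counted in a log message rather than silently
mapped through alias columns; the alias columns of MITAB files are too
inconsistently populated across providers to trust unattended.

## The synthetic-data generator

`generateNull()` draws a background graph — uniform `G(n, p)` or a
heavy-tailed degree distribution (power-law fitness model; the heavy tail is
what makes degree-vs-contextual dissociation realistic in interactomes) —
and labels a uniformly random `K`-subset of edge-bearing nodes contextual.
Under this construction each node's `k` is marginally hypergeometric, so
these datasets calibrate the test's type-I behavior. The calibration
property is evaluated over **all** database nodes: restricting to network
nodes would condition on adjacency to contextual seeds and bias `k` upward.

`generatePlanted()` additionally wires planted hubs with known ground truth:
contextual hubs at degree 30 with 60% contextual partners (stochastic
rounding of the non-integer allocation keeps seeded runs stable), and
promiscuous hubs at degree 60 with uniformly drawn partners, whose contextual
fraction therefore matches the background rate `K/N`. Contextual labels are
sampled from all nodes; planted wiring gives nearly all of them edges, and
`K` is defined downstream as the labels with at least one database edge.
With the heavy-tailed model the target edge count is `round(2.5 * nNodes)`
(mean degree 5, typical of curated interactome subsets), since a power-law
model needs an edge budget rather than an edge probability.

The frozen benchmark conditions are: 500 nodes, `G(n, p = 0.01)`, `K = 50`,
10 planted contextual hubs (degree 30, wiring rate 0.6), 10 promiscuous hubs
(degree 60), seeds 1–20. At these conditions the top-10 contextual ranking
recovers the planted contextual hubs while the top-10 degree ranking is
dominated by the promiscuous hubs; the acceptance suite asserts strictly
higher contextual than degree recall in every seed and a top-10 Jaccard
below 0.20 — a bound calibrated once by simulation at these conditions
(observed Jaccard was 0 in all 20 seeds) and then frozen.

What the generator does **not** emulate: assortativity and clustering of
real interactomes, study bias (heavily studied genes have inflated degree
*and* inflated chance of appearing in expression lists), multi-evidence edge
weights, and identifier noise. Passing the synthetic benchmarks therefore
demonstrates statistical correctness and ranking behavior, not that
contextual hubs found in any particular real database are biologically
validated.

## Numerical choices

* The hypergeometric tail is summed in log-space (`lchoose`) from the
  largest term downward and capped at 1; it matches exhaustive subset
  enumeration to below `1e-12` relative error for all `N <= 12` and the
  reference upper-tail distribution at `N = 20,000` scale to below `1e-9`.
* `P(X >= 0)` is returned as exactly 1; raw p-values are always in `(0, 1]`.
* Ranking ties are broken by a fixed chain — contextual: ascending adjusted
  then raw p, descending `k`, descending degree, lexicographic identifier;
  degree: descending degree, ascending adjusted p, lexicographic — using
  locale-independent radix ordering, so rankings and the written
  `scores.tsv` are byte-identical across runs and platforms. Note that
  p-values equal on paper may differ by ~1 ulp in floating point, in which
  case the p-value keys, not the later tie-breaks, decide — deterministically.
* Probabilities are written with 17 significant digits (round-trip exact).
* Degenerate inputs fail fast with machine-greppable messages: `"empty
  database"`, `"no contextual genes in database"`, `"no seed genes found"`,
  `"invalid hypergeometric parameters"`, `"degenerate spec"`,
  `"infeasible spec"`.

## Problem sizes used in the checks

The test and acceptance workloads are sized for quick, repeated execution:
exhaustive oracle comparison for all `N <= 12` (several thousand parameter
tuples); 200 null databases of 200 nodes for calibration (~40,000 node
tests); 20 replicates of the 500-node planted benchmark; 1,000 random
vectors for the BH oracle. These sizes give tight Monte-Carlo error (the
calibration standard error at `alpha = 0.05` is ~0.001) while keeping the
full suite under a minute.

## Known limitations

* `K` is counted database-wide (contextual genes with any database edge),
  not network-wide; the alternative reading would shrink the background and
  inflate significance for sparsely connected contexts.
* No second-neighbor expansion, no betweenness/bottleneck statistics, no
  depletion test, no live database querying — the package analyzes the files
  it is given.
* The conservative identifier normalization means unmapped namespaces
  surface as "missing" genes rather than being rescued; audit the missing
  list when `K` is unexpectedly small.
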