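---
title: "Feedback loops, node classification, and robustness of Boolean dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feedback loops, node classification, and robustness of Boolean dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fblnet)
```

## The model

A biological network is a directed graph `G(V, E)`; an edge `(u, v)` makes
`u` an input of `v`, and the in-degree `d_in(v)` is the number of inputs. A
*path* of length `L >= 1` is a sequence `u_1 ... u_{L+1}` of consecutive
edges with no repeated nodes, except that `u_1 = u_{L+1}` is allowed — that
closed case is a *feedback loop* (FBL), and a self-loop is an FBL of length
one. A node is *FBL-involved* when some FBL passes through it; operationally
that is membership in a strongly connected component of size two or more, or
possession of a self-loop, which is what `fbl_nodes()` computes and what
makes the classification scale to networks with thousands of nodes.

The dynamic layer is the synchronous Boolean network: each node holds 0 or
1, and all nodes update simultaneously, `v_i(t+1) = f_i(inputs of v_i at t)`
with an arbitrary truth table `f_i` per non-source node. Source nodes (in
degree 0) are held at their initial value — they model fixed external
inputs. A trajectory from any initial state eventually repeats; the repeated
block is the *attractor* (fixed point or limit cycle), the steps before it
the *transient*. Two attractors are *equivalent* when they have the same
period and the same state sequence up to a cyclic time offset; `fblnet`
canonicalizes a cycle by rotating it to start at its lexicographically
smallest state, which turns equivalence into string equality and gives
attractors a hashable identity for deduplication.

## Node classes and what they imply

`classify_nodes()` flags each node as source, FBL-involved, *NFU*
(no-FBL-in-upstream: no upstream path contains an FBL-involved node) and
*NFD* (no-FBL-in-downstream, symmetrically). A cycle node is neither NFU nor
NFD, since its own loop is both an upstream and a downstream path of it.
Equivalently — and this is how the fast path computes it — the NFU set is
the complement of everything reachable *from* the FBL-involved set, and the
NFD set the complement of everything that can *reach* it: two multi-source
breadth-first traversals.

The classes matter because of three exact dynamic properties: every NFU node
is eventually frozen (its value constant in every attractor, determined by
the upstream sources); the network is robust against a state perturbation of
any non-source NFD node (the perturbed trajectory converges to an equivalent
attractor); and a network with no FBL at all only has fixed-point
attractors. The package does not take these on trust: `verify_nfu_frozen()`,
`verify_nfd_robust()` and `verify_acyclic_fixed_points()` check them
exhaustively over random ensembles, and any violation would expose a bug in
the dynamics engine or the classifier.

A corollary worth stating: perturbations of *source* nodes are exactly the
dangerous ones for the frozen part of the network — flipping a source can
move every downstream NFU node's frozen value (see the identity-chain
example in the robustness tests).

## The perturbation-sustainable probability

A perturbation can only have a lasting effect by entering a feedback loop.
Along a downstream path `v u_1 ... u_L`, the chance that a flip at `v`
propagates step by step is modeled as `prod 1/d_in(u_i)`: each of a node's
inputs is assumed an equally influential potential carrier, and a node is
assumed to flip whenever one of its inputs flipped. Both assumptions are
modeling choices — convenient, not verifiable — and the score should be read
as a structural proxy, not a calibrated probability. A path that never
touches an FBL-involved node scores zero. The node score
`gamma(v)` is the maximum over all downstream paths (`gamma_scores()`), so
`gamma(v) = 0` exactly on the NFD nodes, and `gamma(v) <= 1` always, with
equality when some in-degree-1 FBL-involved successor exists.

Numerically, the maximum product is a shortest path on log-weights: edge
`(a, b)` costs `log d_in(b) >= 0`. Two details make the implementation
exact:

* since weights are nonnegative, an optimal walk never benefits from
  revisiting a node, so Dijkstra over walks attains the simple-path optimum
  and no explicit simple-path constraint is needed;
* the path product starts at `u_1`, never at `v` itself, so a cycle member
  must not score through the empty path. `gamma_scores()` therefore
  computes `h(u)` — the cheapest cost from `u` to any FBL-involved node,
  zero if `u` is one — by one multi-source Dijkstra pass on the reversed
  graph (a virtual sink behind the FBL set), and then applies one explicit
  relaxation over each node's out-edges:
  `gamma(v) = exp(-min over (v,u) of [log d_in(u) + h(u)])`.

`gamma_bruteforce()` is the literal oracle — enumerate every simple
downstream path, maximize the product — kept deliberately independent of the
shortest-path route and compared against it node-for-node on random
networks in the tests. `classify_nodes_bruteforce()` plays the same role
for the classifier. Both are guarded to 12 nodes; enumeration is
exponential and meant for verification, not analysis.

## Exhaustive dynamics

`attractors_exhaustive()` enumerates all `2^N` initial states by tabulating
the full synchronous transition map as a vector of integer state codes (bit
`j` of a code is node `j`'s value, most significant bit first) and labeling
the functional graph's cycles. This reduces the robustness check for a node
`v` over *all* initial states to comparing attractor labels of `s` and
`s XOR bit_v` — two distinct cycles of a deterministic map are disjoint, so
label equality is exactly attractor equivalence. The step-by-step route
(`step_state()`, `find_attractor()`, `is_robust()`) is retained as an
independent implementation and the two are cross-checked on sampled states
in the tests. Exhaustive enumeration is capped at 20 nodes by default;
beyond that the state space (over a million states) stops being a desk-scale
object, and sampling initial states is the intended fallback.

## Synthetic data: what it emulates and what it does not

The generators define the conditions under which the dynamic properties are
verified:

* `generate_random_network(n, m)` samples `m` distinct ordered pairs
  uniformly (a directed Erdős–Rényi `G(n, m)`); with `acyclic = TRUE` the
  pairs respect a random topological order, guaranteeing a DAG. Self-loops
  are off by default so cycle structure is driven by multi-node loops.
* `random_boolean_functions()` draws every truth-table output bit by a fair
  coin — the canonical unbiased random-function ensemble.
* The verification ensembles default to `n = 8`, `m = 14`, 200 networks,
  exhaustive over all 256 initial states. At that density cyclic and
  acyclic regions, sources, and all four node classes are all well
  represented, and a full suite runs in seconds; the properties themselves
  are proven for *arbitrary* functions and sizes, so small exhaustive
  networks are the right probe — a counterexample would have to be a bug.
* `rewire_preserving_degrees()` performs double-edge swaps
  (`(a,b), (c,d) -> (a,d), (c,b)`), the standard directed configuration
  null model; both degree sequences are conserved exactly. The default of
  `10 x |E|` successful swaps is a common mixing heuristic. Swaps that
  would create a duplicate edge are rejected (set semantics), and so are
  new self-loops — a rewired control should not acquire length-1 feedback
  loops the original network lacked, which would distort the NFD split.
  Edge signs travel with the tail edge; signs never enter any computation
  here, they are only carried.

What the synthetic ensembles do *not* emulate: real signaling networks are
not Erdős–Rényi — they have heavy-tailed degrees, dense cores, and
annotations correlated with degree. Passing the property suites shows the
algorithms are correct, not that γ is biologically informative; the latter
question is exactly what `compare_groups()`, `threshold_sweep()` and
`rewired_control()` are for, on real annotated networks supplied as local
files.

## Statistical choices

`compare_groups()` compares the annotated proportion in the NFD group
against the complement with the two-sided two-proportion z-test
(`prop.test(correct = FALSE)`; its chi-squared statistic is the squared z),
with Fisher's exact test behind `test = "fisher"` for small counts. No
multiple-testing correction is applied across annotation categories; the
categories are reported side by side. Annotated genes absent from the
network are dropped with a message — proportions always refer to the
network under analysis. The threshold sweep's default grid is the sorted
set of observed γ values (optionally truncated), which is the finest grid
on which the candidate-set curve can change.

For the rewired control, the per-category difference in proportions
(non-NFD minus NFD) is recomputed on each rewired replicate with
annotations held fixed to the nodes; the observed difference's empirical
percentile locates the real network in that null. One subtlety the tests
document: with a *single fixed* annotation draw the null differences need
not center at zero, because the annotated genes keep their degrees across
rewirings; centering holds on average over independent annotation draws. A
replicate whose rewiring happens to remove every cycle has no NFD split and
is recorded as `NA` rather than aborting the control.

## Degenerate inputs and numerical notes

Empty edge sets, isolated nodes, and networks without any feedback loop are
all legal everywhere: classification then marks every node NFU and NFD, and
γ is identically zero. Edge-list files cannot represent isolated nodes, so
a written-then-read network may have fewer nodes than its in-memory source;
all reported counts refer to the loaded network. Duplicate edges are
dropped on construction (with a count), node identifiers are case-sensitive
opaque strings, and no gene-symbol normalization is attempted. γ values are
compared exactly in tests (the arithmetic is products of machine-exact
reciprocals passed through `exp(log(...))`; agreement with the brute-force
product is asserted to 1e-12 in the acceptance script). Truth tables are
indexed by the input tuple read as a binary number, most significant bit =
first input, inputs sorted by node identifier — the convention is recorded
in every serialized function file header.

## Known limitations

* The dynamics of nodes that are neither NFU nor NFD (the cycle-involved
  core) are out of scope; nothing here predicts their behavior.
* Only synchronous updates and initial-state perturbations are modeled —
  no asynchronous schemes, no update-rule (function) perturbations.
* γ's independence assumptions (even input influence, certain flip given a
  flipped input) are untested modeling choices; γ orders nodes plausibly
  but is not a calibrated probability.
* Exhaustive attractor enumeration is exponential and capped; large
  networks get structural results (classification, γ) but not full
  dynamics.
* In networks where almost every gene is NFD (reported for large gene
  regulatory networks, as opposed to signaling networks), the NFD/non-NFD
  split is nearly vacuous and these analyses are uninformative.
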