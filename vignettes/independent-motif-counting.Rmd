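---
title: "Counting independent motifs in probabilistic networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting independent motifs in probabilistic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promote)
```

## The model

A probabilistic network is an undirected graph $G = (V, E, P)$ whose edges
exist independently with probabilities $P : E \to (0, 1]$. It compresses
$2^{|E|}$ deterministic instances (possible worlds); instance
$G^o = (V, E^o)$ has mass $\prod_{e \in E^o} p_e \prod_{e \notin E^o} (1 - p_e)$.
Edges with $p = 1$ are allowed and treated as deterministic.

Given a small motif $M$ (2–5 edges), an *embedding* is an edge subset of
the skeleton $G' = (V, E)$ isomorphic to $M$; its identity is its edge set,
so automorphic relabelings are one embedding. Two embeddings *overlap*
when they share an edge (the F2 measure) or a node (F3). The package
solves: among all pairwise non-overlapping embedding sets
$\mathcal{H}'$, find the one maximizing the expected number of members
fully present across the possible worlds. Because membership of each
embedding is a Bernoulli event with success probability equal to its gain
$a_k = \prod_{e \in H_k} P(e)$, linearity of expectation collapses the
objective to $\sum_{H \in \mathcal{H}'} a_H$ — an identity the test suite
verifies against exhaustive possible-world enumeration on small networks.
The harder, per-world-maximum variant of the problem (take the best set in
every world separately, then average) is out of scope here.

## The greedy selection and the overlap distribution

Selection runs on the overlap graph: repeatedly take the embedding with
the highest priority $\rho_k = a_k / f(B_k)$, add its gain to the count,
and delete it with its neighbours. $B_k$ is the random number of
embeddings overlapping $H_k$; its distribution follows from a bipartite
graph $G_k$: one variable $x_i$ per overlapping embedding
($\mathcal{V}_1$), one node per edge those embeddings need beyond
$H_k$'s own edges ($\mathcal{V}_2$), an edge polynomial
$Z_j = p_j \prod_{i} x_i + q_j$ per $\mathcal{V}_2$ node. Multiplying all
$Z_j$ and applying, per variable, a collapse operator that replaces
$x_r$ by $t$ when its exponent reaches its degree (all required edges
present) and deletes it otherwise, leaves a polynomial in $t$ whose
coefficients are exactly $P(B_k = j)$. A variable collapses as soon as its
last containing polynomial has been multiplied; terms with identical
signatures are merged by summing coefficients, which keeps the total mass
at 1 (checked to $10^{-9}$ at every stage) and keeps the term count small.

**Choice of loss.** Any monotone $f$ preserves the bound structure below;
the package fixes $f(B) = 1 + \mathrm{Exp}(B)$. The $+1$ makes the loss
of an isolated embedding 1 (so $\rho = a_k$) and avoids division by zero,
at the cost that absolute priorities differ from a bare
$f = \mathrm{Exp}$ convention. Only the ordering of priorities matters to
the selection.

**Staleness.** Removing embeddings changes the overlap neighbourhoods —
and hence $B_k$ — of the survivors, so cached priorities of every
neighbour of a removed embedding are invalidated and recomputed on demand;
unaffected embeddings keep their memoized values. The best-priority
threshold $\rho^\star$ used for pruning resets at the start of every outer
iteration; it is a within-iteration bound, and carrying it across
iterations could interact with recomputed losses.

## The three scaling strategies

**Priority-bound early termination.** As edge polynomials are multiplied
in, the partial $t$-marginal is a stochastically smaller version of the
final distribution: $P(B \ge \tau)$ and therefore $\mathrm{Exp}(B)$ can
only grow with each additional polynomial (verified property-style over
random instances and all prefixes). Hence
$\rho_k^j = a_k / (1 + \mathrm{Exp}(B \mid \text{prefix } j))$ is a
monotonically decreasing upper bound on the exact $\rho_k$, and a
candidate is abandoned the moment $\rho_k^j < \rho^\star$ (strictly, so
that ties resolve identically with the strategy off). Candidates are
visited in descending order of the cheap proxy $Q_k = a_k /
\deg(H_k)$ (isolated embeddings first, ties by id) to raise
$\rho^\star$ early.

**Collapse ordering.** The multiplication order controls when variables
collapse, and with them the cost and the width of the intermediate
polynomial. The greedy ordering maintains a matrix $W$ with
$W[r, s] = 1/\deg(x_r)$ when $Z_s$ contains $x_r$, condenses it to a
contribution-count matrix $D$ ($D[r, s]$ = number of level-$1/s$
variables of $Z_r$ times $p_r$), and repeatedly picks the polynomial
winning the left-to-right column scan of $D$, rebuilding both matrices on
the residual graph after each pick. Remaining ties break by lowest edge
id — a deterministic replacement for an arbitrary choice, so runs are
bit-reproducible.

**Cost accounting.** The collapse-operation counter uses the dense,
unmerged convention: the virtual term count doubles with every two-branch
polynomial, and a collapse round costs (terms after the product) ×
(variables collapsing). This convention reproduces the worked example's
totals of 48 (order $Z_1, Z_2, Z_4, Z_8$) and 34 (order
$Z_4, Z_2, Z_8, Z_1$) exactly; the engine's actual memory use (after
merging) is reported separately as `peak_terms`. A complementary
$\mathcal{V}_1$ rewrite pre-collapses degree-1 variables directly into a
$t$ power of their single polynomial ($Z_j = p_j t^m \prod x_i + q_j$),
removing their collapse cost entirely; it is on by default and disabled
wherever the dense accounting is the quantity of interest.

**Memory-bounded products.** With a term budget $T$, batch sizes are
$N_1 = \max(1, \lfloor T / (|\mathcal{V}_2| + 1) \rfloor)$ and $N_2$ the
remainder — the largest $N_1$ for which the live-term bound
$(j + 1) N_1 + N_2$ stays within $T$ at full depth. Each product step
multiplies the next polynomial into at most $N_1$ active terms and defers
the excess on a LIFO stack tagged with the next unapplied polynomial
index; popped batches resume under the same discipline, and fully
processed batches accumulate directly into the distribution, which is
identical to the unbounded product up to summation order ($10^{-12}$ in
the tests). Because the bounded product finishes all polynomials batchwise
before a full distribution exists, it does not stream prefix bounds; with
both strategies enabled, pruning is simply skipped for that candidate —
the selection is unchanged either way.

## Synthetic networks

The generator draws topologies from the three standard random-graph
models at a target average degree (default 2, the regime of interest for
sparse interaction networks) and assigns each edge an independent
uniform(0, 1) probability. The parameterizations achieving the target —
ER edge probability $d/(n-1)$, WS ring lattice with $\mathrm{round}(d)$
neighbours, BA attachment $m = \max(1, \mathrm{round}(d/2))$ — are the
standard ones; the WS rewiring probability is not pinned down by the
evaluation protocol this emulates, so the conventional small-world value
0.1 was chosen once. Replicate suites derive per-replicate seeds from a
master seed, and the companion aggregation drops the extremes at each end
(default 20 replicates, trim 2, so 16 values enter the mean/min/max).

What this emulates — and does not. Uniform probabilities and homogeneous
degree targets exercise the combinatorics (overlap structure, polynomial
growth, strategy interplay), which is what the tests certify. Real
confidence-scored networks have correlated, often bimodal probabilities
and community structure; passing tests here says nothing about the
biological fidelity of a probability assignment, only that the count for
a *given* assignment is computed correctly.

## Numerical and design choices

* Motif catalog: M1 = 2-edge path, M2 = triangle, M3 = 3-edge star,
  M4 = 3-edge path. The drawings behind the four canonical motifs are
  fixed by the constraints that they have two and three edges and that M1
  is a subgraph of M2, M3 and M4 — which this choice satisfies (tested by
  subgraph isomorphism) but which does not uniquely force a drawing.
* Edge ids are dense 1-based integers assigned in file order after
  deduplication; all tie-breaks (greedy ordering, candidate selection,
  least-overlap baseline) use lowest id last, making every code path
  deterministic given a seed.
* The threshold baseline keeps edges with $p > \theta$ (strict), the
  literal reading; under continuous probabilities the boundary has
  measure zero. Its default $\theta = 0.2$ is the value reported to
  maximize that baseline's count. The least-overlap deterministic counter
  is a minimum-degree greedy on the overlap graph — the standard reading
  of "fewest overlapping embeddings", whose original description leaves
  ordering details open.
* Degenerate inputs: isolated embeddings get the point-mass distribution
  at 0 without building a polynomial; networks smaller than the motif
  yield zero embeddings (not an error), which keeps sampled baselines
  total; empty networks count 0.
* Oracles guard their exponential enumerations (20 edges / 16 polynomials
  / 20 embeddings by default) and fail loudly rather than run silently.

Problem sizes in the test suite — bipartite graphs up to 10 polynomials
against $2^{|\mathcal{V}_2|}$ enumeration, networks of 20–40 nodes for the
50-network strategy-invariance sweep, 8–10-edge networks for exhaustive
possible-world checks — were chosen so the whole suite exercises every
guarantee at full depth while remaining quick to run routinely.

## Limitations

* The greedy selection is a heuristic: it matches the exact optimum on
  the small instances enumerated in the tests but carries no approximation
  guarantee; the exact-optimum oracle is available for small inputs.
* The polynomial engine is exact but exponential in the worst case; the
  strategies defer, rather than remove, that growth on dense overlap
  structures (hub-heavy scale-free networks are the stress case).
* Edge existence is assumed independent; correlated uncertainty models
  are not representable.
* Probability assignment from expression data, and enrichment analysis of
  the selected gene sets, are upstream/downstream of this package.
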