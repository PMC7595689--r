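---
title: "Node-based informed modularity: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Node-based informed modularity: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nims)
```

## The problem

Anatomical networks model an anatomical system as a graph: nodes are discrete
parts (skull bones, for instance) and edges are their physical contacts
(sutures, articulations). An *organizational module* is a group of nodes with
more links among themselves than to the rest of the network — a unit of
construction and stability. The standard route to modules, global
optimization of the modularity score Q, misbehaves on exactly the networks
anatomists care about: small ones. Q has a resolution limit that hides small
modules, small input perturbations (an extra accessory bone, a variant
suture) can flip the partition wholesale, and optimizers routinely return
left/right-asymmetric modules on perfectly symmetric networks.

This package implements a bottom-up alternative. Instead of optimizing one
global score it asks, for every node, "what is the best module containing
*this* node?", then reconciles the answers:

1. compute a local module around every node (`all_local_modules()`);
2. drop duplicated member sets (`drop_duplicates()`);
3. drop member sets nested inside larger ones (`drop_nested()`);
4. test every combination of the surviving modules for excess overlap with
   an exact combinatorial test (`supertest()`);
5. merge combinations whose overlap is large and statistically supported
   into *covers* — final modules allowed to share nodes (`select_merges()`,
   `build_covers()`);
6. verify each cover against the definition of a module with a one-sided
   Wilcoxon signed-rank test on per-node in/out link counts
   (`cohesion_test()`).

If a single module survives steps 2–3, the network is fully integrated and
the pipeline stops: there is nothing modular to report. `run_nims()` chains
all six steps.

## Step 1: the local cohesion objective

For a candidate member set $C$ in a network with $m$ edges and node degrees
$k_i$, the local quality is

$$q(C) \;=\; \ell_{in}(C) \;-\; \gamma \sum_{i<j \in C} \frac{k_i k_j}{2m},$$

the realized internal link count minus $\gamma$ times its expectation under
the degree-preserving (configuration-model) null. The node-level module of a
focal node is the maximizer of $q$ over sets containing that node. This is
the single-community spin-glass criterion: internal links are rewarded,
missing internal links are penalized through the null expectation, and the
same expression evaluated on the complement boundary is the adhesion
penalty, so maximizing cohesion of $C$ and minimizing adhesion to its
complement coincide for this null.

The search is simulated annealing over membership indicators: one full sweep
of single-node toggle proposals per temperature, Metropolis acceptance,
geometric cooling. Because a toggle changes $q$ by an $O(\deg)$ quantity,
proposals are cheap; the inner loop is compiled (Rcpp).

Tunable parameters (`spinglass_config()`), all dimensionless:

* `gamma` (default 1.0) — resolution. Larger values demand denser modules.
  The default weighs realized and expected links equally and is not varied
  in routine use; it is exposed because the objective is defined for any
  positive value.
* `replicates` (default 10) — independent annealing chains per focal node.
  The **modal** member set across chains is reported with an *agreement*
  fraction; agreement below 0.6 warns that the local landscape is ambiguous.
  A single run would be faithful to the original recipe, but annealing is
  stochastic and the whole point of the strategy is robustness, so replicate
  consensus is the default.
* `t_start` 1.0, `t_stop` 0.01, `cooling` 0.99 — the annealing schedule
  (about 460 temperatures). On networks of anatomical size (tens of nodes)
  this reaches the enumerated optimum essentially always; the package's
  acceptance suite checks ≥ 95% agreement with exhaustive search on
  ≤ 12-node graphs.
* `seed` — master seed. Per-(node, replicate) sub-seeds are derived by
  hashing the node *label*, so results are independent of node ordering and
  stable under adding unrelated nodes.

Ties between equally modal member sets are broken toward the
lexicographically smallest sorted member list, for reproducibility. Any
other detector with the same signature can be plugged in via the `detector`
argument of `all_local_modules()`/`run_nims()`; the downstream steps only
consume member sets.

Degenerate inputs: an isolated focal node returns itself (every toggle is
score-neutral and the chain's best never improves on the singleton); an
edgeless network scores every set 0.

## Step 4: the exact intersection test

For $k$ non-redundant modules, every combination of two or more
($2^k - k - 1$ of them) is tested. Under the null, each module is an
independent uniform random subset of its observed size drawn from the
universe of all $N$ network nodes; the null distribution of
$|S_1 \cap \dots \cap S_k|$ is computed exactly by chained convolution — a
running intersection of size $s$ meets the next set of size $m_j$ in
$\mathrm{Hypergeometric}(N, s, m_j)$ elements. The p-value is the upper tail
$P(X \ge \text{observed})$ including the observed point; the expectation is
$N \prod_i (n_i/N)$ and fold enrichment is observed/expected.

Design choices the source recipe leaves open, decided here:

* **Universe** = the node set of the analyzed network. The test needs a
  finite background; the network itself is the only natural one.
* **Multiple testing**: Bonferroni with divisor equal to the number of
  tested combinations of size ≥ 2 (singletons are not tests). Correcting
  only pairwise tests would be less conservative; the all-combinations
  divisor is the safer reading and is what `supertest()` implements. With
  this divisor, marginal overlaps need to be a node or two larger to clear
  α = 0.05 than under pairwise-only correction — users comparing against
  older analyses should be aware the corrected p-values here are larger.
* **Numerics**: hypergeometric terms come from `stats::dhyper`, which is
  stable for universes far beyond anatomical sizes; exact rational
  arithmetic is unnecessary.

## Step 5: merging rules

Candidates are the Bonferroni-significant combinations, ranked by (1) larger
observed overlap, (2) smaller corrected p-value, (3) fewer constituent
modules, taken greedily so no module joins two merges. The ordering encodes
a documented preference: enlarging a merge is pointless if it *shrinks* the
common core. A significant superset of an accepted merge with a smaller
overlap is reported as rejected with reason `"overlap-reducing superset"`.
Because intersections are monotone (adding a set can only shrink the core),
a triple can only outrank its pairs when all share the same core, in which
case the smaller p-value of the higher-order test decides for the triple —
which is exactly the behavior wanted.

Step 5 is where a researcher is supposed to exercise judgment; with
`interactive = TRUE` the ranked candidates are printed and, in an
interactive session, each commit is confirmed at the prompt. Batch runs
commit the top-ranked plan; equally supported alternatives remain visible in
the rejected table.

## Step 6: the cohesion test

Every node of the network contributes a pair (links into the cover, links
out of the cover); zero differences are dropped, absolute differences are
mid-ranked, $W$ is the sum of positive-difference ranks, and the p-value is
one-sided (in > out). The exact signed-rank distribution is used when the
non-zero pairs are tie-free and fewer than 50; otherwise the normal
approximation with continuity correction (this is `stats::wilcox.test`'s
convention, with the zeros removed before the call so that ties, not zeros,
decide exactness).

**Population choice.** The default pairs *all* network nodes, not only cover
members. The magnitude of published cover statistics on whole anatomical
networks (e.g. $W = 161.5$ on a 21-node network whose cover has 13 nodes,
while the within-cover maximum would be 91) requires non-members to
contribute pairs. The choice has a consequence worth knowing: for a small or
perfectly mirrored module, non-member nodes contribute negative differences
that can balance the members' positive ones, so a 4-node clique in an 8-node
network is *not* cohesion-significant under the all-nodes pairing no matter
how crisp it is. `cohesion_test(..., population = "members")` asks the
narrower members-only question instead. Both populations are exposed;
`run_nims()` forwards the choice. The test is reported as undefined (not
silently passed) when every difference is zero.

## The synthetic generator: what a green test establishes

`planted_network()` emulates the structure the method assumes: a few dense
modules (`p_in`), a sparse background (`p_out`), optional nodes shared
between consecutive modules (planted covers), and optional exact bilateral
symmetry. In bilateral mode, shared nodes *and the first node of every
module* stay unpaired on the midline, connected identically to both sides;
everything else is mirrored into `_L`/`_R` pairs, and one Bernoulli draw per
base pair is applied to both sides so the L↔R relabeling is an exact
automorphism. The per-module midline node is deliberate realism — anatomical
modules contain unpaired midline bones (frontal, occipital, vomer) — and it
is load-bearing: without it the two sides of a planted module are bound only
through shared hubs, and one-sided chimeric sets tie the planted module's
score *exactly*, making the declared ground truth undetectable in principle.

`perturb()` produces the intraspecific-variation edits used for robustness
checks: single edge swaps (remove one edge, add one previously absent pair;
on a complete graph the swap degenerates to a removal, with a warning) and
an optional extra node with named attachments — the accessory-ossicle case.

Defaults used by the acceptance suite: recovery and robustness run on two
modules of 6 nodes with `p_in = 0.9`, `p_out = 0.05` (strong, imperfect
modules over a noisy background); symmetry runs on mirrored 4-node modules
sharing one midline node at `p_in = 1` (the unambiguous planted optimum).
What a green run establishes: the pipeline recovers planted modules whose
local optima match the declared ground truth, on networks of skull-like
size. What it does not establish: performance on weak or overlapping
community structure near the detectability limit, weighted or geometric
effects, or degree-sequence-exact null behavior — none of which the
generator models.

## Known limitations

* The annealer optimizes the cohesion objective; if several sets tie at the
  optimum (symmetric graphs are the common cause) the modal-set report is a
  draw among them and replicate agreement drops — the warning threshold
  (0.6) is the signal to inspect.
* The all-combinations Bonferroni divisor is conservative; published
  analyses that corrected over fewer tests will show smaller p-values for
  the same overlaps.
* The cohesion test's all-nodes population makes small isolated modules
  insignificant by construction (see above); this is a property of the
  convention, not a bug, and the members-only population is one argument
  away.
* Disconnected inputs are analyzed as given, with a warning in the report.
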