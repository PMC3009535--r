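---
title: "Shared-neighbour log-odds module identification: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shared-neighbour log-odds module identification: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nemor)
```

## The problem

Groups of functionally related molecules leave two distinct footprints in an
interaction network. Protein complexes tend to appear as densely connected,
clique-like subgraphs. But many real modules are *not* densely
interconnected: a family of ligands typically does not interact within the
family, yet all of its members bind many of the same receptors. Such a
group forms an independent set that is connected to the rest of the network
as one side of a dense bipartite structure, and density-based community
finders miss it entirely.

`nemor` identifies both kinds of module with a single statistic: evidence
that two nodes belong together is not their direct adjacency but the number
of **shared neighbours** they have, compared against how many they would
share in a degree-matched random network. Nodes in a clique share many
neighbours, and so do the members of a ligand family — the statistic does
not care whether the pair is itself connected.

## The pair score

Let $s_{ab}$ be the number of nodes adjacent to both $a$ and $b$ (excluding
$a$ and $b$ themselves). We model $s_{ab} \sim \mathrm{Poisson}(\lambda)$
and compare two hypotheses: under the null, $\lambda = \lambda^0_{ab}$, the
expectation in a random network preserving all node degrees; under the
alternative, $\lambda$ is free, and its maximum-likelihood estimate given
the observation is simply $\hat\lambda = s_{ab}$. The log-odds of the
alternative against the null, with the MLE plugged in, is

$$
r_{ab} \;=\; \log \frac{\mathrm{Pois}(s_{ab} \mid s_{ab})}
                       {\mathrm{Pois}(s_{ab} \mid \lambda^0_{ab})}
       \;=\; s_{ab} \log\frac{s_{ab}}{\lambda^0_{ab}} - s_{ab} + \lambda^0_{ab}.
$$

Using the MLE instead of a tuned alternative rate is what makes the method
parameterless. Two conventions complete the definition:

* **Natural logarithm.** The base only rescales every score, so ranks and
  merges are unaffected; we use $\ln$ throughout.
* **Exclusion rule.** Pairs with $s_{ab} \le \lambda^0_{ab}$ (including
  $s_{ab} = 0$) are assigned $r_{ab} = 0$: a pair sharing no more
  neighbours than chance carries no significance, even though the
  likelihood ratio above would be positive again for $s_{ab} \ll
  \lambda^0_{ab}$. The score is therefore non-negative, zero exactly on
  $\{s_{ab} \le \lambda^0_{ab}\}$, and strictly increasing in $s_{ab}$
  above the expectation.

```{r score-example}
net <- interaction_network(undirected = rbind(
  c("a", "c"), c("a", "d"), c("b", "c"), c("b", "d")
))
score_all_pairs(net)
```

On this 4-cycle, $a$ and $b$ share both of their neighbours while being
non-adjacent — the smallest example of the bipartite signal.

### The null expectation

For the null rate we use the configuration-model (degree-preserving)
expectation of the shared-neighbour count,

$$
\lambda^0_{ab} \;=\;
\frac{n_a \, n_b \sum_{c \notin \{a,b\}} n_c (n_c - 1)}{(2e)^2},
$$

where $n_v$ is the degree of $v$, $e$ the total number of edges, and the
sum runs over all other nodes: a two-path $a\!-\!c\!-\!b$ requires one of
$c$'s $n_c(n_c-1)$ ordered stub pairs to catch one of $a$'s and one of
$b$'s stubs among the $2e$ ends. This is a large-network asymptotic, not an
exact finite-graph expectation. The test suite validates it by Monte-Carlo
degree-preserving edge rewiring on fixture graphs with hundreds of edges
and moderate degrees — the regime interactome data occupy — where the
rewired-ensemble mean of $s_{ab}$ agrees with $\lambda^0_{ab}$ within
Monte-Carlo error. On very small or dense graphs, or at extreme hub
degrees, the formula systematically *underestimates* the simple-graph
rewiring null (on the 4-cycle the exact null mean is $2/3$ against
$\lambda^0 = 1/4$), which makes the score mildly anti-conservative there;
this is a known limitation of the closed form, shared with every
stub-counting null.

Two bookkeeping conventions: degrees are always combined-mode
neighbour-set sizes (see directed networks below), and if a degenerate
input ever produced $\lambda^0 = 0$ with $s > 0$, the pipeline floors
$\lambda^0$ at $1/(2e)^2$ — a vanishingly small pseudocount that avoids a
division by zero while preserving all rankings. (Under the shipped scoring
modes this situation is actually impossible: a shared neighbour forces
$n_a, n_b \ge 1$ and $n_c \ge 2$.)

### Directed and undirected edges

Interaction data mix undirected edges (protein–protein) with directed ones
(protein–DNA, kinase–substrate). Two policies are offered:

* `symmetrize` (default): every edge is treated as bidirectional and
  shared neighbours are counted on the combined neighbour sets.
* `split`: shared out-neighbours and shared in-neighbours are counted
  separately and summed, with undirected edges contributing to both. Two
  regulators sharing targets and two targets sharing regulators both score,
  but an out-neighbour of $a$ that is an in-neighbour of $b$ does not.

The null expectation uses combined-mode degrees under both policies. This
is a deliberate simplification: a direction-specific null would need a
directed configuration model with separate in/out stub accounting, at the
cost of a second, less interpretable rate. With the combined-degree null,
`split` scores remain comparable with `symmetrize` scores and the
exclusion rule keeps its meaning.

## The grouping process

Scores feed a standard **hierarchical agglomerative clustering** on
similarity. Every node starts as a singleton; the two clusters with the
highest linkage similarity are merged repeatedly, where

* *single linkage* is the maximum $r_{ab}$ over cross-pairs, and
* *complete linkage* is the minimum $r_{ab}$ over cross-pairs,

with pairs absent from the score table contributing similarity 0. The
first merges therefore process node pairs in descending score order, and
cluster-cluster merges are the standard generalisation of that order.

**Stopping.** A merge requires strictly positive linkage similarity.
Because the exclusion rule zeroes every pair with $s_{ab} \le
\lambda^0_{ab}$, agglomeration halts exactly when every remaining
candidate pair shares no more neighbours than expected by chance — the
method's automatic convergence criterion, again with no threshold to tune.
Nodes never merged remain singletons outside all modules. Note that under
complete linkage a cluster pair with *any* unscored cross-pair has linkage
0 and can never merge, so complete-linkage modules are fully
score-connected.

**Determinism.** Tied linkage values are broken towards the cluster pair
whose smallest member identifiers sort first (byte-wise, locale
independent), children of a merge are ordered the same way, and module
output is ordered by size then member list, so identical input yields
byte-identical output.

**Collapse.** The raw binary dendrogram contains insignificant caterpillar
structure: a chain of internal nodes each accreting one more leaf would
emit a nested module per accretion. Wherever an internal node has exactly
two children, one leaf and one internal, the internal child is spliced out
(its children are promoted), bottom-up to a fixpoint — the only
order-independent reading of the rule. Leaf sets are unchanged; a pure
chain collapses to a single n-ary node.

**Module extraction.** One putative module per remaining internal node:
its descendant leaf set. Modules from one tree are laminar (disjoint or
nested); balanced subtrees that survive the collapse yield nested
modules, which is intended — a complex and its stable sub-complex are both
real modules. Size-1 modules are never reported; the `min_size` filter on
the command line is output plumbing, not an algorithm parameter.

```{r pipeline-example}
left <- c("a", "b"); right <- c("w", "x", "y", "z")
k24 <- interaction_network(
  undirected = as.matrix(expand.grid(left, right, stringsAsFactors = FALSE))
)
run_nemo(k24, linkage = "complete")
```

Both sides of the complete bipartite graph $K_{2,4}$ are recovered, the
right side despite being an independent set.

## The synthetic benchmark

`generate_instance()` draws planted-partition networks: the cluster count
$k$ uniform on $\{5,\dots,10\}$, each cluster's size uniform on
$\{5,\dots,10\}$ (discrete, both ends inclusive), each cluster's within
density uniform on $[0.05, 0.08]$, and a
single between-cluster density for the whole network uniform on
$[0.05, 0.1]$. Every within-cluster pair receives an undirected edge with its
cluster's density, every cross-cluster pair with the between density;
planted modules are disjoint and cover all 25–100 nodes. All draws come
from a seeded generator, so instances and whole benchmark runs are
reproducible.

**The default density ranges carry no signal.** The defaults reproduce the
benchmark protocol this generator follows verbatim, but with within
densities of 0.05–0.08 against a background of 0.05–0.1, planted clusters
are no denser than the rest of the network — there is no structure, of
either the clique or the bipartite kind, and recovery is essentially zero;
the ranges read like a transcription slip. We keep them literally as the
defaults and additionally document one corrected variant,
`within_range = c(0.5, 0.8)`: a dropped decimal point is the most
plausible correction, it is the only single-field change that makes planted
clusters denser than background, and 5–10 clusters of 5–10 nodes at
density 0.5–0.8 over a 0.05–0.1 background is a conventional
planted-partition design. The benchmark functions and the command line
accept the override explicitly (`--within 0.5,0.8`), and the acceptance
script reports results under both settings side by side.

What the generator deliberately does not emulate about real interactomes:
degree heterogeneity and hubs (edges are Bernoulli with shared rates, so
degrees are near-Poisson), overlapping complexes, directed edges, and
assay noise such as false-positive edges concentrated on sticky proteins.
Passing the benchmark therefore demonstrates recovery of homogeneous
planted structure, not performance on interactome-scale data.

## Evaluation

*Reconstruction fidelity* of a gold module is the Jaccard coefficient
between its node set and the most similar putative module; *reconstruction
error* is one minus fidelity. Fidelity is monotone non-decreasing as
putative modules are added, so a method returning everything looks good —
which motivates the second protocol: *randomized complexes* are generated
by one global permutation of node labels (size distribution preserved
exactly), real and randomized modules are ranked together by fidelity, and
the ranking is swept into ROC and precision–recall curves. Tied fidelities
are grouped — all items at a score value enter together — so ties between
real and random modules are treated neither optimistically nor
pessimistically. AUC uses the trapezoidal rule, which under tie-grouping
equals the Mann–Whitney pair statistic with the ½ tie correction (asserted
as a property in the tests). A per-module resampling alternative to the
global permutation is available behind `method = "resample"`.

## Problem sizes and numerical choices

The shipped test suite and the acceptance script run the benchmark at 200
networks per density setting (roughly 1500 planted modules), validate the
sparse pair enumeration against a brute-force all-pairs scorer on 1000
random graphs of up to 25 nodes, check the AUC identity on 1000 random
score vectors, and validate $\lambda^0$ by degree-preserving rewiring with
4000 ensemble samples per fixture graph (batch-means standard errors).
These sizes were chosen so the whole suite runs comfortably on a laptop
while keeping Monte-Carlo errors far below the effects being checked.

Other numerical conventions, in one place: node identifiers are
case-sensitive, whitespace-stripped strings ordered byte-wise; self-loops
are dropped on load (a node cannot be its own shared neighbour) and
duplicate edges stored once; reciprocal directed edges are kept as two
edges and both count in $e$ (preserving the input's information rather
than guessing an intent); scores are compared exactly for the stopping
rule (no epsilon — the exclusion rule produces exact zeros); and the
agglomeration matrix is dense in the number of scored nodes, which is the
right trade-off up to a few thousand scored nodes.

## Known limitations

* The closed-form $\lambda^0$ is asymptotic; on tiny dense graphs and at
  extreme hub degrees it underestimates the rewiring null (mildly
  anti-conservative scores).
* Scores are rank evidence, not calibrated p-values; no multiple-testing
  control is attempted or claimed.
* Modules are laminar by construction; genuinely overlapping complexes can
  only be represented by nesting.
* The benchmark generator's homogeneous edge model understates the
  difficulty of real interactomes (see above).
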