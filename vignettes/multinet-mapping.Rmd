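---
title: "Mapping protein modules across function and disease layers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping protein modules across function and disease layers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Protein-protein interaction (PPI) networks, Gene Ontology annotations,
pathway databases and disease-gene catalogues each describe one facet of
cellular organization. Analyses that treat them separately miss the most
interesting structures: groups of physically interacting proteins that also
share a function, sit on the same pathway, and are implicated in the same
class of disease. `netmodmap` implements an integrative mapping of all of
these layers onto one object — the *topological module*, a locally dense
protein group found by graph clustering of the PPI network.

The pipeline is:

1. **Network construction.** Interactions from scored tables are kept only
   when they reach a confidence cutoff and are reported by at least two
   evidence databases (and, optionally, are direct physical interactions).
   The surviving records form an undirected simple graph.
2. **Module detection.** A pluggable community detector partitions the
   graph. Modules with at least three proteins ("large" modules) go
   downstream.
3. **Layer calling.** Each large module is tested for Gene Ontology term
   over-representation (hypergeometric test, Benjamini–Hochberg correction,
   adjusted $p < \alpha$) at a single GO-slim depth, and for pathway
   enrichment; disease and protein-complex modules are called by a plain
   counting rule (more than two module proteins sharing one disease class
   or complex).
4. **Integration.** A module whose disease module overlaps a functional
   module on *more than half* of the disease module's proteins is
   *non-trivial*; with a pathway module in place of the functional module it
   is *significant*.
5. **Evaluation.** Detectors are compared by Newman modularity $Q$ and by
   mapping frequencies — the fraction of large modules carrying each kind of
   layer module.

## Models and statistics

**Enrichment.** For a module with $n$ annotated proteins out of a background
of $N$, and a term annotating $K$ background genes of which $k$ fall in the
module, the upper-tail hypergeometric probability

$$P(X \ge k) = \sum_{i=k}^{\min(K,n)}
  \frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}}$$

is computed through the survival function of the hypergeometric
distribution (numerically stable for large $N$). Within one module, raw
p-values are adjusted per namespace (BP, CC, MF, pathway) with the
Benjamini–Hochberg step-up procedure — mirroring enrichment tools that
correct per test set — and terms with adjusted $p < \alpha$ (default 0.05)
are reported. The background defaults to the annotated proteins of the
analyzed network, not the whole genome: the network itself is the sampling
frame from which modules are drawn. Both choices are configurable
(`bh_scope`, `background`).

**Coverage.** A module is *fully covered* when a single significant term's
hit genes equal the module's annotated proteins. Because hit genes are by
construction a subset of the annotated module genes, this is exactly the
condition $k = n$ on a significant row, which lets staged runs recompute
coverage from the enrichment table alone. A union-of-terms variant
(`coverage = "union"`) is available but off by default, since the
single-term reading is the stricter and more interpretable notion of a
module "doing one thing".

**Modularity.** Partitions are scored with Newman's
$Q = \sum_c \left[ L_c/m - (d_c/2m)^2 \right]$, where $m$ is the edge
count, $L_c$ the intra-module edges and $d_c$ the total degree of module
$c$. Nodes left out of every module (possible with the random-walk
detector) contribute as singletons. $Q$ is undefined on an edgeless graph
and the function refuses to compute it.

## Detectors

* **default** — multilevel greedy modularity maximization (Louvain, via
  igraph) followed by a local node-move refinement pass: nodes are swept in
  order and moved to a neighbouring community whenever the move increases
  $Q$ (computed incrementally), with ties going to the lower community id.
  The multilevel core was chosen over single-level CNM agglomeration
  because CNM's path-dependent merges routinely fuse small dense modules,
  while the multilevel scheme with refinement recovers planted 8-protein
  modules essentially always at the densities used in the package's tests.
  The refinement pass also rescues individual nodes of sparse modules that
  the agglomeration attached greedily. The detector interface is pluggable,
  and `read_partition()` lets an externally computed clustering be injected
  unchanged.
* **mcl** — Markov clustering: the column-stochastic adjacency matrix with
  unit self-loops is alternately squared (expansion) and entrywise powered
  with exponent $r$ then column-renormalized (inflation; default $r = 2$),
  with entries below $10^{-8}$ pruned, until successive matrices differ by
  less than the pruning threshold or 100 iterations pass (a warning is
  raised if they do). Each node joins the cluster of its strongest
  attractor row; overlap ties go to the lowest-numbered cluster, so the
  result is a true partition.
* **rwr** — random walk with restart: for each seed $s$ the stationary
  vector of $p \leftarrow (1-r)\,W p + r\,e_s$ is iterated to an $L_1$
  tolerance of $10^{-10}$ ($r = 0.4$ by default, $W$ the column-normalized
  adjacency). Nodes are assigned to the seed of maximal affinity, ties to
  the lexicographically smaller seed identifier. How walk affinities become
  disjoint clusters, and how seeds are chosen, are not standardized
  anywhere; the argmax rule and the seed default (disease genes when
  disease annotations are loaded, otherwise $\lfloor\sqrt{n}\rfloor$ random
  nodes under the run seed) are this package's documented choices. Nodes
  unreachable from every seed land in an explicit `"unassigned"` module.

All detectors are deterministic given the run seed.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `min_sources` | 2 | distinct evidence databases required per interaction |
| `min_score` | 0.73 | confidence cutoff on the normalized interaction score (a configurable stand-in for a database's "high-confidence" tier, which is not standardized across releases) |
| `level` | 3 | GO-slim depth tested; term level = 1 + shortest `is_a` path to the namespace root, computed from an OBO file when no precomputed level column is supplied |
| `alpha` | 0.05 | adjusted-p threshold for enrichment |
| `threshold` | 0.5 | strict overlap threshold for non-trivial/significant calls — an overlap of exactly one half does **not** qualify |
| `min_module_size` | 3 | large-module floor; also the floor for every layer module ("more than two proteins") |
| `inflation` | 2 | MCL granularity |
| `restart` | 0.4 | RWR restart probability |

The "more than two proteins" counting rule is read as $\ge 3$, consistent
with the three-protein floor used for topological and functional modules.
The overlap denominator is the disease module's size (configurable to the
smaller module via `denominator = "min"`), so a disease module fully inside
a larger functional module counts as overlap 1.

## The synthetic study generator

`synth_config()` defines a planted-partition benchmark: by default 10
modules of 8 proteins, within-module edge probability 0.9, between-module
0.01 — dense modules in a sparse background, the regime PPI module
detection assumes. A seeded 70% of modules receive one level-3 functional
term covering exactly their genes (plus 20 random background terms of 3–16
genes as noise), the same modules receive an exact-copy pathway gene set,
every module is copied as a protein complex, and a seeded 50% of modules
receive a planted disease module: a $\ge 3$-gene subset annotated with two
raw disease names of one phenotype class (two names, so disease–disease
networks have edges to exercise). Node identifiers are randomly permuted so
they encode nothing about the planted labels.

Because the plants are exact covers, a pipeline run that recovers the
planted partition must report a fully-covered frequency equal to the
covering fraction, a disease mapped frequency equal to the disease
fraction, and non-trivial flags exactly on modules carrying both plants —
this is what the package's acceptance tests assert.

What the generator does *not* emulate: scale-free degree distributions,
hub proteins shared between modules, annotation incompleteness and bias,
overlapping complexes, or the noisy many-to-many structure of real
disease-gene catalogues. Passing the planted-recovery tests therefore shows
the machinery is correct, not that any particular biological dataset will
map as cleanly.

## Numerical and degenerate-input choices

* Hypergeometric tails are taken from the survival function, never by
  summing densities in linear space.
* MCL columns that prune to zero get their self-entry restored before
  renormalization, so the matrix stays stochastic.
* Result ordering is always (adjusted p, term id), and file writers sort
  rows, so identical runs are byte-identical — the pipeline's manifest
  deliberately records no timestamps.
* Empty inputs: an empty record list builds an empty network without error;
  an edgeless network makes modularity raise a degenerate-input error; an
  empty background or an empty seed set is an error.
* Problem sizes in the test-suite simulations (planted networks of 80
  nodes, 20 seeded recovery runs, 1000-tuple oracle sweeps) were chosen so
  the statistical properties under test are sharp at desk scale.

## Limitations

* The default detector is a documented stand-in for topology-aware
  algorithms tuned to PPI data; the pluggable interface and partition
  injection exist precisely so such a method can replace it.
* Pathway enrichment uses the plain hypergeometric test for all
  namespaces; tools built on variants such as the EASE-adjusted score will
  give slightly more conservative p-values.
* Identifier matching is case-sensitive and exact; alias resolution is the
  caller's responsibility.
* The graph is treated as unweighted after filtering; confidence scores
  gate inclusion but do not weight edges.
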