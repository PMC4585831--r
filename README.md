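# netmodmap

Integrative mapping of topological, functional and disease modules in
protein–protein interaction (PPI) networks.

Groups of physically interacting proteins often share a function, a
pathway, and a disease phenotype — but each of those statements lives in a
different database. `netmodmap` puts them on one object: it builds a
high-confidence PPI graph from scored interaction tables, partitions it
into *topological modules* with a pluggable community detector, annotates
each large module against Gene Ontology terms, pathway gene sets,
disease–gene associations and protein complexes, and classifies modules by
how their layers overlap. It is written for systems-biology analysts who
have flat exports of interaction and annotation data and want a
reproducible, scriptable multi-network analysis.

## The method in brief

* **Network** — keep interactions with confidence ≥ `min_score` that are
  reported by ≥ 2 evidence databases (optionally direct physical only);
  build an undirected simple graph.
* **Modules** — partition with one of three detectors: multilevel greedy
  modularity maximization with a node-move rescue pass (default), Markov
  clustering (MCL, inflation r = 2), or seeded random walk with restart
  (r = 0.4). Modules with ≥ 3 proteins go downstream. Partition quality is
  Newman's Q = Σ_c [ L_c/m − (d_c/2m)² ].
* **Layers** — per module, hypergeometric over-representation
  P(X ≥ k) with Benjamini–Hochberg correction (adjusted p < 0.05) at one
  GO-slim level (default 3) for functional terms and pathways; a counting
  rule (> 2 proteins sharing one of 15 disease phenotype classes, or one
  complex) for disease and complex modules.
* **Integration** — a module is **non-trivial** when a disease module
  overlaps a functional module on more than half of the disease module's
  proteins, and **significant** when the same holds against a pathway
  module. A module is **fully covered** when one enriched term hits all of
  its annotated proteins.
* **Evaluation** — detectors are compared by Q and by mapping frequencies:
  the fraction of large modules carrying each kind of layer module.

## Worked example

The bundled generator plants a ground-truth study: 10 modules of 8
proteins (within-module edge probability 0.9, between 0.01), a covering
functional term in 70% of modules, a disease class in 50%.

```r
library(netmodmap)

study <- generate_synthetic_study(synth_config(seed = 42), dir = "demo")
cfg <- run_config(
  interactions  = "demo/interactions.tsv",
  gene_term     = "demo/gene_term.tsv",
  term_metadata = "demo/term_metadata.tsv",
  pathways_gmt  = "demo/pathways.gmt",
  complexes_gmt = "demo/complexes.gmt",
  gene_disease  = "demo/gene_disease.tsv",
  class_map     = "demo/disease_classes.tsv",
  outdir = "demo_out", seed = 42L)
res <- run_pipeline(cfg)
#> build-net: 80 proteins, 272 interactions
#> detect (default): 10 large and 0 small modules
#> call-layers: functional=8, pathway=7, disease=5, complex=10
#> integrate: 4 non-trivial, 4 significant of 10 large modules

print(res$report, row.names = FALSE)
#>   method         Q n_modules_large mapped_functional mapped_pathway
#>  default 0.7966723              10               0.7            0.7
#>  mapped_disease mapped_complex fully_covered avg_functional avg_pathway
#>             0.5              1           0.7            0.7         0.7
#>  avg_disease avg_complex n_non_trivial n_significant n_disease_complex
#>       0.3375           1             4             4                 5
```

Reading the numbers: the detector recovered all 10 planted modules
(Q ≈ 0.80 on this dense-in/sparse-out graph); 7 of 10 modules are mapped
to — and fully covered by — a functional term, matching the planted 70%;
5 of 10 carry a disease module, matching the planted 50%; the 4 modules
carrying both plants are exactly the non-trivial (and, via the planted
pathway copies, significant) ones. Every artifact (network, partition,
enrichment, layer modules, classification, report, manifest) is written
under `demo_out/`.

The same run works from a shell via the thin CLI launcher:

```sh
NMM=$(Rscript -e 'cat(system.file("cli/netmodmap.R", package = "netmodmap"))')
Rscript $NMM synth --out demo --seed 42
Rscript $NMM pipeline --config run.yaml
```

with `run.yaml` holding the `run_config()` keys. Each stage (`build-net`,
`detect`, `enrich`/`call-layers`, `integrate`, `evaluate`) is also an
independent subcommand operating on the previous stage's files, and an
externally computed clustering can be injected with the `partition` key.

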