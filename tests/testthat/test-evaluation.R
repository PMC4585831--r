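test_that("mapping frequency counts large modules with a layer call", {
  part <- module_partition(list(c("a", "b", "c"), c("d", "e", "f"),
                                c("g", "h", "i"), c("j", "k", "l"),
                                c("z1", "z2")), method = "toy")
  lc <- list(
    `1` = list(functional = list(layer_module("functional", "1",
                                              c("a", "b", "c"), "t")),
               pathway = list(), disease = list(), complex = list(),
               fully_covered = TRUE),
    `2` = list(functional = list(layer_module("functional", "2",
                                              c("d", "e", "f"), "t")),
               pathway = list(), disease = list(), complex = list(),
               fully_covered = FALSE),
    `3` = list(functional = list(layer_module("functional", "3",
                                              c("g", "h", "i"), "t")),
               pathway = list(), disease = list(), complex = list(),
               fully_covered = FALSE),
    `4` = list(functional = list(), pathway = list(), disease = list(),
               complex = list(), fully_covered = FALSE))
  expect_equal(mapping_frequency(part, lc, "functional"), 0.75)
  expect_equal(mapping_frequency(part, lc, "functional",
                                 mode = "fully_covered"), 0.25)
  expect_equal(mapping_frequency(part, lc, "disease"), 0)
  small_only <- module_partition(list(c("a", "b")), method = "toy")
  expect_error(mapping_frequency(small_only, lc, "functional"),
               "no large modules")
})

test_that("average mapping frequency is the mean best per-module coverage", {
  part <- module_partition(list(c("a", "b", "c", "d"),
                                c("e", "f", "g", "h")), method = "toy")
  lc <- list(
    `1` = list(functional = list(
      layer_module("functional", "1", c("a", "b", "c"), "t1"),
      layer_module("functional", "1", c("a", "b", "c", "d"), "t2")),
      pathway = list(), disease = list(), complex = list(),
      fully_covered = TRUE),
    `2` = list(functional = list(), pathway = list(), disease = list(),
               complex = list(), fully_covered = FALSE))
  # module 1: best coverage 4/4; module 2 unmapped: 0
  expect_equal(average_mapping_frequency(part, lc, "functional"), 0.5)
  lc$`1`$functional[[2]] <- NULL
  expect_equal(average_mapping_frequency(part, lc, "functional"),
               mean(c(3 / 4, 0)))
  # per-layer-module variant averages every call's coverage
  expect_equal(average_mapping_frequency(part, lc, "functional",
                                         per_layer_module = TRUE), 3 / 4)
  # unmapped everywhere -> 0
  expect_equal(average_mapping_frequency(part, lc, "disease"), 0)
})

test_that("frequency metrics respect their ordering invariants", {
  study <- generate_synthetic_study(synth_config(seed = 17))
  part <- detect_modules(study$network, "default", seed = 17)
  lc <- call_layers(part, functional_annotations = study$functions,
                    pathway_annotations = study$pathways,
                    gene_diseases = study$gene_diseases,
                    class_map = study$class_map,
                    complex_annotations = study$complexes)
  expect_lte(mapping_frequency(part, lc, "functional", "fully_covered"),
             mapping_frequency(part, lc, "functional", "mapped"))
  for (layer in c("functional", "pathway", "disease", "complex")) {
    expect_lte(average_mapping_frequency(part, lc, layer),
               mapping_frequency(part, lc, layer, "mapped") + 1e-12)
  }
})

test_that("benchmark network keeps exactly disease-gene-touching interactions", {
  rec <- make_records(c("a", "b", "c", "d", "e", "f", "g", "h", "i", "j"),
                      c("b", "c", "d", "e", "f", "g", "h", "i", "j", "a"))
  dg <- c("a", "e")
  net <- build_benchmark_network(rec, dg)
  touching <- rec$protein_a %in% dg | rec$protein_b %in% dg
  expect_equal(igraph::gsize(net), sum(touching))  # 4 of 10 edges
  expect_error(build_benchmark_network(rec, character(0)), "empty")
  expect_error(build_benchmark_network(rec, "absent_gene"),
               "benchmark network is empty")
})

test_that("disease-complex modules mirror the non-trivial overlap rule", {
  d <- layer_module("disease", "1", c("a", "b", "c"), "Cancer")
  cx_hit <- layer_module("complex", "1", c("a", "b", "d"), "C1")
  cx_miss <- layer_module("complex", "1", c("x", "y", "z"), "C2")
  expect_true(has_disease_complex_module(
    list(disease = list(d), complex = list(cx_hit))))
  expect_false(has_disease_complex_module(
    list(disease = list(d), complex = list(cx_miss))))
  expect_false(has_disease_complex_module(
    list(disease = list(), complex = list(cx_hit))))
})

test_that("method comparison reports all detectors and is deterministic", {
  study <- generate_synthetic_study(synth_config(module_sizes = rep(6L, 4),
                                                 seed = 19))
  layers <- list(functional = study$functions, pathway = study$pathways,
                 gene_diseases = study$gene_diseases,
                 class_map = study$class_map, complex = study$complexes)
  rep1 <- skip_msgs(compare_methods(study$network, annotation_layers = layers,
                                    seed = 19))
  expect_setequal(rep1$method, c("default", "mcl", "rwr"))
  expect_true(all(rep1$Q > -0.5 & rep1$Q < 1))
  freq_cols <- grep("^(mapped_|avg_|fully)", names(rep1))
  expect_true(all(rep1[, freq_cols] >= 0 & rep1[, freq_cols] <= 1,
                  na.rm = TRUE))
  rep2 <- skip_msgs(compare_methods(study$network, annotation_layers = layers,
                                    seed = 19))
  expect_identical(rep1, rep2)
})

test_that("compare_methods on planted cliques composes the module oracles", {
  # two planted 5-cliques with covering terms: Q = 0.5, full functional map
  study <- generate_synthetic_study(synth_config(
    module_sizes = c(5L, 5L), p_in = 1, p_out = 0,
    covering_term_fraction = 1, disease_class_fraction = 1,
    n_background_terms = 0L, seed = 23))
  expect_equal(igraph::gsize(study$network), 20)
  rep <- compare_methods(study$network,
                         methods = list(list(method = "default")),
                         annotation_layers = list(
                           functional = study$functions,
                           gene_diseases = study$gene_diseases,
                           class_map = study$class_map),
                         seed = 23)
  expect_equal(rep$Q, 0.5)
  expect_equal(rep$mapped_functional, 1)
  expect_equal(rep$fully_covered, 1)
  expect_equal(rep$mapped_disease, 1)
  expect_equal(rep$n_non_trivial, 2)
})
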