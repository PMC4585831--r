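# Build a minimal significant-enrichment data.frame by hand.
enr_row <- function(term_id, hits, n, namespace = "BP",
                    p = 1e-6, padj = 1e-5) {
  out <- data.frame(term_id = term_id, name = term_id, namespace = namespace,
                    k = length(hits), K = length(hits) + 2L, n = n,
                    N = 100L, p_value = p, p_adjusted = padj,
                    stringsAsFactors = FALSE)
  out$hit_genes <- list(hits)
  out
}

test_that("functional modules follow the single-term coverage rule", {
  # four-protein module with two three-gene terms, neither covering it
  mod <- c("BL1S1", "BL1S2", "BL1S3", "SNAPN")
  enr <- rbind(enr_row("pigmentation", c("BL1S1", "BL1S2", "BL1S3"), 4),
               enr_row("vesicle_transport", c("BL1S1", "BL1S3", "SNAPN"), 4))
  fm <- call_functional_modules(mod, enr, parent_module_id = "9")
  expect_equal(length(fm), 2)
  expect_equal(lengths(lapply(fm, `[[`, "genes")), c(3L, 3L))
  expect_false(attr(fm, "fully_covered"))

  # eight-gene module hit in full by one term -> fully covered
  mod8 <- sprintf("COP%d", 1:8)
  enr8 <- enr_row("golgi_transport", mod8, 8)
  fm8 <- call_functional_modules(mod8, enr8, parent_module_id = "3")
  expect_equal(length(fm8), 1)
  expect_true(attr(fm8, "fully_covered"))

  # a significant term with only two hit genes emits nothing
  enr2 <- enr_row("small", c("BL1S1", "BL1S2"), 4)
  expect_equal(length(call_functional_modules(mod, enr2)), 0)
})

test_that("union coverage is a strictly weaker rule than single-term coverage", {
  mod <- c("a", "b", "c", "d")
  enr <- rbind(enr_row("t1", c("a", "b", "c"), 4),
               enr_row("t2", c("b", "c", "d"), 4))
  single <- call_functional_modules(mod, enr, coverage = "single")
  union_ <- call_functional_modules(mod, enr, coverage = "union")
  expect_false(attr(single, "fully_covered"))
  expect_true(attr(union_, "fully_covered"))
})

test_that("pathway modules are emitted per significant pathway", {
  mod <- sprintf("g%02d", 1:17)
  enr <- enr_row("DNA_replication", mod, 17, namespace = "pathway")
  pm <- call_pathway_modules(mod, enr, parent_module_id = "23")
  expect_equal(length(pm), 1)
  expect_equal(length(pm[[1]]$genes), 17)

  two <- rbind(enr_row("pw_a", mod[1:5], 17, namespace = "pathway"),
               enr_row("pw_b", mod[4:6], 17, namespace = "pathway"))
  expect_equal(length(call_pathway_modules(mod, two)), 2)
  expect_equal(length(call_pathway_modules(mod, enr[0, , drop = FALSE])), 0)
})

test_that("disease modules need more than two genes of one class", {
  cm <- disease_class_map(c(HeartFailure = "Cardiovascular",
                            Osteoporosis = "Bone",
                            Arrhythmia = "Cardiovascular",
                            Depression = "Psychiatric"))
  mod <- c("EGLN", "TGFB1", "TGFR1", "TGFR2", "OTHER")
  gd <- list(EGLN = "HeartFailure", TGFB1 = c("HeartFailure", "Osteoporosis"),
             TGFR1 = "Arrhythmia", TGFR2 = "HeartFailure")
  dm <- call_disease_modules(mod, gd, cm, parent_module_id = "6")
  expect_equal(length(dm), 1)
  expect_equal(dm[[1]]$term_id, "Cardiovascular")
  expect_setequal(dm[[1]]$genes, c("EGLN", "TGFB1", "TGFR1", "TGFR2"))

  # exactly two genes sharing a class is below the "more than two" bar
  gd2 <- list(a = "HeartFailure", b = "Arrhythmia")
  expect_equal(length(call_disease_modules(c("a", "b", "c"), gd2, cm)), 0)

  # a gene may sit in two disease modules of one parent
  cm2 <- disease_class_map(c(d1 = "Metabolic", d2 = "Cancer"))
  gd3 <- list(a = "d1", b = "d1", c = c("d1", "d2"), d = "d2", e = "d2")
  dm3 <- call_disease_modules(c("a", "b", "c", "d", "e"), gd3, cm2)
  expect_equal(length(dm3), 2)
  shared <- Reduce(intersect, lapply(dm3, `[[`, "genes"))
  expect_equal(shared, "c")

  # unmapped disease names are skipped, not fatal
  gd4 <- list(a = "mystery", b = "d1", c = "d1", d = "d1")
  expect_message(out <- call_disease_modules(letters[1:4], gd4, cm2),
                 "missing from the class map")
  expect_equal(length(out), 1)
})

test_that("complex modules use the same counting rule on complex membership", {
  cx <- annotation_set(list(
    C1 = list(name = "complex 1", namespace = "complex", level = NULL,
              genes = c("a", "b", "c", "d", "z")),
    C2 = list(name = "complex 2", namespace = "complex", level = NULL,
              genes = c("c", "d", "e", "q", "r")),
    C3 = list(name = "complex 3", namespace = "complex", level = NULL,
              genes = c("a", "q"))))
  mod <- c("a", "b", "c", "d", "e", "f")
  cmods <- call_complex_modules(mod, cx)
  # C1 hits 4 module genes, C2 hits 3 (c, d, e): both emitted; C3 hits 1
  expect_equal(vapply(cmods, `[[`, character(1), "term_id"), c("C1", "C2"))
  expect_setequal(cmods[[1]]$genes, c("a", "b", "c", "d"))
  expect_setequal(cmods[[2]]$genes, c("c", "d", "e"))
  expect_equal(length(call_complex_modules(c("a", "q", "x"), cx)), 0)
})

test_that("every layer module is a >=3-gene subset of its parent", {
  study <- generate_synthetic_study(synth_config(seed = 31))
  lc <- call_layers(study$truth$planted_partition,
                    functional_annotations = study$functions,
                    pathway_annotations = study$pathways,
                    gene_diseases = study$gene_diseases,
                    class_map = study$class_map,
                    complex_annotations = study$complexes)
  parents <- study$truth$planted_partition$modules
  for (mid in names(lc)) {
    for (layer in c("functional", "pathway", "disease", "complex")) {
      for (lm in lc[[mid]][[layer]]) {
        expect_gte(length(lm$genes), 3)
        expect_true(all(lm$genes %in% parents[[mid]]))
      }
    }
  }
})

test_that("layer module TSV round trip preserves genes and layers", {
  lm1 <- layer_module("disease", "4", c("a", "b", "c"), "Cancer")
  lm2 <- layer_module("functional", "4", c("a", "b", "d"), "GO:1",
                      support = enr_row("GO:1", c("a", "b", "d"), 4))
  path <- tempfile(fileext = ".tsv")
  write_layer_modules(list(lm1, lm2), path)
  back <- read_layer_modules(path)
  expect_equal(length(back), 2)
  layers <- vapply(back, `[[`, character(1), "layer")
  expect_setequal(layers, c("disease", "functional"))
  d <- back[[which(layers == "disease")]]
  expect_setequal(d$genes, c("a", "b", "c"))
})
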