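test_that("hypergeometric tail matches closed forms and enumeration", {
  expect_equal(hypergeom_pvalue(0, 3, 4, 10), 1)
  expect_equal(hypergeom_pvalue(5, 5, 5, 10), 1 / 252)
  expect_equal(hypergeom_pvalue(2, 3, 3, 6), 0.5)
  set.seed(21)
  for (i in 1:50) {
    N <- sample(2:12, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(hypergeom_pvalue(k, K, n, N), hyper_enum_oracle(k, K, n, N),
                 tolerance = 1e-12)
  }
  expect_error(hypergeom_pvalue(4, 3, 3, 6), "invalid")
  expect_error(hypergeom_pvalue(1, 7, 3, 6), "invalid")
})

test_that("hypergeometric tail is monotone non-increasing in k", {
  for (tuple in list(c(5, 8, 20), c(3, 3, 6), c(10, 15, 40))) {
    K <- tuple[1]; n <- tuple[2]; N <- tuple[3]
    p <- vapply(0:min(K, n), hypergeom_pvalue, numeric(1), K = K, n = n,
                N = N)
    expect_true(all(diff(p) <= 1e-15))
  }
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(0.04, 0.5)), c(0.08, 0.5))
  expect_identical(bh_adjust(numeric(0)), numeric(0))
  set.seed(22)
  for (i in 1:30) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
    expect_true(all(bh_adjust(p) >= p))
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm], tolerance = 1e-12)
  }
})

test_that("level filtering keeps exactly the requested GO-slim depth", {
  aset <- annotation_set(list(
    t2 = list(name = "two", namespace = "BP", level = 2L, genes = c("a", "b")),
    t3a = list(name = "three a", namespace = "BP", level = 3L,
               genes = c("a", "c")),
    t3b = list(name = "three b", namespace = "CC", level = 3L,
               genes = c("b", "d")),
    t4 = list(name = "four", namespace = "BP", level = 4L, genes = "d"),
    tna = list(name = "none", namespace = "MF", level = NULL, genes = "a")))
  kept <- skip_msgs(filter_terms_by_level(aset, 3L))
  expect_setequal(names(kept$terms), c("t3a", "t3b"))
  all_na <- annotation_set(list(
    x = list(name = "x", namespace = "BP", level = NULL, genes = "g")))
  expect_equal(length(skip_msgs(filter_terms_by_level(all_na, 3L))$terms), 0)
})

test_that("OBO parsing assigns levels by shortest is_a path from the root", {
  obo <- tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "",
               "[Term]", "id: GO:0", "name: root",
               "namespace: biological_process", "",
               "[Term]", "id: GO:1", "name: a",
               "namespace: biological_process", "is_a: GO:0 ! root", "",
               "[Term]", "id: GO:2", "name: b",
               "namespace: biological_process", "is_a: GO:1 ! a", "",
               "[Term]", "id: GO:3", "name: c",
               "namespace: biological_process", "is_a: GO:2 ! b", "",
               "[Term]", "id: GO:4", "name: shortcut",
               "namespace: biological_process",
               "is_a: GO:0 ! root", "is_a: GO:3 ! c", "",
               "[Term]", "id: GO:9", "name: gone", "is_obsolete: true"),
             obo)
  lv <- obo_term_levels(obo)
  expect_equal(lv$level[match(c("GO:0", "GO:1", "GO:2", "GO:3"), lv$term)],
               c(1L, 2L, 3L, 4L))
  expect_equal(lv$level[lv$term == "GO:4"], 2L)  # shortest path wins
  expect_false("GO:9" %in% lv$term)

  aset <- annotation_set(list(
    `GO:3` = list(name = "c", namespace = "BP", level = NULL,
                  genes = c("a", "b", "c"))))
  aset <- set_term_levels(aset, lv)
  expect_equal(aset$terms$`GO:3`$level, 4L)
})

test_that("module enrichment agrees with an all-by-hand oracle", {
  background <- sprintf("g%04d", 1:1000)
  module <- background[1:8]
  aset <- annotation_set(list(
    hit = list(name = "the term", namespace = "BP", level = 3L,
               genes = module),
    noise = list(name = "noise", namespace = "BP", level = 3L,
                 genes = background[5:600])))
  res <- enrich_module(module, aset, background, alpha = 0.05)
  expect_true("hit" %in% res$term_id)
  expect_equal(res$term_id[1], "hit")  # rank 1 by adjusted p
  i <- match("hit", res$term_id)
  expect_equal(res$p_value[i], hyper_enum_oracle_big(8, 8, 8, 1000),
               tolerance = 1e-12)
  expect_equal(res$k[i], 8)
  expect_equal(res$n[i], 8)

  # module with no annotated genes -> empty result
  none <- enrich_module(sprintf("x%d", 1:5), aset, background)
  expect_equal(nrow(none), 0)
  expect_error(enrich_module(module, aset, character(0)), "background")
})

test_that("borderline BH membership is decided by the independent oracle", {
  background <- sprintf("g%02d", 1:40)
  module <- background[1:6]
  # two BP terms engineered to give distinct raw p-values
  aset <- annotation_set(list(
    ta = list(name = "a", namespace = "BP", level = 3L,
              genes = background[c(1:4, 30:34)]),
    tb = list(name = "b", namespace = "BP", level = 3L,
              genes = background[c(1:3, 20:36)])))
  raw <- c(hypergeom_pvalue(4, 9, 6, 40), hypergeom_pvalue(3, 20, 6, 40))
  adj <- bh_oracle(raw)
  res <- enrich_module(module, aset, background, alpha = 0.05)
  expect_setequal(res$term_id, c("ta", "tb")[adj < 0.05])
  for (i in seq_len(nrow(res))) {
    j <- match(res$term_id[i], c("ta", "tb"))
    expect_equal(res$p_adjusted[i], adj[j], tolerance = 1e-12)
  }
})

test_that("enrichment results satisfy their structural invariants", {
  set.seed(23)
  background <- sprintf("g%03d", 1:60)
  aset <- annotation_set(stats::setNames(lapply(1:12, function(i) {
    list(name = paste0("t", i), namespace = sample(c("BP", "CC"), 1),
         level = 3L, genes = sample(background, sample(3:20, 1)))
  }), paste0("t", 1:12)))
  for (rep in 1:5) {
    module <- sample(background, sample(4:10, 1))
    res <- enrich_module(module, aset, background, alpha = 0.2)
    expect_true(all(lengths(res$hit_genes) >= 1))
    expect_true(all(res$p_adjusted < 0.2))
    expect_true(all(res$p_adjusted >= res$p_value - 1e-15))
    expect_true(all(res$k <= pmin(res$K, res$n)))
    expect_false(is.unsorted(res$p_adjusted))
  }
})

test_that("GMT and annotation TSV round trips preserve gene sets", {
  aset <- annotation_set(list(
    p1 = list(name = "pw one", namespace = "pathway", level = NULL,
              genes = c("b", "a", "c")),
    p2 = list(name = "pw two", namespace = "pathway", level = NULL,
              genes = c("d", "e", "f"))))
  gmt <- tempfile(fileext = ".gmt")
  write_gmt(aset, gmt)
  back <- read_gmt(gmt)
  expect_setequal(back$terms$p1$genes, c("a", "b", "c"))
  expect_equal(back$terms$p2$name, "pw two")

  gt <- tempfile(fileext = ".tsv")
  meta <- tempfile(fileext = ".tsv")
  bp <- annotation_set(list(
    t1 = list(name = "n1", namespace = "BP", level = 3L, genes = c("x", "y")),
    t2 = list(name = "n2", namespace = "CC", level = 2L, genes = "z")))
  write_annotation_tsv(bp, gt, meta)
  back2 <- read_annotation_tsv(gt, meta)
  expect_equal(back2$terms$t1$level, 3L)
  expect_equal(back2$terms$t2$namespace, "CC")
  expect_setequal(back2$terms$t1$genes, c("x", "y"))
})
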