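#' Configuration for the synthetic study generator
#'
#' Defines the planted-partition study conditions: module sizes, within- and
#' between-module edge probabilities, and the fractions of modules receiving
#' a covering functional term and a planted disease class. Defaults describe
#' a network of 10 modules of 8 proteins with dense modules (p_in = 0.9) and
#' sparse background (p_out = 0.01), a covering term planted in 70% of
#' modules and a disease class in 50%.
#'
#' @param module_sizes Integer vector of planted module sizes.
#' @param p_in Within-module edge probability.
#' @param p_out Between-module edge probability (warn when >= p_in).
#' @param covering_term_fraction Fraction of modules receiving one level-3
#'   term covering exactly their genes.
#' @param disease_class_fraction Fraction of modules receiving a planted
#'   disease-class gene subset (>= 3 genes).
#' @param n_background_terms Number of random noise terms added to the
#'   functional layer.
#' @param n_disease_classes Number of disease classes drawn from (cycled
#'   over the default 15-class vocabulary).
#' @param seed Integer seed; every random choice derives from it.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(module_sizes = rep(8L, 10L), p_in = 0.9,
                         p_out = 0.01, covering_term_fraction = 0.7,
                         disease_class_fraction = 0.5,
                         n_background_terms = 20L, n_disease_classes = 15L,
                         seed = 1L) {
  stopifnot(p_in >= 0, p_in <= 1, p_out >= 0, p_out <= 1,
            covering_term_fraction >= 0, covering_term_fraction <= 1,
            disease_class_fraction >= 0, disease_class_fraction <= 1,
            sum(module_sizes) >= 3)
  if (p_in <= p_out) {
    warning("p_in <= p_out: planted structure will not be recoverable")
  }
  structure(list(module_sizes = as.integer(module_sizes), p_in = p_in,
                 p_out = p_out,
                 covering_term_fraction = covering_term_fraction,
                 disease_class_fraction = disease_class_fraction,
                 n_background_terms = as.integer(n_background_terms),
                 n_disease_classes = as.integer(n_disease_classes),
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a planted-partition PPI graph
#'
#' Node pairs within a planted module are connected independently with
#' probability `p_in`, pairs across modules with `p_out`. Node identifiers
#' are randomly permuted protein labels, so an identifier encodes nothing
#' about its planted module. Deterministic per seed.
#'
#' @param config A [synth_config()].
#' @return A list with `network` (igraph) and `truth` (a list holding the
#'   planted [module_partition()]).
#' @export
planted_partition_graph <- function(config) {
  set.seed(config$seed)
  sizes <- config$module_sizes
  n <- sum(sizes)
  labels <- rep(seq_along(sizes), sizes)
  ids <- sprintf("P%04d", sample(n))  # shuffled: id order is uninformative
  same <- outer(labels, labels, "==")
  prob <- ifelse(same, config$p_in, config$p_out)
  up <- which(upper.tri(prob), arr.ind = TRUE)
  draw <- runif(nrow(up)) < prob[up]
  edges <- up[draw, , drop = FALSE]
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (nrow(edges)) {
    g <- igraph::add_edges(g, as.vector(t(matrix(ids[edges], ncol = 2))))
  }
  planted <- module_partition(split(ids, labels), method = "planted",
                              n_nodes = n)
  list(network = g, truth = list(planted_partition = planted,
                                 covering_terms = list(),
                                 planted_disease_modules = list()))
}

#' Plant annotation layers over a planted partition
#'
#' A seeded selection of `covering_term_fraction` of the modules each
#' receive one level-3 functional term covering exactly their genes;
#' `n_background_terms` random gene sets are added as noise (sizes uniform
#' between 3 and twice the mean module size). The same covered modules
#' receive a pathway gene set (an exact module copy), every module is copied
#' as a protein complex, and a seeded `disease_class_fraction` of modules
#' receive a planted disease module: a gene subset of >= 3 genes annotated
#' with two raw disease names of one phenotype class (two names, so
#' disease-disease edges exist).
#'
#' @param truth Truth object from [planted_partition_graph()].
#' @param config The same [synth_config()].
#' @return A list with `functions`, `pathways`, `complexes`
#'   ([annotation_set()]s), `gene_diseases` (named list), `class_map`
#'   ([disease_class_map()]) and the updated `truth` (fields
#'   `covering_terms`, `planted_disease_modules`).
#' @export
plant_annotations <- function(truth, config) {
  set.seed(config$seed + 1L)
  part <- truth$planted_partition
  mods <- part$modules
  k <- length(mods)
  genes_all <- unlist(mods, use.names = FALSE)
  covered <- sort(sample(names(mods), round(config$covering_term_fraction * k)))
  diseased <- sort(sample(names(mods), round(config$disease_class_fraction * k)))

  func <- list()
  for (mid in covered) {
    func[[paste0("TERM_COV_", mid)]] <- list(
      name = paste("covering term for module", mid), namespace = "BP",
      level = 3L, genes = mods[[mid]])
  }
  max_bg <- max(3L, as.integer(2 * mean(lengths(mods))))
  for (i in seq_len(config$n_background_terms)) {
    sz <- sample(3:max_bg, 1)
    func[[sprintf("TERM_BG_%03d", i)]] <- list(
      name = sprintf("background term %d", i), namespace = "BP", level = 3L,
      genes = sample(genes_all, min(sz, length(genes_all))))
  }

  paths <- list()
  for (mid in covered) {
    paths[[paste0("PW_", mid)]] <- list(
      name = paste("planted pathway for module", mid), namespace = "pathway",
      level = NULL, genes = mods[[mid]])
  }
  cplx <- list()
  for (mid in names(mods)) {
    cplx[[paste0("CPX_", mid)]] <- list(
      name = paste("planted complex for module", mid), namespace = "complex",
      level = NULL, genes = mods[[mid]])
  }

  classes <- disease_classes_default()
  classes <- classes[((seq_len(config$n_disease_classes) - 1L) %%
                        length(classes)) + 1L]
  gene_diseases <- list()
  assignments <- character(0)
  planted_dm <- list()
  diseased <- diseased[lengths(mods[diseased]) >= 3]  # need a >=3-gene subset
  for (i in seq_along(diseased)) {
    mid <- diseased[i]
    cl <- classes[((i - 1L) %% length(classes)) + 1L]
    size <- if (length(mods[[mid]]) == 3) 3L else
      sample(3:length(mods[[mid]]), 1)
    sub <- sort(sample(mods[[mid]], size))
    d_names <- paste0(cl, "_disease_", mid, c("a", "b"))
    assignments[d_names] <- cl
    for (g in sub) {
      gene_diseases[[g]] <- union(gene_diseases[[g]], d_names)
    }
    planted_dm[[mid]] <- list(class = cl, genes = sub)
  }

  truth$covering_terms <- stats::setNames(as.list(paste0("TERM_COV_", covered)),
                                          covered)
  truth$planted_disease_modules <- planted_dm
  list(functions = annotation_set(func),
       pathways = annotation_set(paths),
       complexes = annotation_set(cplx),
       gene_diseases = gene_diseases,
       class_map = disease_class_map(assignments),
       truth = truth)
}

#' Generate a complete synthetic study
#'
#' Runs [planted_partition_graph()] and [plant_annotations()] and, when
#' `dir` is given, writes every input the pipeline consumes: a scored
#' interaction TSV (confidence 0.9, two synthetic source databases, direct
#' physical type, so the default filters keep every edge), an edge-list TSV,
#' gene-term + term-metadata TSVs for the functional layer, a pathway GMT, a
#' complex GMT, gene-disease and class-map TSVs, and a truth JSON.
#'
#' @param config A [synth_config()].
#' @param dir Output directory, or `NULL` to skip writing.
#' @return A list with `network`, `truth`, the annotation layers of
#'   [plant_annotations()], and (when written) `paths`.
#' @export
generate_synthetic_study <- function(config = synth_config(), dir = NULL) {
  pg <- planted_partition_graph(config)
  layers <- plant_annotations(pg$truth, config)
  out <- c(list(network = pg$network), layers)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    p <- list(
      interactions = file.path(dir, "interactions.tsv"),
      edgelist = file.path(dir, "network.tsv"),
      gene_term = file.path(dir, "gene_term.tsv"),
      term_meta = file.path(dir, "term_metadata.tsv"),
      pathways = file.path(dir, "pathways.gmt"),
      complexes = file.path(dir, "complexes.gmt"),
      gene_disease = file.path(dir, "gene_disease.tsv"),
      class_map = file.path(dir, "disease_classes.tsv"),
      truth = file.path(dir, "truth.json"))
    el <- igraph::as_edgelist(pg$network, names = TRUE)
    swap <- el[, 1] > el[, 2]
    el[swap, ] <- el[swap, c(2, 1), drop = FALSE]
    el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
    inter <- data.frame(protein_a = el[, 1], protein_b = el[, 2],
                        score = 0.9, sources = "synthDB1;synthDB2",
                        type = "direct physical", stringsAsFactors = FALSE)
    write.table(inter, p$interactions, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write_network_edgelist(pg$network, p$edgelist)
    write_annotation_tsv(layers$functions, p$gene_term, p$term_meta)
    write_gmt(layers$pathways, p$pathways)
    write_gmt(layers$complexes, p$complexes)
    write_gene_diseases(layers$gene_diseases, p$gene_disease)
    write_disease_class_map(layers$class_map, p$class_map)
    truth_json <- list(
      modules = lapply(layers$truth$planted_partition$modules, sort),
      covering_terms = layers$truth$covering_terms,
      planted_disease_modules = layers$truth$planted_disease_modules,
      config = unclass(config))
    jsonlite::write_json(truth_json, p$truth, auto_unbox = TRUE, pretty = TRUE)
    out$paths <- p
  }
  out
}
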