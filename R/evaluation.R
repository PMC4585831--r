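#' Run enrichment and layer calling over every large module
#'
#' For each large module of a partition this runs the functional and pathway
#' over-representation tests and the disease/complex counting rules, yielding
#' the per-module layer calls consumed by [classify_all_modules()],
#' [mapping_frequency()] and [average_mapping_frequency()].
#'
#' @param partition A [module_partition()].
#' @param functional_annotations [annotation_set()] of GO-style terms
#'   (already level-filtered), or `NULL` to skip the layer.
#' @param pathway_annotations [annotation_set()] of pathway gene sets, or
#'   `NULL`.
#' @param gene_diseases Named list gene -> disease names, or `NULL`.
#' @param class_map A [disease_class_map()] (required with `gene_diseases`).
#' @param complex_annotations [annotation_set()] of complexes, or `NULL`.
#' @param background Background gene set for the enrichment tests; defaults
#'   to all annotated proteins appearing in the partition's network nodes.
#' @param alpha Adjusted-p significance threshold (default 0.05).
#' @param min_size Large-module threshold (default 3).
#' @param coverage Coverage rule for the fully-covered flag
#'   (see [call_functional_modules()]).
#' @return A named list keyed by module id; each element has components
#'   `functional`, `pathway`, `disease`, `complex` (lists of
#'   [layer_module()]s) and `fully_covered` (logical).
#' @export
call_layers <- function(partition, functional_annotations = NULL,
                        pathway_annotations = NULL, gene_diseases = NULL,
                        class_map = NULL, complex_annotations = NULL,
                        background = NULL, alpha = 0.05, min_size = 3L,
                        coverage = "single") {
  large <- large_modules(partition, min_size = min_size)
  all_nodes <- unlist(partition$modules, use.names = FALSE)
  func_bg <- if (!is.null(functional_annotations)) {
    background %||% intersect(all_nodes, annotated_genes(functional_annotations))
  }
  path_bg <- if (!is.null(pathway_annotations)) {
    background %||% intersect(all_nodes, annotated_genes(pathway_annotations))
  }
  out <- list()
  for (mid in names(large)) {
    genes <- large[[mid]]
    func_enr <- if (!is.null(functional_annotations) && length(func_bg)) {
      enrich_module(genes, functional_annotations, func_bg, alpha = alpha)
    } else empty_enrichment()
    path_enr <- if (!is.null(pathway_annotations) && length(path_bg)) {
      enrich_module(genes, pathway_annotations, path_bg, alpha = alpha)
    } else empty_enrichment()
    functional <- call_functional_modules(genes, func_enr, mid,
                                          coverage = coverage)
    pathway <- call_pathway_modules(genes, path_enr, mid)
    disease <- if (!is.null(gene_diseases)) {
      call_disease_modules(genes, gene_diseases, class_map, mid)
    } else list()
    cplx <- if (!is.null(complex_annotations)) {
      call_complex_modules(genes, complex_annotations, mid)
    } else list()
    out[[mid]] <- list(functional = functional, pathway = pathway,
                       disease = disease, complex = cplx,
                       fully_covered = isTRUE(attr(functional, "fully_covered")),
                       enrichment = rbind(func_enr, path_enr))
  }
  out
}

#' Mapping frequency of a layer over large modules
#'
#' Fraction of the partition's large modules carrying at least one module of
#' the given layer (`mode = "mapped"`), or flagged fully covered
#' (`mode = "fully_covered"`, functional layer only).
#'
#' @param partition A [module_partition()].
#' @param layer_calls Per-module layer calls from [call_layers()].
#' @param layer One of `"functional"`, `"pathway"`, `"disease"`,
#'   `"complex"`.
#' @param mode `"mapped"` (default) or `"fully_covered"`.
#' @param min_size Large-module threshold (default 3).
#' @return A real number in \[0, 1\].
#' @export
mapping_frequency <- function(partition, layer_calls,
                              layer = c("functional", "pathway", "disease",
                                        "complex"),
                              mode = c("mapped", "fully_covered"),
                              min_size = 3L) {
  layer <- match.arg(layer)
  mode <- match.arg(mode)
  large <- names(large_modules(partition, min_size = min_size))
  if (length(large) == 0) {
    stop("partition has no large modules", call. = FALSE)
  }
  hit <- vapply(large, function(mid) {
    lc <- layer_calls[[mid]]
    if (is.null(lc)) return(FALSE)
    if (mode == "fully_covered") isTRUE(lc$fully_covered)
    else length(lc[[layer]]) > 0
  }, logical(1))
  mean(hit)
}

#' Average mapping frequency (mapping accuracy) of a layer
#'
#' For each large module, the best coverage by a single layer module —
#' max over its layer modules of |layer genes| / |module proteins|, 0 when
#' unmapped — averaged over all large modules. With
#' `per_layer_module = TRUE` the mean is instead taken over every layer
#' module's coverage.
#'
#' @inheritParams mapping_frequency
#' @param per_layer_module Use the per-layer-module mean variant.
#' @return A real number in \[0, 1\].
#' @export
average_mapping_frequency <- function(partition, layer_calls,
                                      layer = c("functional", "pathway",
                                                "disease", "complex"),
                                      min_size = 3L,
                                      per_layer_module = FALSE) {
  layer <- match.arg(layer)
  large <- large_modules(partition, min_size = min_size)
  if (length(large) == 0) {
    stop("partition has no large modules", call. = FALSE)
  }
  if (per_layer_module) {
    cov <- unlist(lapply(names(large), function(mid) {
      vapply(layer_calls[[mid]][[layer]],
             function(lm) length(lm$genes) / length(large[[mid]]), numeric(1))
    }))
    return(if (length(cov)) mean(cov) else 0)
  }
  per_mod <- vapply(names(large), function(mid) {
    lms <- layer_calls[[mid]][[layer]]
    if (length(lms) == 0) return(0)
    max(vapply(lms, function(lm) length(lm$genes) / length(large[[mid]]),
               numeric(1)))
  }, numeric(1))
  mean(per_mod)
}

#' Build the disease-gene-filtered benchmark network
#'
#' Keeps exactly the interactions with at least one endpoint in the disease
#' gene set, then builds the PPI graph, so every edge of the benchmark
#' network touches a disease gene.
#'
#' @param records Interaction records.
#' @param disease_genes Non-empty character vector of disease gene
#'   identifiers.
#' @return An igraph object.
#' @export
build_benchmark_network <- function(records, disease_genes) {
  if (length(disease_genes) == 0) {
    stop("disease gene set is empty", call. = FALSE)
  }
  keep <- records$protein_a %in% disease_genes |
    records$protein_b %in% disease_genes
  g <- build_network(records[keep, , drop = FALSE])
  if (igraph::vcount(g) == 0) {
    stop("benchmark network is empty: no interaction touches a disease gene",
         call. = FALSE)
  }
  g
}

#' Whether a module carries an overlapping disease-complex pair
#'
#' A module counts as a disease-complex module when some disease module and
#' some complex module within it overlap on more than `threshold` of the
#' disease module's genes (mirroring the non-trivial rule).
#'
#' @param layer_call One element of [call_layers()] output.
#' @param threshold Strict overlap threshold (default 0.5).
#' @return Logical.
#' @export
has_disease_complex_module <- function(layer_call, threshold = 0.5) {
  for (d in layer_call$disease) {
    for (cx in layer_call$complex) {
      if (overlap_fraction(d, cx) > threshold) return(TRUE)
    }
  }
  FALSE
}

#' Compare module detectors on one network
#'
#' Runs each configured detector, the full layer-calling and classification
#' pipeline, and summarizes every method with Newman modularity, module
#' counts, per-layer mapping frequencies and average mapping frequencies,
#' and classified-module counts. A failing detector is skipped with a
#' warning and the remaining methods still run.
#'
#' @param network An igraph PPI network.
#' @param methods A list of detector configs, each a list with `method`
#'   (`"default"`, `"mcl"`, `"rwr"`) and optional `params`.
#' @param annotation_layers A list with any of `functional`, `pathway`,
#'   `complex` ([annotation_set()]s), `gene_diseases`, `class_map`.
#' @param seed Integer seed shared by all methods.
#' @param alpha,threshold Enrichment and overlap thresholds.
#' @return A data.frame, one row per method, with columns `method`, `Q`,
#'   `n_modules_large`, `mapped_functional`, `mapped_pathway`,
#'   `mapped_disease`, `mapped_complex`, `fully_covered`,
#'   `avg_functional`, `avg_pathway`, `avg_disease`, `avg_complex`,
#'   `n_non_trivial`, `n_significant`, `n_disease_complex`.
#' @export
compare_methods <- function(network,
                            methods = list(list(method = "default"),
                                           list(method = "mcl"),
                                           list(method = "rwr")),
                            annotation_layers = list(), seed = 1L,
                            alpha = 0.05, threshold = 0.5) {
  al <- annotation_layers
  if (is.null(al$class_map) && !is.null(al$gene_diseases)) {
    stop("gene_diseases given without a class_map", call. = FALSE)
  }
  rows <- list()
  for (cfg in methods) {
    method <- cfg$method
    params <- cfg$params %||% list()
    if (method == "rwr" && is.null(params$seeds) &&
        !is.null(al$gene_diseases)) {
      params$seeds <- intersect(igraph::V(network)$name,
                                names(al$gene_diseases))
    }
    rep_row <- tryCatch({
      part <- detect_modules(network, method = method, params = params,
                             seed = seed)
      evaluate_partition(network, part, annotation_layers = al,
                         alpha = alpha, threshold = threshold)
    }, error = function(e) {
      warning("detector '", method, "' failed: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (!is.null(rep_row)) rows[[length(rows) + 1L]] <- rep_row
  }
  do.call(rbind, rows)
}

#' Evaluate one partition against the annotation layers
#'
#' @param network The source igraph network.
#' @param partition A [module_partition()].
#' @param annotation_layers As in [compare_methods()].
#' @param alpha,threshold Enrichment and overlap thresholds.
#' @return A one-row data.frame (see [compare_methods()]).
#' @export
evaluate_partition <- function(network, partition, annotation_layers = list(),
                               alpha = 0.05, threshold = 0.5) {
  al <- annotation_layers
  lc <- call_layers(partition,
                    functional_annotations = al$functional,
                    pathway_annotations = al$pathway,
                    gene_diseases = al$gene_diseases,
                    class_map = al$class_map,
                    complex_annotations = al$complex,
                    alpha = alpha)
  cls <- classify_all_modules(lc, threshold = threshold)
  freq <- function(layer, mode = "mapped") {
    if (length(lc) == 0) return(NA_real_)
    mapping_frequency(partition, lc, layer, mode = mode)
  }
  avg <- function(layer) {
    if (length(lc) == 0) return(NA_real_)
    average_mapping_frequency(partition, lc, layer)
  }
  data.frame(
    method = partition$method,
    Q = modularity_q(network, partition),
    n_modules_large = length(large_modules(partition)),
    mapped_functional = freq("functional"),
    mapped_pathway = freq("pathway"),
    mapped_disease = freq("disease"),
    mapped_complex = freq("complex"),
    fully_covered = freq("functional", mode = "fully_covered"),
    avg_functional = avg("functional"),
    avg_pathway = avg("pathway"),
    avg_disease = avg("disease"),
    avg_complex = avg("complex"),
    n_non_trivial = sum(cls$non_trivial),
    n_significant = sum(cls$significant),
    n_disease_complex = sum(vapply(lc, has_disease_complex_module,
                                   logical(1))),
    stringsAsFactors = FALSE)
}
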