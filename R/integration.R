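#' Overlap fraction between a disease module and another layer module
#'
#' Fraction of the disease module's genes also present in the other module:
#' |D intersect O| / |D| (the disease module's size is the denominator). With
#' `denominator = "min"` the smaller module's size is used instead.
#'
#' @param disease_module,other [layer_module()]s sharing a parent.
#' @param denominator `"disease"` (default) or `"min"`.
#' @return A real number in \[0, 1\]; 1 iff the disease module is a subset
#'   of the other module (under the default denominator).
#' @export
overlap_fraction <- function(disease_module, other,
                             denominator = c("disease", "min")) {
  denominator <- match.arg(denominator)
  d <- disease_module$genes
  o <- other$genes
  if (length(d) == 0) stop("empty disease module", call. = FALSE)
  den <- if (denominator == "disease") length(d) else min(length(d), length(o))
  length(intersect(d, o)) / den
}

#' Classify one topological module from its layer calls
#'
#' A module is *non-trivial* when some disease module overlaps some
#' functional module on more than `threshold` of the disease module's
#' proteins (strictly more than half by default), and *significant* when the
#' same holds against a pathway module. Mapped/fully-covered flags summarize
#' the layer calls.
#'
#' @param parent_module_id Identifier of the module being classified.
#' @param functional List of functional [layer_module()]s (as returned by
#'   [call_functional_modules()], whose `fully_covered` attribute is read if
#'   present).
#' @param pathway,disease Lists of pathway / disease [layer_module()]s.
#' @param threshold Strict overlap threshold (default 0.5).
#' @param fully_covered Override for the fully-covered flag; defaults to the
#'   attribute on `functional`.
#' @param denominator Passed to [overlap_fraction()].
#' @return A one-row data.frame with columns `module_id`,
#'   `mapped_functional`, `fully_covered`, `mapped_pathway`,
#'   `mapped_disease`, `non_trivial`, `significant`.
#' @export
classify_module <- function(parent_module_id, functional = list(),
                            pathway = list(), disease = list(),
                            threshold = 0.5, fully_covered = NULL,
                            denominator = "disease") {
  if (is.null(fully_covered)) {
    fully_covered <- isTRUE(attr(functional, "fully_covered"))
  }
  over <- function(targets) {
    for (d in disease) {
      for (t in targets) {
        if (overlap_fraction(d, t, denominator = denominator) > threshold) {
          return(TRUE)
        }
      }
    }
    FALSE
  }
  data.frame(module_id = as.character(parent_module_id),
             mapped_functional = length(functional) > 0,
             fully_covered = fully_covered,
             mapped_pathway = length(pathway) > 0,
             mapped_disease = length(disease) > 0,
             non_trivial = length(disease) > 0 && over(functional),
             significant = length(disease) > 0 && over(pathway),
             stringsAsFactors = FALSE)
}

#' Build a disease-disease network from in-scope genes
#'
#' Nodes are the raw disease names hit by at least one in-scope gene; two
#' diseases are linked when they share at least one in-scope disease gene.
#' The shared genes are recorded on each edge.
#'
#' @param genes_in_scope Character vector of gene identifiers (one module's
#'   genes, or the whole network's).
#' @param gene_diseases Named list: gene -> character vector of disease
#'   names.
#' @return An undirected igraph object whose edges carry a `shared_genes`
#'   attribute (comma-joined gene identifiers).
#' @export
build_disease_disease_network <- function(genes_in_scope, gene_diseases) {
  present <- intersect(genes_in_scope, names(gene_diseases))
  pair_genes <- list()
  diseases <- character(0)
  for (g in present) {
    ds <- sort(unique(gene_diseases[[g]]))
    diseases <- union(diseases, ds)
    if (length(ds) >= 2) {
      pr <- utils::combn(ds, 2)
      for (j in seq_len(ncol(pr))) {
        key <- paste(pr[1, j], pr[2, j], sep = "\r")
        pair_genes[[key]] <- c(pair_genes[[key]], g)
      }
    }
  }
  g <- igraph::make_empty_graph(0, directed = FALSE)
  g <- igraph::add_vertices(g, length(diseases), name = sort(diseases))
  if (length(pair_genes)) {
    keys <- sort(names(pair_genes))
    ends <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
    g <- igraph::add_edges(g, as.vector(t(ends)),
                           shared_genes = unname(vapply(pair_genes[keys],
                             function(x) paste(sort(unique(x)), collapse = ","),
                             character(1))))
  }
  g
}

#' Build a bipartite protein-term network from layer modules
#'
#' One side holds the proteins, the other the supporting terms (or disease
#' classes); every gene of a layer module is linked to that module's term.
#'
#' @param layer_mods A list of [layer_module()]s sharing a parent module.
#' @return An undirected bipartite igraph object; vertex attribute `type` is
#'   `FALSE` for proteins, `TRUE` for terms.
#' @export
build_bipartite_layer_network <- function(layer_mods) {
  edges <- do.call(rbind, lapply(layer_mods, function(lm) {
    cbind(gene = lm$genes, term = as.character(lm$term_id))
  }))
  if (is.null(edges)) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  genes <- sort(unique(edges[, "gene"]))
  terms <- sort(unique(edges[, "term"]))
  g <- igraph::make_empty_graph(0, directed = FALSE)
  g <- igraph::add_vertices(g, length(genes), name = genes, type = FALSE)
  g <- igraph::add_vertices(g, length(terms), name = terms, type = TRUE)
  igraph::add_edges(g, as.vector(t(edges)))
}

#' Classify every large module of a partition
#'
#' Convenience wrapper running [classify_module()] over per-module layer
#' calls (as produced by [call_layers()]).
#'
#' @param layer_calls Named list keyed by module id, each element a list
#'   with components `functional`, `pathway`, `disease` and a
#'   `fully_covered` flag.
#' @param threshold Strict overlap threshold (default 0.5).
#' @return A data.frame with one row per module.
#' @export
classify_all_modules <- function(layer_calls, threshold = 0.5) {
  rows <- lapply(names(layer_calls), function(mid) {
    lc <- layer_calls[[mid]]
    classify_module(mid, functional = lc$functional, pathway = lc$pathway,
                    disease = lc$disease, threshold = threshold,
                    fully_covered = lc$fully_covered)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(module_id = character(0), mapped_functional = logical(0),
                      fully_covered = logical(0), mapped_pathway = logical(0),
                      mapped_disease = logical(0), non_trivial = logical(0),
                      significant = logical(0), stringsAsFactors = FALSE)
  }
  out[order(out$module_id), , drop = FALSE]
}
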