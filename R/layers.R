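#' Layer module constructor
#'
#' A layer module is a called functional, pathway, disease, or complex
#' module: a gene subset (>= 3 genes) of one topological module, with the
#' supporting term (or disease class) and, for enrichment-based layers, the
#' supporting statistics.
#'
#' @param layer One of `"functional"`, `"pathway"`, `"disease"`,
#'   `"complex"`.
#' @param parent_module_id Identifier of the parent topological module.
#' @param genes Character vector of gene identifiers (length >= 3).
#' @param term_id Supporting term identifier or disease-class name.
#' @param support One-row enrichment data.frame, or `NULL` for the
#'   counting-rule layers (disease, complex).
#' @return An object of class `layer_module`.
#' @export
layer_module <- function(layer, parent_module_id, genes, term_id,
                         support = NULL) {
  layer <- match.arg(layer, c("functional", "pathway", "disease", "complex"))
  genes <- sort(unique(as.character(genes)))
  if (length(genes) < 3) {
    stop("a layer module needs at least 3 genes", call. = FALSE)
  }
  structure(list(layer = layer, parent_module_id = as.character(parent_module_id),
                 genes = genes, term_id = term_id, support = support),
            class = "layer_module")
}

#' @export
print.layer_module <- function(x, ...) {
  cat(x$layer, " module [", x$term_id, "] in topological module ",
      x$parent_module_id, ": ", length(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' Call functional modules on one topological module
#'
#' Each significantly enriched term whose hit genes number at least
#' `min_genes` defines a functional module over those genes. The parent is
#' "fully covered" when a single term's hits equal the module's annotated
#' proteins (unannotated proteins are not counted against coverage); since
#' hit genes are always a subset of the annotated module genes, this is
#' equivalent to a row with `k == n`. With `coverage = "union"` the union of
#' all significant terms' hits may cover the module instead.
#'
#' @param module_genes The topological module's proteins.
#' @param enrichments Significance- and level-filtered enrichment data.frame
#'   from [enrich_module()] (functional namespaces).
#' @param parent_module_id Identifier of the parent module.
#' @param min_genes Minimum layer-module size (default 3).
#' @param coverage `"single"` (default) or `"union"` coverage rule.
#' @return A list of [layer_module()]s with attribute `fully_covered`
#'   (logical).
#' @export
call_functional_modules <- function(module_genes, enrichments,
                                    parent_module_id = "1", min_genes = 3L,
                                    coverage = c("single", "union")) {
  coverage <- match.arg(coverage)
  mods <- list()
  for (i in seq_len(nrow(enrichments))) {
    hits <- enrichments$hit_genes[[i]]
    if (length(hits) >= min_genes) {
      mods[[length(mods) + 1L]] <- layer_module(
        "functional", parent_module_id, hits, enrichments$term_id[i],
        support = enrichments[i, , drop = FALSE])
    }
  }
  fully <- if (nrow(enrichments) == 0) {
    FALSE
  } else if (coverage == "single") {
    any(enrichments$k == enrichments$n & enrichments$n > 0)
  } else {
    n <- enrichments$n[1]
    n > 0 && length(unique(unlist(enrichments$hit_genes))) == n
  }
  structure(mods, fully_covered = fully)
}

#' Call pathway modules on one topological module
#'
#' One pathway module per significantly enriched pathway (corrected p below
#' the threshold already applied upstream) with at least `min_genes` hit
#' genes.
#'
#' @inheritParams call_functional_modules
#' @param pathway_enrichments Enrichment data.frame restricted to the
#'   pathway namespace.
#' @return A list of [layer_module()]s.
#' @export
call_pathway_modules <- function(module_genes, pathway_enrichments,
                                 parent_module_id = "1", min_genes = 3L) {
  mods <- list()
  for (i in seq_len(nrow(pathway_enrichments))) {
    hits <- pathway_enrichments$hit_genes[[i]]
    if (length(hits) >= min_genes) {
      mods[[length(mods) + 1L]] <- layer_module(
        "pathway", parent_module_id, hits, pathway_enrichments$term_id[i],
        support = pathway_enrichments[i, , drop = FALSE])
    }
  }
  mods
}

#' Disease class map
#'
#' Maps raw disease names to a fixed vocabulary of phenotype classes. The
#' default vocabulary has 15 classes spanning the major organ systems and
#' disease etiologies.
#'
#' @param assignments Named character vector: disease name -> class name.
#' @param classes Class vocabulary; defaults to [disease_classes_default()].
#' @return An object of class `disease_class_map`.
#' @export
disease_class_map <- function(assignments = character(0),
                              classes = disease_classes_default()) {
  assignments <- stats::setNames(as.character(assignments),
                                 names(assignments))
  bad <- setdiff(unique(assignments), classes)
  if (length(bad)) {
    stop("assignment to unknown class(es): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(classes = classes, assignments = assignments),
            class = "disease_class_map")
}

#' @rdname disease_class_map
#' @export
disease_classes_default <- function() {
  c("Neurological", "Ophthamological", "Cardiovascular", "Bone",
    "Dermatological", "Endocrine", "Metabolic", "Cancer", "Immunological",
    "Psychiatric", "Hematological", "Renal", "Respiratory",
    "Ear-Nose-Throat", "Gastrointestinal")
}

#' Read and write disease inputs
#'
#' Gene-disease associations are a TSV with columns `gene`, `disease_name`
#' and optionally `source`; the class map is a TSV with columns
#' `disease_name`, `class`.
#'
#' @param path File path.
#' @return `read_gene_diseases()` returns a named list mapping gene ->
#'   character vector of disease names; `read_disease_class_map()` returns a
#'   [disease_class_map()].
#' @export
read_gene_diseases <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  lapply(split(df$disease_name, df$gene), unique)
}

#' @rdname read_gene_diseases
#' @param classes Class vocabulary to validate against.
#' @export
read_disease_class_map <- function(path, classes = disease_classes_default()) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  disease_class_map(stats::setNames(df$class, df$disease_name),
                    classes = union(classes, unique(df$class)))
}

#' @rdname read_gene_diseases
#' @param gene_diseases Named list gene -> disease names.
#' @export
write_gene_diseases <- function(gene_diseases, path) {
  rows <- do.call(rbind, lapply(sort(names(gene_diseases)), function(g) {
    data.frame(gene = g, disease_name = sort(gene_diseases[[g]]),
               source = "synthetic", stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    rows <- data.frame(gene = character(0), disease_name = character(0),
                       source = character(0))
  }
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_gene_diseases
#' @param class_map A [disease_class_map()].
#' @export
write_disease_class_map <- function(class_map, path) {
  df <- data.frame(disease_name = names(class_map$assignments),
                   class = unname(class_map$assignments),
                   stringsAsFactors = FALSE)
  df <- df[order(df$disease_name), , drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Call disease modules on one topological module
#'
#' For each disease class, the module's genes carrying at least one disease
#' of that class form a candidate; when more than two genes (>= 3) share the
#' class, they are emitted as a disease module. A gene may belong to several
#' disease modules of one parent. Disease names missing from the class map
#' are skipped with a message.
#'
#' @param module_genes The topological module's proteins.
#' @param gene_diseases Named list: gene -> character vector of disease
#'   names.
#' @param class_map A [disease_class_map()].
#' @param parent_module_id Identifier of the parent module.
#' @param min_genes Minimum disease-module size (default 3, the "more than
#'   two proteins" rule).
#' @return A list of [layer_module()]s, `term_id` = disease class.
#' @export
call_disease_modules <- function(module_genes, gene_diseases, class_map,
                                 parent_module_id = "1", min_genes = 3L) {
  present <- intersect(module_genes, names(gene_diseases))
  unmapped <- character(0)
  class_genes <- list()
  for (g in present) {
    ds <- gene_diseases[[g]]
    known <- ds %in% names(class_map$assignments)
    unmapped <- union(unmapped, ds[!known])
    for (cl in unique(class_map$assignments[ds[known]])) {
      class_genes[[cl]] <- c(class_genes[[cl]], g)
    }
  }
  if (length(unmapped)) {
    message("call_disease_modules: skipped ", length(unmapped),
            " disease name(s) missing from the class map")
  }
  mods <- list()
  for (cl in sort(names(class_genes))) {
    genes <- unique(class_genes[[cl]])
    if (length(genes) >= min_genes) {
      mods[[length(mods) + 1L]] <- layer_module(
        "disease", parent_module_id, genes, cl)
    }
  }
  mods
}

#' Call protein-complex modules on one topological module
#'
#' Same counting rule as disease modules, keyed on complex membership: at
#' least `min_genes` of the module's genes in one annotated complex emit a
#' complex module.
#'
#' @param module_genes The topological module's proteins.
#' @param complex_annotations An [annotation_set()] with namespace
#'   `"complex"`.
#' @param parent_module_id Identifier of the parent module.
#' @param min_genes Minimum complex-module size (default 3).
#' @return A list of [layer_module()]s, `term_id` = complex identifier.
#' @export
call_complex_modules <- function(module_genes, complex_annotations,
                                 parent_module_id = "1", min_genes = 3L) {
  mods <- list()
  for (id in sort(names(complex_annotations$terms))) {
    genes <- intersect(module_genes, complex_annotations$terms[[id]]$genes)
    if (length(genes) >= min_genes) {
      mods[[length(mods) + 1L]] <- layer_module(
        "complex", parent_module_id, genes, id)
    }
  }
  mods
}

#' Flatten layer modules to a data.frame / TSV
#'
#' Columns: `layer`, `parent_module_id`, `term_or_class`, `n_genes`,
#' `genes` (comma-joined), `p_value`, `p_adjusted` (NA for counting-rule
#' layers).
#'
#' @param layer_mods A list of [layer_module()]s (possibly nested lists).
#' @return A data.frame, one row per layer module.
#' @export
layer_modules_df <- function(layer_mods) {
  flat <- list()
  collect <- function(x) {
    if (inherits(x, "layer_module")) flat[[length(flat) + 1L]] <<- x
    else if (is.list(x)) lapply(x, collect)
    invisible(NULL)
  }
  collect(layer_mods)
  if (length(flat) == 0) {
    return(data.frame(layer = character(0), parent_module_id = character(0),
                      term_or_class = character(0), n_genes = integer(0),
                      genes = character(0), p_value = numeric(0),
                      p_adjusted = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(flat, function(lm) {
    data.frame(layer = lm$layer, parent_module_id = lm$parent_module_id,
               term_or_class = as.character(lm$term_id),
               n_genes = length(lm$genes),
               genes = paste(lm$genes, collapse = ","),
               p_value = if (is.null(lm$support)) NA_real_ else lm$support$p_value,
               p_adjusted = if (is.null(lm$support)) NA_real_ else lm$support$p_adjusted,
               stringsAsFactors = FALSE)
  }))
}

#' @rdname layer_modules_df
#' @param path Output/input TSV path.
#' @export
write_layer_modules <- function(layer_mods, path) {
  df <- layer_modules_df(layer_mods)
  df <- df[order(df$parent_module_id, df$layer, df$term_or_class), ,
           drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname layer_modules_df
#' @export
read_layer_modules <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(parent_module_id = "character"))
  out <- list()
  for (i in seq_len(nrow(df))) {
    out[[i]] <- layer_module(df$layer[i], df$parent_module_id[i],
                             strsplit(df$genes[i], ",", fixed = TRUE)[[1]],
                             df$term_or_class[i])
  }
  out
}
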