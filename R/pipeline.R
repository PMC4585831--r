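#' Run configuration for the analysis pipeline
#'
#' Collects input paths and tuning parameters. Defaults follow the study
#' settings: at least two evidence databases, GO-slim level 3, alpha 0.05,
#' MCL inflation 2, restart probability 0.4, overlap threshold 0.5 and a
#' minimum module size of 3. Unknown keys are rejected.
#'
#' @param ... Key = value overrides of the defaults below.
#' @return A list of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    interactions = NULL, network = NULL, partition = NULL,
    gene_term = NULL, term_metadata = NULL, obo = NULL,
    pathways_gmt = NULL, complexes_gmt = NULL,
    gene_disease = NULL, class_map = NULL,
    method = "default", inflation = 2, restart = 0.4,
    min_score = 0.73, min_sources = 2L, required_type = NULL,
    alpha = 0.05, level = 3L, threshold = 0.5, min_module_size = 3L,
    coverage = "single", seed = 1L, outdir = "netmodmap_out")
  over <- list(...)
  if (length(over) == 1 && is.list(over[[1]]) && is.null(names(over))) {
    over <- over[[1]]
  }
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    stop("unknown run_config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, over, keep.null = TRUE)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path Path to a YAML file whose keys are [run_config()] keys.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  run_config(yaml::read_yaml(path))
}

#' Pipeline stage: build the filtered PPI network
#'
#' Reads the interaction table, applies the high-confidence filters, builds
#' the graph and writes `network.tsv` (+ `network.graphml`) under `outdir`.
#'
#' @param config A [run_config()] with `interactions` set (or `network`, in
#'   which case the edge list is used as-is).
#' @return The igraph network, invisibly; path in attribute `"path"`.
#' @export
stage_build_net <- function(config) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(config$interactions)) {
    rec <- read_interactions(config$interactions)
    rec <- filter_high_confidence(rec, min_score = config$min_score,
                                  min_sources = config$min_sources,
                                  required_type = config$required_type)
    net <- build_network(rec)
  } else if (!is.null(config$network)) {
    net <- read_network_edgelist(config$network)
  } else {
    stop("stage build-net: config needs 'interactions' or 'network'",
         call. = FALSE)
  }
  message("build-net: ", igraph::vcount(net), " proteins, ",
          igraph::gsize(net), " interactions")
  path <- file.path(config$outdir, "network.tsv")
  write_network_edgelist(net, path)
  write_network_graphml(net, file.path(config$outdir, "network.graphml"))
  invisible(structure(net, path = path))
}

#' Pipeline stage: detect topological modules
#'
#' Reads `network.tsv` from `outdir` (or `config$network`), runs the
#' configured detector (or loads an injected partition from
#' `config$partition`), and writes `partition.tsv`.
#'
#' @param config A [run_config()].
#' @return The [module_partition()], invisibly.
#' @export
stage_detect <- function(config) {
  net <- pipeline_network(config)
  if (!is.null(config$partition)) {
    part <- read_partition(config$partition)
  } else {
    params <- switch(config$method,
      mcl = list(inflation = config$inflation),
      rwr = {
        p <- list(restart = config$restart)
        if (!is.null(config$gene_disease)) {
          gd <- read_gene_diseases(config$gene_disease)
          seeds <- intersect(igraph::V(net)$name, names(gd))
          if (length(seeds)) p$seeds <- seeds
        }
        p
      },
      list())
    part <- detect_modules(net, method = config$method, params = params,
                           seed = config$seed)
  }
  message("detect (", part$method, "): ",
          length(large_modules(part, config$min_module_size)), " large and ",
          length(small_modules(part, config$min_module_size)),
          " small modules")
  write_partition(part, file.path(config$outdir, "partition.tsv"))
  invisible(part)
}

pipeline_network <- function(config) {
  staged <- file.path(config$outdir, "network.tsv")
  if (file.exists(staged)) return(read_network_edgelist(staged))
  if (!is.null(config$network)) return(read_network_edgelist(config$network))
  stop("no network available: run the build-net stage first or set 'network'",
       call. = FALSE)
}

pipeline_partition <- function(config) {
  staged <- file.path(config$outdir, "partition.tsv")
  if (file.exists(staged)) return(read_partition(staged))
  if (!is.null(config$partition)) return(read_partition(config$partition))
  stop("no partition available: run the detect stage first or set 'partition'",
       call. = FALSE)
}

load_annotation_layers <- function(config) {
  al <- list()
  if (!is.null(config$gene_term)) {
    func <- read_annotation_tsv(config$gene_term, config$term_metadata)
    if (!is.null(config$obo)) {
      func <- set_term_levels(func, obo_term_levels(config$obo))
    }
    al$functional <- filter_terms_by_level(func, config$level)
  }
  if (!is.null(config$pathways_gmt)) {
    al$pathway <- read_gmt(config$pathways_gmt, namespace = "pathway")
  }
  if (!is.null(config$complexes_gmt)) {
    al$complex <- read_gmt(config$complexes_gmt, namespace = "complex")
  }
  if (!is.null(config$gene_disease)) {
    al$gene_diseases <- read_gene_diseases(config$gene_disease)
    if (is.null(config$class_map)) {
      stop("gene_disease input given without a class_map", call. = FALSE)
    }
    al$class_map <- read_disease_class_map(config$class_map)
  }
  al
}

#' Pipeline stage: enrichment and layer calling
#'
#' Loads the staged partition and the annotation layers, runs
#' [call_layers()] over the large modules, and writes `enrichment.tsv` and
#' `layer_modules.tsv` plus a per-module `module_summary.tsv` holding the
#' fully-covered flags.
#'
#' @param config A [run_config()].
#' @return The per-module layer calls, invisibly.
#' @export
stage_call_layers <- function(config) {
  part <- pipeline_partition(config)
  al <- load_annotation_layers(config)
  lc <- call_layers(part,
                    functional_annotations = al$functional,
                    pathway_annotations = al$pathway,
                    gene_diseases = al$gene_diseases,
                    class_map = al$class_map,
                    complex_annotations = al$complex,
                    alpha = config$alpha,
                    min_size = config$min_module_size,
                    coverage = config$coverage)
  enr <- lapply(lc, function(x) x$enrichment)
  write_enrichment(enr, file.path(config$outdir, "enrichment.tsv"))
  all_mods <- lapply(lc, function(x) c(x$functional, x$pathway, x$disease,
                                       x$complex))
  write_layer_modules(all_mods, file.path(config$outdir, "layer_modules.tsv"))
  summ <- data.frame(module_id = names(lc),
                     n_proteins = lengths(large_modules(part,
                                                        config$min_module_size))[names(lc)],
                     fully_covered = vapply(lc, `[[`, logical(1),
                                            "fully_covered"),
                     stringsAsFactors = FALSE)
  summ <- summ[order(summ$module_id), , drop = FALSE]
  write.table(summ, file.path(config$outdir, "module_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  n_layer <- vapply(c("functional", "pathway", "disease", "complex"),
                    function(l) sum(vapply(lc, function(x) length(x[[l]]),
                                           integer(1))), integer(1))
  message("call-layers: ", paste(names(n_layer), n_layer, sep = "=",
                                 collapse = ", "))
  invisible(lc)
}

#' Pipeline stage: classification and cross-layer networks
#'
#' Classifies every large module as non-trivial/significant and writes
#' `classification.tsv` and the global disease-disease network GraphML.
#'
#' @param config A [run_config()].
#' @param layer_calls Layer calls from [stage_call_layers()]; recomputed
#'   from the staged files when missing.
#' @return The classification data.frame, invisibly.
#' @export
stage_integrate <- function(config, layer_calls = NULL) {
  if (is.null(layer_calls)) layer_calls <- stage_call_layers(config)
  cls <- classify_all_modules(layer_calls, threshold = config$threshold)
  write.table(cls, file.path(config$outdir, "classification.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(config$gene_disease)) {
    gd <- read_gene_diseases(config$gene_disease)
    part <- pipeline_partition(config)
    dd <- build_disease_disease_network(
      unlist(part$modules, use.names = FALSE), gd)
    write_network_graphml(dd, file.path(config$outdir,
                                        "disease_disease.graphml"))
  }
  message("integrate: ", sum(cls$non_trivial), " non-trivial, ",
          sum(cls$significant), " significant of ", nrow(cls),
          " large modules")
  invisible(cls)
}

#' Pipeline stage: evaluation report
#'
#' Computes modularity, mapping frequencies and classification counts for
#' the staged partition and writes `report.tsv` and `report.json`.
#'
#' @param config A [run_config()].
#' @return The one-row report data.frame, invisibly.
#' @export
stage_evaluate <- function(config) {
  net <- pipeline_network(config)
  part <- pipeline_partition(config)
  al <- load_annotation_layers(config)
  rep <- evaluate_partition(net, part, annotation_layers = al,
                            alpha = config$alpha,
                            threshold = config$threshold)
  write.table(rep, file.path(config$outdir, "report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(as.list(rep), file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(rep)
}

#' Run the full analysis pipeline
#'
#' Executes build-net, detect, call-layers, integrate and evaluate in order,
#' writing every artifact plus a `manifest.json` recording inputs,
#' parameters and seed (no timestamps, so identical config + seed runs are
#' byte-identical).
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the network, partition, layer calls,
#'   classification and evaluation report.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  net <- stage_build_net(config)
  part <- stage_detect(config)
  lc <- stage_call_layers(config)
  cls <- stage_integrate(config, layer_calls = lc)
  rep <- stage_evaluate(config)
  manifest <- unclass(config)
  manifest$outdir <- NULL  # keep runs relocatable and byte-comparable
  manifest$package_version <- as.character(utils::packageVersion("netmodmap"))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(list(network = net, partition = part, layer_calls = lc,
                 classification = cls, report = rep))
}
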