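#' Annotation set: term -> gene set with metadata
#'
#' An `annotation_set` maps term identifiers to gene sets with the term's
#' name, namespace (one of `BP`, `CC`, `MF`, `pathway`, `disease`,
#' `complex`) and optional ontology level (depth below the namespace root,
#' root = level 1).
#'
#' @param terms A named list; each element a list with fields `name`,
#'   `namespace`, `level` (integer or `NULL`) and `genes` (non-empty
#'   character vector).
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(terms = list()) {
  for (id in names(terms)) {
    t <- terms[[id]]
    if (length(t$genes) == 0) {
      stop("term ", id, " has an empty gene set", call. = FALSE)
    }
    if (!is.null(t$level) && t$level < 1) {
      stop("term ", id, " has level < 1", call. = FALSE)
    }
    terms[[id]]$genes <- unique(as.character(t$genes))
  }
  structure(list(terms = terms), class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  ns <- vapply(x$terms, function(t) t$namespace, character(1))
  cat("annotation_set: ", length(x$terms), " terms (",
      paste(sprintf("%s=%d", names(table(ns)), table(ns)), collapse = ", "),
      "); ", length(annotated_genes(x)), " genes\n", sep = "")
  invisible(x)
}

#' All genes carrying at least one annotation
#'
#' @param annotations An [annotation_set()].
#' @return Character vector of gene identifiers.
#' @export
annotated_genes <- function(annotations) {
  unique(unlist(lapply(annotations$terms, function(t) t$genes),
                use.names = FALSE))
}

#' Read gene sets in GMT format
#'
#' One term per line: `term_id<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path Path to the GMT file.
#' @param namespace Namespace to assign to all terms (default `"pathway"`).
#' @return An [annotation_set()].
#' @export
read_gmt <- function(path, namespace = "pathway") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  terms <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) next
    terms[[f[1]]] <- list(name = f[2], namespace = namespace, level = NULL,
                          genes = f[-(1:2)])
  }
  annotation_set(terms)
}

#' Write gene sets in GMT format
#'
#' @param annotations An [annotation_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(annotations, path) {
  ids <- sort(names(annotations$terms))
  lines <- vapply(ids, function(id) {
    t <- annotations$terms[[id]]
    paste(c(id, t$name, sort(t$genes)), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene-term annotations from flat TSV files
#'
#' `gene_term_path` is a two-column TSV (`gene`, `term`). Term metadata
#' (name, namespace, level) may be supplied in a second TSV with columns
#' `term`, `name`, `namespace`, `level`; terms without metadata default to
#' namespace `default_namespace` with no level.
#'
#' @param gene_term_path Path to the gene-term TSV.
#' @param metadata_path Optional path to the term-metadata TSV.
#' @param default_namespace Namespace for terms lacking metadata.
#' @return An [annotation_set()].
#' @export
read_annotation_tsv <- function(gene_term_path, metadata_path = NULL,
                                default_namespace = "BP") {
  gt <- read.delim(gene_term_path, stringsAsFactors = FALSE)
  meta <- if (!is.null(metadata_path)) {
    read.delim(metadata_path, stringsAsFactors = FALSE)
  }
  terms <- lapply(split(gt[[1]], gt[[2]]), unique)
  out <- list()
  for (id in names(terms)) {
    name <- id
    namespace <- default_namespace
    level <- NULL
    if (!is.null(meta) && id %in% meta$term) {
      row <- meta[match(id, meta$term), ]
      if (!is.na(row$name)) name <- row$name
      if (!is.na(row$namespace)) namespace <- row$namespace
      if (!is.null(row$level) && !is.na(row$level)) {
        level <- as.integer(row$level)
      }
    }
    out[[id]] <- list(name = name, namespace = namespace, level = level,
                      genes = terms[[id]])
  }
  annotation_set(out)
}

#' Write an annotation set as gene-term + term-metadata TSVs
#'
#' @param annotations An [annotation_set()].
#' @param gene_term_path,metadata_path Output paths.
#' @return `gene_term_path`, invisibly.
#' @export
write_annotation_tsv <- function(annotations, gene_term_path, metadata_path) {
  ids <- sort(names(annotations$terms))
  gt <- do.call(rbind, lapply(ids, function(id) {
    data.frame(gene = sort(annotations$terms[[id]]$genes), term = id,
               stringsAsFactors = FALSE)
  }))
  write.table(gt, gene_term_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  meta <- do.call(rbind, lapply(ids, function(id) {
    t <- annotations$terms[[id]]
    data.frame(term = id, name = t$name, namespace = t$namespace,
               level = if (is.null(t$level)) NA_integer_ else t$level,
               stringsAsFactors = FALSE)
  }))
  write.table(meta, metadata_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(gene_term_path)
}

#' Compute ontology term levels from an OBO v1.2 file
#'
#' Parses `[Term]` stanzas (`id`, `name`, `namespace`, `is_a`) and defines a
#' term's level as 1 plus the length of the shortest `is_a` path to its
#' namespace root (a term with no `is_a` parent), so roots are level 1.
#' Obsolete terms are skipped.
#'
#' @param path Path to an OBO v1.2 file.
#' @return A data.frame with columns `term`, `name`, `namespace`, `level`.
#' @export
obo_term_levels <- function(path) {
  lines <- readLines(path, warn = FALSE)
  terms <- list()
  cur <- NULL
  in_term <- FALSE
  flush <- function(cur, terms) {
    if (!is.null(cur) && !isTRUE(cur$obsolete) && !is.null(cur$id)) {
      terms[[cur$id]] <- cur
    }
    terms
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") {
      terms <- flush(cur, terms)
      cur <- list(parents = character(0))
      in_term <- TRUE
    } else if (grepl("^\\[", ln)) {
      terms <- flush(cur, terms)
      cur <- NULL
      in_term <- FALSE
    } else if (in_term && nzchar(ln)) {
      if (startsWith(ln, "id: ")) cur$id <- sub("^id: ", "", ln)
      else if (startsWith(ln, "name: ")) cur$name <- sub("^name: ", "", ln)
      else if (startsWith(ln, "namespace: ")) {
        cur$namespace <- sub("^namespace: ", "", ln)
      } else if (startsWith(ln, "is_a: ")) {
        p <- sub("^is_a: ", "", ln)
        p <- trimws(sub("!.*$", "", p))
        cur$parents <- c(cur$parents, p)
      } else if (ln == "is_obsolete: true") cur$obsolete <- TRUE
    }
  }
  terms <- flush(cur, terms)
  ids <- names(terms)
  level <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  roots <- ids[vapply(terms, function(t) length(t$parents) == 0, logical(1))]
  level[roots] <- 1L
  # shortest-path relaxation over is_a edges; converges in <= depth sweeps
  repeat {
    changed <- FALSE
    for (id in ids) {
      pl <- level[intersect(terms[[id]]$parents, ids)]
      if (length(pl) && any(!is.na(pl))) {
        cand <- min(pl, na.rm = TRUE) + 1L
        if (is.na(level[id]) || cand < level[id]) {
          level[id] <- cand
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  data.frame(term = ids,
             name = vapply(terms, function(t) t$name %||% t$id, character(1)),
             namespace = vapply(terms, function(t) t$namespace %||% NA_character_,
                                character(1)),
             level = unname(level),
             stringsAsFactors = FALSE, row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Attach ontology levels to an annotation set
#'
#' @param annotations An [annotation_set()].
#' @param levels_df A data.frame from [obo_term_levels()] (or with columns
#'   `term` and `level`).
#' @return The annotation set with `level` (and, when available, `name`,
#'   `namespace`) filled in for matching terms.
#' @export
set_term_levels <- function(annotations, levels_df) {
  for (id in names(annotations$terms)) {
    i <- match(id, levels_df$term)
    if (!is.na(i)) {
      if (!is.na(levels_df$level[i])) {
        annotations$terms[[id]]$level <- as.integer(levels_df$level[i])
      }
      if ("namespace" %in% names(levels_df) && !is.na(levels_df$namespace[i])) {
        annotations$terms[[id]]$namespace <- levels_df$namespace[i]
      }
      if ("name" %in% names(levels_df) && !is.na(levels_df$name[i])) {
        annotations$terms[[id]]$name <- levels_df$name[i]
      }
    }
  }
  annotations
}

#' Keep only terms at a given ontology level
#'
#' Terms whose level is missing are dropped with a message, mirroring the
#' GO-slim practice of testing a single coherent depth.
#'
#' @param annotations An [annotation_set()].
#' @param level Integer level to keep (>= 1); default 3.
#' @return A filtered [annotation_set()].
#' @export
filter_terms_by_level <- function(annotations, level = 3L) {
  stopifnot(level >= 1)
  lv <- lapply(annotations$terms, function(t) t$level)
  no_level <- vapply(lv, is.null, logical(1))
  if (any(no_level)) {
    message("filter_terms_by_level: dropped ", sum(no_level),
            " term(s) with no level metadata")
  }
  keep <- !no_level & vapply(lv, function(x) isTRUE(x == level), logical(1))
  annotation_set(annotations$terms[keep])
}
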