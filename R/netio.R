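#' Column mapping for interaction tables
#'
#' Interaction tables from different sources name their columns differently; a
#' dialect maps the table's column names onto the fields the package needs.
#'
#' @param protein_a,protein_b Names of the columns holding the two interactor
#'   identifiers.
#' @param score Name of the column holding the normalized confidence score in
#'   \[0, 1\].
#' @param sources Name of the column listing the evidence databases,
#'   delimiter-separated.
#' @param source_delimiter Delimiter between database names in the sources
#'   column.
#' @param type Name of the column holding the interaction type (e.g.
#'   `"direct physical"`), or `NULL` if the table has none.
#' @return A list of class `interaction_dialect`.
#' @export
#' @examples
#' interaction_dialect(protein_a = "geneA", protein_b = "geneB")
interaction_dialect <- function(protein_a = "protein_a",
                                protein_b = "protein_b",
                                score = "score",
                                sources = "sources",
                                source_delimiter = ";",
                                type = NULL) {
  structure(list(protein_a = protein_a, protein_b = protein_b,
                 score = score, sources = sources,
                 source_delimiter = source_delimiter, type = type),
            class = "interaction_dialect")
}

#' Read a scored protein interaction table
#'
#' Reads a TSV of protein-protein interactions with a header row. Each data
#' row becomes one interaction record; rows in which either protein identifier
#' is missing or empty are dropped and counted in a message.
#'
#' @param path Path to the TSV file.
#' @param dialect An [interaction_dialect()] mapping the file's columns.
#' @return A data.frame with columns `protein_a`, `protein_b`, `confidence`,
#'   `sources` (a list column of character vectors) and `interaction_type`
#'   (`NA` when the dialect declares no type column). The number of dropped
#'   rows is attached as attribute `"n_dropped"`.
#' @export
read_interactions <- function(path, dialect = interaction_dialect()) {
  if (!file.exists(path)) {
    stop("interaction file not found: ", path, call. = FALSE)
  }
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  needed <- c(dialect$protein_a, dialect$protein_b, dialect$score,
              dialect$sources, dialect$type)
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols)) {
    stop("dialect column(s) not present in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  a <- trimws(as.character(tab[[dialect$protein_a]]))
  b <- trimws(as.character(tab[[dialect$protein_b]]))
  keep <- !is.na(a) & !is.na(b) & nzchar(a) & nzchar(b)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message("read_interactions: dropped ", n_dropped,
            " row(s) with missing protein identifiers")
  }
  src_raw <- as.character(tab[[dialect$sources]])[keep]
  sources <- lapply(strsplit(src_raw, dialect$source_delimiter, fixed = TRUE),
                    function(s) unique(trimws(s[nzchar(trimws(s))])))
  type <- if (is.null(dialect$type)) {
    rep(NA_character_, sum(keep))
  } else {
    trimws(as.character(tab[[dialect$type]])[keep])
  }
  rec <- data.frame(protein_a = a[keep], protein_b = b[keep],
                    confidence = as.numeric(tab[[dialect$score]])[keep],
                    interaction_type = type,
                    stringsAsFactors = FALSE)
  rec$sources <- sources
  structure(rec, n_dropped = n_dropped)
}

#' Keep high-confidence, multiply-reported interactions
#'
#' Applies the evidence filter used to build the analysis network: an
#' interaction is retained only if its confidence score reaches `min_score`,
#' it is reported by at least `min_sources` distinct databases, and (when
#' `required_type` is given) its interaction type matches, e.g. restricting to
#' direct physical interactions.
#'
#' @param records Interaction records from [read_interactions()].
#' @param min_score Minimum confidence score; the default 0.73 is a
#'   configurable stand-in for a database's "high-confidence" tier.
#' @param min_sources Minimum number of distinct evidence databases
#'   (default 2).
#' @param required_type Interaction type to require, or `NULL` for no type
#'   filter.
#' @return The subset of `records` passing all predicates.
#' @export
filter_high_confidence <- function(records, min_score = 0.73,
                                   min_sources = 2L, required_type = NULL) {
  stopifnot(min_sources >= 1, min_score >= 0, min_score <= 1)
  keep <- records$confidence >= min_score &
    vapply(records$sources, length, integer(1)) >= min_sources
  if (!is.null(required_type)) {
    keep <- keep & !is.na(records$interaction_type) &
      records$interaction_type == required_type
  }
  out <- records[which(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build an undirected simple PPI graph from interaction records
#'
#' Nodes are proteins and edges are interactions. Self-interactions are
#' dropped (and counted in a message) and duplicate pairs in either order are
#' collapsed, so the result is a simple undirected graph. Proteins appearing
#' only in dropped records are excluded.
#'
#' @param records Interaction records (typically already filtered with
#'   [filter_high_confidence()]).
#' @return An [igraph][igraph::graph] object, undirected and simple.
#' @export
build_network <- function(records) {
  self <- records$protein_a == records$protein_b
  if (any(self)) {
    message("build_network: dropped ", sum(self), " self-interaction(s)")
    records <- records[!self, , drop = FALSE]
  }
  if (nrow(records) == 0) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  g <- igraph::graph_from_data_frame(
    records[, c("protein_a", "protein_b")], directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Write and read a network as an edge-list TSV
#'
#' The edge list has two columns, `protein_a` and `protein_b`, one row per
#' undirected edge with endpoints in sorted order so output is reproducible.
#'
#' @param network An undirected igraph object.
#' @param path Output/input file path.
#' @return `write_network_edgelist()` returns `path` invisibly;
#'   `read_network_edgelist()` returns an igraph object.
#' @export
write_network_edgelist <- function(network, path) {
  el <- igraph::as_edgelist(network, names = TRUE)
  if (nrow(el)) {
    swap <- el[, 1] > el[, 2]
    el[swap, ] <- el[swap, c(2, 1), drop = FALSE]
    el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  }
  df <- data.frame(protein_a = el[, 1], protein_b = el[, 2],
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_network_edgelist
#' @export
read_network_edgelist <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) return(igraph::make_empty_graph(0, directed = FALSE))
  g <- igraph::graph_from_data_frame(df[, 1:2], directed = FALSE)
  igraph::simplify(g)
}

#' Write a network to GraphML for interoperability
#'
#' @param network An igraph object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(network, path) {
  igraph::write_graph(network, path, format = "graphml")
  invisible(path)
}
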