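#' Upper-tail hypergeometric p-value
#'
#' Probability of drawing at least `k` annotated genes when `n` genes are
#' sampled without replacement from a background of `N` genes of which `K`
#' carry the annotation: P(X >= k) = sum_{i=k}^{min(K,n)}
#' C(K,i) C(N-K, n-i) / C(N,n). Computed via the hypergeometric survival
#' function for numerical stability.
#'
#' @param k Observed overlap (module genes with the term).
#' @param K Background genes with the term.
#' @param n Annotated module size.
#' @param N Background size.
#' @return The upper-tail probability in \[0, 1\].
#' @export
#' @examples
#' hypergeom_pvalue(2, 3, 3, 6)  # 0.5
hypergeom_pvalue <- function(k, K, n, N) {
  if (N < 1 || K > N || n > N || k < 0 || k > min(K, n)) {
    stop("invalid hypergeometric arguments: require 0 <= k <= min(K, n), ",
         "K <= N, n <= N, N >= 1", call. = FALSE)
  }
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: with p-values sorted ascending, the adjusted value
#' at rank i is min over j >= i of p_j * m / j, capped at 1, returned in the
#' input order.
#'
#' @param p_values Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Hypergeometric over-representation test of one module
#'
#' Tests every annotation term hitting at least one of the module's genes for
#' over-representation against the background, adjusting with
#' Benjamini-Hochberg separately within each namespace of the module (the
#' per-test-set correction used by GO enrichment tools), and keeps terms with
#' adjusted p below `alpha`.
#'
#' @param module_genes Character vector: the topological module's proteins.
#' @param annotations An [annotation_set()] (already level-filtered if GO
#'   slim depth filtering is wanted).
#' @param background Character vector of background gene identifiers
#'   (typically all annotated proteins of the network). Must be non-empty.
#' @param alpha Significance threshold on the adjusted p-value
#'   (default 0.05).
#' @param bh_scope `"namespace"` (default) adjusts within each namespace of
#'   one module; `"module"` adjusts across all the module's tested terms.
#' @return A data.frame sorted by (`p_adjusted`, `term_id`) with columns
#'   `term_id`, `name`, `namespace`, `k`, `K`, `n`, `N`, `p_value`,
#'   `p_adjusted`, and a list column `hit_genes`. Zero rows when nothing is
#'   significant.
#' @export
enrich_module <- function(module_genes, annotations, background,
                          alpha = 0.05, bh_scope = c("namespace", "module")) {
  bh_scope <- match.arg(bh_scope)
  if (length(background) == 0) {
    stop("background gene set is empty", call. = FALSE)
  }
  stopifnot(alpha > 0, alpha < 1)
  background <- unique(background)
  module_bg <- intersect(module_genes, background)
  n <- length(module_bg)
  N <- length(background)
  rows <- list()
  for (id in names(annotations$terms)) {
    t <- annotations$terms[[id]]
    genes_bg <- intersect(t$genes, background)
    hits <- intersect(module_bg, genes_bg)
    if (length(hits) == 0) next
    k <- length(hits)
    K <- length(genes_bg)
    rows[[id]] <- data.frame(
      term_id = id, name = t$name, namespace = t$namespace,
      k = k, K = K, n = n, N = N,
      p_value = hypergeom_pvalue(k, K, n, N),
      stringsAsFactors = FALSE)
    rows[[id]]$hit_genes <- list(sort(hits))
  }
  if (length(rows) == 0) return(empty_enrichment())
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$p_adjusted <- if (bh_scope == "namespace") {
    stats::ave(res$p_value, res$namespace, FUN = bh_adjust)
  } else {
    bh_adjust(res$p_value)
  }
  res <- res[res$p_adjusted < alpha, , drop = FALSE]
  res <- res[order(res$p_adjusted, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res[, c("term_id", "name", "namespace", "k", "K", "n", "N",
          "p_value", "p_adjusted", "hit_genes")]
}

empty_enrichment <- function() {
  out <- data.frame(term_id = character(0), name = character(0),
                    namespace = character(0), k = integer(0), K = integer(0),
                    n = integer(0), N = integer(0), p_value = numeric(0),
                    p_adjusted = numeric(0), stringsAsFactors = FALSE)
  out$hit_genes <- list()
  out
}

#' Write per-module enrichment results as TSV
#'
#' Flattens the `hit_genes` list column into a comma-joined string and adds a
#' `module_id` column, so results for many modules can share one file.
#'
#' @param results A list of enrichment data.frames, named by module id (or a
#'   single data.frame, taken as module `"1"`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(results, path) {
  if (is.data.frame(results)) results <- list(`1` = results)
  rows <- lapply(names(results), function(mid) {
    r <- results[[mid]]
    if (nrow(r) == 0) return(NULL)
    data.frame(module_id = mid,
               r[, c("term_id", "name", "namespace", "k", "K", "n", "N",
                     "p_value", "p_adjusted")],
               hit_genes = vapply(r$hit_genes, paste, character(1),
                                  collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(module_id = character(0), term_id = character(0),
                      name = character(0), namespace = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p_value = numeric(0),
                      p_adjusted = numeric(0), hit_genes = character(0),
                      stringsAsFactors = FALSE)
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a multi-module enrichment TSV back into per-module data.frames
#'
#' @param path Path written by [write_enrichment()].
#' @return A named list of enrichment data.frames keyed by module id.
#' @export
read_enrichment <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(module_id = "character"))
  out <- lapply(split(df, df$module_id), function(r) {
    res <- r[, c("term_id", "name", "namespace", "k", "K", "n", "N",
                 "p_value", "p_adjusted")]
    res$hit_genes <- strsplit(r$hit_genes, ",", fixed = TRUE)
    rownames(res) <- NULL
    res
  })
  out
}
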