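#' Module partition of a PPI network
#'
#' A `module_partition` holds disjoint topological modules (protein sets)
#' found by a community detector, together with the detector's name. Modules
#' with at least `min_size` proteins (default 3) are "large" and are the only
#' ones carried into downstream layer calling; the rest are "small" but are
#' retained in outputs.
#'
#' @param modules A list of character vectors of protein identifiers, one per
#'   module. Names, if absent, are assigned as consecutive integers.
#' @param method Name of the detector that produced the partition.
#' @param n_nodes Number of nodes in the source network (for records only).
#' @return An object of class `module_partition`.
#' @export
module_partition <- function(modules, method = "unknown", n_nodes = NA_integer_) {
  modules <- lapply(modules, as.character)
  if (is.null(names(modules)) || any(!nzchar(names(modules)))) {
    names(modules) <- seq_along(modules)
  }
  all_p <- unlist(modules, use.names = FALSE)
  if (anyDuplicated(all_p)) {
    stop("modules must be pairwise disjoint", call. = FALSE)
  }
  structure(list(modules = modules, method = method,
                 n_nodes = as.integer(n_nodes)),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  sizes <- lengths(x$modules)
  cat("module_partition (", x$method, "): ", length(sizes), " modules over ",
      sum(sizes), " proteins; ", sum(sizes >= 3), " large (>=3), ",
      sum(sizes < 3), " small\n", sep = "")
  invisible(x)
}

#' Large and small modules of a partition
#'
#' @param partition A [module_partition()].
#' @param min_size Minimum size of a "large" module (default 3).
#' @return A named list of protein-identifier vectors.
#' @export
large_modules <- function(partition, min_size = 3L) {
  partition$modules[lengths(partition$modules) >= min_size]
}

#' @rdname large_modules
#' @export
small_modules <- function(partition, min_size = 3L) {
  partition$modules[lengths(partition$modules) < min_size]
}

#' Membership vector of a partition
#'
#' @param partition A [module_partition()].
#' @return A named character vector mapping protein -> module id.
#' @export
partition_membership <- function(partition) {
  ids <- rep(names(partition$modules), lengths(partition$modules))
  stats::setNames(ids, unlist(partition$modules, use.names = FALSE))
}

#' Detect topological modules in a PPI network
#'
#' Dispatches to one of three detectors: `"default"` (multilevel greedy
#' modularity maximization followed by a local node-move refinement pass that
#' rescues misassigned nodes of sparse modules), `"mcl"` (Markov clustering,
#' see [mcl_cluster()]), or `"rwr"` (seeded random walk with restart, see
#' [rwr_cluster()]). Results are deterministic given `seed`.
#'
#' @param network An undirected igraph object, non-empty.
#' @param method One of `"default"`, `"mcl"`, `"rwr"`.
#' @param params A list of method-specific parameters (`inflation`,
#'   `max_iters`, `prune_tol` for MCL; `seeds`, `restart`, `tol` for RWR).
#' @param seed Integer seed controlling any randomness.
#' @return A [module_partition()].
#' @export
detect_modules <- function(network, method = c("default", "mcl", "rwr"),
                           params = list(), seed = 1L) {
  if (igraph::vcount(network) == 0) {
    stop("network is empty", call. = FALSE)
  }
  if (length(method) != 1 || !method %in% c("default", "mcl", "rwr")) {
    stop("unknown detector method: ", paste(method, collapse = "/"),
         " (expected one of default, mcl, rwr)", call. = FALSE)
  }
  switch(method,
    default = default_cluster(network, seed = seed),
    mcl = do.call(mcl_cluster, c(list(network = network), params)),
    rwr = {
      if (is.null(params$seeds)) {
        set.seed(seed)
        n <- igraph::vcount(network)
        k <- max(2L, floor(sqrt(n)))
        params$seeds <- sample(igraph::V(network)$name, min(k, n))
      }
      do.call(rwr_cluster, c(list(network = network), params))
    }
  )
}

# Multilevel greedy modularity maximization + node-move refinement.
default_cluster <- function(network, seed = 1L, max_passes = 10L) {
  set.seed(seed)
  fg <- igraph::cluster_louvain(network)
  memb <- igraph::membership(fg)
  memb <- refine_partition(network, as.integer(memb), max_passes = max_passes)
  membership_to_partition(network, memb, method = "default")
}

membership_to_partition <- function(network, memb, method) {
  nm <- igraph::V(network)$name
  mods <- split(nm, memb)
  # stable ids: order modules by size desc, then first member
  ord <- order(-lengths(mods), vapply(mods, min, character(1)))
  mods <- mods[ord]
  names(mods) <- seq_along(mods)
  module_partition(mods, method = method, n_nodes = igraph::vcount(network))
}

# One-node move refinement: sweep nodes in order, move a node to a
# neighbouring community when the modularity gain is positive. Gains are
# computed incrementally; ties go to the lower community id.
refine_partition <- function(network, memb, max_passes = 10L) {
  m <- igraph::gsize(network)
  if (m == 0) return(memb)
  deg <- igraph::degree(network)
  adj <- igraph::as_adj_list(network)
  adj <- lapply(adj, as.integer)
  comm_deg <- vapply(split(deg, memb), sum, numeric(1))
  cd <- numeric(max(memb))
  cd[as.integer(names(comm_deg))] <- comm_deg
  for (pass in seq_len(max_passes)) {
    moved <- FALSE
    for (v in seq_along(memb)) {
      nb <- adj[[v]]
      if (!length(nb)) next
      a <- memb[v]
      nb_comm <- memb[nb]
      cnt <- tapply(rep(1L, length(nb_comm)), nb_comm, sum)
      cand <- as.integer(names(cnt))
      e_va <- if (a %in% cand) cnt[[as.character(a)]] else 0
      other <- cand[cand != a]
      if (!length(other)) next
      gain <- (cnt[match(other, cand)] - e_va) / m -
        deg[v] * (cd[other] - cd[a] + deg[v]) / (2 * m^2)
      top <- max(gain)
      if (top > 1e-12) {
        best_b <- min(other[gain >= top - 1e-12])  # ties: lower community id
        cd[a] <- cd[a] - deg[v]
        cd[best_b] <- cd[best_b] + deg[v]
        memb[v] <- best_b
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  memb
}

#' Markov clustering (MCL) of a PPI network
#'
#' Simulates flow on the graph by alternating expansion (matrix squaring) and
#' inflation (entrywise power followed by column re-normalization) of the
#' column-stochastic adjacency matrix with unit self-loops, until successive
#' matrices differ by less than `prune_tol` or `max_iters` is reached.
#' Clusters are read off the converged matrix by assigning each node to its
#' strongest attractor row; attractor-overlap ties go to the lowest-numbered
#' cluster. Every node is assigned to exactly one cluster.
#'
#' @param network An undirected igraph object, non-empty.
#' @param inflation Inflation exponent r > 1 controlling granularity
#'   (default 2).
#' @param max_iters Maximum expansion/inflation iterations (default 100).
#' @param prune_tol Entries below this are pruned to zero; also the
#'   convergence threshold on the max absolute change (default 1e-8).
#' @return A [module_partition()] with `method = "mcl"`.
#' @export
mcl_cluster <- function(network, inflation = 2, max_iters = 100L,
                        prune_tol = 1e-8) {
  stopifnot(inflation > 1)
  n <- igraph::vcount(network)
  if (n == 0) stop("network is empty", call. = FALSE)
  A <- as.matrix(igraph::as_adjacency_matrix(network, sparse = FALSE))
  diag(A) <- 1
  M <- sweep(A, 2, colSums(A), "/")
  converged <- FALSE
  for (iter in seq_len(max_iters)) {
    M2 <- M %*% M                  # expansion
    M2 <- M2^inflation             # inflation
    M2[M2 < prune_tol] <- 0
    cs <- colSums(M2)
    zero <- cs == 0
    if (any(zero)) {               # fully pruned column: restore self flow
      M2[cbind(which(zero), which(zero))] <- 1
      cs[zero] <- 1
    }
    M2 <- sweep(M2, 2, cs, "/")
    if (max(abs(M2 - M)) < prune_tol) {
      M <- M2
      converged <- TRUE
      break
    }
    M <- M2
  }
  if (!converged) {
    warning("mcl_cluster: no convergence after ", max_iters,
            " iterations; returning current clustering")
  }
  attractor <- apply(M, 2, which.max)  # ties -> lowest row index
  membership_to_partition(network, as.integer(attractor), method = "mcl")
}

#' Random-walk-with-restart clustering of a PPI network
#'
#' For each seed s the stationary affinity vector of the restarting walk
#' p <- (1 - restart) * W p + restart * e_s is computed, with W the
#' column-normalized adjacency matrix, iterating until the L1 change drops
#' below `tol`. Each node is then assigned to the seed of maximal affinity,
#' ties going to the lexicographically smaller seed identifier; nodes
#' unreachable from every seed go to a designated `"unassigned"` module.
#'
#' @param network An undirected igraph object.
#' @param seeds Character vector of seed protein identifiers (must be nodes).
#' @param restart Restart probability in (0, 1); default 0.4.
#' @param tol L1 convergence tolerance (default 1e-10).
#' @param max_iters Iteration cap per seed (default 10000).
#' @return A [module_partition()] with `method = "rwr"`; the module named
#'   `"unassigned"` (if present) holds unreachable nodes.
#' @export
rwr_cluster <- function(network, seeds, restart = 0.4, tol = 1e-10,
                        max_iters = 10000L) {
  if (missing(seeds) || length(seeds) == 0) {
    stop("rwr_cluster requires a non-empty seed set", call. = FALSE)
  }
  stopifnot(restart > 0, restart < 1)
  nm <- igraph::V(network)$name
  if (!all(seeds %in% nm)) {
    stop("seed(s) not in network: ",
         paste(setdiff(seeds, nm), collapse = ", "), call. = FALSE)
  }
  seeds <- sort(unique(seeds))
  n <- igraph::vcount(network)
  A <- as.matrix(igraph::as_adjacency_matrix(network, sparse = FALSE))
  cs <- colSums(A)
  W <- A
  pos <- cs > 0
  W[, pos] <- sweep(A[, pos, drop = FALSE], 2, cs[pos], "/")
  aff <- matrix(0, n, length(seeds), dimnames = list(nm, seeds))
  for (j in seq_along(seeds)) {
    e <- numeric(n)
    e[match(seeds[j], nm)] <- 1
    p <- e
    for (it in seq_len(max_iters)) {
      p_new <- (1 - restart) * as.vector(W %*% p) + restart * e
      if (sum(abs(p_new - p)) < tol) {
        p <- p_new
        break
      }
      p <- p_new
    }
    aff[, j] <- p
  }
  best <- apply(aff, 1, which.max)  # seeds sorted, so ties -> lexicographic
  reached <- apply(aff, 1, max) > 0
  assign <- ifelse(reached, seeds[best], "unassigned")
  if (any(!reached)) {
    message("rwr_cluster: ", sum(!reached),
            " node(s) unreachable from every seed")
  }
  mods <- split(nm, assign)
  seed_mods <- mods[names(mods) != "unassigned"]
  ord <- order(-lengths(seed_mods), vapply(seed_mods, min, character(1)))
  seed_mods <- seed_mods[ord]
  names(seed_mods) <- seq_along(seed_mods)
  if ("unassigned" %in% names(mods)) {
    seed_mods <- c(seed_mods, mods["unassigned"])
  }
  module_partition(seed_mods, method = "rwr", n_nodes = n)
}

#' Newman modularity of a partition
#'
#' Computes Q = sum_c \[ L_c / m - (d_c / 2m)^2 \] over modules c, where m is
#' the number of edges, L_c the number of edges with both endpoints in c, and
#' d_c the total degree of c's nodes. Nodes outside every module contribute
#' as singletons.
#'
#' @param network An undirected igraph object with at least one edge.
#' @param partition A [module_partition()] whose modules are node subsets.
#' @return Q, a real number in \[-0.5, 1).
#' @export
modularity_q <- function(network, partition) {
  m <- igraph::gsize(network)
  if (m == 0) stop("modularity is undefined for an edgeless network",
                   call. = FALSE)
  nm <- igraph::V(network)$name
  memb <- partition_membership(partition)
  bad <- setdiff(names(memb), nm)
  if (length(bad)) {
    stop("partition contains proteins absent from the network: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  full <- memb[nm]
  names(full) <- nm  # NA entries would otherwise lose their name
  missing <- is.na(full)
  full[missing] <- paste0(".singleton", seq_len(sum(missing)))
  deg <- igraph::degree(network)
  el <- igraph::as_edgelist(network, names = TRUE)
  same <- full[el[, 1]] == full[el[, 2]]
  L_c <- tapply(rep(1, sum(same)), full[el[same, 1]], sum)
  d_c <- tapply(deg, full, sum)
  Lc_full <- stats::setNames(numeric(length(d_c)), names(d_c))
  Lc_full[names(L_c)] <- L_c
  sum(Lc_full / m - (d_c / (2 * m))^2)
}

#' Write and read a module partition as TSV
#'
#' Columns: `protein_id`, `module_id`, `method`. The reader accepts any file
#' with these columns, so externally computed clusterings can be injected
#' into the pipeline.
#'
#' @param partition A [module_partition()].
#' @param path File path.
#' @return `write_partition()` returns `path` invisibly; `read_partition()`
#'   returns a [module_partition()].
#' @export
write_partition <- function(partition, path) {
  memb <- partition_membership(partition)
  df <- data.frame(protein_id = names(memb), module_id = unname(memb),
                   method = partition$method, stringsAsFactors = FALSE)
  df <- df[order(df$module_id, df$protein_id), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(module_id = "character"))
  mods <- split(df$protein_id, df$module_id)
  method <- if (nrow(df)) df$method[1] else "unknown"
  module_partition(mods, method = method)
}
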