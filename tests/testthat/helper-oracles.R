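# Independent oracles used to check the package's statistics. These never
# call the implementation paths they verify.

# Exhaustive hypergeometric upper tail: enumerate every n-subset of 1..N,
# where 1..K carry the annotation, and count draws with >= k hits.
hyper_enum_oracle <- function(k, K, n, N) {
  if (k == 0) return(1)
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)
  mean(hits >= k)
}

# Closed-form hypergeometric tail via log-binomials, for backgrounds too
# large to enumerate.
hyper_enum_oracle_big <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# Manual Benjamini-Hochberg step-up, written from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Brute-force Newman modularity: full double sum over ordered node pairs,
# Q = 1/(2m) * sum_ij (A_ij - k_i k_j / (2m)) [c_i == c_j].
brute_modularity <- function(graph, membership) {
  A <- as.matrix(igraph::as_adjacency_matrix(graph, sparse = FALSE))
  deg <- rowSums(A)
  m <- sum(A) / 2
  same <- outer(membership, membership, "==")
  sum((A - outer(deg, deg) / (2 * m)) * same) / (2 * m)
}

# Membership vector (with unassigned nodes as singletons) for a partition
# over a given node ordering.
membership_for <- function(partition, nodes) {
  memb <- netmodmap::partition_membership(partition)
  out <- memb[nodes]
  miss <- is.na(out)
  out[miss] <- paste0("solo", seq_len(sum(miss)))
  unname(out)
}

# k disjoint cliques of a given size, with neutral node names.
make_cliques <- function(k, size = 4) {
  g <- Reduce(igraph::disjoint_union,
              replicate(k, igraph::make_full_graph(size), simplify = FALSE))
  igraph::set_vertex_attr(g, "name",
                          value = sprintf("n%03d", seq_len(k * size)))
}

# Small interaction-record data.frame builder.
make_records <- function(a, b, score = 0.9, sources = list(c("dbA", "dbB")),
                         type = "direct physical") {
  n <- length(a)
  rec <- data.frame(protein_a = a, protein_b = b,
                    confidence = rep_len(score, n),
                    interaction_type = rep_len(type, n),
                    stringsAsFactors = FALSE)
  rec$sources <- rep_len(sources, n)
  rec
}

# Adjusted Rand index between two labelings (contingency-table formula).
ari_oracle <- function(x, y) {
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  c_ <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expected <- b * c_ / choose(n, 2)
  (a - expected) / ((b + c_) / 2 - expected)
}

skip_msgs <- function(expr) suppressMessages(expr)
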