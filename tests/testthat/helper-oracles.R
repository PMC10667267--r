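# Independent brute-force oracles. These deliberately avoid igraph and
# stats::phyper so that the package's results are checked against a second,
# unrelated computation path.

# --- graph oracle -----------------------------------------------------------

# BFS all-pairs distances on an adjacency matrix (Inf when unreachable)
oracle_distances <- function(adj) {
  n <- nrow(adj)
  dist <- matrix(Inf, n, n)
  diag(dist) <- 0
  for (s in seq_len(n)) {
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- unique(unlist(lapply(frontier, function(v) which(adj[v, ] == 1))))
      nxt <- nxt[is.infinite(dist[s, nxt])]
      nxt <- setdiff(nxt, s)
      dist[s, nxt] <- d
      frontier <- nxt
    }
  }
  dist
}

# enumerate every shortest s->t path explicitly (list of vertex vectors)
oracle_all_shortest_paths <- function(adj, dist, s, t) {
  if (is.infinite(dist[s, t])) return(list())
  recurse <- function(v) {
    if (v == t) return(list(t))
    nxt <- which(adj[v, ] == 1 & dist[, t] == dist[v, t] - 1)
    unlist(lapply(nxt, function(u) {
      lapply(recurse(u), function(p) c(v, p))
    }), recursive = FALSE)
  }
  recurse(s)
}

# degree / normalised betweenness / component-local closeness by enumeration
oracle_centralities <- function(adj) {
  n <- nrow(adj)
  dist <- oracle_distances(adj)
  deg <- rowSums(adj)
  btw <- numeric(n)
  if (n >= 3) {
    for (s in seq_len(n - 1)) {
      for (t in seq((s + 1), n)) {
        paths <- oracle_all_shortest_paths(adj, dist, s, t)
        sigma <- length(paths)
        if (sigma == 0) next
        inner <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
        if (length(inner)) {
          counts <- table(inner)
          idx <- as.integer(names(counts))
          btw[idx] <- btw[idx] + as.numeric(counts) / sigma
        }
      }
    }
    btw <- btw / ((n - 1) * (n - 2) / 2)
  }
  cc <- vapply(seq_len(n), function(v) {
    reach <- which(is.finite(dist[v, ]) & seq_len(n) != v)
    if (!length(reach)) return(0)
    length(reach) / sum(dist[v, reach])
  }, numeric(1))
  list(degree = as.numeric(deg), betweenness = btw, closeness = cc)
}

# adjacency matrix -> edge tibble with stable node names V01, V02, ...
adj_to_edges <- function(adj) {
  nm <- oracle_node_names(nrow(adj))
  idx <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  tibble::tibble(gene_a = nm[idx[, 1]], gene_b = nm[idx[, 2]])
}

oracle_node_names <- function(n) sprintf("V%02d", seq_len(n))

# package centralities for an adjacency matrix, rows ordered as the oracle's
package_centralities <- function(adj, ...) {
  nm <- oracle_node_names(nrow(adj))
  g <- build_ppi(adj_to_edges(adj), restrict_to = nm)
  cent <- ppi_centralities(g, ...)
  cent[match(nm, cent$gene), ]
}

random_adjacency <- function(n, p) {
  adj <- matrix(0L, n, n)
  up <- which(upper.tri(adj))
  on <- up[stats::runif(length(up)) < p]
  adj[on] <- 1L
  adj + t(adj)
}

is_connected_adj <- function(adj) {
  all(is.finite(oracle_distances(adj)[1, ]))
}

random_connected_adjacency <- function(n, p = 0.35) {
  repeat {
    adj <- random_adjacency(n, p)
    if (is_connected_adj(adj)) return(adj)
  }
}

# --- hypergeometric oracle --------------------------------------------------

# P(overlap >= k) by enumerating every size-n draw from a universe of N genes
# of which the first K are annotated
oracle_hyper_tail <- function(k, n, K, N) {
  if (n == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  overlap <- colSums(draws <= K)
  mean(overlap >= k)
}
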