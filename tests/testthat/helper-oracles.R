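# Brute-force reference implementations used as independent oracles.
# They work on a plain dense 0/1 adjacency matrix (no self-loops) and are
# deliberately naive: all-pairs Floyd-Warshall distances and explicit
# shortest-path counting, dense eigendecomposition, dense linear solves.

floyd_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj > 0] <- 1
  for (k in seq_len(n)) {
    dk <- outer(d[, k], d[k, ], `+`)
    d <- pmin(d, dk)
  }
  d
}

# number of shortest paths between every pair: sigma[s, t]
shortest_path_counts <- function(adj, d) {
  n <- nrow(adj)
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  for (s in seq_len(n)) {
    ord <- order(d[s, ])
    for (t in ord) {
      if (t == s || !is.finite(d[s, t])) next
      preds <- which(adj[, t] > 0 & d[s, ] == d[s, t] - 1)
      sigma[s, t] <- sum(sigma[s, preds])
    }
  }
  sigma
}

oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- floyd_distances(adj)
  sigma <- shortest_path_counts(adj, d)
  btw <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) {
      for (t in (s + 1):n) {
        if (s == v || t == v || !is.finite(d[s, t]) || sigma[s, t] == 0) next
        if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
            d[s, v] + d[v, t] == d[s, t]) {
          btw[v] <- btw[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
  }
  btw
}

oracle_closeness <- function(adj) {
  d <- floyd_distances(adj)
  apply(d, 1, function(row) {
    reach <- row[is.finite(row) & row > 0]
    if (length(reach) == 0) 0 else 1 / mean(reach)
  })
}

# principal-eigenvector hub scores from a dense eigendecomposition of the
# (possibly multiplicity-weighted) adjacency matrix, max-normalized
oracle_hits <- function(A) {
  e <- eigen(A, symmetric = TRUE)
  v <- abs(e$vectors[, which.max(e$values)])
  if (max(v) == 0) v else v / max(v)
}

oracle_global_stats <- function(adj) {
  n <- nrow(adj)
  m <- sum(adj[upper.tri(adj)])
  d <- floyd_distances(adj)
  membership <- bfs_components(adj)
  sizes <- table(membership)
  giant_label <- as.integer(names(sizes)[which.max(sizes)])
  giant <- which(membership == giant_label)
  dg <- d[giant, giant, drop = FALSE]
  finite <- dg[upper.tri(dg)]
  list(
    density = if (n < 2) 0 else m / (n * (n - 1) / 2),
    diameter = if (length(finite) == 0) 0 else max(finite),
    average_path_length = if (length(finite) == 0) 0 else mean(finite)
  )
}

# connected components by breadth-first flooding (no igraph)
bfs_components <- function(adj) {
  n <- nrow(adj)
  membership <- rep(NA_integer_, n)
  label <- 0L
  for (start in seq_len(n)) {
    if (!is.na(membership[start])) next
    label <- label + 1L
    queue <- start
    membership[start] <- label
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(adj[v, ] > 0 & is.na(membership))
      membership[nb] <- label
      queue <- c(queue, nb)
    }
  }
  membership
}

# set-arithmetic seed-similarity oracle on an edge list (character pairs)
oracle_seed_sim <- function(edges, nodes, seeds, query) {
  nb <- function(v) {
    unique(c(edges[edges[, 1] == v, 2], edges[edges[, 2] == v, 1]))
  }
  eff <- setdiff(seeds, query)
  A <- nb(query)
  B <- unique(unlist(lapply(eff, nb)))
  inter <- intersect(A, B)
  deg <- vapply(nodes, function(v) length(nb(v)), numeric(1))
  names(deg) <- nodes
  ilw <- sum(vapply(inter, function(v) if (deg[[v]] > 1) 1 / log(deg[[v]]) else 0,
                    numeric(1)))
  list(
    shared = length(inter),
    jaccard = if (length(union(A, B)) == 0) 0 else length(inter) / length(union(A, B)),
    dice = if (length(A) + length(B) == 0) 0 else 2 * length(inter) / (length(A) + length(B)),
    inv_log_weighted = ilw
  )
}

# dense Gaussian-field solve: (I + L) f = y with base solve()
oracle_labelprop <- function(W, seeds_mask, lambda = 1) {
  n <- nrow(W)
  k <- sum(seeds_mask) / n
  y <- ifelse(seeds_mask, 1, k)
  L <- diag(rowSums(W)) - W
  as.numeric(solve(diag(n) + lambda * L, y))
}

# random connected-ish test graph as a plain adjacency matrix
random_adjacency <- function(n, p, seed) {
  set.seed(seed)
  adj <- matrix(0, n, n)
  adj[upper.tri(adj)] <- as.numeric(runif(n * (n - 1) / 2) < p)
  adj + t(adj)
}

# wrap a dense adjacency matrix as a one-layer multinet
net_from_adjacency <- function(adj, nodes = sprintf("n%02d", seq_len(nrow(adj)))) {
  idx <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  edges <- cbind(nodes[idx[, 1]], nodes[idx[, 2]])
  integrate_layers(list(subnetwork(edges, "L1", nodes = nodes)))
}

# small multi-layer net from a list of edge matrices
net_from_layers <- function(layers, nodes = NULL) {
  subs <- lapply(seq_along(layers), function(i) {
    subnetwork(layers[[i]], paste0("L", i),
               nodes = if (is.null(nodes)) character() else nodes)
  })
  integrate_layers(subs)
}

edge_mat <- function(...) {
  v <- c(...)
  matrix(v, ncol = 2, byrow = TRUE)
}
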