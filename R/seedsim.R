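#' Seed-set similarity features for one query gene
#'
#' Six topology-based similarity measures between a query gene and the
#' seed set S, computed on the simple projection except where noted. The
#' query is always excluded from S for its own computation, so a seed
#' member is compared against the other members only. With A the
#' neighbourhood of the query and B the union of the neighbourhoods of the
#' (effective) seed members:
#'
#' * `direct_connections` — edges from the query into S, with multiplicity;
#' * `shared_neighbors` — `|A intersect B|`;
#' * `jaccard` — `|A intersect B| / |A union B|`;
#' * `dice` — `2 |A intersect B| / (|A| + |B|)`;
#' * `inv_log_weighted` — sum over shared neighbours v of `1 / log deg(v)`
#'   (natural log; simple degree; degree-1 neighbours contribute 0);
#' * `shortest_path_to_seeds` — hops to the nearest seed (0 for a seed
#'   member); unreachable encoded as network diameter + 1 so models see a
#'   finite value.
#'
#' @param net A `multinet`.
#' @param seeds A [seed_set()] or character vector.
#' @param query A gene identifier present in the network.
#' @return One-row data frame with the six features.
#' @export
seed_sim_features <- function(net, seeds, query) {
  stopifnot(inherits(net, "multinet"))
  if (!query %in% net$nodes) stop("query gene not in network: ", query)
  seeds <- match_seeds(net, seeds)
  in_seeds <- query %in% seeds
  eff <- setdiff(seeds, query)
  if (length(eff) == 0) stop("effective seed set is empty for query ", query)

  g <- net$graph
  A <- setdiff(igraph::neighbors(g, query)$name, character(0))
  B <- unique(unlist(lapply(eff, function(s) igraph::neighbors(g, s)$name)))
  inter <- intersect(A, B)
  uni <- union(A, B)
  deg_simple <- igraph::degree(g)
  ilw_terms <- vapply(inter, function(v) {
    dv <- deg_simple[[v]]
    if (dv > 1) 1 / log(dv) else 0
  }, numeric(1))
  q_idx <- match(query, net$nodes)
  s_idx <- match(eff, net$nodes)
  direct <- sum(net$mult[q_idx, s_idx])
  if (in_seeds) {
    sp <- 0
  } else {
    d <- igraph::distances(g, v = query, to = eff)
    sp <- min(d)
    if (!is.finite(sp)) sp <- unreachable_distance(g)
  }
  data.frame(
    direct_connections = direct,
    shared_neighbors = length(inter),
    jaccard = if (length(uni) == 0) 0 else length(inter) / length(uni),
    dice = if (length(A) + length(B) == 0) 0 else 2 * length(inter) / (length(A) + length(B)),
    inv_log_weighted = sum(ilw_terms),
    shortest_path_to_seeds = sp
  )
}

# finite sentinel for unreachable shortest paths: diameter of the largest
# component plus one
unreachable_distance <- function(g) {
  igraph::diameter(g, directed = FALSE, unconnected = TRUE) + 1
}

#' Seed-set similarity features for all genes
#'
#' Vectorized computation of the six features of [seed_sim_features()] for
#' every node of the network. Seed members are handled with leave-self-out
#' seed sets, matching the single-query semantics.
#'
#' @param net A `multinet`.
#' @param seeds A [seed_set()] or character vector (at least two members
#'   present in the network).
#' @return Data frame: `gene` plus the six feature columns, one row per
#'   network node.
#' @export
seed_sim_matrix <- function(net, seeds) {
  stopifnot(inherits(net, "multinet"))
  seeds <- match_seeds(net, seeds)
  if (length(seeds) < 2)
    warning("single-member seed set: its member gets empty-set similarities")
  nodes <- net$nodes
  n <- length(nodes)
  adj <- net$adj
  deg_simple <- as.numeric(Matrix::rowSums(adj))
  z <- as.numeric(nodes %in% seeds)
  s_idx <- which(z > 0)

  # counts[v] = number of seed genes adjacent to v
  counts <- as.numeric(adj %*% z)
  b <- as.numeric(counts > 0)               # union neighbourhood of S
  ilw_w <- ifelse(deg_simple > 1, 1 / log(deg_simple), 0)

  inter <- as.numeric(adj %*% b)
  size_B <- sum(b)
  ilw <- as.numeric(adj %*% (b * ilw_w))
  direct <- as.numeric(net$mult %*% z)      # no self-loops, so exact for seeds too

  uni <- deg_simple + size_B - inter
  jac <- ifelse(uni > 0, inter / uni, 0)
  dice_den <- deg_simple + size_B
  dice <- ifelse(dice_den > 0, 2 * inter / dice_den, 0)

  # leave-self-out correction for seed members: drop that seed's own
  # neighbourhood contribution from the union before intersecting
  for (q in s_idx) {
    adj_q <- adj[, q]
    b_q <- as.numeric((counts - adj_q) > 0)
    inter_q <- sum(adj_q * b_q)
    size_Bq <- sum(b_q)
    inter[q] <- inter_q
    ilw[q] <- sum(adj_q * b_q * ilw_w)
    uni_q <- deg_simple[q] + size_Bq - inter_q
    jac[q] <- if (uni_q > 0) inter_q / uni_q else 0
    den_q <- deg_simple[q] + size_Bq
    dice[q] <- if (den_q > 0) 2 * inter_q / den_q else 0
  }

  d <- igraph::distances(net$graph, v = nodes[s_idx])
  sp <- apply(d, 2L, min)
  if (any(!is.finite(sp))) sp[!is.finite(sp)] <- unreachable_distance(net$graph)

  data.frame(
    gene = nodes,
    direct_connections = direct,
    shared_neighbors = inter,
    jaccard = jac,
    dice = dice,
    inv_log_weighted = ilw,
    shortest_path_to_seeds = as.numeric(sp),
    row.names = NULL
  )
}
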