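#' Global statistics of an integrated network
#'
#' Density is the ratio of actual to possible edges; by default it is
#' computed on the simple projection (each gene pair counted once), with an
#' option to put the multi-edge count in the numerator instead. The
#' clustering coefficient is the global transitivity of the simple graph.
#' Diameter and average path length are unweighted hop counts on the
#' largest connected component of the simple graph (multiplicities never
#' affect path-based statistics). `pct_unique_edges` is the fraction of
#' simple edges present in exactly one layer.
#'
#' @param net A `multinet`.
#' @param count_multiedges If `TRUE`, density uses the edge count with
#'   multiplicity in the numerator (still over `n(n-1)/2` possible pairs).
#' @return A one-row data frame: `n_nodes`, `n_edges` (with multiplicity),
#'   `n_simple_edges`, `density`, `clustering_coefficient`, `diameter`,
#'   `average_path_length`, `pct_unique_edges`.
#' @export
global_stats <- function(net, count_multiedges = FALSE) {
  stopifnot(inherits(net, "multinet"))
  n <- length(net$nodes)
  if (n == 0) stop("network has no nodes")
  g <- net$graph
  m_simple <- igraph::ecount(g)
  m_multi <- n_edges(net)
  possible <- n * (n - 1) / 2
  density <- if (n < 2) 0 else (if (count_multiedges) m_multi else m_simple) / possible
  cc <- igraph::transitivity(g, type = "global")
  if (is.nan(cc)) cc <- 0
  if (n == 1 || m_simple == 0) {
    diam <- 0
    apl <- 0
  } else {
    comp <- igraph::components(g)
    if (comp$no > 1) {
      message("network is disconnected; diameter and average path length computed on the largest component")
      giant <- igraph::induced_subgraph(
        g, which(comp$membership == which.max(comp$csize))
      )
    } else {
      giant <- g
    }
    diam <- igraph::diameter(giant, directed = FALSE, unconnected = FALSE)
    apl <- igraph::mean_distance(giant, directed = FALSE, unconnected = FALSE)
  }
  mult_vals <- Matrix::triu(net$mult, k = 1L)@x
  pct_unique <- if (m_simple == 0) 0 else mean(mult_vals == 1)
  data.frame(
    n_nodes = n,
    n_edges = m_multi,
    n_simple_edges = m_simple,
    density = density,
    clustering_coefficient = cc,
    diameter = diam,
    average_path_length = apl,
    pct_unique_edges = pct_unique
  )
}

#' Per-layer contribution to a seed-anchored subgraph
#'
#' Induces a subgraph on the seed genes (optionally extended by their first
#' neighbours in the simple integrated graph) and counts, for every layer,
#' that layer's edges with both endpoints in the subgraph. `percent_total`
#' is each layer's share of the subgraph's edges; `percent_individual`
#' normalizes by the layer's own total edge count, measuring the fraction
#' of a layer that flows into the seed neighbourhood.
#'
#' @param net A `multinet`.
#' @param seeds A [seed_set()] or character vector; members absent from the
#'   network are dropped with a warning.
#' @param first_neighbors Extend the subgraph to seeds plus their first
#'   neighbours.
#' @return A data frame with one row per layer plus columns `layer`,
#'   `edge_count`, `percent_total`, `percent_individual`, and attributes
#'   `n_subgraph_nodes` and `total_edges`.
#' @export
layer_contribution <- function(net, seeds, first_neighbors = FALSE) {
  stopifnot(inherits(net, "multinet"))
  seeds <- match_seeds(net, seeds)
  sub_nodes <- seeds
  if (first_neighbors) {
    idx <- match(seeds, net$nodes)
    nb <- unique(Matrix::summary(net$adj[, idx, drop = FALSE])$i)
    sub_nodes <- union(seeds, net$nodes[nb])
  }
  in_sub <- net$nodes %in% sub_nodes
  counts <- vapply(net$layer_edges, function(e) {
    if (nrow(e) == 0) return(0L)
    sum(in_sub[match(e[, 1], net$nodes)] & in_sub[match(e[, 2], net$nodes)])
  }, integer(1))
  layer_totals <- vapply(net$layer_edges, nrow, integer(1))
  total <- sum(counts)
  res <- data.frame(
    layer = net$layers,
    edge_count = as.integer(counts),
    percent_total = if (total > 0) counts / total else rep(NA_real_, length(counts)),
    percent_individual = ifelse(layer_totals > 0, counts / layer_totals, 0),
    row.names = NULL
  )
  attr(res, "n_subgraph_nodes") <- length(sub_nodes)
  attr(res, "total_edges") <- total
  res
}

#' Compare connectivity to the seed set between seeds and non-seeds
#'
#' For every gene, counts its direct edges (with multiplicity) to seed
#' genes; a seed's own membership is excluded, so for seeds this is the
#' internal degree. Reports the median for seeds and non-seeds separately,
#' and how many non-seeds reach the seed-internal median — a measure of
#' how unspecific pure guilt-by-association would be.
#'
#' @param net A `multinet`.
#' @param seeds A [seed_set()] or character vector.
#' @return A list: `seed_median`, `nonseed_median`,
#'   `n_nonseeds_at_seed_median` (non-seeds with at least the seed-internal
#'   median number of edges to seeds), and the per-gene count vectors
#'   `seed_counts`, `nonseed_counts`.
#' @export
seed_degree_summary <- function(net, seeds) {
  stopifnot(inherits(net, "multinet"))
  seeds <- match_seeds(net, seeds)
  idx <- match(seeds, net$nodes)
  to_seeds <- as.numeric(Matrix::rowSums(net$mult[, idx, drop = FALSE]))
  names(to_seeds) <- net$nodes
  is_seed <- net$nodes %in% seeds
  seed_counts <- to_seeds[is_seed]   # self excluded: no self-loops exist
  nonseed_counts <- to_seeds[!is_seed]
  seed_median <- stats::median(seed_counts)
  list(
    seed_median = seed_median,
    nonseed_median = stats::median(nonseed_counts),
    n_nonseeds_at_seed_median = sum(nonseed_counts >= seed_median),
    seed_counts = seed_counts,
    nonseed_counts = nonseed_counts
  )
}
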