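#' General topological features per gene
#'
#' Five centrality features for every gene in the integrated network:
#' degree (summing edge multiplicities), betweenness and closeness on the
#' simple unweighted projection (parallel edges never change shortest
#' paths), and Kleinberg hub/authority scores from the principal
#' eigenvector of the multiplicity-weighted adjacency matrix. On an
#' undirected network the adjacency matrix is symmetric, so hub and
#' authority coincide; both columns are kept for a stable feature layout.
#'
#' Betweenness is reported unnormalized (shortest-path pair counts).
#' Closeness is the reciprocal of the mean shortest-path distance to the
#' reachable nodes, 0 for isolated nodes. Hub scores are obtained by
#' deterministic power iteration (uniform start, tolerance `tol`,
#' max-normalized so the largest score is 1).
#'
#' @param net A `multinet`.
#' @param tol Power-iteration convergence tolerance.
#' @param max_iter Maximum power iterations.
#' @return Data frame with columns `gene`, `degree`, `betweenness`,
#'   `closeness`, `hub`, `authority`, one row per network node.
#' @export
topo_features <- function(net, tol = 1e-10, max_iter = 1000L) {
  stopifnot(inherits(net, "multinet"))
  g <- net$graph
  n <- length(net$nodes)
  if (n == 0) stop("network has no nodes")
  degree <- as.numeric(Matrix::rowSums(net$mult))
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  d <- igraph::distances(g)
  closeness <- apply(d, 1L, function(row) {
    reach <- row[is.finite(row) & row > 0]
    if (length(reach) == 0) 0 else 1 / mean(reach)
  })
  hub <- hits_power_iteration(net$mult, tol = tol, max_iter = max_iter)
  data.frame(
    gene = net$nodes,
    degree = degree,
    betweenness = as.numeric(btw),
    closeness = as.numeric(closeness),
    hub = hub,
    authority = hub,
    row.names = NULL
  )
}

# principal-eigenvector scores of a symmetric (multiplicity-weighted)
# adjacency matrix via power iteration; uniform start so the result is
# reproducible without any RNG; max-normalized to 1
hits_power_iteration <- function(A, tol = 1e-10, max_iter = 1000L) {
  n <- nrow(A)
  if (n == 0) return(numeric(0))
  x <- rep(1 / sqrt(n), n)
  if (sum(A) == 0) return(rep(0, n))
  # shifted iteration (A + I)x: same eigenvectors as A, but the shift
  # separates the +/- eigenvalue pair of bipartite components so the
  # iteration converges to the Perron vector instead of oscillating
  for (it in seq_len(max_iter)) {
    y <- as.numeric(A %*% x) + x
    nrm <- sqrt(sum(y^2))
    if (nrm == 0) return(rep(0, n))
    y <- y / nrm
    if (max(abs(y - x)) < tol) {
      x <- y
      break
    }
    x <- y
  }
  m <- max(abs(x))
  if (m == 0) rep(0, n) else abs(x) / m
}
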