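# canonicalize an edge matrix: drop self-loops, order endpoints
# lexicographically within each pair, drop duplicate pairs
canonical_edges <- function(from, to) {
  keep <- from != to
  n_loops <- sum(!keep)
  from <- from[keep]
  to <- to[keep]
  a <- pmin(from, to)
  b <- pmax(from, to)
  key <- paste(a, b, sep = "\r")
  dup <- duplicated(key)
  list(
    edges = cbind(from = a[!dup], to = b[!dup]),
    n_loops = n_loops,
    n_dups = sum(dup)
  )
}

#' Construct a single network layer
#'
#' A sub-network is one undirected layer of an integrated association
#' network: a set of unordered gene pairs plus the set of genes it covers
#' (which may include isolated genes declared without edges). Self-loops
#' and duplicate pairs are removed.
#'
#' @param edges Two-column character matrix or data frame of gene pairs.
#' @param name Layer identifier.
#' @param nodes Optional character vector of gene identifiers; the node set
#'   is the union of `nodes` and all edge endpoints.
#' @return An object of class `subnetwork` with elements `name`, `edges`
#'   (two-column character matrix, endpoints ordered within each pair) and
#'   `nodes` (sorted character vector).
#' @export
subnetwork <- function(edges, name, nodes = character()) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (length(edges) == 0) {
    edges <- matrix(character(), ncol = 2)
  }
  stopifnot(ncol(edges) == 2)
  ce <- canonical_edges(as.character(edges[, 1]), as.character(edges[, 2]))
  if (ce$n_loops > 0)
    warning(sprintf("layer '%s': dropped %d self-loop(s)", name, ce$n_loops))
  structure(
    list(
      name = as.character(name),
      edges = ce$edges,
      # endpoints of dropped self-loops stay in the node set as isolates
      nodes = sort(unique(c(as.character(nodes), as.character(edges))))
    ),
    class = "subnetwork"
  )
}

#' @export
print.subnetwork <- function(x, ...) {
  cat(sprintf(
    "<subnetwork '%s': %d nodes, %d edges>\n",
    x$name, length(x$nodes), nrow(x$edges)
  ))
  invisible(x)
}

#' Read an edge-list file into a network layer
#'
#' Parses a plain-text edge list: one edge per line, two
#' whitespace-separated gene identifiers, `#` starting a comment line.
#' Identifiers are opaque, case-sensitive strings. Self-loops are dropped
#' with a warning and duplicate pairs are collapsed.
#'
#' @param path Path to the edge-list file.
#' @param layer_name Layer identifier; defaults to the file name without
#'   extension.
#' @return A [subnetwork()].
#' @export
read_edge_list <- function(path, layer_name = NULL) {
  if (!file.exists(path)) stop("edge-list file not found: ", path)
  if (is.null(layer_name))
    layer_name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0) {
    warning(sprintf("edge-list '%s' contains no edges", path))
    return(subnetwork(matrix(character(), ncol = 2), layer_name))
  }
  toks <- strsplit(trimws(lines[idx]), "\\s+")
  bad <- which(lengths(toks) != 2)
  if (length(bad) > 0)
    stop(sprintf(
      "malformed edge list '%s': line %d has %d token(s), expected 2",
      path, idx[bad[1]], lengths(toks)[bad[1]]
    ))
  m <- matrix(unlist(toks), ncol = 2, byrow = TRUE)
  subnetwork(m, layer_name)
}

#' Integrate network layers into one multi-edge network
#'
#' Layers are combined quantitatively by summing their adjacency matrices:
#' the multiplicity of a gene pair is the number of layers that contain it,
#' so a pair present in all of `k` layers is connected by `k` parallel
#' edges. No weighting or preference between layers is applied.
#'
#' @param subnets List of [subnetwork()] objects with distinct names.
#' @return An object of class `multinet` with elements `layers` (layer
#'   names), `layer_edges` (per-layer canonical edge matrices), `nodes`,
#'   `mult` (sparse symmetric multiplicity matrix) and `graph` (the simple
#'   unweighted igraph projection used for path-based statistics).
#' @export
integrate_layers <- function(subnets) {
  if (length(subnets) == 0) stop("need at least one layer to integrate")
  if (inherits(subnets, "subnetwork")) subnets <- list(subnets)
  stopifnot(all(vapply(subnets, inherits, logical(1), "subnetwork")))
  layer_names <- vapply(subnets, `[[`, character(1), "name")
  if (anyDuplicated(layer_names))
    stop("duplicate layer names: ", paste(unique(layer_names[duplicated(layer_names)]), collapse = ", "))
  nodes <- sort(unique(unlist(lapply(subnets, `[[`, "nodes"))))
  n <- length(nodes)
  layer_edges <- lapply(subnets, `[[`, "edges")
  names(layer_edges) <- layer_names
  layer_nodes <- lapply(subnets, `[[`, "nodes")
  names(layer_nodes) <- layer_names

  all_i <- unlist(lapply(layer_edges, function(e) match(e[, 1], nodes)))
  all_j <- unlist(lapply(layer_edges, function(e) match(e[, 2], nodes)))
  if (length(all_i) > 0) {
    mult <- Matrix::sparseMatrix(
      i = c(all_i, all_j), j = c(all_j, all_i), x = 1,
      dims = c(n, n), dimnames = list(nodes, nodes)
    )
  } else {
    mult <- Matrix::sparseMatrix(
      i = integer(), j = integer(), x = numeric(),
      dims = c(n, n), dimnames = list(nodes, nodes)
    )
  }
  adj <- mult
  adj@x[] <- 1
  graph <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  structure(
    list(
      layers = layer_names,
      layer_edges = layer_edges,
      layer_nodes = layer_nodes,
      nodes = nodes,
      mult = mult,
      adj = adj,
      graph = graph
    ),
    class = "multinet"
  )
}

#' @export
print.multinet <- function(x, ...) {
  cat(sprintf(
    "<multinet: %d nodes, %d edges (with multiplicity) across %d layer(s): %s>\n",
    length(x$nodes), n_edges(x), length(x$layers),
    paste(x$layers, collapse = ", ")
  ))
  invisible(x)
}

#' Total edge count of an integrated network, with multiplicity
#' @param net A `multinet`.
#' @return Integer edge count summed over layers.
#' @export
n_edges <- function(net) {
  sum(vapply(net$layer_edges, nrow, integer(1)))
}

# unique simple pairs of the integrated network with their multiplicity,
# as a data.frame (from, to, multiplicity); canonical endpoint order
edge_multiplicities <- function(net) {
  tri <- Matrix::triu(net$mult, k = 1L)
  tt <- Matrix::summary(tri)
  if (nrow(tt) == 0)
    return(data.frame(from = character(), to = character(), multiplicity = integer()))
  data.frame(
    from = net$nodes[tt$i],
    to = net$nodes[tt$j],
    multiplicity = as.integer(tt$x),
    stringsAsFactors = FALSE
  )
}

#' Remove one layer from an integrated network
#'
#' @param net A `multinet`.
#' @param layer Name of the layer to drop.
#' @return A `multinet` rebuilt from the remaining layers (node set may
#'   shrink to the remaining layers' nodes).
#' @export
drop_layer <- function(net, layer) {
  if (!layer %in% net$layers) stop("no such layer: ", layer)
  keep <- setdiff(net$layers, layer)
  if (length(keep) == 0) stop("cannot drop the only layer")
  subnets <- lapply(keep, function(nm) {
    subnetwork(net$layer_edges[[nm]], nm, nodes = net$layer_nodes[[nm]])
  })
  integrate_layers(subnets)
}

#' Define a seed set of genes of interest
#'
#' The seed set holds the known positive genes (for example curated growth
#' regulators) that anchor similarity features, training labels and
#' cross-validation.
#'
#' @param genes Character vector of gene identifiers.
#' @param name Label for the set.
#' @return Object of class `seed_set`: a character vector of unique genes
#'   with a `name` attribute.
#' @export
seed_set <- function(genes, name = "seeds") {
  genes <- unique(as.character(genes))
  if (length(genes) == 0) stop("seed set is empty")
  structure(sort(genes), name = name, class = "seed_set")
}

#' @export
print.seed_set <- function(x, ...) {
  cat(sprintf("<seed_set '%s': %d genes>\n", attr(x, "name"), length(x)))
  invisible(x)
}

#' Read a seed gene list from a plain-text file
#'
#' One gene identifier per line; `#` comments and blank lines ignored.
#'
#' @param path File path.
#' @param name Label for the set; defaults to the file name.
#' @return A [seed_set()].
#' @export
read_seed_list <- function(path, name = NULL) {
  if (!file.exists(path)) stop("seed-list file not found: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[!grepl("^(#|$)", lines)]
  seed_set(lines, name)
}

# seeds restricted to the network, warning about (or erroring on) absentees
match_seeds <- function(net, seeds, error_if_empty = TRUE) {
  present <- intersect(as.character(seeds), net$nodes)
  missing <- setdiff(as.character(seeds), net$nodes)
  if (length(missing) > 0)
    warning(sprintf(
      "%d seed gene(s) not present in the network were dropped", length(missing)
    ))
  if (error_if_empty && length(present) == 0)
    stop("no seed gene is present in the network")
  present
}

#' Serialize an integrated network to a JSON bundle
#'
#' Writes layer names and per-layer edge lists so the network can be
#' reconstructed exactly (multiplicities are recomputed on load).
#'
#' @param net A `multinet`.
#' @param path Output file path.
#' @export
write_network <- function(net, path) {
  bundle <- list(
    format = "netprior-multinet",
    version = 1L,
    nodes = net$nodes,
    layers = lapply(net$layers, function(nm) {
      e <- net$layer_edges[[nm]]
      list(name = nm, nodes = net$layer_nodes[[nm]],
           from = unname(e[, 1]), to = unname(e[, 2]))
    })
  )
  jsonlite::write_json(bundle, path, auto_unbox = TRUE)
  invisible(path)
}

#' Read an integrated network from a JSON bundle
#' @param path Path written by [write_network()].
#' @return A `multinet`.
#' @export
read_network <- function(path) {
  bundle <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(bundle$format, "netprior-multinet"))
    stop("not a netprior network bundle: ", path)
  subnets <- lapply(bundle$layers, function(lay) {
    subnetwork(
      cbind(unlist(lay$from), unlist(lay$to)),
      lay$name,
      nodes = unlist(lay$nodes)
    )
  })
  integrate_layers(subnets)
}
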