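TOPO_FEATURES <- c("degree", "betweenness", "closeness", "hub", "authority")
SEED_FEATURES <- c("direct_connections", "shared_neighbors", "jaccard",
                   "dice", "inv_log_weighted", "shortest_path_to_seeds")

#' Assemble the gene-by-feature matrix for model-based prioritization
#'
#' Joins the three feature groups into one table with a fixed, documented
#' column order: 5 general topological features, 6 seed-set similarity
#' features, and (when annotations are supplied) 24 GO-based similarity
#' features — 35 model features in total, or 11 without GO. Seed-dependent
#' features are computed against the supplied seed set with leave-self-out
#' handling for members; the `unannotated` flag rides along as metadata,
#' not as a model feature. Values are stored raw; scale-sensitive models
#' standardize internally at training time.
#'
#' @param net A `multinet`.
#' @param seeds A [seed_set()] or character vector.
#' @param ann A [go_annotation()], or `NULL` to skip GO features.
#' @param with_go Include the 24 GO features (requires `ann`).
#' @param go_method Test used for the `2 x k` enrichment tables (see
#'   [enrichment_similarity()]).
#' @param topo Optional precomputed result of [topo_features()] for this
#'   network (they do not depend on the seed set, so cross-validation
#'   loops reuse them).
#' @return Object of class `feature_matrix`: a data frame with `gene`,
#'   the feature columns, and `unannotated` when GO is enabled; the model
#'   feature names are in `attr(, "feature_cols")`.
#' @export
build_feature_matrix <- function(net, seeds, ann = NULL,
                                 with_go = !is.null(ann),
                                 go_method = "chisq",
                                 topo = NULL) {
  stopifnot(inherits(net, "multinet"))
  if (with_go && is.null(ann))
    stop("GO features requested but no annotation map supplied")
  if (is.null(topo)) topo <- topo_features(net)
  ss <- seed_sim_matrix(net, seeds)
  fm <- merge(topo, ss, by = "gene", sort = FALSE)
  cols <- c(TOPO_FEATURES, SEED_FEATURES)
  if (with_go) {
    gf <- go_feature_matrix(net, seeds, ann, method = go_method)
    fm <- merge(fm, gf, by = "gene", sort = FALSE)
    cols <- c(cols, go_measure_names())
  }
  fm <- fm[match(net$nodes, fm$gene), , drop = FALSE]
  rownames(fm) <- NULL
  if (any(!is.finite(as.matrix(fm[, cols]))))
    stop("internal error: non-finite feature values")
  attr(fm, "feature_cols") <- cols
  attr(fm, "with_go") <- with_go
  class(fm) <- c("feature_matrix", "data.frame")
  fm
}

#' Model feature column names of a feature matrix
#' @param fm A `feature_matrix`.
#' @param with_go If `FALSE`, restrict to the 11 topology-derived columns
#'   even when GO columns are present.
#' @return Character vector of column names.
#' @export
feature_cols <- function(fm, with_go = attr(fm, "with_go")) {
  cols <- attr(fm, "feature_cols")
  if (!isTRUE(with_go)) cols <- intersect(cols, c(TOPO_FEATURES, SEED_FEATURES))
  cols
}
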