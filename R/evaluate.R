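#' Rank statistics of held-out positives
#'
#' Summarizes a vector of held-out ranks with nearest-rank (type-1)
#' quantiles — the convention that always returns an observed integer
#' rank — plus the fraction of positives ranked within the first quartile
#' of the candidate list (threshold `floor(n_candidates / 4)`).
#'
#' @param ranks Integer vector of held-out ranks.
#' @param n_candidates Number of candidates ranked (scalar or per-rank
#'   vector).
#' @return One-row data frame: `n`, `min`, `q1`, `median`, `q3`, `max`,
#'   `iqr`, `pct_first_quartile`.
#' @export
rank_stats <- function(ranks, n_candidates) {
  ranks <- ranks[!is.na(ranks)]
  if (length(ranks) == 0)
    return(data.frame(n = 0L, min = NA, q1 = NA, median = NA, q3 = NA,
                      max = NA, iqr = NA, pct_first_quartile = NA))
  s <- sort(ranks)
  qt <- function(p) s[ceiling(p * length(s))]
  thresh <- floor(n_candidates / 4)
  data.frame(
    n = length(ranks),
    min = s[1],
    q1 = qt(0.25),
    median = qt(0.5),
    q3 = qt(0.75),
    max = s[length(s)],
    iqr = qt(0.75) - qt(0.25),
    pct_first_quartile = mean(ranks <= thresh)
  )
}

# rank the candidate genes (network genes minus training positives) from
# one fitted ranking and look up the held-out genes
heldout_ranks_from <- function(ranking, training_pos, heldout) {
  cand <- !(ranking$gene %in% training_pos)
  genes <- ranking$gene[cand]
  scores <- ranking$score[cand]
  r <- score_to_rank(genes, scores)
  list(
    ranks = r[match(heldout, genes)],
    n_candidates = length(genes)
  )
}

# cross-validation engine shared by loocv_rank() and kfold_rank():
# `folds` is a list of held-out seed-gene vectors
cv_engine <- function(net, seeds, ann, models, with_go, folds,
                      seed = 42L, params = list(), go_method = "chisq") {
  stopifnot(inherits(net, "multinet"))
  seeds <- match_seeds(net, seeds)
  models <- match.arg(models, c(MODEL_NAMES, "labelprop"), several.ok = TRUE)
  feature_models <- setdiff(models, "labelprop")
  if (length(feature_models) > 0 && is.null(ann) && any(with_go))
    stop("GO features requested but no annotation map supplied")
  need_go <- length(feature_models) > 0 && any(with_go)
  topo <- if (length(feature_models) > 0) topo_features(net) else NULL

  combos <- list()
  for (m in models) {
    if (m == "labelprop") {
      combos[[length(combos) + 1]] <- list(model = m, feature_set = "network", go = FALSE)
    } else {
      for (wg in unique(with_go)) {
        combos[[length(combos) + 1]] <- list(
          model = m,
          feature_set = if (wg) "with_go" else "without_go",
          go = wg
        )
      }
    }
  }

  rows <- list()
  n_failed <- 0L
  for (i in seq_along(folds)) {
    held <- folds[[i]]
    s_prime <- setdiff(seeds, held)
    res <- tryCatch({
      if (length(s_prime) < 1)
        stop("no training positives left in fold ", i)
      fm <- if (length(feature_models) > 0) {
        suppressWarnings(build_feature_matrix(
          net, s_prime, ann,
          with_go = need_go, go_method = go_method, topo = topo
        ))
      } else NULL
      fold_rows <- list()
      for (cb in combos) {
        ranking <- if (cb$model == "labelprop") {
          propagate_labels(net, s_prime)$ranking
        } else {
          suppressWarnings(train_and_rank(
            fm, s_prime, model = cb$model, with_go = cb$go,
            seed = seed + i, params = params
          ))$ranking
        }
        hr <- heldout_ranks_from(ranking, s_prime, held)
        fold_rows[[length(fold_rows) + 1]] <- data.frame(
          gene = held,
          rank = hr$ranks,
          n_candidates = hr$n_candidates,
          model = cb$model,
          feature_set = cb$feature_set,
          fold = i,
          row.names = NULL
        )
      }
      do.call(rbind, fold_rows)
    }, error = function(e) {
      warning(sprintf("fold %d failed and was excluded: %s", i, conditionMessage(e)))
      NULL
    })
    if (is.null(res)) n_failed <- n_failed + 1L else rows[[length(rows) + 1]] <- res
  }
  if (length(rows) == 0) stop("all cross-validation folds failed")
  ranks <- do.call(rbind, rows)
  stats <- do.call(rbind, lapply(split(ranks, list(ranks$model, ranks$feature_set), drop = TRUE),
    function(d) {
      cbind(
        data.frame(model = d$model[1], feature_set = d$feature_set[1]),
        rank_stats(d$rank, d$n_candidates)
      )
    }))
  rownames(stats) <- NULL
  structure(
    list(ranks = ranks, stats = stats, n_failed = n_failed),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result: %d held-out rank(s), %d failed fold(s)>\n",
              nrow(x$ranks), x$n_failed))
  print(x$stats)
  invisible(x)
}

#' Leave-one-out cross-validated prioritization
#'
#' For every seed gene: remove it from the seed set, recompute all
#' seed-dependent features against the reduced set, train the model with
#' the reduced positives, rank all candidate genes (everything except the
#' training positives — the held-out gene competes with all unknowns),
#' and record the held-out gene's rank. Rank statistics summarize the
#' resulting distribution.
#'
#' @param net A `multinet`.
#' @param seeds A [seed_set()] or character vector (>= 2 members in the
#'   network).
#' @param ann A [go_annotation()] (required when `with_go` is `TRUE`).
#' @param models Character vector of model names (see [train_and_rank()]),
#'   optionally including `"labelprop"` for the propagation baseline.
#' @param with_go Logical vector: evaluate with the full 35-feature set,
#'   the 11-feature topology-only set, or both (`c(TRUE, FALSE)`; the
#'   feature matrix is built once per fold and reused).
#' @param seed RNG seed; fold-level fits derive their seeds from it.
#' @param params Hyperparameters forwarded to [train_and_rank()].
#' @param go_method Enrichment-table test (see [enrichment_similarity()]).
#' @return Object of class `cv_result`: `ranks` (one row per held-out
#'   gene and method), `stats` (rank statistics per method and feature
#'   set) and `n_failed`.
#' @export
loocv_rank <- function(net, seeds, ann = NULL, models = "rf",
                       with_go = !is.null(ann), seed = 42L,
                       params = list(), go_method = "chisq") {
  seeds <- match_seeds(net, seeds)
  if (length(seeds) < 2) stop("need at least two seed genes for LOOCV")
  cv_engine(net, seeds, ann, models, with_go, as.list(seeds),
            seed = seed, params = params, go_method = go_method)
}

#' K-fold cross-validated prioritization
#'
#' Seeds are partitioned into `k` folds by a seeded RNG; per fold, all
#' held-out seeds are ranked against the candidates with the remaining
#' seeds as positives. With `k` equal to the number of seeds the fold
#' structure coincides with [loocv_rank()].
#'
#' @inheritParams loocv_rank
#' @param k Number of folds (at most the number of seeds).
#' @return A `cv_result`.
#' @export
kfold_rank <- function(net, seeds, ann = NULL, models = "rf", k = 10L,
                       with_go = !is.null(ann), seed = 42L,
                       params = list(), go_method = "chisq") {
  seeds <- match_seeds(net, seeds)
  k <- as.integer(k)
  if (k < 2) stop("k must be at least 2")
  if (k > length(seeds)) stop("k exceeds the number of seed genes")
  assignment <- with_local_seed(seed, sample(rep(seq_len(k), length.out = length(seeds))))
  folds <- split(seeds, assignment)
  cv_engine(net, seeds, ann, models, with_go, folds,
            seed = seed, params = params, go_method = go_method)
}

# pull one method's held-out rank table out of a cv_result
extract_cv_ranks <- function(x, model = NULL, feature_set = NULL) {
  if (is.numeric(x)) return(data.frame(gene = NA_character_, rank = x))
  stopifnot(inherits(x, "cv_result"))
  d <- x$ranks
  if (!is.null(model)) d <- d[d$model == model, , drop = FALSE]
  if (!is.null(feature_set)) d <- d[d$feature_set == feature_set, , drop = FALSE]
  if (length(unique(paste(d$model, d$feature_set))) > 1)
    stop("cv_result contains several methods; specify `model`/`feature_set`")
  d[, c("gene", "rank")]
}

#' Compare the held-out rank distributions of two methods
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test on the two held-out
#' rank lists (exact for small samples without ties, normal approximation
#' with tie correction otherwise), plus a paired per-gene rank table for
#' dot-plot export when both inputs carry gene identifiers.
#'
#' @param a,b `cv_result` objects (each restricted to one method, or
#'   disambiguated via `model_a` etc.) or plain numeric rank vectors.
#' @param model_a,feature_set_a,model_b,feature_set_b Optional selectors
#'   when a `cv_result` holds several methods.
#' @return List: `p_value`, `statistic` (Mann-Whitney U), `table` (merged
#'   per-gene ranks, or `NULL` for anonymous vectors).
#' @export
compare_rankings <- function(a, b, model_a = NULL, feature_set_a = NULL,
                             model_b = NULL, feature_set_b = NULL) {
  da <- extract_cv_ranks(a, model_a, feature_set_a)
  db <- extract_cv_ranks(b, model_b, feature_set_b)
  tab <- NULL
  if (!anyNA(da$gene) && !anyNA(db$gene)) {
    common <- intersect(da$gene, db$gene)
    if (length(common) < length(union(da$gene, db$gene)))
      warning("unequal gene coverage; comparing on the intersection")
    tab <- data.frame(
      gene = common,
      rank_a = da$rank[match(common, da$gene)],
      rank_b = db$rank[match(common, db$gene)],
      row.names = NULL
    )
    ra <- tab$rank_a
    rb <- tab$rank_b
  } else {
    ra <- da$rank
    rb <- db$rank
  }
  wt <- suppressWarnings(stats::wilcox.test(ra, rb))
  list(p_value = wt$p.value, statistic = unname(wt$statistic), table = tab)
}

#' Impact of removing each network layer on prioritization
#'
#' Re-integrates the network without each layer in turn, reruns the
#' leave-one-out evaluation, and reports rank statistics next to the
#' all-layers baseline (`layer_removed = "none"`). Seeds disconnected by
#' a removal are dropped by the reduced network with a warning and the
#' statistics cover the remaining folds.
#'
#' @inheritParams loocv_rank
#' @param model Single model name.
#' @return Data frame of rank statistics, one row per removed layer plus
#'   the baseline.
#' @export
leave_one_network_out <- function(net, seeds, ann = NULL, model = "rf",
                                  with_go = !is.null(ann), seed = 42L,
                                  params = list()) {
  stopifnot(inherits(net, "multinet"), length(model) == 1)
  run <- function(network, label) {
    cv <- loocv_rank(network, seeds, ann, models = model,
                     with_go = with_go, seed = seed, params = params)
    cbind(data.frame(layer_removed = label), cv$stats)
  }
  out <- list(run(net, "none"))
  for (layer in net$layers) {
    reduced <- drop_layer(net, layer)
    out[[length(out) + 1]] <- tryCatch(
      suppressWarnings(run(reduced, layer)),
      error = function(e) {
        warning(sprintf("evaluation without layer '%s' failed: %s",
                        layer, conditionMessage(e)))
        NULL
      }
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
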