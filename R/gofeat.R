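# ---- shared statistical primitives ------------------------------------

# two-sided Fisher exact P for the 2x2 table [[k1, n1-k1], [k2, n2-k2]]
# (counts of genes carrying a term / not carrying it, in two groups),
# summing hypergeometric point probabilities <= the observed one
fisher_p_2x2 <- function(k1, n1, k2, n2) {
  r1 <- n1
  r2 <- n2
  c1 <- k1 + k2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == r1 + r2) return(1)
  lo <- max(0, c1 - r2)
  hi <- min(r1, c1)
  x <- lo:hi
  d <- stats::dhyper(x, r1, r2, c1)
  pobs <- stats::dhyper(k1, r1, r2, c1)
  min(1, sum(d[d <= pobs * (1 + 1e-7)]))
}

# Pearson chi-square homogeneity P for a 2xk frequency table given as two
# count vectors; zero-sum columns dropped; degenerate tables (empty row,
# fewer than two informative columns) carry no evidence of dissimilarity
# and return 1
chisq_p_2xk <- function(row1, row2) {
  cs <- row1 + row2
  keep <- cs > 0
  row1 <- row1[keep]
  row2 <- row2[keep]
  t1 <- sum(row1)
  t2 <- sum(row2)
  kk <- length(row1)
  if (t1 == 0 || t2 == 0 || kk < 2) return(1)
  N <- t1 + t2
  cs <- row1 + row2
  e1 <- t1 * cs / N
  e2 <- t2 * cs / N
  stat <- sum((row1 - e1)^2 / e1) + sum((row2 - e2)^2 / e2)
  stats::pchisq(stat, df = kk - 1, lower.tail = FALSE)
}

# Monte-Carlo homogeneity P (tables simulated with fixed margins); RNG
# state is isolated so the surrounding analysis stays reproducible
montecarlo_p_2xk <- function(row1, row2, B = 100000L, mc_seed = 42L) {
  cs <- row1 + row2
  keep <- cs > 0
  row1 <- row1[keep]
  row2 <- row2[keep]
  if (sum(row1) == 0 || sum(row2) == 0 || length(row1) < 2) return(1)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(mc_seed)
  res <- suppressWarnings(
    stats::chisq.test(rbind(row1, row2), simulate.p.value = TRUE, B = B)
  )
  as.numeric(res$p.value)
}

# vectorized chi-square homogeneity P: fixed seed-side counts `row1`
# against one query-side count row per gene (matrix C, genes x k)
chisq_p_rows <- function(row1, C) {
  n <- nrow(C)
  k <- length(row1)
  if (k == 0) return(rep(1, n))
  t1 <- sum(row1)
  t2 <- rowSums(C)
  N <- t1 + t2
  R1 <- matrix(row1, n, k, byrow = TRUE)
  CS <- C + R1
  mask <- CS > 0
  E1 <- CS * (t1 / N)
  E2 <- CS * (t2 / N)
  term <- matrix(0, n, k)
  ok <- mask & E1 > 0
  term[ok] <- (R1[ok] - E1[ok])^2 / E1[ok] + (C[ok] - E2[ok])^2 / E2[ok]
  stat <- rowSums(term)
  df <- rowSums(mask) - 1
  p <- rep(1, n)
  valid <- t1 > 0 & t2 > 0 & df >= 1
  p[valid] <- stats::pchisq(stat[valid], df = df[valid], lower.tail = FALSE)
  p
}

jaccard_coef <- function(inter, size_a, size_b) {
  uni <- size_a + size_b - inter
  ifelse(uni > 0, inter / uni, 0)
}

go_measure_names <- function() {
  meas <- c(
    "go_overlap_neighbors", "go_overlap_self", "go_overlap_both",
    "go_fisher_top10", "go_fisher_top5", "go_fisher_top1"
  )
  unlist(lapply(tolower(GO_CATEGORIES), function(cat) paste0(meas, "_", cat)))
}

# ---- scalar operations ------------------------------------------------

# category-filtered term set of a gene vector
terms_of <- function(ann, genes, category) {
  sub <- if (category == "all") ann else ann[ann$namespace == category, , drop = FALSE]
  unique(sub$term[sub$gene %in% genes])
}

#' GO term-overlap similarity between a query gene and the seed set
#'
#' Jaccard coefficient between a category-filtered term set on the query
#' side and the union of the seed members' term sets. The query side is
#' the query's own terms (`mode = "self"`), the union of its first
#' neighbours' terms (`"neighbors"`), or both combined (`"both"`). The
#' query is excluded from the seed set for its own computation. An empty
#' intersection of empty sets is defined as 0.
#'
#' @param query Gene identifier (must be a network node).
#' @param seeds A [seed_set()] or character vector.
#' @param ann A [go_annotation()].
#' @param net A `multinet`.
#' @param mode One of `"neighbors"`, `"self"`, `"both"`.
#' @param category One of `"all"`, `"BP"`, `"CC"`, `"MF"`.
#' @return Jaccard overlap in `[0, 1]`.
#' @export
term_overlap <- function(query, seeds, ann, net,
                         mode = c("neighbors", "self", "both"),
                         category = "all") {
  mode <- match.arg(mode)
  category <- match.arg(category, GO_CATEGORIES)
  stopifnot(inherits(net, "multinet"), inherits(ann, "go_annotation"))
  if (!query %in% net$nodes) stop("query gene not in network: ", query)
  eff <- setdiff(match_seeds(net, seeds), query)
  seed_terms <- terms_of(ann, eff, category)
  nb <- igraph::neighbors(net$graph, query)$name
  q_genes <- switch(mode,
    self = query,
    neighbors = nb,
    both = c(query, nb)
  )
  q_terms <- terms_of(ann, q_genes, category)
  inter <- length(intersect(q_terms, seed_terms))
  jaccard_coef(inter, length(q_terms), length(seed_terms))
}

#' GO enrichment-profile similarity between a query gene and the seed set
#'
#' The terms most overrepresented in the seed set (one-sided
#' hypergeometric test against all annotated network genes in the
#' category; ties broken by term identifier) are selected; the top `k`
#' term frequencies among seed genes and among the query plus its first
#' neighbours form a two-way table whose Fisher-style homogeneity P-value
#' is returned as the similarity — the higher the P-value, the more alike
#' the two GO profiles. For `k = 1` the table is the exact 2x2
#' term/not-term layout; for `k > 1` a chi-square approximation is the
#' default, with a Monte-Carlo test (100,000 simulated tables) available.
#' Frequencies count genes carrying a term, restricted to annotated genes.
#'
#' @inheritParams term_overlap
#' @param k Number of top overrepresented terms (10, 5 or 1).
#' @param method Test for the `2 x k` table when `k > 1`: `"chisq"`
#'   (default) or `"montecarlo"`.
#' @return P-value in `(0, 1]` used as a similarity score.
#' @export
enrichment_similarity <- function(query, seeds, ann, net, k = 10,
                                  category = "all",
                                  method = c("chisq", "montecarlo")) {
  method <- match.arg(method)
  category <- match.arg(category, GO_CATEGORIES)
  stopifnot(inherits(net, "multinet"), inherits(ann, "go_annotation"))
  if (!query %in% net$nodes) stop("query gene not in network: ", query)
  k <- as.integer(k)
  eff <- setdiff(match_seeds(net, seeds), query)
  inc <- go_incidence(net, ann, category)
  sel <- enrichment_top_terms(inc, net$nodes %in% eff, k)
  if (length(sel$top) == 0) return(1)
  nb <- igraph::neighbors(net$graph, query)$name
  q_group <- intersect(c(query, nb), sel$ann_genes)
  row1 <- sel$k_t[sel$top]
  row2 <- as.numeric(Matrix::colSums(inc$M[match(q_group, net$nodes), sel$top, drop = FALSE]))
  if (k == 1) {
    fisher_p_2x2(row1, sel$n_s, row2, length(q_group))
  } else if (method == "chisq") {
    chisq_p_2xk(row1, row2)
  } else {
    montecarlo_p_2xk(row1, row2)
  }
}

# hypergeometric overrepresentation of seed terms against the annotated
# background; returns top-k column indices (ascending P, ties by term id)
enrichment_top_terms <- function(inc, seed_mask, k) {
  M <- inc$M
  anno <- as.numeric(Matrix::rowSums(M) > 0)
  inc$ann_genes <- rownames(M)[anno > 0]
  N <- sum(anno)
  seed_idx <- which(seed_mask)
  n_s <- sum(anno[seed_idx])
  if (ncol(M) == 0 || n_s == 0) {
    return(list(top = integer(), k_t = numeric(), n_s = n_s, ann_genes = inc$ann_genes))
  }
  k_t <- as.numeric(Matrix::colSums(M[seed_idx, , drop = FALSE]))
  K_t <- as.numeric(Matrix::colSums(M))
  relevant <- which(k_t > 0)
  if (length(relevant) == 0) {
    return(list(top = integer(), k_t = k_t, n_s = n_s, ann_genes = inc$ann_genes))
  }
  p <- stats::phyper(k_t[relevant] - 1, K_t[relevant], N - K_t[relevant],
                     n_s, lower.tail = FALSE)
  ord <- relevant[order(p, inc$terms[relevant])]
  list(
    top = utils::head(ord, k),
    k_t = k_t,
    n_s = n_s,
    ann_genes = inc$ann_genes
  )
}

#' All 24 GO-based similarity features for one query gene
#'
#' Six measures (three Jaccard term overlaps and three enrichment
#' similarities over the top 10/5/1 overrepresented terms) computed four
#' times: over all GO terms and within each namespace, yielding 24
#' features in a fixed column order (`all`, then `bp`, `cc`, `mf`). A
#' query with no annotation in any namespace receives the missing-value
#' policy — overlaps 0, enrichment similarities 1 — and is flagged by the
#' `unannotated` column.
#'
#' @inheritParams enrichment_similarity
#' @return One-row data frame: 24 feature columns plus `unannotated`.
#' @export
go_features <- function(query, seeds, ann, net, method = c("chisq", "montecarlo")) {
  method <- match.arg(method)
  vals <- numeric(0)
  for (cat in GO_CATEGORIES) {
    vals <- c(
      vals,
      term_overlap(query, seeds, ann, net, "neighbors", cat),
      term_overlap(query, seeds, ann, net, "self", cat),
      term_overlap(query, seeds, ann, net, "both", cat),
      enrichment_similarity(query, seeds, ann, net, 10, cat, method),
      enrichment_similarity(query, seeds, ann, net, 5, cat, method),
      enrichment_similarity(query, seeds, ann, net, 1, cat, method)
    )
  }
  names(vals) <- go_measure_names()
  unann <- !query %in% ann$gene
  if (unann) {
    warning("query gene has no GO annotation; missing-value policy applied: ", query)
    vals[grepl("overlap", names(vals))] <- 0
    vals[grepl("fisher", names(vals))] <- 1
  }
  out <- as.data.frame(as.list(vals))
  out$unannotated <- unann
  out
}

# ---- vectorized per-category block ------------------------------------

# 6 GO features for every network node in one category
go_category_block <- function(net, seed_genes, inc, method = "chisq") {
  nodes <- net$nodes
  n <- length(nodes)
  out <- matrix(rep(c(0, 0, 0, 1, 1, 1), each = n), n, 6)
  colnames(out) <- c("overlap_neighbors", "overlap_self", "overlap_both",
                     "fisher_top10", "fisher_top5", "fisher_top1")
  M <- inc$M
  if (ncol(M) == 0) return(out)
  anno <- as.numeric(Matrix::rowSums(M) > 0)
  N <- sum(anno)
  z <- as.numeric(nodes %in% seed_genes)
  seed_idx <- which(z > 0)
  n_s <- sum(anno[seed_idx])
  k_t <- as.numeric(Matrix::colSums(M[seed_idx, , drop = FALSE]))
  K_t <- as.numeric(Matrix::colSums(M))
  adj <- net$adj
  P <- adj + Matrix::Diagonal(n)
  NM <- P %*% M                       # counts of each term in {q} + neighbours
  n_q <- as.numeric(P %*% anno)       # annotated genes in {q} + neighbours

  # term-overlap features (Jaccard against the seed term union)
  s_ind <- as.numeric(k_t > 0)
  nsb <- sum(s_ind)
  Un <- adj %*% M
  Un@x[] <- 1
  NMb <- NM
  NMb@x[] <- 1
  inter_self <- as.numeric(M %*% s_ind)
  inter_nb <- as.numeric(Un %*% s_ind)
  inter_both <- as.numeric(NMb %*% s_ind)
  out[, "overlap_self"] <- jaccard_coef(inter_self, Matrix::rowSums(M), nsb)
  out[, "overlap_neighbors"] <- jaccard_coef(inter_nb, Matrix::rowSums(Un), nsb)
  out[, "overlap_both"] <- jaccard_coef(inter_both, Matrix::rowSums(NMb), nsb)

  if (n_s > 0 && any(k_t > 0)) {
    relevant <- which(k_t > 0)
    p <- stats::phyper(k_t[relevant] - 1, K_t[relevant], N - K_t[relevant],
                       n_s, lower.tail = FALSE)
    ord <- relevant[order(p, inc$terms[relevant])]
    top10 <- utils::head(ord, 10)
    top5 <- utils::head(ord, 5)
    top1 <- ord[1]
    C10 <- as.matrix(NM[, top10, drop = FALSE])
    if (method == "chisq") {
      out[, "fisher_top10"] <- chisq_p_rows(k_t[top10], C10)
      out[, "fisher_top5"] <- chisq_p_rows(k_t[top5],
                                           C10[, seq_along(top5), drop = FALSE])
    } else {
      for (g in seq_len(n)) {
        out[g, "fisher_top10"] <- montecarlo_p_2xk(k_t[top10], C10[g, ])
        out[g, "fisher_top5"] <- montecarlo_p_2xk(k_t[top5], C10[g, seq_along(top5)])
      }
    }
    m1 <- as.numeric(NM[, top1])
    key <- paste(m1, n_q)
    uk <- !duplicated(key)
    pv <- vapply(which(uk), function(i) {
      fisher_p_2x2(k_t[top1], n_s, m1[i], n_q[i])
    }, numeric(1))
    out[, "fisher_top1"] <- pv[match(key, key[uk])]
  }

  # leave-self-out: a seed member's features are computed against the
  # remaining members
  for (q in seed_idx) {
    Mq <- as.numeric(M[q, ])
    k_t_q <- k_t - Mq
    n_s_q <- n_s - anno[q]
    if (n_s_q == 0 || all(k_t_q == 0)) {
      out[q, ] <- c(0, 0, 0, 1, 1, 1)
      next
    }
    s_ind_q <- as.numeric(k_t_q > 0)
    nsb_q <- sum(s_ind_q)
    out[q, "overlap_self"] <- jaccard_coef(sum(Mq * s_ind_q), sum(Mq), nsb_q)
    un_q <- as.numeric(Un[q, ])
    out[q, "overlap_neighbors"] <- jaccard_coef(sum(un_q * s_ind_q), sum(un_q), nsb_q)
    nmb_q <- as.numeric(NMb[q, ])
    out[q, "overlap_both"] <- jaccard_coef(sum(nmb_q * s_ind_q), sum(nmb_q), nsb_q)
    rel_q <- which(k_t_q > 0)
    p_q <- stats::phyper(k_t_q[rel_q] - 1, K_t[rel_q], N - K_t[rel_q],
                         n_s_q, lower.tail = FALSE)
    ord_q <- rel_q[order(p_q, inc$terms[rel_q])]
    row2_q <- as.numeric(NM[q, utils::head(ord_q, 10)])
    row1_q <- k_t_q[utils::head(ord_q, 10)]
    if (method == "chisq") {
      out[q, "fisher_top10"] <- chisq_p_2xk(row1_q, row2_q)
      out[q, "fisher_top5"] <- chisq_p_2xk(utils::head(row1_q, 5), utils::head(row2_q, 5))
    } else {
      out[q, "fisher_top10"] <- montecarlo_p_2xk(row1_q, row2_q)
      out[q, "fisher_top5"] <- montecarlo_p_2xk(utils::head(row1_q, 5), utils::head(row2_q, 5))
    }
    out[q, "fisher_top1"] <- fisher_p_2x2(row1_q[1], n_s_q, row2_q[1], n_q[q])
  }
  out
}

#' All 24 GO-based similarity features for every gene
#'
#' Vectorized equivalent of [go_features()] over all network nodes; seed
#' members are computed with leave-self-out seed sets.
#'
#' @param net A `multinet`.
#' @param seeds A [seed_set()] or character vector.
#' @param ann A [go_annotation()].
#' @param method Test for the `2 x k` tables with `k > 1` (see
#'   [enrichment_similarity()]).
#' @return Data frame: `gene`, 24 feature columns in the documented order,
#'   and the logical `unannotated` flag.
#' @export
go_feature_matrix <- function(net, seeds, ann, method = c("chisq", "montecarlo")) {
  method <- match.arg(method)
  stopifnot(inherits(net, "multinet"), inherits(ann, "go_annotation"))
  seed_genes <- match_seeds(net, seeds)
  blocks <- lapply(GO_CATEGORIES, function(cat) {
    go_category_block(net, seed_genes, go_incidence(net, ann, cat), method)
  })
  vals <- do.call(cbind, blocks)
  colnames(vals) <- go_measure_names()
  unann <- !net$nodes %in% ann$gene
  if (any(unann)) {
    vals[unann, grepl("overlap", colnames(vals))] <- 0
    vals[unann, grepl("fisher", colnames(vals))] <- 1
  }
  out <- data.frame(gene = net$nodes, vals, row.names = NULL,
                    check.names = FALSE)
  out$unannotated <- unann
  out
}
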