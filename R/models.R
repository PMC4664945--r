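MODEL_NAMES <- c("nb", "lda", "svm", "glmnet", "rf", "gbm")

`%||%` <- function(a, b) if (is.null(a)) b else a

# stable ranking: higher score first, ties broken by gene identifier
score_to_rank <- function(gene, score) {
  ord <- order(-score, gene, method = "radix")
  rank <- integer(length(score))
  rank[ord] <- seq_along(ord)
  rank
}

#' Train a two-class ranker and score all genes
#'
#' Frames prioritization as binary classification: seed genes form the
#' positive class, every other gene the "negative and unknown" class. The
#' chosen model is fitted on all genes and each gene is scored by its
#' positive-class score; ranks are assigned by descending score with ties
#' broken by gene identifier. Because positives are rare, all models are
#' fitted with class weights (or balanced priors) inversely proportional
#' to class frequency. Scale-sensitive models (`nb`, `lda`, `svm`,
#' `glmnet`) standardize features internally; tree ensembles (`rf`,
#' `gbm`) use them raw. Zero-variance features are dropped with a
#' warning.
#'
#' Models: `nb` naive Bayes, `lda` linear discriminant analysis, `svm`
#' RBF-kernel support vector machine (cost tuned over `{0.1, 1, 10}` by
#' internal 3-fold cross-validation unless fixed via `params$cost`),
#' `glmnet` elastic-net logistic regression (lambda by internal
#' cross-validation), `rf` random forest, `gbm` gradient-boosted trees.
#'
#' @param fm A [build_feature_matrix()] result.
#' @param positives A [seed_set()] or character vector of positive genes.
#' @param model One of `"nb"`, `"lda"`, `"svm"`, `"glmnet"`, `"rf"`,
#'   `"gbm"`.
#' @param with_go Use the full feature set or only the 11 topology-derived
#'   features.
#' @param seed RNG seed controlling every stochastic step of the fit.
#' @param params Named list of model hyperparameters
#'   (`cost`, `gamma`, `alpha`, `ntree`, `nrounds`, `max_depth`, `eta`).
#' @return Object of class `ranking_result`: list with `method`,
#'   `ranking` (data frame `gene`, `score`, `rank`), `feature_set` and
#'   `params`.
#' @export
train_and_rank <- function(fm, positives, model = "rf",
                           with_go = attr(fm, "with_go"),
                           seed = 42L, params = list()) {
  model <- match.arg(model, MODEL_NAMES)
  pos <- intersect(as.character(positives), fm$gene)
  if (length(pos) < 1) stop("no positive gene present in the matrix")
  cols <- feature_cols(fm, with_go = with_go)
  x <- as.matrix(fm[, cols, drop = FALSE])
  rownames(x) <- fm$gene
  y <- factor(ifelse(fm$gene %in% pos, "pos", "neg"), levels = c("neg", "pos"))

  keep <- apply(x, 2L, function(col) stats::sd(col) > 0)
  if (!all(keep)) {
    warning("dropping zero-variance feature(s): ",
            paste(colnames(x)[!keep], collapse = ", "))
    x <- x[, keep, drop = FALSE]
  }
  if (ncol(x) == 0) stop("no informative features left for model ", model)
  score <- with_local_seed(seed, fit_and_score(model, x, y, params))
  structure(
    list(
      method = model,
      ranking = data.frame(
        gene = fm$gene,
        score = as.numeric(score),
        rank = score_to_rank(fm$gene, as.numeric(score)),
        row.names = NULL
      ),
      feature_set = if (isTRUE(with_go)) "with_go" else "without_go",
      params = params
    ),
    class = "ranking_result"
  )
}

#' @export
print.ranking_result <- function(x, ...) {
  cat(sprintf("<ranking_result '%s' (%s): %d genes>\n",
              x$method, x$feature_set, nrow(x$ranking)))
  invisible(x)
}

fit_and_score <- function(model, x, y, params) {
  n_pos <- sum(y == "pos")
  n_neg <- sum(y == "neg")
  w_pos <- n_neg / n_pos
  switch(model,
    nb = {
      xs <- scale(x)
      # class-conditional zero variance breaks the Gaussian likelihoods
      ok <- apply(xs, 2L, function(col) {
        stats::sd(col[y == "pos"]) > 0 && stats::sd(col[y == "neg"]) > 0
      })
      if (!any(ok)) stop("naive Bayes: no feature varies within both classes")
      if (!all(ok))
        warning("naive Bayes: dropping feature(s) constant within a class: ",
                paste(colnames(xs)[!ok], collapse = ", "))
      fit <- e1071::naiveBayes(xs[, ok, drop = FALSE], y)
      predict(fit, xs[, ok, drop = FALSE], type = "raw")[, "pos"]
    },
    lda = {
      xs <- scale(x)
      fit <- MASS::lda(xs, grouping = y, prior = c(0.5, 0.5))
      predict(fit, xs)$posterior[, "pos"]
    },
    svm = {
      xs <- scale(x)
      cost <- params$cost %||% svm_tune_cost(xs, y, w_pos,
                                             gamma = params$gamma,
                                             costs = c(0.1, 1, 10))
      dv <- svm_decision(xs, y, cost, params$gamma, w_pos, xs)
      dv
    },
    glmnet = {
      xs <- scale(x)
      w <- ifelse(y == "pos", w_pos, 1)
      cv <- glmnet::cv.glmnet(xs, y, family = "binomial", weights = w,
                              alpha = params$alpha %||% 1, nfolds = 5)
      as.numeric(predict(cv, xs, s = "lambda.min", type = "link"))
    },
    rf = {
      fit <- randomForest::randomForest(
        x, y,
        ntree = params$ntree %||% 500L,
        classwt = c(neg = 1, pos = w_pos)
      )
      predict(fit, x, type = "prob")[, "pos"]
    },
    gbm = {
      dtrain <- xgboost::xgb.DMatrix(x, label = as.numeric(y == "pos"))
      fit <- xgboost::xgb.train(
        params = list(
          objective = "binary:logistic",
          max_depth = params$max_depth %||% 3L,
          eta = params$eta %||% 0.1,
          scale_pos_weight = w_pos,
          nthread = 1L
        ),
        data = dtrain,
        nrounds = params$nrounds %||% 100L,
        verbose = 0
      )
      predict(fit, x)
    }
  )
}

# decision values of an RBF SVM oriented so that larger = more positive
svm_decision <- function(xtr, ytr, cost, gamma, w_pos, xte) {
  args <- list(
    x = xtr, y = ytr, kernel = "radial", cost = cost, scale = FALSE,
    class.weights = c(neg = 1, pos = w_pos)
  )
  if (!is.null(gamma)) args$gamma <- gamma
  fit <- do.call(e1071::svm, args)
  dv <- attr(predict(fit, xte, decision.values = TRUE), "decision.values")[, 1]
  tr_dv <- attr(predict(fit, xtr, decision.values = TRUE), "decision.values")[, 1]
  if (mean(tr_dv[ytr == "pos"]) < mean(tr_dv[ytr == "neg"])) dv <- -dv
  dv
}

# pick the SVM cost maximizing AUC in stratified 3-fold CV
svm_tune_cost <- function(x, y, w_pos, gamma = NULL, costs = c(0.1, 1, 10)) {
  folds <- integer(length(y))
  folds[y == "pos"] <- sample(rep(1:3, length.out = sum(y == "pos")))
  folds[y == "neg"] <- sample(rep(1:3, length.out = sum(y == "neg")))
  auc_for <- function(cost) {
    mean(vapply(1:3, function(f) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2 || sum(y[!tr] == "pos") == 0) return(0.5)
      dv <- svm_decision(x[tr, , drop = FALSE], y[tr], cost, gamma, w_pos,
                         x[!tr, , drop = FALSE])
      yte <- y[!tr]
      r <- rank(dv)
      n1 <- sum(yte == "pos")
      n0 <- sum(yte == "neg")
      (sum(r[yte == "pos"]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    }, numeric(1)))
  }
  perf <- vapply(costs, auc_for, numeric(1))
  costs[which.max(perf)]
}

#' Aggregate several model rankings into one consensus ranking
#'
#' Keeps only the methods whose top `top_n` genes contain at least
#' `purity_threshold` known positives, unions the surviving methods' top
#' lists, and orders the union by the sum of per-method ranks (ties by
#' gene identifier).
#'
#' @param results List of `ranking_result` objects.
#' @param known A [seed_set()] or character vector of known positives.
#' @param top_n Depth of each method's top list.
#' @param purity_threshold Minimum fraction of known positives in a
#'   method's top list for it to enter the consensus.
#' @return Data frame `gene`, `rank_sum`, `rank`, with attribute
#'   `purities` (named per-method purity) and `methods_kept`.
#' @export
aggregate_rankings <- function(results, known, top_n = 200L,
                               purity_threshold = 0.25) {
  if (inherits(results, "ranking_result")) results <- list(results)
  stopifnot(all(vapply(results, inherits, logical(1), "ranking_result")))
  known <- as.character(known)
  labels <- vapply(results, function(r) paste(r$method, r$feature_set, sep = "/"),
                   character(1))
  top_sets <- lapply(results, function(r) {
    r$ranking$gene[r$ranking$rank <= top_n]
  })
  purity <- vapply(top_sets, function(g) mean(g %in% known), numeric(1))
  names(purity) <- labels
  keep <- purity >= purity_threshold
  if (!any(keep))
    stop("no method passes the purity filter; purities: ",
         paste(sprintf("%s=%.3f", labels, purity), collapse = ", "))
  union_genes <- sort(unique(unlist(top_sets[keep])))
  rank_mat <- matrix(
    unlist(lapply(results[keep], function(r) {
      r$ranking$rank[match(union_genes, r$ranking$gene)]
    })),
    nrow = length(union_genes)
  )
  rank_sum <- rowSums(rank_mat)
  ord <- order(rank_sum, union_genes, method = "radix")
  out <- data.frame(
    gene = union_genes[ord],
    rank_sum = rank_sum[ord],
    rank = seq_along(ord),
    row.names = NULL
  )
  attr(out, "purities") <- purity
  attr(out, "methods_kept") <- labels[keep]
  out
}
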