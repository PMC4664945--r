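test_that("rank statistics use nearest-rank quantiles", {
  set.seed(801)
  for (rep in 1:10) {
    ranks <- sample(1:5000, sample(5:40, 1))
    st <- rank_stats(ranks, n_candidates = 5000)
    expect_equal(st$min, min(ranks))
    expect_equal(st$max, max(ranks))
    expect_equal(st$q1, unname(quantile(ranks, 0.25, type = 1)))
    expect_equal(st$median, unname(quantile(ranks, 0.5, type = 1)))
    expect_equal(st$q3, unname(quantile(ranks, 0.75, type = 1)))
    expect_equal(st$iqr, st$q3 - st$q1)
    expect_equal(st$pct_first_quartile, mean(ranks <= floor(5000 / 4)))
  }
})

# shared small benchmark for the cross-validation tests
cv_fixture <- function(seed = 41) {
  dat <- synth_generate(synth_config(
    n_genes = 150, n_layers = 2, n_seeds = 8, p_background = 0.03,
    seed_multiplier = 10, n_go_terms = 12, n_enriched_terms = 3,
    enrichment_odds = 8, seed = seed
  ))
  list(dat = dat, net = integrate_layers(dat$subnets))
}

test_that("LOOCV executes one fold per seed and finds a separable module", {
  fx <- cv_fixture()
  two <- as.character(fx$dat$seeds)[1:2]
  cv2 <- suppressWarnings(loocv_rank(fx$net, two, models = "lda", seed = 1))
  expect_equal(nrow(cv2$ranks), 2)
  expect_equal(sort(unique(cv2$ranks$fold)), 1:2)

  cv <- suppressWarnings(
    loocv_rank(fx$net, fx$dat$seeds, fx$dat$ann, models = "rf", seed = 1)
  )
  expect_equal(nrow(cv$ranks), length(fx$dat$seeds))
  expect_equal(unique(cv$ranks$n_candidates), 150 - 8 + 1)
  expect_lt(cv$stats$median, 0.25 * unique(cv$ranks$n_candidates))
})

test_that("k-fold partitions are seeded and reproducible, k = |S| matches LOOCV folds", {
  fx <- cv_fixture()
  seeds <- fx$dat$seeds
  a <- suppressWarnings(kfold_rank(fx$net, seeds, models = "lda", k = 4, seed = 2))
  b <- suppressWarnings(kfold_rank(fx$net, seeds, models = "lda", k = 4, seed = 2))
  expect_identical(a$ranks, b$ranks)
  expect_identical(a$stats, b$stats)
  loo_like <- suppressWarnings(kfold_rank(fx$net, seeds, models = "lda",
                                          k = length(seeds), seed = 2))
  expect_equal(sort(table(loo_like$ranks$fold)), sort(table(1:length(seeds))),
               ignore_attr = TRUE)
  expect_error(kfold_rank(fx$net, seeds, models = "lda", k = 99), "exceeds")
})

test_that("method comparison runs a Mann-Whitney test and pairs genes", {
  same <- compare_rankings(c(5, 9, 2, 14, 7), c(5, 9, 2, 14, 7))
  expect_gt(same$p_value, 0.99)
  far <- compare_rankings(1:20, 1001:1020)
  expect_lt(far$p_value, 1e-6)

  fx <- cv_fixture()
  cv <- suppressWarnings(
    loocv_rank(fx$net, fx$dat$seeds, models = c("lda", "labelprop"), seed = 3)
  )
  cmp <- compare_rankings(cv, cv, model_a = "lda", model_b = "lda")
  expect_equal(cmp$table$rank_a, cmp$table$rank_b)  # self-comparison: diagonal
  cmp2 <- compare_rankings(cv, cv, model_a = "lda", model_b = "labelprop")
  expect_equal(nrow(cmp2$table), length(fx$dat$seeds))
  expect_error(compare_rankings(cv, cv), "several")
})

test_that("held-out ranks do not depend on the ordering of the remaining seeds", {
  fx <- cv_fixture()
  seeds <- as.character(fx$dat$seeds)
  held <- seeds[1]
  net <- fx$net
  topo <- topo_features(net)
  rank_with <- function(order_of_rest) {
    fm <- build_feature_matrix(net, order_of_rest, topo = topo)
    r <- train_and_rank(fm, order_of_rest, "lda", seed = 4)
    hr <- netprior:::heldout_ranks_from(r$ranking, order_of_rest, held)
    hr$ranks
  }
  rest <- seeds[-1]
  expect_equal(rank_with(rest), rank_with(rev(rest)))
})

test_that("layer ablation leaves duplicate layers' results unchanged", {
  fx <- cv_fixture(seed = 43)
  # two identical copies of one layer: removing one rescales degree-type
  # features uniformly, which standardized LDA cannot see
  lay <- fx$dat$subnets[[1]]
  net <- integrate_layers(list(
    subnetwork(lay$edges, "A", nodes = lay$nodes),
    subnetwork(lay$edges, "B", nodes = lay$nodes)
  ))
  res <- suppressWarnings(suppressMessages(
    leave_one_network_out(net, fx$dat$seeds, model = "lda", seed = 5)
  ))
  base <- res[res$layer_removed == "none", -1]
  dropA <- res[res$layer_removed == "A", -1]
  expect_equal(base$median, dropA$median)
  expect_equal(base$q1, dropA$q1)
  expect_equal(base$pct_first_quartile, dropA$pct_first_quartile)
})

test_that("removing the only informative layer degrades the ranking", {
  dat <- synth_generate(synth_config(
    n_genes = 150, n_layers = 3, n_seeds = 10, p_background = 0.03,
    seed_multiplier = 12, uninformative_layer = FALSE, seed = 44
  ))
  # layers 1-2 informative, build a third pure-noise layer
  noise <- synth_generate(synth_config(
    n_genes = 150, n_layers = 1, n_seeds = 10, p_background = 0.03,
    seed_multiplier = 1, seed = 45
  ))$subnets[[1]]
  noise$name <- "noise"
  net <- integrate_layers(c(dat$subnets[1:2], list(noise)))
  res <- suppressWarnings(suppressMessages(
    leave_one_network_out(net, dat$seeds, model = "lda", seed = 6)
  ))
  med <- setNames(res$median, res$layer_removed)
  # dropping the noise layer hurts no more than dropping a signal layer
  expect_lte(med[["noise"]], max(med[c("layer1", "layer2")]))
})
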