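# line graph s1-s2-q-v plus annotations used across the scalar examples
go_toy <- function() {
  net <- net_from_layers(list(edge_mat("s1", "s2", "s2", "q", "q", "v")))
  ann <- go_annotation(
    gene = c("s1", "s1", "s2", "s2", "q", "q", "v"),
    term = c("t2", "t3", "t3", "t4", "t1", "t2", "t5"),
    namespace = "BP"
  )
  list(net = net, ann = ann)
}

test_that("term overlap is the Jaccard of the category term sets", {
  toy <- go_toy()
  seeds <- seed_set(c("s1", "s2"))
  # query terms {t1,t2}; seed terms {t2,t3,t4} -> intersection 1, union 4
  expect_equal(term_overlap("q", seeds, toy$ann, toy$net, "self", "BP"), 1 / 4)
  expect_equal(term_overlap("q", seeds, toy$ann, toy$net, "self", "all"), 1 / 4)
  # neighbours of q are {s2, v}: terms {t3,t4,t5} -> intersection 2, union 4
  expect_equal(term_overlap("q", seeds, toy$ann, toy$net, "neighbors", "BP"), 2 / 4)
  # both: {t1..t5} vs {t2,t3,t4}
  expect_equal(term_overlap("q", seeds, toy$ann, toy$net, "both", "BP"), 3 / 5)
  # CC category is empty on both sides -> defined as 0
  expect_equal(term_overlap("q", seeds, toy$ann, toy$net, "self", "CC"), 0)
})

test_that("term overlap reaches its bounds on identical and disjoint annotations", {
  net <- net_from_layers(list(edge_mat("q", "s")))
  ann_same <- go_annotation(c("q", "q", "s", "s"), c("t1", "t2", "t1", "t2"), "MF")
  expect_equal(term_overlap("q", seed_set("s"), ann_same, net, "self", "MF"), 1)
  ann_disj <- go_annotation(c("q", "s"), c("t1", "t2"), "MF")
  expect_equal(term_overlap("q", seed_set("s"), ann_disj, net, "self", "MF"), 0)
})

test_that("enrichment similarity returns exact 2x2 Fisher P-values", {
  # 10 seeds all carry TA; query and its 9 neighbours carry TB only:
  # top-1 table [[10, 0], [0, 10]]
  seeds <- sprintf("s%02d", 1:10)
  others <- sprintf("q%02d", 1:9)
  edges <- rbind(
    cbind("q", others),
    cbind(seeds[1], seeds[-1])
  )
  net <- net_from_layers(list(edges))
  ann <- go_annotation(
    gene = c(seeds, "q", others),
    term = c(rep("TA", 10), rep("TB", 10)),
    namespace = "BP"
  )
  p <- enrichment_similarity("q", seed_set(seeds), ann, net, k = 1, category = "BP")
  oracle <- stats::fisher.test(matrix(c(10, 0, 0, 10), 2, byrow = TRUE))$p.value
  expect_equal(p, oracle, tolerance = 1e-10)
  expect_equal(p, 1.082509e-05, tolerance = 1e-4)

  # proportional profiles are maximally similar
  ann2 <- go_annotation(
    gene = c(seeds, "q", others),
    term = c(rep(c("TA", "TB"), each = 5), rep(c("TA", "TB"), each = 5)),
    namespace = "BP"
  )
  p2 <- enrichment_similarity("q", seed_set(seeds), ann2, net, k = 1, category = "BP")
  expect_equal(p2, 1)
})

test_that("exact 2x2 P-values match fisher.test on random tables", {
  set.seed(501)
  for (rep in 1:25) {
    n1 <- sample(1:50, 1)
    n2 <- sample(1:50, 1)
    k1 <- sample(0:n1, 1)
    k2 <- sample(0:n2, 1)
    mine <- netprior:::fisher_p_2x2(k1, n1, k2, n2)
    tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), 2, byrow = TRUE)
    if (sum(tab) == 0) next
    expect_equal(mine, stats::fisher.test(tab)$p.value, tolerance = 1e-10,
                 info = paste(k1, n1, k2, n2))
  }
})

test_that("2xk homogeneity approximations agree with chisq.test and behave at the degenerate limits", {
  set.seed(502)
  for (rep in 1:10) {
    row1 <- rpois(6, 4)
    row2 <- rpois(6, 4)
    if (sum(row1) == 0 || sum(row2) == 0) next
    keep <- (row1 + row2) > 0
    if (sum(keep) < 2) next
    mine <- netprior:::chisq_p_2xk(row1, row2)
    oracle <- suppressWarnings(
      stats::chisq.test(rbind(row1[keep], row2[keep]), correct = FALSE)$p.value
    )
    expect_equal(mine, oracle, tolerance = 1e-10)
  }
  expect_equal(netprior:::chisq_p_2xk(c(0, 0), c(0, 0)), 1)
  expect_equal(netprior:::chisq_p_2xk(c(4, 2), c(0, 0)), 1)
  expect_equal(netprior:::chisq_p_2xk(c(4, 2), c(8, 4)), 1)  # proportional
  # Monte-Carlo variant is reproducible and close to the exact tail
  p1 <- netprior:::montecarlo_p_2xk(c(9, 1, 1), c(1, 9, 9))
  p2 <- netprior:::montecarlo_p_2xk(c(9, 1, 1), c(1, 9, 9))
  expect_equal(p1, p2)
  expect_lt(p1, 0.05)
})

test_that("top-term selection is deterministic and nested", {
  dat <- synth_generate(synth_config(
    n_genes = 200, n_layers = 2, n_seeds = 15, p_background = 0.02,
    seed_multiplier = 5, n_go_terms = 20, n_enriched_terms = 4,
    enrichment_odds = 6, seed = 3
  ))
  net <- integrate_layers(dat$subnets)
  inc <- netprior:::go_incidence(net, dat$ann, "BP")
  mask <- net$nodes %in% dat$seeds
  top10 <- netprior:::enrichment_top_terms(inc, mask, 10)$top
  top5 <- netprior:::enrichment_top_terms(inc, mask, 5)$top
  top1 <- netprior:::enrichment_top_terms(inc, mask, 1)$top
  expect_identical(top5, top10[1:5])
  expect_identical(top1, top10[1])
  expect_identical(top10, netprior:::enrichment_top_terms(inc, mask, 10)$top)
  # planted enriched terms dominate the top of the list
  expect_true(any(inc$terms[top5] %in% dat$truth$enriched_terms$BP))
})

test_that("go_features emits 24 values and applies the missing-value policy", {
  toy <- go_toy()
  seeds <- seed_set(c("s1", "s2"))
  gf <- suppressWarnings(go_features("q", seeds, toy$ann, toy$net))
  expect_equal(sum(grepl("^go_", names(gf))), 24)
  expect_false(gf$unannotated)

  # v's neighbour q is annotated, but the policy zeroes everything for an
  # unannotated query
  net2 <- net_from_layers(list(edge_mat("q", "s", "q", "u")), nodes = c("q", "s", "u"))
  ann2 <- go_annotation(c("q", "s"), c("t1", "t1"), "BP")
  expect_warning(go_features("u", seed_set("s"), ann2, net2), "missing-value")
  gf2 <- suppressWarnings(go_features("u", seed_set("s"), ann2, net2))
  vals <- unlist(gf2[grepl("^go_", names(gf2))])
  expect_equal(unname(vals[grepl("overlap", names(vals))]), rep(0, 12))
  expect_equal(unname(vals[grepl("fisher", names(vals))]), rep(1, 12))
  expect_true(gf2$unannotated)
})

test_that("fully shared annotations drive all twelve overlap features to one", {
  net <- net_from_layers(list(edge_mat("q", "s1", "q", "s2")))
  genes <- c("q", "s1", "s2")
  ann <- go_annotation(
    gene = rep(genes, times = 3),
    term = rep(c("tb", "tc", "tm"), each = 3),
    namespace = rep(c("BP", "CC", "MF"), each = 3)
  )
  gf <- go_features("q", seed_set(c("s1", "s2")), ann, net)
  ov <- unlist(gf[grepl("overlap", names(gf))])
  expect_equal(unname(ov), rep(1, 12))
})

test_that("vectorized GO features agree with the scalar path, including seed members", {
  dat <- synth_generate(synth_config(
    n_genes = 120, n_layers = 2, n_seeds = 10, p_background = 0.03,
    seed_multiplier = 6, n_go_terms = 12, n_enriched_terms = 3,
    enrichment_odds = 6, seed = 17
  ))
  net <- integrate_layers(dat$subnets)
  mat <- go_feature_matrix(net, dat$seeds, dat$ann)
  set.seed(18)
  queries <- c(sample(setdiff(net$nodes, dat$seeds), 4), sample(as.character(dat$seeds), 3))
  for (q in queries) {
    gf <- suppressWarnings(go_features(q, dat$seeds, dat$ann, net))
    row <- mat[mat$gene == q, ]
    for (col in grep("^go_", names(gf), value = TRUE))
      expect_equal(row[[col]], gf[[col]], tolerance = 1e-10,
                   info = paste(q, col))
    expect_equal(row$unannotated, gf$unannotated)
  }
})

test_that("annotation readers parse GAF and TSV formats", {
  gaf_row <- function(gene, term, aspect) {
    paste(c("DB", gene, gene, "", term, "REF", "IEA", "", aspect,
            "", "", "protein", "taxon:3702", "20240101", "DB", "", ""),
          collapse = "\t")
  }
  f <- withr::local_tempfile(lines = c(
    "!gaf-version: 2.1",
    gaf_row("g1", "GO:0001", "P"),
    gaf_row("g1", "GO:0002", "F"),
    gaf_row("g2", "GO:0001", "P")
  ))
  ann <- read_gaf(f)
  expect_equal(nrow(ann), 3)
  expect_setequal(ann$namespace[ann$term == "GO:0001"], "BP")
  expect_equal(ann$namespace[ann$term == "GO:0002"], "MF")

  f2 <- withr::local_tempfile(lines = c("g1\tGO:0001\tBP", "g2\tGO:0003\tCC"))
  ann2 <- read_go_tsv(f2)
  expect_equal(ann2$namespace, c("BP", "CC"))
  f3 <- withr::local_tempfile(lines = c("g1\tGO:0001", "g2\tGO:0003"))
  ann3 <- read_go_tsv(f3, namespace = "MF")
  expect_equal(unique(ann3$namespace), "MF")
})
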