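test_that("edge-list reader deduplicates, drops self-loops and flags bad lines", {
  f <- withr::local_tempfile(lines = c("# comment", "g1 g2", "g2\tg1", "g3 g3"))
  expect_warning(read_edge_list(f, "L1"), "self-loop")
  sn <- suppressWarnings(read_edge_list(f, "L1"))
  expect_equal(nrow(sn$edges), 1)
  expect_setequal(sn$nodes, c("g1", "g2", "g3"))

  f2 <- withr::local_tempfile(lines = c("a b", "b c"))
  sn2 <- read_edge_list(f2, "L2")
  expect_equal(nrow(sn2$edges), 2)
  expect_equal(length(sn2$nodes), 3)

  f3 <- withr::local_tempfile(lines = "# nothing here")
  expect_warning(read_edge_list(f3, "L3"), "no edges")
  sn3 <- suppressWarnings(read_edge_list(f3, "L3"))
  expect_equal(nrow(sn3$edges), 0)
  expect_equal(length(sn3$nodes), 0)

  f4 <- withr::local_tempfile(lines = c("a b", "a b c"))
  expect_error(read_edge_list(f4, "L4"), "line 2")
})

test_that("integration counts layer multiplicity and conserves edge totals", {
  seven <- lapply(1:7, function(i) subnetwork(edge_mat("a", "b"), paste0("L", i)))
  net7 <- integrate_layers(seven)
  expect_equal(as.numeric(net7$mult["a", "b"]), 7)
  expect_equal(n_edges(net7), 7)

  l1 <- subnetwork(edge_mat("a", "b", "c", "d", "e", "f"), "L1")
  l2 <- subnetwork(edge_mat("u", "v", "w", "x", "y", "z"), "L2")
  net <- integrate_layers(list(l1, l2))
  expect_equal(n_edges(net), 6)
  expect_true(all(edge_multiplicities(net)$multiplicity == 1))

  net2 <- net_from_layers(list(
    edge_mat("a", "b", "b", "c"),
    edge_mat("a", "b")
  ))
  em <- edge_multiplicities(net2)
  expect_equal(em$multiplicity[em$from == "a" & em$to == "b"], 2L)
  expect_equal(em$multiplicity[em$from == "b" & em$to == "c"], 1L)
  expect_equal(n_edges(net2), 3)

  expect_error(integrate_layers(list()), "at least one")
})

test_that("multiplicity conservation and uniqueness partition hold for random layer sets", {
  set.seed(7)
  for (rep in 1:5) {
    n_layers <- sample(2:6, 1)
    nodes <- sprintf("n%02d", 1:15)
    layers <- lapply(seq_len(n_layers), function(i) {
      adj <- random_adjacency(15, runif(1, 0.1, 0.4), seed = rep * 10 + i)
      idx <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
      subnetwork(cbind(nodes[idx[, 1]], nodes[idx[, 2]]), paste0("L", i),
                 nodes = nodes)
    })
    net <- integrate_layers(layers)
    expect_equal(n_edges(net), sum(vapply(layers, function(s) nrow(s$edges), integer(1))))
    em <- edge_multiplicities(net)
    expect_equal(sum(em$multiplicity), n_edges(net))
    expect_true(all(em$multiplicity >= 1 & em$multiplicity <= n_layers))
    expect_equal(mean(em$multiplicity == 1) + mean(em$multiplicity >= 2), 1)
  }
})

test_that("network JSON bundle round-trips exactly", {
  net <- net_from_layers(list(
    edge_mat("a", "b", "b", "c"),
    edge_mat("a", "b", "c", "d")
  ))
  f <- withr::local_tempfile(fileext = ".json")
  write_network(net, f)
  back <- read_network(f)
  expect_equal(back$layers, net$layers)
  expect_equal(back$nodes, net$nodes)
  expect_equal(edge_multiplicities(back), edge_multiplicities(net))
})

test_that("drop_layer rebuilds the integration from the remaining layers", {
  net <- net_from_layers(list(
    edge_mat("a", "b", "b", "c"),
    edge_mat("a", "b")
  ))
  red <- drop_layer(net, "L2")
  expect_equal(red$layers, "L1")
  expect_equal(n_edges(red), 2)
  expect_error(drop_layer(net, "nope"), "no such layer")

  # dropping an empty layer leaves the integrated network unchanged
  with_empty <- integrate_layers(list(
    subnetwork(edge_mat("a", "b", "b", "c"), "L1"),
    subnetwork(matrix(character(), ncol = 2), "empty", nodes = c("a", "b", "c"))
  ))
  red2 <- drop_layer(with_empty, "empty")
  expect_equal(red2$nodes, with_empty$nodes)
  expect_equal(edge_multiplicities(red2), edge_multiplicities(with_empty))
  expect_equal(global_stats(red2), global_stats(with_empty))
})

test_that("seed sets deduplicate and read from file", {
  s <- seed_set(c("b", "a", "a"))
  expect_equal(as.character(s), c("a", "b"))
  expect_error(seed_set(character()), "empty")
  f <- withr::local_tempfile(lines = c("# my seeds", "g1", "", "g2"))
  expect_equal(as.character(read_seed_list(f)), c("g1", "g2"))
})
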