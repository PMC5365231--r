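test_that("reverse-traversal Dijkstra returns cost-to-anchor distances", {
  chain <- interaction_network(data.frame(
    tail = c("s", "a"), head = c("a", "t"), weight = c(1, 2)))
  g <- costed_graph(chain, cost_config("additive"))
  d <- reverse_dijkstra(g, "t")
  expect_equal(d[["t"]], 0)
  expect_equal(d[["a"]], 2)
  expect_equal(d[["s"]], 3)

  iso <- interaction_network(data.frame(tail = "t", head = "x", weight = 1),
                             nodes = c("u"))
  g2 <- costed_graph(iso, cost_config("additive"))
  expect_equal(reverse_dijkstra(g2, "t")[["u"]], Inf)
  expect_equal(reverse_dijkstra(g2, "t")[["x"]], Inf)  # edge points away
  expect_error(reverse_dijkstra(g2, "zzz"), "not in graph")
})

test_that("A* finds the shortest path and respects hidden elements", {
  g <- costed_graph(diamond_net(), cost_config("additive"))
  h <- reverse_dijkstra(g, "t")
  best <- astar_shortest_path(g, "s", "t", h)
  expect_identical(best$nodes, c("s", "a", "t"))
  expect_equal(best$cost, 2)

  hide_edges(g, "s", "a")
  alt <- astar_shortest_path(g, "s", "t", h)
  expect_identical(alt$nodes, c("s", "b", "t"))
  expect_equal(alt$cost, 4)
  unhide_all(g)

  hide_nodes(g, c("a", "b"))
  expect_null(astar_shortest_path(g, "s", "t", h))
  unhide_all(g)

  same <- astar_shortest_path(g, "s", "s", h)
  expect_equal(same$cost, 0)
  expect_identical(same$nodes, "s")
})

test_that("yen_ksp enumerates loopless paths in cost order on the diamond", {
  g <- costed_graph(diamond_net(), cost_config("additive"))
  two <- yen_ksp(g, "s", "t", k = 2)
  expect_equal(path_costs(two), c(2, 4))
  expect_identical(path_ids(two), c("s|a|t", "s|b|t"))

  one <- yen_ksp(g, "s", "t", k = 1)
  expect_identical(one[[1]]$nodes, astar_shortest_path(g, "s", "t")$nodes)

  all_of_them <- yen_ksp(g, "s", "t", k = 100)
  expect_length(all_of_them, 2)          # exhaustion: no padding, no dupes
  expect_identical(path_ids(all_of_them), unique(path_ids(all_of_them)))

  expect_length(yen_ksp(g, "t", "s", k = 3), 0)   # unreachable
  expect_error(yen_ksp(g, "s", "t", k = 0), "positive integer")
})

test_that("yen_ksp agrees exactly with exhaustive enumeration", {
  for (spec in random_instances(30, seed_base = 5000L)) {
    net <- instance_network(spec)
    ep <- instance_endpoints(net)
    cfg <- cost_config(if (spec$mode == "unweighted") "unweighted"
                       else spec$mode)
    oracle <- enumerate_all_paths(net, ep$origin, ep$anchor, cfg)
    g <- costed_graph(net, cfg)
    full <- yen_ksp(g, ep$origin, ep$anchor, k = length(oracle) + 2)
    expect_matches_oracle(full, oracle, k = length(oracle) + 2)
    # smaller k values return exactly the oracle prefix
    for (k in unique(c(1L, 2L, min(5L, length(oracle))))) {
      if (k < 1 || length(oracle) == 0) next
      expect_matches_oracle(yen_ksp(g, ep$origin, ep$anchor, k = k),
                            oracle, k = k)
    }
  }
})

test_that("the heuristic never changes the result (A* neutrality)", {
  for (spec in random_instances(12, seed_base = 7000L)) {
    net <- instance_network(spec)
    ep <- instance_endpoints(net)
    cfg <- cost_config(spec$mode)
    g <- costed_graph(net, cfg)
    zeros <- stats::setNames(numeric(length(net$nodes)), net$nodes)
    with_h <- yen_ksp(g, ep$origin, ep$anchor, k = 25)
    without_h <- yen_ksp(g, ep$origin, ep$anchor, k = 25, heuristic = zeros)
    expect_identical(path_ids(with_h), path_ids(without_h))
    expect_identical(path_costs(with_h), path_costs(without_h))
  }
})

test_that("yen_ksp restores the hidden sets it found on entry", {
  g <- costed_graph(diamond_net(), cost_config("additive"))
  invisible(yen_ksp(g, "s", "t", k = 5))
  expect_false(any(g$hidden_edge))
  expect_false(any(g$hidden_node))

  hide_edges(g, "s", "a")
  pre <- g$hidden_edge
  res <- yen_ksp(g, "s", "t", k = 5)
  expect_identical(g$hidden_edge, pre)   # caller's hiding untouched
  expect_identical(path_ids(res), "s|b|t")  # and respected by the search
})

test_that("equal-cost paths are ordered by edge count then node sequence", {
  net <- interaction_network(data.frame(
    tail = c("s", "s", "b", "a", "s", "c"),
    head = c("a", "b", "t", "t", "c", "t"),
    weight = c(1, 1, 1, 1, 1, 1)))
  g <- costed_graph(net, cost_config("unweighted"))
  res <- yen_ksp(g, "s", "t", k = 10)
  # all three paths cost 2; lexicographic middle node breaks the ties
  expect_identical(path_ids(res), c("s|a|t", "s|b|t", "s|c|t"))
})
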