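test_that("endpoint validation skips absent nodes and aborts on empty sets", {
  net <- interaction_network(data.frame(
    tail = c("EGFR", "KDR", "TEK", "x"), head = c("x", "x", "y", "SMAD1"),
    weight = c(0.9, 0.8, 0.7, 0.6)))
  ok <- validate_endpoints(net, c("EGFR", "KDR", "TEK"), "SMAD1")
  expect_identical(ok$sources, c("EGFR", "KDR", "TEK"))
  expect_length(ok$warnings, 0)

  expect_warning(part <- validate_endpoints(net, c("EGFR", "zzz"), "SMAD1"),
                 "zzz")
  expect_identical(part$sources, "EGFR")
  expect_length(part$warnings, 1)

  expect_error(suppressWarnings(validate_endpoints(net, "zzz", "SMAD1")),
               "none of the sources")
  expect_error(suppressWarnings(validate_endpoints(net, "EGFR", "zzz")),
               "none of the targets")
  expect_error(validate_endpoints(net, c("EGFR", "zzz"), "SMAD1",
                                  strict = TRUE), "strict")
})

test_that("the query graph gains a zero-cost super source and target", {
  net <- prob_diamond_net()
  q <- path_query("s", "t", k = 5)
  g <- prepare_query_graph(net, q, cost_config("probability"))
  expect_equal(g$n, length(net$nodes) + 2)
  ss <- g$super_source; st <- g$super_target
  d <- reverse_dijkstra(g, st)
  # super edges add no cost: distance from s equals the real path cost
  expect_equal(d[[ss]], d[["s"]])
  expect_equal(d[["t"]], 0)
  expect_equal(d[[st]], 0)
})

test_that("endpoint edges are removed unless explicitly allowed", {
  net <- interaction_network(data.frame(
    tail = c("x", "a", "t", "z"), head = c("a", "t", "z", "a"),
    weight = c(0.5, 0.5, 0.5, 0.5)))
  q_off <- path_query("a", "t", k = 5)
  g_off <- prepare_query_graph(net, q_off, cost_config("probability"))
  expect_error(kspathway:::edge_id(g_off, "x", "a"), "not in graph")   # in-edge to source
  expect_error(kspathway:::edge_id(g_off, "t", "z"), "not in graph")   # out-edge of target

  q_on <- path_query("a", "t", k = 5, allow_sources_targets_in_paths = TRUE)
  g_on <- prepare_query_graph(net, q_on, cost_config("probability"))
  expect_silent(kspathway:::edge_id(g_on, "x", "a"))
  expect_silent(kspathway:::edge_id(g_on, "t", "z"))
})

test_that("sources stay first and targets last under the exclusion default", {
  net <- interaction_network(data.frame(
    tail = c("s2", "s1", "s2"), head = c("s1", "t", "t"),
    weight = c(0.5, 0.5, 0.1)))
  off <- run_pathlinker(net, c("s1", "s2"), "t", k = 10)
  for (p in off$path_nodes) {
    inner <- p[-c(1, length(p))]
    expect_false(any(inner %in% c("s1", "s2")))
    expect_false(any(p[-length(p)] == "t"))
  }
  # with the option on, a source may sit mid-path
  on <- run_pathlinker(net, c("s1", "s2"), "t", k = 10,
                       allow_sources_targets_in_paths = TRUE)
  expect_true("s2|s1|t" %in% on$paths$path)
  expect_identical(on$paths$path[1], "s1|t")  # highest score 0.5 first
  expect_true(all(diff(on$paths$score) <= 0)) # decreasing order of score
})

test_that("targets-are-sources connects a node set to itself", {
  net <- interaction_network(data.frame(tail = "a", head = "b", weight = 0.5))
  res <- run_pathlinker(net, c("a", "b"), k = 10, targets_are_sources = TRUE)
  expect_equal(nrow(res$paths), 1)
  expect_identical(res$paths$path, "a|b")
  expect_equal(res$paths$score, 0.5)

  # a single node admits no loopless path at all
  lone <- run_pathlinker(net, "a", k = 10, targets_are_sources = TRUE)
  expect_equal(nrow(lone$paths), 0)
  expect_equal(nrow(lone$subnetwork$nodes), 0)

  expect_error(path_query("a", "b", targets_are_sources = TRUE),
               "targets_are_sources")
})

test_that("invalid k falls back to the default 200 with a warning", {
  expect_warning(q <- path_query("a", "b", k = -5), "default")
  expect_equal(q$k, 200L)
  expect_warning(q2 <- path_query("a", "b", k = 2.5), "default")
  expect_equal(q2$k, 200L)
})

test_that("reported scores recompute exactly from the network", {
  for (spec in random_instances(8, seed_base = 9100L)) {
    net <- instance_network(spec)
    srcs <- net$nodes[1:2]
    tgts <- net$nodes[(length(net$nodes) - 1):length(net$nodes)]
    res <- tryCatch(
      run_pathlinker(net, srcs, tgts, k = 20, weight_mode = spec$mode),
      kspathway_error = function(cond) NULL)   # disconnected instance
    if (is.null(res) || nrow(res$paths) == 0) next
    cfg <- res$config
    for (i in seq_along(res$path_nodes)) {
      expect_identical(res$paths$score[i],
                       path_score(res$path_nodes[[i]], net, cfg))
    }
  }
})

test_that("rank 1 is the cheapest pairwise source-target path", {
  for (spec in random_instances(8, seed_base = 9200L)) {
    net <- instance_network(spec)
    srcs <- net$nodes[1:2]
    tgts <- net$nodes[(length(net$nodes) - 1):length(net$nodes)]
    cfg <- cost_config(spec$mode)
    res <- tryCatch(
      run_pathlinker(net, srcs, tgts, k = 1, weight_mode = spec$mode,
                     allow_sources_targets_in_paths = TRUE),
      kspathway_error = function(cond) NULL)
    best <- Inf
    for (s in srcs) for (t in setdiff(tgts, s)) {
      paths <- enumerate_all_paths(net, s, t, cfg)
      if (length(paths)) best <- min(best, paths[[1]]$cost)
    }
    if (is.null(res) || nrow(res$paths) == 0) {
      expect_identical(best, Inf)
    } else {
      expect_equal(res$paths$cost[1], best)
    }
  }
})

test_that("first-path indices equal the true minimum rank", {
  res <- run_pathlinker(prob_diamond_net(), "s", "t", k = 10)
  sub <- res$subnetwork
  expect_identical(path_ids(lapply(res$path_nodes, function(n) list(nodes = n))),
                   c("s|a|t", "s|b|t"))
  expect_equal(sub$nodes$first_path_index[match(c("s", "a", "t", "b"),
                                               sub$nodes$node)],
               c(1L, 1L, 1L, 2L))
  ekey <- paste(sub$edges$tail, sub$edges$head)
  expect_equal(sub$edges$first_path_index[match(c("s a", "a t", "s b", "b t"),
                                               ekey)],
               c(1L, 1L, 2L, 2L))

  # recomputation on a random instance
  spec <- list(seed = 42L, n = 8L, p = 0.4, mode = "probability")
  net <- instance_network(spec)
  res2 <- tryCatch(run_pathlinker(net, net$nodes[1], net$nodes[8], k = 15),
                   kspathway_error = function(cond) NULL)
  if (!is.null(res2) && nrow(res2$paths) > 0) {
    sub2 <- res2$subnetwork
    for (i in seq_len(nrow(sub2$nodes))) {
      truth <- min(which(vapply(res2$path_nodes,
                                function(p) sub2$nodes$node[i] %in% p,
                                logical(1))))
      expect_identical(sub2$nodes$first_path_index[i], as.integer(truth))
    }
    # every sub-network element occurs in at least one path (minimality)
    all_nodes <- unique(unlist(res2$path_nodes))
    expect_setequal(sub2$nodes$node, all_nodes)
  }
})
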