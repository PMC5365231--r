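#' k shortest loopless paths (Yen's algorithm with A*)
#'
#' Computes up to `k` minimum-cost loopless directed paths from `origin` to
#' `anchor`, in non-decreasing internal cost.  Candidate spur paths are
#' generated per Yen: for each accepted path and each spur position, the
#' nodes of the root prefix (except the spur node) and the next edge of every
#' previously accepted path sharing that root prefix are hidden, and a
#' canonical shortest spur path is found with [astar_shortest_path()].
#' Looplessness is therefore enforced by construction, never by
#' post-filtering.
#'
#' Ties are broken by the total order (cost, number of edges, lexicographic
#' node sequence), both among candidates and in the underlying single-pair
#' search, so the output is fully deterministic and identical for any
#' admissible heuristic.  The returned costs satisfy the gap guarantee: no
#' loopless origin-to-anchor path has cost strictly between two consecutive
#' returned costs.
#'
#' The heuristic is computed once (on the graph with nothing hidden) and
#' reused for every spur search; hiding only removes options, so it stays an
#' admissible lower bound.  On return the graph's hidden sets are restored to
#' their entry state.
#'
#' @param graph a [costed_graph()].
#' @param origin,anchor node identifiers.
#' @param k positive integer: maximum number of paths.
#' @param heuristic named numeric lower-bound vector (see
#'   [reverse_dijkstra()]); `NULL` computes it internally.
#' @return list of paths, each `list(rank, nodes, cost)`, ranked from 1; an
#'   empty list when `anchor` is unreachable.  Fewer than `k` paths are
#'   returned when the graph holds fewer distinct loopless paths.
#' @export
#' @examples
#' net <- interaction_network(data.frame(
#'   tail = c("s", "a", "s", "b"), head = c("a", "t", "b", "t"),
#'   weight = c(1, 1, 2, 2)))
#' g <- costed_graph(net, cost_config("additive"))
#' yen_ksp(g, "s", "t", k = 2)
yen_ksp <- function(graph, origin, anchor, k, heuristic = NULL) {
  stopifnot(inherits(graph, "costed_graph"))
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k < 1 ||
      k != floor(k))
    ksp_stop("k must be a positive integer")
  k <- as.integer(k)
  o <- node_index(graph, origin)
  a <- node_index(graph, anchor)
  h <- if (is.null(heuristic)) dijkstra_idx(graph, a, reverse = TRUE)$dist
       else prep_heuristic(graph, heuristic)

  # restore the caller's hidden state no matter how we exit
  saved_edge <- graph$hidden_edge
  saved_node <- graph$hidden_node
  on.exit({
    graph$hidden_edge <- saved_edge
    graph$hidden_node <- saved_node
  })

  first <- astar_idx(graph, o, a, h)
  if (is.null(first) || first$hops == 0L) return(list())
  first$cost <- path_cost_seq(graph, first$path)

  acc_paths <- vector("list", k)      # accepted paths (integer node indices)
  acc_costs <- numeric(k)
  acc_paths[[1L]] <- first$path
  acc_costs[1L] <- first$cost
  n_acc <- 1L

  # prefix trie: key = space-joined root prefix -> integer vector of the
  # next node of every accepted path having that root prefix
  trie <- new.env(parent = emptyenv(), size = 4L * k)
  seen <- new.env(parent = emptyenv(), size = 4L * k)  # accepted + pooled keys
  add_to_trie <- function(p) {
    key <- as.character(p[1L])
    for (j in seq_len(length(p) - 1L)) {
      nxt <- p[j + 1L]
      cur <- trie[[key]]
      if (is.null(cur) || !(nxt %in% cur)) trie[[key]] <- c(cur, nxt)
      key <- paste(key, nxt)
    }
    assign(path_key(p), TRUE, envir = seen)
  }
  path_key <- function(p) paste(p, collapse = " ")
  add_to_trie(first$path)

  # candidate pool (flat arrays + list of paths)
  pool_cost <- numeric()
  pool_hops <- integer()
  pool_lexkey <- character()
  pool_paths <- list()
  pool_alive <- logical()
  lexr <- graph$lexr
  lex_key <- function(p) paste(sprintf("%06d", lexr[p]), collapse = " ")

  while (n_acc < k) {
    prev <- acc_paths[[n_acc]]
    plen <- length(prev)
    # per-edge costs along prev, for root-prefix costs
    eids <- integer(plen - 1L)
    for (j in seq_len(plen - 1L)) eids[j] <- edge_id(graph, prev[j], prev[j + 1L])
    root_cost <- c(0, cumsum(graph$cost[eids]))

    key <- as.character(prev[1L])
    for (j in seq_len(plen - 1L)) {
      spur <- prev[j]
      hidden_e <- integer()
      if (j > 1L) graph$hidden_node[prev[seq_len(j - 1L)]] <- TRUE
      for (nxt in trie[[key]]) {
        e <- tryCatch(edge_id(graph, spur, nxt), error = function(cond) NA_integer_)
        if (!is.na(e)) hidden_e <- c(hidden_e, e)
      }
      graph$hidden_edge[hidden_e] <- TRUE

      sp <- astar_idx(graph, spur, a, h)

      graph$hidden_edge[hidden_e] <- saved_edge[hidden_e]
      if (j > 1L) {
        root <- prev[seq_len(j - 1L)]
        graph$hidden_node[root] <- saved_node[root]
      }

      if (!is.null(sp)) {
        full <- c(prev[seq_len(j - 1L)], sp$path)
        pk <- path_key(full)
        if (is.null(seen[[pk]])) {
          assign(pk, TRUE, envir = seen)
          # canonical left-to-right cost so equal paths always get equal
          # floats, whatever spur position produced them
          pool_cost <- c(pool_cost, path_cost_seq(graph, full))
          pool_hops <- c(pool_hops, length(full) - 1L)
          pool_lexkey <- c(pool_lexkey, lex_key(full))
          pool_paths <- c(pool_paths, list(full))
          pool_alive <- c(pool_alive, TRUE)
        }
      }
      key <- paste(key, prev[j + 1L])
    }

    live <- which(pool_alive)
    if (length(live) == 0L) break
    best <- live[pool_cost[live] == min(pool_cost[live])]
    if (length(best) > 1L) best <- best[pool_hops[best] == min(pool_hops[best])]
    if (length(best) > 1L)
      best <- best[which(pool_lexkey[best] ==
                           sort(pool_lexkey[best], method = "radix")[1L])[1L]]
    pool_alive[best] <- FALSE
    n_acc <- n_acc + 1L
    acc_paths[[n_acc]] <- pool_paths[[best]]
    acc_costs[n_acc] <- pool_cost[best]
    add_to_trie(pool_paths[[best]])
  }

  lapply(seq_len(n_acc), function(i) {
    list(rank = i, nodes = graph$nodes[acc_paths[[i]]], cost = acc_costs[i])
  })
}

# strict left-to-right sum of edge costs along an index path: the canonical
# float every component (engine, oracle, pool) agrees on
#' @noRd
path_cost_seq <- function(graph, p) {
  cost <- 0
  for (j in seq_len(length(p) - 1L))
    cost <- cost + graph$cost[edge_id(graph, p[j], p[j + 1L])]
  cost
}
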