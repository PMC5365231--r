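# Costed-graph machinery.
#
# The engine works on an environment-based graph object so that hiding edges
# or nodes mutates cheap logical masks instead of copying topology.  Hidden
# elements are ignored by A* but are invisible to the plain Dijkstra passes,
# which by construction run before any hiding happens.

#' Build the internal costed graph for a network
#'
#' Converts an [interaction_network()] into the mutable search structure used
#' by the path engine: integer adjacency (out- and in-edges per node), one
#' internal additive cost per edge derived from [edge_cost()], and initially
#' empty hidden-edge / hidden-node masks.
#'
#' @param network an [interaction_network()].
#' @param config a [cost_config()].
#' @return an environment of class `costed_graph`.
#' @seealso [prepare_query_graph()] for the query-augmented variant with a
#'   super source and super target.
#' @export
costed_graph <- function(network, config) {
  stopifnot(inherits(network, "interaction_network"),
            inherits(config, "cost_config"))
  if (config$weight_mode != "unweighted" && !network$weighted &&
      nrow(network$edges) > 0)
    ksp_stop("%s mode requires a weighted network", config$weight_mode)
  tail_i <- match(network$edges$tail, network$nodes)
  head_i <- match(network$edges$head, network$nodes)
  cost <- if (nrow(network$edges)) edge_cost(network$edges$weight, config) else numeric()
  build_costed_graph(network$nodes, tail_i, head_i, cost,
                     network$edges$weight)
}

#' @noRd
build_costed_graph <- function(nodes, tail_i, head_i, cost, weight,
                               super_source = NA_character_,
                               super_target = NA_character_) {
  n <- length(nodes)
  m <- length(tail_i)
  if (m > 0 && (any(cost < 0) || any(!is.finite(cost))))
    ksp_stop("internal edge costs must be finite and non-negative")
  g <- new.env(parent = emptyenv())
  g$nodes <- nodes
  g$n <- n
  g$tail <- as.integer(tail_i)
  g$head <- as.integer(head_i)
  g$cost <- as.numeric(cost)
  g$weight <- as.numeric(weight)
  g$out <- split_edges(g$tail, n, m)
  g$inc <- split_edges(g$head, n, m)
  g$hidden_edge <- logical(m)
  g$hidden_node <- logical(n)
  g$lexr <- lex_ranks(nodes)
  g$super_source <- super_source
  g$super_target <- super_target
  class(g) <- "costed_graph"
  g
}

#' @noRd
split_edges <- function(endpoint, n, m) {
  out <- vector("list", n)
  if (m > 0) {
    sp <- split(seq_len(m), factor(endpoint, levels = seq_len(n)))
    for (i in seq_len(n)) out[[i]] <- sp[[i]]
  } else {
    for (i in seq_len(n)) out[[i]] <- integer()
  }
  out
}

#' @export
print.costed_graph <- function(x, ...) {
  cat(sprintf("Costed graph: %d nodes, %d edges (%d hidden), %d hidden nodes\n",
              x$n, length(x$tail), sum(x$hidden_edge), sum(x$hidden_node)))
  invisible(x)
}

#' Hide or reveal graph elements
#'
#' Hidden edges and nodes are skipped by [astar_shortest_path()] (and hence by
#' [yen_ksp()]'s spur searches) without touching the underlying topology;
#' hiding is always reversible.  These are exposed mainly for testing — the
#' engine manages hiding itself and always restores the entry state.
#'
#' @param graph a [costed_graph()].
#' @param tails,heads character vectors naming the edges to (un)hide.
#' @param nodes character vector of node identifiers.
#' @return the graph, invisibly.
#' @export
hide_edges <- function(graph, tails, heads) {
  ids <- mapply(edge_id, tails, heads, MoreArgs = list(graph = graph))
  graph$hidden_edge[ids] <- TRUE
  invisible(graph)
}

#' @rdname hide_edges
#' @export
hide_nodes <- function(graph, nodes) {
  idx <- node_index(graph, nodes)
  graph$hidden_node[idx] <- TRUE
  invisible(graph)
}

#' @rdname hide_edges
#' @export
unhide_all <- function(graph) {
  graph$hidden_edge[] <- FALSE
  graph$hidden_node[] <- FALSE
  invisible(graph)
}

#' @noRd
node_index <- function(graph, nodes) {
  idx <- match(nodes, graph$nodes)
  if (anyNA(idx))
    ksp_stop("node not in graph: %s", nodes[is.na(idx)][1L])
  idx
}

# edge id for (tail name/idx -> head name/idx); NA if absent
#' @noRd
edge_id <- function(graph, tail, head) {
  if (is.character(tail)) tail <- node_index(graph, tail)
  if (is.character(head)) head <- node_index(graph, head)
  es <- graph$out[[tail]]
  hit <- es[match(head, graph$head[es])]
  if (is.na(hit)) ksp_stop("edge %s -> %s not in graph",
                           graph$nodes[tail], graph$nodes[head])
  hit
}

#' Shortest-path distances to an anchor by reverse traversal
#'
#' Runs Dijkstra's algorithm following in-edges from the anchor, so that the
#' result maps every node `v` to the cost of the cheapest directed `v -> anchor`
#' path — without ever materialising the reversed graph.  This is the
#' admissible A* heuristic used by the path engine: it is computed once, on
#' the graph with nothing hidden, and remains a valid lower bound afterwards
#' because hiding elements can only lengthen true distances.
#'
#' @param graph a [costed_graph()].
#' @param anchor node identifier.
#' @return named numeric vector over all nodes; unreachable nodes map to
#'   `Inf`, the anchor to 0.
#' @export
reverse_dijkstra <- function(graph, anchor) {
  a <- node_index(graph, anchor)
  res <- dijkstra_idx(graph, a, reverse = TRUE)
  stats::setNames(res$dist, graph$nodes)
}

# Plain binary-heap Dijkstra on the full (unhidden) graph.
# reverse = TRUE follows in-edges: dist[v] = cost of v -> src path.
#' @noRd
dijkstra_idx <- function(graph, src, reverse = FALSE, want_pred = FALSE) {
  n <- graph$n
  dist <- rep(Inf, n)
  dist[src] <- 0
  pred <- if (want_pred) rep(NA_integer_, n) else NULL
  done <- logical(n)
  heap <- new_min_heap(max(64L, n))
  heap$push(0, src)
  adj <- if (reverse) graph$inc else graph$out
  other <- if (reverse) graph$tail else graph$head
  cost <- graph$cost
  while (heap$size() > 0L) {
    pk <- heap$pop()
    u <- as.integer(pk[2L])
    if (done[u]) next
    done[u] <- TRUE
    du <- dist[u]
    for (e in adj[[u]]) {
      v <- other[e]
      nd <- du + cost[e]
      if (nd < dist[v]) {
        dist[v] <- nd
        if (want_pred) pred[v] <- u
        heap$push(nd, v)
      }
    }
  }
  list(dist = dist, pred = pred)
}

#' Single-pair shortest path with A*
#'
#' Finds a minimum-cost directed path from `origin` to `anchor` that respects
#' the graph's hidden-edge and hidden-node sets.  Among equal-cost paths the
#' result is canonical under the package's tie order (cost, then number of
#' edges, then lexicographic node sequence), so the outcome is identical with
#' any admissible heuristic — including the all-zeros one, where the search
#' degenerates to Dijkstra.
#'
#' @param graph a [costed_graph()].
#' @param origin,anchor node identifiers.
#' @param heuristic named numeric vector of admissible lower bounds on the
#'   cost-to-anchor (typically [reverse_dijkstra()] output); `NULL` means all
#'   zeros.
#' @return `list(nodes, cost)` for the best path, or `NULL` when no path
#'   exists.
#' @export
astar_shortest_path <- function(graph, origin, anchor, heuristic = NULL) {
  o <- node_index(graph, origin)
  a <- node_index(graph, anchor)
  h <- prep_heuristic(graph, heuristic)
  res <- astar_idx(graph, o, a, h)
  if (is.null(res)) return(NULL)
  list(nodes = graph$nodes[res$path], cost = res$cost)
}

#' @noRd
prep_heuristic <- function(graph, heuristic) {
  if (is.null(heuristic)) return(numeric(graph$n))
  if (!is.null(names(heuristic)))
    heuristic <- heuristic[graph$nodes]
  if (length(heuristic) != graph$n || anyNA(heuristic))
    ksp_stop("heuristic must provide a value for every node")
  if (any(heuristic[is.finite(heuristic)] < 0))
    ksp_stop("heuristic values must be non-negative")
  as.numeric(heuristic)
}

# Label-correcting A*.  Each node label stores (cost, hops, explicit path);
# a label is replaced only by one strictly smaller under the global tie
# order, and replacements re-enter the queue, so the search converges to the
# canonical shortest path regardless of heuristic or pop order among ties.
#' @noRd
astar_idx <- function(graph, o, a, h) {
  if (graph$hidden_node[o] || graph$hidden_node[a]) return(NULL)
  if (o == a) return(list(path = o, cost = 0, hops = 0L))
  if (is.infinite(h[o])) return(NULL)
  n <- graph$n
  dist <- rep(Inf, n)
  hops <- integer(n)
  paths <- vector("list", n)
  dist[o] <- 0
  paths[[o]] <- o
  heap <- new_min_heap()
  heap$push(h[o], o)
  out <- graph$out; ehead <- graph$head; ecost <- graph$cost
  hedge <- graph$hidden_edge; hnode <- graph$hidden_node
  lexr <- graph$lexr
  while (heap$size() > 0L && heap$peek_key() <= dist[a]) {
    pk <- heap$pop()
    u <- as.integer(pk[2L])
    du <- dist[u]
    pu <- paths[[u]]
    for (e in out[[u]]) {
      if (hedge[e]) next
      v <- ehead[e]
      if (hnode[v] || is.infinite(h[v])) next
      ng <- du + ecost[e]
      if (ng > dist[a]) next
      upd <- FALSE
      if (ng < dist[v]) {
        upd <- TRUE
      } else if (ng == dist[v]) {
        nh <- hops[u] + 1L
        if (nh < hops[v]) {
          upd <- TRUE
        } else if (nh == hops[v]) {
          upd <- lex_less_idx(lexr[c(pu, v)], lexr[paths[[v]]])
        }
      }
      if (upd) {
        np <- c(pu, v)
        if (anyDuplicated(np)) next   # never extend into a loop
        dist[v] <- ng
        hops[v] <- hops[u] + 1L
        paths[[v]] <- np
        if (v != a) heap$push(ng + h[v], v)
      }
    }
  }
  if (is.infinite(dist[a])) return(NULL)
  list(path = paths[[a]], cost = dist[a], hops = hops[a])
}
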