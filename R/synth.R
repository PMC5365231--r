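#' Generate a random directed network
#'
#' Erdős–Rényi-style generator used for property testing and scaling runs:
#' directed edges without self-loops, either each ordered pair independently
#' with probability `edge_probability` or exactly `m_edges` pairs sampled
#' uniformly.  Probability weights are uniform on `(0, 1]`, additive weights
#' uniform on `(0, 10]`; both are rounded to 6 decimals (and kept strictly
#' positive) so edge lists are platform-stable in text form.  The same
#' `seed` always yields the identical network; the caller's RNG state is
#' left untouched.
#'
#' @param n_nodes number of nodes (at least 2); identifiers are `v1..vN`,
#'   zero-padded to a fixed width.
#' @param edge_probability per-ordered-pair edge probability (exclusive with
#'   `m_edges`).
#' @param m_edges exact number of edges (at most `n_nodes * (n_nodes - 1)`).
#' @param weight_mode `"probability"`, `"additive"` or `"unweighted"`.
#' @param seed integer random seed.
#' @return an [interaction_network()].
#' @export
#' @examples
#' generate_network(5, edge_probability = 0.5, seed = 1)
generate_network <- function(n_nodes, edge_probability = NULL, m_edges = NULL,
                             weight_mode = c("probability", "additive",
                                             "unweighted"),
                             seed = 1L) {
  weight_mode <- match.arg(weight_mode)
  if (!is.numeric(n_nodes) || n_nodes < 2)
    ksp_stop("n_nodes must be at least 2")
  n <- as.integer(n_nodes)
  npairs <- as.numeric(n) * (n - 1)
  if (is.null(edge_probability) == is.null(m_edges))
    ksp_stop("give exactly one of edge_probability or m_edges")
  if (!is.null(m_edges) && m_edges > npairs)
    ksp_stop("m_edges = %d exceeds the %d possible directed edges",
             m_edges, npairs)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))

  if (!is.null(edge_probability)) {
    if (edge_probability < 0 || edge_probability > 1)
      ksp_stop("edge_probability must be in [0, 1]")
    pick <- which(stats::runif(npairs) < edge_probability)
  } else {
    pick <- sort(sample.int(npairs, as.integer(m_edges)))
  }

  width <- nchar(as.character(n))
  ids <- sprintf("v%0*d", width, seq_len(n))
  tl <- (pick - 1) %/% (n - 1) + 1
  off <- (pick - 1) %% (n - 1) + 1
  hd <- off + (off >= tl)

  w <- switch(weight_mode,
    probability = pmin(pmax(round(stats::runif(length(pick)), 6), 1e-6), 1),
    additive = pmax(round(stats::runif(length(pick), 0, 10), 6), 1e-6),
    unweighted = rep(NA_real_, length(pick))
  )
  interaction_network(
    data.frame(tail = ids[tl], head = ids[hd], weight = w,
               stringsAsFactors = FALSE),
    nodes = ids
  )
}

#' Enumerate every loopless path between two nodes (ground-truth oracle)
#'
#' Depth-first enumeration of all loopless `origin -> anchor` paths with
#' their internal costs, sorted by the same (cost, edges, lexicographic)
#' tie order the engine uses — so agreement with [yen_ksp()] can be checked
#' exactly, not approximately.  Enumeration is exponential, so the input is
#' guarded to at most 12 network nodes.
#'
#' @param x an [interaction_network()] (with `config`) or a ready
#'   [costed_graph()].
#' @param origin,anchor node identifiers.  `origin == anchor` yields zero
#'   paths (loopless semantics).
#' @param config a [cost_config()]; required when `x` is a network.
#' @return list of `list(nodes, cost)` in tie order.
#' @export
enumerate_all_paths <- function(x, origin, anchor, config = NULL) {
  if (inherits(x, "interaction_network")) {
    if (is.null(config)) ksp_stop("config is required with a network input")
    graph <- costed_graph(x, config)
    limit <- 12L
  } else if (inherits(x, "costed_graph")) {
    graph <- x
    limit <- 14L  # allow two super nodes on top of the 12-node guard
  } else ksp_stop("x must be an interaction_network or costed_graph")
  if (graph$n > limit)
    ksp_stop("refusing to enumerate paths on %d nodes (limit %d): exponential",
             graph$n, limit)

  o <- node_index(graph, origin)
  a <- node_index(graph, anchor)
  if (o == a) return(list())

  out <- graph$out; ehead <- graph$head; ecost <- graph$cost
  hedge <- graph$hidden_edge; hnode <- graph$hidden_node
  found_paths <- list()
  found_costs <- numeric()
  visited <- logical(graph$n)

  dfs <- function(u, path, cost) {
    for (e in out[[u]]) {
      if (hedge[e]) next
      v <- ehead[e]
      if (hnode[v] || visited[v]) next
      if (v == a) {
        found_paths[[length(found_paths) + 1L]] <<- c(path, v)
        found_costs[[length(found_costs) + 1L]] <<- cost + ecost[e]
      } else {
        visited[v] <<- TRUE
        dfs(v, c(path, v), cost + ecost[e])
        visited[v] <<- FALSE
      }
    }
  }
  if (!hnode[o] && !hnode[a]) {
    visited[o] <- TRUE
    dfs(o, o, 0)
  }
  if (length(found_paths) == 0L) return(list())

  lexr <- graph$lexr
  keys <- vapply(found_paths, function(p)
    paste(sprintf("%06d", lexr[p]), collapse = " "), character(1))
  hops <- lengths(found_paths)
  ord <- order(found_costs, hops, keys, method = "radix")
  lapply(ord, function(i)
    list(nodes = graph$nodes[found_paths[[i]]], cost = found_costs[i]))
}
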