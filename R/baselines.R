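#' Through-node shortest paths (StrongestPath-style baseline)
#'
#' A reference implementation of the through-node shortest-path procedure
#' used as a comparison baseline: attach a super source `s*` to all sources
#' and all targets to a super target `t*`; run a forward Dijkstra from `s*`
#' and a reverse-traversal Dijkstra from `t*`; for every network node `v`
#' record `d(v)`, the cost of the cheapest source-to-target path through `v`;
#' let `a = min d(v)`; and emit the through-`v` path for every node with
#' `d(v) <= a + tau`.
#'
#' Because at most one path is emitted per node, at most `n` distinct paths
#' are ever returned — so for `tau > 0` there is no guarantee that *all*
#' source-to-target paths of cost `<= a + tau` are found (a limitation
#' [yen_ksp()] does not share).  With `tau = 0` every emitted path is a
#' global shortest source-to-target path.
#'
#' The through-`v` path is the forward predecessor chain `s* .. v` joined to
#' the backward chain `v .. t*` (super nodes stripped); if the concatenation
#' repeats a node, that node's path is discarded with a warning.  Ties in
#' `d(v)` are ordered by node identifier.
#'
#' @param network an [interaction_network()].
#' @param sources,targets endpoint identifier sets.
#' @param tau non-negative slack above the best through-node cost.
#' @param config a [cost_config()]; defaults to probability weights for a
#'   weighted network and unweighted otherwise.
#' @param strict abort on absent endpoints (see [validate_endpoints()]).
#' @return data.frame with one row per emitted node, sorted by
#'   `(d_value, via)`: columns `via`, `d_value`, `path` (pipe-joined) and
#'   `score` (user-facing score of the path, as in [path_score()]).
#' @export
#' @examples
#' net <- interaction_network(data.frame(
#'   tail = c("s", "a", "s", "b"), head = c("a", "t", "b", "t"),
#'   weight = c(1, 1, 2, 2)))
#' strongest_paths(net, "s", "t", tau = 2, config = cost_config("additive"))
strongest_paths <- function(network, sources, targets, tau = 0,
                            config = NULL, strict = FALSE) {
  stopifnot(inherits(network, "interaction_network"))
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau < 0)
    ksp_stop("tau must be a non-negative number")
  if (is.null(config))
    config <- cost_config(if (network$weighted) "probability" else "unweighted")

  val <- validate_endpoints(network, sources, targets, strict = strict)
  query <- path_query(val$sources, val$targets, k = 1,
                      allow_sources_targets_in_paths = TRUE)
  graph <- prepare_query_graph(network, query, config)

  s_i <- node_index(graph, graph$super_source)
  t_i <- node_index(graph, graph$super_target)
  fwd <- dijkstra_idx(graph, s_i, reverse = FALSE, want_pred = TRUE)
  bwd <- dijkstra_idx(graph, t_i, reverse = TRUE, want_pred = TRUE)

  real <- setdiff(seq_len(graph$n), c(s_i, t_i))
  d <- fwd$dist[real] + bwd$dist[real]
  ok <- is.finite(d)
  real <- real[ok]; d <- d[ok]
  if (length(real) == 0L)
    return(data.frame(via = character(), d_value = numeric(),
                      path = character(), score = numeric(),
                      stringsAsFactors = FALSE))

  a <- min(d)
  emit <- which(d <= a + tau)
  via <- graph$nodes[real[emit]]
  ord <- order(d[emit], via, method = "radix")
  emit <- emit[ord]

  rows <- lapply(emit, function(i) {
    v <- real[i]
    back <- chain(fwd$pred, v)            # s* .. v
    fore <- rev(chain(bwd$pred, v))       # v .. t*
    p <- c(back, fore[-1L])
    p <- p[!(p %in% c(s_i, t_i))]
    if (length(p) < 2L) return(NULL)      # shared endpoint, no real edge
    if (anyDuplicated(p)) {
      ksp_warn("through-node path for '%s' repeats a node; discarded",
               graph$nodes[v])
      return(NULL)
    }
    nodes <- graph$nodes[p]
    data.frame(via = graph$nodes[v], d_value = d[i],
               path = paste(nodes, collapse = "|"),
               score = path_score(nodes, network, config),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    return(data.frame(via = character(), d_value = numeric(),
                      path = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# predecessor chain from the search root down to v (root first)
#' @noRd
chain <- function(pred, v) {
  p <- v
  while (!is.na(pred[v])) {
    v <- pred[v]
    p <- c(v, p)
  }
  p
}
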