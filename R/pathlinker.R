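#' Describe a source-to-target path query
#'
#' Bundles the endpoint sets and algorithm options of a reconstruction run.
#'
#' @param sources,targets character vectors of node identifiers (or anything
#'   [node_set()] accepts).  `targets` may be omitted when
#'   `targets_are_sources = TRUE`.
#' @param k number of paths sought; an invalid value (negative, non-integer,
#'   non-numeric) falls back to the default 200 with a warning.
#' @param allow_sources_targets_in_paths normally edges into sources and out
#'   of targets are removed before the search, so endpoints can only open or
#'   close a path; set `TRUE` to keep those edges and let endpoints appear as
#'   intermediate nodes.
#' @param targets_are_sources copy the sources to the targets, to connect a
#'   single node set to itself; this forces
#'   `allow_sources_targets_in_paths = TRUE`.  With a single node no loopless
#'   path exists, so no paths are returned.
#' @return an object of class `path_query`.
#' @export
path_query <- function(sources, targets = NULL, k = 200,
                       allow_sources_targets_in_paths = FALSE,
                       targets_are_sources = FALSE) {
  sources <- node_set(sources)
  if (targets_are_sources) {
    if (!is.null(targets))
      ksp_stop("'targets' must not be given together with 'targets_are_sources'")
    targets <- sources
    allow_sources_targets_in_paths <- TRUE
  } else {
    if (is.null(targets)) ksp_stop("'targets' is required")
    targets <- node_set(targets)
  }
  ok <- is.numeric(k) && length(k) == 1L && is.finite(k) && k >= 1 &&
    k == floor(k)
  if (!ok) {
    ksp_warn("invalid k; using the default k = 200")
    k <- 200
  }
  structure(
    list(sources = sources, targets = targets, k = as.integer(k),
         allow_sources_targets_in_paths = isTRUE(allow_sources_targets_in_paths),
         targets_are_sources = isTRUE(targets_are_sources)),
    class = "path_query"
  )
}

#' Check that endpoints exist in the network
#'
#' Endpoints absent from the network are reported; by default they are
#' skipped with a warning (the non-interactive analogue of confirming a
#' "continue with the remaining nodes" prompt), while `strict = TRUE` aborts
#' on any absent endpoint.  If no source or no target survives, the run is
#' aborted in either mode.
#'
#' @param network an [interaction_network()].
#' @param sources,targets character vectors of node identifiers.
#' @param strict abort on any absent endpoint instead of skipping it.
#' @return `list(sources, targets, warnings)` with the surviving endpoint
#'   sets and one message per absent node.
#' @export
validate_endpoints <- function(network, sources, targets, strict = FALSE) {
  sources <- node_set(sources)
  targets <- node_set(targets)
  miss_s <- setdiff(sources, network$nodes)
  miss_t <- setdiff(targets, network$nodes)
  warnings <- c(
    if (length(miss_s)) sprintf("source '%s' is not in the network", miss_s),
    if (length(miss_t)) sprintf("target '%s' is not in the network", miss_t)
  )
  if (strict && length(warnings))
    ksp_stop("absent endpoints in strict mode: %s",
             paste(c(miss_s, miss_t), collapse = ", "))
  keep_s <- setdiff(sources, miss_s)
  keep_t <- setdiff(targets, miss_t)
  if (length(keep_s) == 0L)
    ksp_stop("none of the sources are in the network")
  if (length(keep_t) == 0L)
    ksp_stop("none of the targets are in the network")
  for (w in warnings) ksp_warn("%s; skipping it", w)
  list(sources = keep_s, targets = keep_t, warnings = warnings)
}

#' Build the augmented query graph
#'
#' Constructs the [costed_graph()] on which the engine runs: unless
#' `allow_sources_targets_in_paths`, every edge into a source and out of a
#' target is removed, so sources can only start and targets only end a path;
#' then a super source with zero-cost edges to every source and a super
#' target with zero-cost edges from every target are added, reducing the
#' set-to-set search to a single-pair search.  Super edges cost exactly 0 in
#' every weight mode, so neither costs nor reported scores ever count them.
#'
#' @param network an [interaction_network()].
#' @param query a [path_query()] whose endpoints are already validated.
#' @param config a [cost_config()].
#' @return a [costed_graph()] whose `super_source` / `super_target` fields
#'   name the two auxiliary nodes.
#' @export
prepare_query_graph <- function(network, query, config) {
  stopifnot(inherits(network, "interaction_network"),
            inherits(query, "path_query"), inherits(config, "cost_config"))
  ed <- network$edges
  keep <- rep(TRUE, nrow(ed))
  if (!query$allow_sources_targets_in_paths) {
    keep <- !(ed$head %in% query$sources) & !(ed$tail %in% query$targets)
  }
  ed <- ed[keep, , drop = FALSE]

  ss <- unique_id("SUPER_SOURCE", network$nodes)
  st <- unique_id("SUPER_TARGET", network$nodes)
  nodes <- c(network$nodes, ss, st)

  tail_i <- match(ed$tail, nodes)
  head_i <- match(ed$head, nodes)
  cost <- if (nrow(ed)) edge_cost(ed$weight, config) else numeric()
  weight <- ed$weight

  src_i <- match(query$sources, nodes)
  tgt_i <- match(query$targets, nodes)
  n <- length(nodes)
  tail_i <- c(tail_i, rep(n - 1L, length(src_i)), tgt_i)
  head_i <- c(head_i, src_i, rep(n, length(tgt_i)))
  cost <- c(cost, numeric(length(src_i) + length(tgt_i)))
  weight <- c(weight, rep(NA_real_, length(src_i) + length(tgt_i)))

  build_costed_graph(nodes, tail_i, head_i, cost, weight,
                     super_source = ss, super_target = st)
}

#' @noRd
unique_id <- function(base, existing) {
  id <- paste0("__", base, "__")
  while (id %in% existing) id <- paste0(id, "_")
  id
}

#' Reconstruct a pathway as the k best-scoring source-to-target paths
#'
#' The full reconstruction pipeline: validates the endpoints against the
#' network, builds the augmented query graph ([prepare_query_graph()]),
#' computes reverse-traversal Dijkstra distances to the super target as the
#' A* heuristic, runs [yen_ksp()], strips the super nodes, attaches
#' user-facing scores ([path_score()]) and assembles the annotated
#' sub-network ([compute_subnetwork()]).  In probability mode the ranked
#' paths appear in non-increasing score order (the engine minimises the
#' summed negative-log cost).
#'
#' @param network an [interaction_network()].
#' @param sources,targets endpoint identifier sets (see [node_set()]);
#'   alternatively pass a ready-made [path_query()] as `query`.
#' @param k,allow_sources_targets_in_paths,targets_are_sources see
#'   [path_query()].
#' @param weight_mode `"auto"` (probability when the network is weighted,
#'   unweighted otherwise) or one of the [cost_config()] modes.
#' @param edge_penalty see [cost_config()].
#' @param strict abort on absent endpoints (see [validate_endpoints()]).
#' @param query,config optional pre-built [path_query()] / [cost_config()]
#'   overriding the individual arguments.
#' @return an object of class `pathlinker_result`: a list with
#'   * `paths`: data.frame `rank`, `score`, `cost`, `length`, `path`
#'     (pipe-joined node sequence);
#'   * `path_nodes`: list of node-identifier vectors, one per path;
#'   * `subnetwork`: the annotated sub-network (see [compute_subnetwork()]);
#'   * `query`, `config`: the effective query and cost configuration.
#' @export
#' @examples
#' net <- interaction_network(data.frame(
#'   tail = c("s", "a", "s", "b"), head = c("a", "t", "b", "t"),
#'   weight = c(0.8, 0.8, 0.5, 0.5)))
#' res <- run_pathlinker(net, sources = "s", targets = "t", k = 10)
#' res$paths
run_pathlinker <- function(network, sources = NULL, targets = NULL, k = 200,
                           weight_mode = c("auto", "unweighted", "additive",
                                           "probability"),
                           edge_penalty = NULL,
                           allow_sources_targets_in_paths = FALSE,
                           targets_are_sources = FALSE,
                           strict = FALSE, query = NULL, config = NULL) {
  stopifnot(inherits(network, "interaction_network"))
  if (is.null(query))
    query <- path_query(sources, targets, k = k,
                        allow_sources_targets_in_paths =
                          allow_sources_targets_in_paths,
                        targets_are_sources = targets_are_sources)
  if (is.null(config)) {
    weight_mode <- match.arg(weight_mode)
    if (weight_mode == "auto")
      weight_mode <- if (network$weighted) "probability" else "unweighted"
    config <- cost_config(weight_mode, edge_penalty)
  }

  val <- validate_endpoints(network, query$sources, query$targets,
                            strict = strict)
  query$sources <- val$sources
  query$targets <- val$targets

  graph <- prepare_query_graph(network, query, config)
  heur <- reverse_dijkstra(graph, graph$super_target)

  # paths consisting of a single shared endpoint (super edges only) carry no
  # real edge; ask for enough extra paths to absorb and then drop them
  n_trivial <- length(intersect(query$sources, query$targets))
  raw <- yen_ksp(graph, graph$super_source, graph$super_target,
                 k = query$k + n_trivial, heuristic = heur)

  paths <- list()
  costs <- numeric()
  for (p in raw) {
    nodes <- p$nodes[c(-1L, -length(p$nodes))]   # strip super nodes
    if (length(nodes) < 2L) next                 # no real edge
    paths <- c(paths, list(nodes))
    costs <- c(costs, p$cost)
    if (length(paths) == query$k) break
  }

  scores <- vapply(paths, path_score, numeric(1),
                   network = network, config = config)
  tab <- data.frame(
    rank = seq_along(paths),
    score = scores,
    cost = costs,
    length = vapply(paths, length, integer(1)) - 1L,
    path = vapply(paths, paste, character(1), collapse = "|"),
    stringsAsFactors = FALSE
  )
  structure(
    list(paths = tab, path_nodes = paths,
         subnetwork = compute_subnetwork(paths, network),
         query = query, config = config),
    class = "pathlinker_result"
  )
}

#' Assemble the annotated sub-network of a path list
#'
#' The sub-network is exactly the union of the nodes and edges of the ranked
#' paths; every element is annotated with its first-path index — the rank of
#' the first path that contains it — which orders reconstructed pathway
#' elements by how early they enter the result.
#'
#' @param paths list of node-identifier vectors in rank order (rank =
#'   position in the list), or a `pathlinker_result`.
#' @param network the [interaction_network()] the paths live in (used to copy
#'   edge weights).
#' @return an object of class `pathlinker_subnetwork`: a list of two
#'   data.frames, `nodes` (`node`, `first_path_index`) and `edges` (`tail`,
#'   `head`, `weight`, `first_path_index`).
#' @export
compute_subnetwork <- function(paths, network) {
  if (inherits(paths, "pathlinker_result")) paths <- paths$path_nodes
  stopifnot(inherits(network, "interaction_network"))
  node_idx <- list()
  edge_idx <- list()
  ekey_all <- paste(network$edges$tail, network$edges$head, sep = "\t")
  for (r in seq_along(paths)) {
    p <- paths[[r]]
    for (v in p) if (is.null(node_idx[[v]])) node_idx[[v]] <- r
    if (length(p) >= 2L) {
      ek <- paste(p[-length(p)], p[-1L], sep = "\t")
      if (anyNA(match(ek, ekey_all))) {
        bad <- which(is.na(match(ek, ekey_all)))[1L]
        ksp_stop("path %d uses edge %s which is not in the network", r,
                 gsub("\t", " -> ", ek[bad]))
      }
      for (e in ek) if (is.null(edge_idx[[e]])) edge_idx[[e]] <- r
    }
  }
  nodes <- data.frame(
    node = names(node_idx),
    first_path_index = as.integer(unlist(node_idx, use.names = FALSE)),
    stringsAsFactors = FALSE
  )
  ek <- names(edge_idx)
  if (length(ek) > 0L) {
    parts <- strsplit(ek, "\t", fixed = TRUE)
    edges <- data.frame(
      tail = vapply(parts, `[[`, "", 1L),
      head = vapply(parts, `[[`, "", 2L),
      weight = network$edges$weight[match(ek, ekey_all)],
      first_path_index = as.integer(unlist(edge_idx, use.names = FALSE)),
      stringsAsFactors = FALSE
    )
  } else {
    edges <- data.frame(tail = character(), head = character(),
                        weight = numeric(), first_path_index = integer(),
                        stringsAsFactors = FALSE)
  }
  if (length(node_idx) == 0L)
    nodes <- data.frame(node = character(), first_path_index = integer(),
                        stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges),
            class = "pathlinker_subnetwork")
}

#' @export
print.pathlinker_result <- function(x, ...) {
  cat(sprintf("Pathway reconstruction: %d path(s) from %d source(s) to %d target(s)\n",
              nrow(x$paths), length(x$query$sources), length(x$query$targets)))
  cat(sprintf("  weight mode: %s, edge penalty: %g, k requested: %d\n",
              x$config$weight_mode, x$config$edge_penalty, x$query$k))
  if (nrow(x$paths)) {
    print(utils::head(x$paths, 10L), row.names = FALSE)
    if (nrow(x$paths) > 10L)
      cat(sprintf("  ... and %d more paths\n", nrow(x$paths) - 10L))
  }
  invisible(x)
}

#' @export
summary.pathlinker_result <- function(object, ...) {
  cat(sprintf("%d path(s); sub-network: %d nodes, %d edges\n",
              nrow(object$paths), nrow(object$subnetwork$nodes),
              nrow(object$subnetwork$edges)))
  if (nrow(object$paths)) {
    cat(sprintf("  path lengths: %d-%d edges; score range: [%g, %g]\n",
                min(object$paths$length), max(object$paths$length),
                min(object$paths$score), max(object$paths$score)))
  }
  invisible(object)
}

#' @export
print.pathlinker_subnetwork <- function(x, ...) {
  cat(sprintf("Annotated sub-network: %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Plot a reconstruction result
#'
#' Draws the annotated sub-network with nodes shaded by first-path index
#' (early paths dark).  Uses \pkg{igraph} for the layout when available and a
#' simple circular layout otherwise.
#'
#' @param x a `pathlinker_result`.
#' @param ... passed on to [graphics::plot()] / `plot.igraph`.
#' @return `x`, invisibly.
#' @export
plot.pathlinker_result <- function(x, ...) {
  sub <- x$subnetwork
  if (nrow(sub$nodes) == 0L) {
    plot.new(); title("empty sub-network"); return(invisible(x))
  }
  shade <- grDevices::gray(0.2 + 0.6 * (sub$nodes$first_path_index - 1) /
                             max(1, max(sub$nodes$first_path_index) - 1))
  if (requireNamespace("igraph", quietly = TRUE)) {
    g <- igraph::graph_from_data_frame(sub$edges[, c("tail", "head")],
                                       vertices = sub$nodes$node)
    igraph::plot.igraph(g, vertex.color = shade, vertex.label.cex = 0.8,
                        edge.arrow.size = 0.3, ...)
  } else {
    n <- nrow(sub$nodes)
    th <- 2 * pi * seq_len(n) / n
    xy <- cbind(cos(th), sin(th))
    rownames(xy) <- sub$nodes$node
    graphics::plot(xy, pch = 21, bg = shade, xlab = "", ylab = "",
                   axes = FALSE, asp = 1, ...)
    graphics::arrows(xy[sub$edges$tail, 1], xy[sub$edges$tail, 2],
                     xy[sub$edges$head, 1], xy[sub$edges$head, 2],
                     length = 0.08, col = "grey50")
    graphics::text(xy, labels = sub$nodes$node, pos = 3, cex = 0.8)
  }
  invisible(x)
}
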