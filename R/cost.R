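#' Edge-weight interpretation and edge penalty
#'
#' A cost configuration fixes how user-facing edge weights map to the internal
#' additive cost minimised by the path engine, and how a path's user-facing
#' score is computed:
#'
#' * `"unweighted"` — every edge costs 1; a path's score is its edge count
#'   and the k lowest-score paths are sought.
#' * `"additive"` — an edge of weight `w` costs `w + edge_penalty`; a path's
#'   score is the sum of its raw weights (lowest score = best).
#' * `"probability"` — weights in `(0, 1]` are multiplicative reliabilities;
#'   an edge of weight `w` costs `|log w| + log(edge_penalty)` (natural log),
#'   so minimising summed cost maximises the product of weights; a path's
#'   score is that product (highest score = best).
#'
#' The edge penalty discourages long paths: each edge adds `edge_penalty` to
#' the cost (additive case), or `log(edge_penalty)` after the log transform
#' (probability case).  Defaults: 1 for probability weights, 0 otherwise.
#' The penalty affects ranking only; reported path scores are computed from
#' the raw weights and exclude it.
#'
#' @param weight_mode one of `"unweighted"`, `"additive"`, `"probability"`.
#' @param edge_penalty non-negative number; must be `>= 1` in probability
#'   mode.  An invalid value falls back to the mode's default with a warning.
#' @return an object of class `cost_config` with elements `weight_mode` and
#'   `edge_penalty`.
#' @export
#' @examples
#' cost_config("probability")            # penalty defaults to 1
#' cost_config("additive", edge_penalty = 2)
cost_config <- function(weight_mode = c("unweighted", "additive", "probability"),
                        edge_penalty = NULL) {
  weight_mode <- match.arg(weight_mode)
  default <- if (weight_mode == "probability") 1 else 0
  if (is.null(edge_penalty)) {
    edge_penalty <- default
  } else {
    ok <- is.numeric(edge_penalty) && length(edge_penalty) == 1L &&
      is.finite(edge_penalty) &&
      (if (weight_mode == "probability") edge_penalty >= 1 else edge_penalty >= 0)
    if (!ok) {
      ksp_warn("invalid edge penalty for %s mode; using the default (%g)",
               weight_mode, default)
      edge_penalty <- default
    }
  }
  structure(list(weight_mode = weight_mode, edge_penalty = edge_penalty),
            class = "cost_config")
}

#' @export
print.cost_config <- function(x, ...) {
  cat(sprintf("Cost configuration: %s weights, edge penalty %g\n",
              x$weight_mode, x$edge_penalty))
  invisible(x)
}

#' Internal additive cost of a single edge
#'
#' Maps a raw edge weight to the internal cost summed along paths by the
#' search engine (see [cost_config()] for the three weight models).
#'
#' @param weight numeric vector of raw weights (`NA` allowed only in
#'   unweighted mode, where it is ignored).
#' @param config a [cost_config()].
#' @return numeric vector of non-negative costs.
#' @export
#' @examples
#' edge_cost(NA, cost_config("unweighted"))                    # 1
#' edge_cost(0.5, cost_config("probability"))                  # log(2)
#' edge_cost(2, cost_config("additive", edge_penalty = 3))     # 5
edge_cost <- function(weight, config) {
  stopifnot(inherits(config, "cost_config"))
  switch(config$weight_mode,
    unweighted = rep(1, length(weight)),
    additive = {
      check_weights(weight, config)
      weight + config$edge_penalty
    },
    probability = {
      check_weights(weight, config)
      abs(log(weight)) + log(config$edge_penalty)
    }
  )
}

#' @noRd
check_weights <- function(weight, config) {
  if (anyNA(weight))
    ksp_stop("%s mode requires every edge to carry a weight", config$weight_mode)
  if (config$weight_mode == "probability") {
    if (any(weight <= 0 | weight > 1))
      ksp_stop("probability weights must lie in (0, 1]; found %s",
               format(weight[weight <= 0 | weight > 1][1L]))
  } else if (any(weight < 0)) {
    ksp_stop("additive weights must be non-negative; found %s",
             format(min(weight)))
  }
  invisible(NULL)
}

#' User-facing score of a path
#'
#' Computes the reported score of a node sequence from the raw edge weights of
#' the network: edge count (unweighted), sum of weights (additive) or product
#' of weights (probability).  The edge penalty never enters the score.
#'
#' @param nodes character vector, the ordered node sequence of the path.
#' @param network an [interaction_network()] containing every consecutive
#'   `(nodes[i], nodes[i+1])` edge.
#' @param config a [cost_config()].
#' @return a single number.
#' @export
#' @examples
#' net <- interaction_network(data.frame(tail = c("s", "a"), head = c("a", "t"),
#'                                       weight = c(0.5, 0.5)))
#' path_score(c("s", "a", "t"), net, cost_config("probability"))  # 0.25
path_score <- function(nodes, network, config) {
  stopifnot(inherits(network, "interaction_network"),
            inherits(config, "cost_config"))
  if (length(nodes) < 2L)
    ksp_stop("a path needs at least two nodes")
  key <- paste(network$edges$tail, network$edges$head, sep = "\t")
  want <- paste(nodes[-length(nodes)], nodes[-1L], sep = "\t")
  idx <- match(want, key)
  if (anyNA(idx)) {
    miss <- which(is.na(idx))[1L]
    ksp_stop("path uses edge %s -> %s which is not in the network",
             nodes[miss], nodes[miss + 1L])
  }
  w <- network$edges$weight[idx]
  switch(config$weight_mode,
    unweighted = length(nodes) - 1,
    additive = {
      check_weights(w, config)
      sum(w)
    },
    probability = {
      check_weights(w, config)
      prod(w)
    }
  )
}
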