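#' Construct an interaction network
#'
#' Builds the directed interaction network object used throughout the package.
#' Nodes are opaque, case-sensitive string identifiers; every edge is directed
#' and may carry a non-negative real weight.  Either all edges are weighted or
#' none are (mixed weighting is rejected): weights are typically experimental
#' reliabilities (probabilities in `(0, 1]`) or additive costs.
#'
#' Normalisation applied on construction:
#' * identifiers are whitespace-trimmed; empty identifiers are an error;
#' * self-loops are dropped with a warning (a loopless path can never use one);
#' * duplicate `(tail, head)` pairs are collapsed keeping the **maximum**
#'   weight — the strongest evidence for the interaction — with a warning.
#'
#' @param edges a data.frame with character columns `tail`, `head` and an
#'   optional numeric `weight` column (all present or all absent/`NA`).
#' @param nodes optional character vector of additional (possibly isolated)
#'   node identifiers.
#' @return an object of class `interaction_network`: a list with elements
#'   `nodes` (character vector, input order, duplicates removed) and `edges`
#'   (data.frame `tail`, `head`, `weight`), plus a logical `weighted` flag.
#' @seealso [read_edge_list()] to load one from a file.
#' @export
#' @examples
#' net <- interaction_network(data.frame(
#'   tail = c("a", "a", "b"), head = c("b", "c", "c"),
#'   weight = c(0.5, 0.25, 0.9)))
#' net
interaction_network <- function(edges, nodes = NULL) {
  if (!is.data.frame(edges)) ksp_stop("'edges' must be a data.frame")
  if (nrow(edges) > 0 && !all(c("tail", "head") %in% names(edges)))
    ksp_stop("'edges' must have columns 'tail' and 'head'")
  if (nrow(edges) == 0) {
    edges <- data.frame(tail = character(), head = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  }
  tail <- trimws(as.character(edges$tail))
  head <- trimws(as.character(edges$head))
  if (any(!nzchar(tail)) || any(!nzchar(head)))
    ksp_stop("empty node identifier in edge list")

  weighted <- "weight" %in% names(edges) && nrow(edges) > 0 &&
    !all(is.na(edges$weight))
  if (weighted) {
    weight <- as.numeric(edges$weight)
    if (anyNA(weight))
      ksp_stop("mixed weighted and unweighted edges are not allowed")
    if (any(weight < 0))
      ksp_stop("negative edge weight: %s", format(min(weight)))
  } else {
    weight <- rep(NA_real_, length(tail))
  }

  all_ids <- c(tail, head)   # node set before any edge is dropped
  loops <- tail == head
  if (any(loops)) {
    ksp_warn("dropped %d self-loop edge(s) (loopless paths cannot use them)",
             sum(loops))
    tail <- tail[!loops]; head <- head[!loops]; weight <- weight[!loops]
  }

  key <- paste(tail, head, sep = "\t")
  if (anyDuplicated(key)) {
    ksp_warn("collapsed %d duplicate edge(s), keeping the maximum weight",
             sum(duplicated(key)))
    if (weighted) {
      keep <- order(key, -weight)           # max weight first within key
      keep <- keep[!duplicated(key[keep])]
      keep <- sort(keep)                    # restore input order
    } else {
      keep <- which(!duplicated(key))
    }
    tail <- tail[keep]; head <- head[keep]; weight <- weight[keep]
  }

  node_ids <- unique(c(all_ids,
                       if (!is.null(nodes)) trimws(as.character(nodes))))
  structure(
    list(
      nodes = node_ids,
      edges = data.frame(tail = tail, head = head, weight = weight,
                         stringsAsFactors = FALSE),
      weighted = weighted
    ),
    class = "interaction_network"
  )
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("Directed interaction network: %d nodes, %d edges (%s)\n",
              length(x$nodes), nrow(x$edges),
              if (x$weighted) "weighted" else "unweighted"))
  if (nrow(x$edges) > 0) {
    show <- utils::head(x$edges, 5L)
    for (i in seq_len(nrow(show))) {
      cat(sprintf("  %s -> %s%s\n", show$tail[i], show$head[i],
                  if (x$weighted) sprintf("  [%g]", show$weight[i]) else ""))
    }
    if (nrow(x$edges) > 5) cat(sprintf("  ... and %d more\n", nrow(x$edges) - 5L))
  }
  invisible(x)
}

#' Read a directed network from an edge-list file
#'
#' Reads a tab-separated edge list (`tail<TAB>head[<TAB>weight]`) or a SIF file
#' (`tail relation head`, whitespace-separated; the relation is discarded and
#' the network is treated as unweighted).  Lines starting with `#` and blank
#' lines are ignored.  All lines of a TSV file must agree on whether a weight
#' column is present.
#'
#' @param file path to the file, or a character vector of lines (for testing).
#' @param format `"auto"` (SIF if the extension is `.sif`), `"tsv"` or `"sif"`.
#' @param undirected if `TRUE`, each input edge `(u, v)` also yields `(v, u)`
#'   with the same weight (default `FALSE`: input is taken as directed).
#' @return an [interaction_network()].
#' @export
read_edge_list <- function(file, format = c("auto", "tsv", "sif"),
                           undirected = FALSE) {
  format <- match.arg(format)
  if (length(file) == 1L && !grepl("\n", file) &&
      (file.exists(file) || grepl("[/\\\\]", file))) {
    if (!file.exists(file)) ksp_stop("network file not found: %s", file)
    if (format == "auto")
      format <- if (grepl("\\.sif$", file, ignore.case = TRUE)) "sif" else "tsv"
    lines <- readLines(file, warn = FALSE)
  } else {
    lines <- unlist(strsplit(file, "\n", fixed = TRUE), use.names = FALSE)
    if (format == "auto") format <- "tsv"
  }

  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  if (length(keep) == 0L)
    return(interaction_network(data.frame(tail = character(),
                                          head = character())))

  if (format == "sif") {
    parts <- strsplit(trimws(lines[keep]), "\\s+")
    nf <- lengths(parts)
    if (any(nf != 3L))
      ksp_stop("line %d: expected 3 whitespace-separated fields (tail relation head), got %d",
               keep[which(nf != 3L)[1L]], nf[nf != 3L][1L])
    tails <- vapply(parts, `[[`, "", 1L)
    heads <- vapply(parts, `[[`, "", 3L)
    weights <- rep(NA_real_, length(tails))
  } else {
    parts <- strsplit(lines[keep], "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf < 2L | nf > 3L))
      ksp_stop("line %d: expected 2 or 3 tab-separated fields, got %d",
               keep[which(nf < 2L | nf > 3L)[1L]], nf[nf < 2L | nf > 3L][1L])
    if (length(unique(nf)) > 1L)
      ksp_stop("mixed weighted and unweighted lines (first mismatch at line %d)",
               keep[which(nf != nf[1L])[1L]])
    tails <- vapply(parts, `[[`, "", 1L)
    heads <- vapply(parts, `[[`, "", 2L)
    if (nf[1L] == 3L) {
      wtxt <- vapply(parts, `[[`, "", 3L)
      weights <- suppressWarnings(as.numeric(wtxt))
      if (anyNA(weights))
        ksp_stop("line %d: weight '%s' is not a number",
                 keep[which(is.na(weights))[1L]], wtxt[is.na(weights)][1L])
      if (any(weights < 0))
        ksp_stop("line %d: negative weight %s",
                 keep[which(weights < 0)[1L]], format(weights[weights < 0][1L]))
    } else {
      weights <- rep(NA_real_, length(tails))
    }
  }

  if (undirected) {
    tails2 <- c(tails, heads)
    heads2 <- c(heads, tails)
    weights <- c(weights, weights)
    tails <- tails2; heads <- heads2
  }
  interaction_network(data.frame(tail = tails, head = heads, weight = weights,
                                 stringsAsFactors = FALSE))
}

#' Parse a node-identifier set
#'
#' Accepts a space-separated string, a character vector, or a file of
#' identifiers (one per line), trims whitespace and removes duplicates keeping
#' first occurrences.
#'
#' @param x a character vector (each element may hold several space-separated
#'   identifiers) or, with `from_file = TRUE`, a file path.
#' @param from_file read identifiers from the named file.
#' @return character vector of unique identifiers in input order.
#' @export
node_set <- function(x, from_file = FALSE) {
  if (from_file) {
    if (!file.exists(x)) ksp_stop("node file not found: %s", x)
    x <- readLines(x, warn = FALSE)
  }
  ids <- trimws(unlist(strsplit(as.character(x), "\\s+"), use.names = FALSE))
  ids <- ids[nzchar(ids)]
  if (length(ids) == 0L) ksp_stop("empty node set")
  unique(ids)
}
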