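# Writers for the tab-separated output formats: the ranked path table and
# the two sub-network tables.  All outputs are UTF-8 with '\n' line endings
# and '.' as the decimal separator.

#' Write the ranked path table
#'
#' One TSV row per path after a header: `rank`, `score` (decimal text) and
#' the pipe-delimited node sequence.
#'
#' @param paths a `pathlinker_result` or its `paths` data.frame (columns
#'   `rank`, `score`, `path`).
#' @param file path or connection.
#' @return the input, invisibly.
#' @export
write_path_table <- function(paths, file) {
  tab <- if (inherits(paths, "pathlinker_result")) paths$paths else paths
  stopifnot(is.data.frame(tab), all(c("rank", "score", "path") %in% names(tab)))
  lines <- c("rank\tscore\tpath",
             sprintf("%d\t%s\t%s", tab$rank, num_text(tab$score), tab$path))
  writeLines(lines, file, useBytes = TRUE)
  invisible(paths)
}

#' Write the annotated sub-network tables
#'
#' Emits an edge table (`tail`, `head`, `weight`, `edge_first_path_index`)
#' and a node table (`node`, `node_first_path_index`).  Re-reading the edge
#' table with [read_edge_list()] reproduces the sub-network's edge set and
#' weights exactly.
#'
#' @param sub a `pathlinker_subnetwork` (or a `pathlinker_result`).
#' @param edges_file,nodes_file output paths or connections.
#' @return the input, invisibly.
#' @export
write_subnetwork <- function(sub, edges_file, nodes_file) {
  if (inherits(sub, "pathlinker_result")) sub <- sub$subnetwork
  stopifnot(inherits(sub, "pathlinker_subnetwork"))
  e <- sub$edges
  elines <- c("tail\thead\tweight\tedge_first_path_index",
              if (nrow(e)) sprintf("%s\t%s\t%s\t%d", e$tail, e$head,
                                   num_text(e$weight), e$first_path_index))
  writeLines(elines, edges_file, useBytes = TRUE)
  n <- sub$nodes
  nlines <- c("node\tnode_first_path_index",
              if (nrow(n)) sprintf("%s\t%d", n$node, n$first_path_index))
  writeLines(nlines, nodes_file, useBytes = TRUE)
  invisible(sub)
}

# decimal text with '.' separator, full precision, no scientific notation
# surprises for the magnitudes this package produces
#' @noRd
num_text <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else format(v, digits = 15, scientific = FALSE,
                                   trim = TRUE, decimal.mark = ".")
  }, character(1))
  out
}
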