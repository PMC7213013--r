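# Graph export for haplotype/genotype networks.

#' Convert a network to an igraph object
#'
#' Node attributes `kind`, `frequency` (and `group` if supplied), edge
#' attributes `weight` (mutation steps) and `alternative`.
#'
#' @param x a `haplo_network` or `sp_network`.
#' @param grouping optional named vector node -> group id, recorded as a
#'   node attribute.
#' @return an `igraph` graph.
#' @export
as_igraph <- function(x, grouping = NULL) {
  if (inherits(x, "haplo_network")) {
    vertices <- data.frame(name = rownames(x$states), kind = x$kind,
                           frequency = ifelse(x$kind == "observed",
                                              x$frequency[rownames(x$states)], 0),
                           stringsAsFactors = FALSE)
    edges <- data.frame(from = x$edges$u, to = x$edges$v,
                        weight = x$edges$weight, alternative = FALSE)
  } else if (inherits(x, "sp_network")) {
    vertices <- data.frame(name = x$nodes$id, kind = x$nodes$kind,
                           frequency = x$nodes$frequency,
                           stringsAsFactors = FALSE)
    edges <- data.frame(from = x$edges$u, to = x$edges$v,
                        weight = x$edges$steps, alternative = x$edges$alternative)
  } else stop("cannot convert ", paste(class(x), collapse = "/"))
  if (!is.null(grouping))
    vertices$group <- unname(grouping[vertices$name])
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vertices)
}

#' Write a network as GraphML
#' @param x network object (see [as_igraph()]).
#' @param path output path.
#' @param grouping optional node grouping attribute.
#' @export
write_graphml <- function(x, path, grouping = NULL) {
  igraph::write_graph(as_igraph(x, grouping), path, format = "graphml")
  invisible(path)
}

#' Write a network as DOT
#' @inheritParams write_graphml
#' @export
write_dot <- function(x, path, grouping = NULL) {
  igraph::write_graph(as_igraph(x, grouping), path, format = "dot")
  invisible(path)
}
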