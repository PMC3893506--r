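#' Read a directed pathway edge list
#'
#' TSV with columns \code{pathway_id}, \code{source}, \code{target},
#' \code{edge_type}.
#'
#' @param path File path.
#' @return \code{data.frame} with those four character columns.
#' @export
read_pathway_edges <- function(path) {
  df <- read.delim(path, colClasses = "character")
  need <- c("pathway_id", "source", "target", "edge_type")
  if (!all(need %in% names(df)))
    abort_input("edge list needs columns: ", paste(need, collapse = ", "))
  df[need]
}

#' Build a cleaned directed pathway graph
#'
#' Drops self-loops, collapses duplicate edges (the first occurrence's
#' \code{edge_type} wins; conflicting duplicates are reported in the
#' \code{"type_conflicts"} attribute).
#'
#' @param edges \code{data.frame} with columns \code{source},
#'   \code{target}, optional \code{edge_type}.
#' @param nodes Optional node universe (isolated nodes retained).
#' @return A list of class \code{"pathway_graph"} with \code{edges} and
#'   \code{nodes}.
#' @export
pathway_graph <- function(edges, nodes = NULL) {
  if (is.null(edges$edge_type)) edges$edge_type <- ""
  edges <- edges[, c("source", "target", "edge_type")]
  edges <- edges[edges$source != edges$target, , drop = FALSE]
  key <- paste(edges$source, edges$target, sep = "\r")
  dup <- duplicated(key)
  conflicts <- unique(key[dup][edges$edge_type[dup] !=
                                 edges$edge_type[match(key[dup], key)]])
  edges <- edges[!dup, , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- unique(c(nodes, edges$source, edges$target))
  structure(list(edges = edges, nodes = nodes,
                 type_conflicts = conflicts),
            class = "pathway_graph")
}

#' Merge several pathway graphs into one
#'
#' Node union and deduplicated edge union; on conflicting duplicate edge
#' types the first occurrence wins and the conflict is reported.
#'
#' @param graphs List of \code{"pathway_graph"} objects (or edge
#'   \code{data.frame}s).
#' @return A single \code{"pathway_graph"}.
#' @export
merge_graphs <- function(graphs) {
  if (length(graphs) == 0L)
    return(pathway_graph(data.frame(source = character(),
                                    target = character(),
                                    edge_type = character(),
                                    stringsAsFactors = FALSE)))
  parts <- lapply(graphs, function(g) {
    if (inherits(g, "pathway_graph")) g$edges else
      g[, intersect(c("source", "target", "edge_type"), names(g)),
        drop = FALSE]
  })
  all_nodes <- unique(unlist(lapply(graphs, function(g)
    if (inherits(g, "pathway_graph")) g$nodes else NULL)))
  pathway_graph(do.call(rbind, parts), nodes = all_nodes)
}

#' Relative betweenness centrality of graph nodes
#'
#' Standard shortest-path betweenness on the directed, unweighted graph
#' (endpoints excluded, fractional credit over equal-length shortest
#' paths), normalized by \code{(n-1)(n-2)} so values lie in [0, 1]. Graphs
#' with fewer than 3 nodes score all zeros; isolated nodes score 0.
#'
#' @param graph A \code{"pathway_graph"} (or edge \code{data.frame}).
#' @return \code{data.frame} with \code{node} and \code{centrality},
#'   ordered by node id.
#' @export
relative_betweenness <- function(graph) {
  if (!inherits(graph, "pathway_graph")) graph <- pathway_graph(graph)
  n <- length(graph$nodes)
  nodes <- sort(graph$nodes)
  if (n < 3L)
    return(data.frame(node = nodes, centrality = rep(0, n),
                      stringsAsFactors = FALSE))
  g <- igraph::graph_from_data_frame(graph$edges[, c("source", "target")],
                                     directed = TRUE,
                                     vertices = data.frame(name = nodes))
  bw <- igraph::betweenness(g, directed = TRUE, weights = NA)
  data.frame(node = nodes,
             centrality = unname(bw[nodes]) / ((n - 1) * (n - 2)),
             stringsAsFactors = FALSE)
}

#' Select core nodes above a centrality cut
#'
#' Nodes with relative betweenness strictly greater than \code{cut};
#' optionally intersected with a set of selected microRNA targets, yielding
#' the "core microRNA targets" of a multi-pathway network.
#'
#' @param table Output of \code{\link{relative_betweenness}}.
#' @param cut Threshold (default 0.01, strict).
#' @param targets Optional character vector to intersect with.
#' @return Character vector of core node ids.
#' @export
select_core_nodes <- function(table, cut = 0.01, targets = NULL) {
  core <- table$node[table$centrality > cut]
  if (!is.null(targets)) core <- intersect(core, targets)
  core
}
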