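#' Build the thresholded chapter co-occurrence network for one stratum
#'
#' Undirected graph over the full chapter set (isolated nodes retained so
#' every stratum shares the same fixed node layout) with an edge between two
#' chapters whenever their predicted Jaccard index is at or above the
#' threshold and the pair's model is unflagged. The default 0.30 threshold
#' marks a clinically meaningful (>= 30%) probability of co-occurrence within
#' the profile's followup window; the boundary is inclusive.
#'
#' @param jmatrix A `jaccard_matrix` (see [assemble_matrices()]).
#' @param threshold Edge threshold on the Jaccard index, in `[0, 1]`.
#' @return Object of class `chapter_network`: `nodes` (fixed chapter order),
#'   `edges` (data frame `chapter1`, `chapter2`, `weight`, lexicographically
#'   sorted), `threshold`, `stratum`.
#' @export
build_network <- function(jmatrix, threshold = 0.30) {
  stopifnot(inherits(jmatrix, "jaccard_matrix"))
  if (threshold < 0 || threshold > 1) {
    stop("threshold must be in [0, 1]", call. = FALSE)
  }
  idx <- jmatrix$index
  chapters <- rownames(idx)
  ut <- which(upper.tri(idx), arr.ind = TRUE)
  w <- idx[ut]
  flagged <- jmatrix$flags[ut]
  keep <- !is.na(w) & !flagged & w >= threshold
  edges <- data.frame(chapter1 = chapters[ut[keep, 1]],
                      chapter2 = chapters[ut[keep, 2]],
                      weight = w[keep],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$chapter1, edges$chapter2), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = chapters, edges = edges, threshold = threshold,
                 stratum = jmatrix$stratum),
            class = "chapter_network")
}

#' Number of edges in a chapter network
#' @param graph A `chapter_network`.
#' @return Integer edge count.
#' @export
count_edges <- function(graph) {
  stopifnot(inherits(graph, "chapter_network"))
  nrow(graph$edges)
}

#' @export
print.chapter_network <- function(x, ...) {
  cat(sprintf("Chapter network — %s: %d nodes, %d edges at index >= %.2f\n",
              stratum_label(x$stratum), length(x$nodes), count_edges(x),
              x$threshold))
  invisible(x)
}

#' Convert a chapter network to an igraph object
#'
#' @param graph A `chapter_network`.
#' @return An \pkg{igraph} undirected graph with edge attribute `weight`.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "chapter_network"))
  igraph::graph_from_data_frame(graph$edges, directed = FALSE,
                                vertices = data.frame(name = graph$nodes))
}

#' @export
plot.chapter_network <- function(x, ...) {
  g <- as_igraph(x)
  igraph::plot.igraph(g, layout = igraph::layout_in_circle(g),
                      main = stratum_label(x$stratum), ...)
  invisible(x)
}

#' Export a chapter network
#'
#' `export_edge_list()` writes a CSV with one row per edge (`stratum`,
#' `chapter1`, `chapter2`, `weight` with fixed 6-decimal formatting), sorted
#' lexicographically — byte-stable across runs on identical inputs. An empty
#' graph yields a header-only file. `export_graphml()` writes GraphML for
#' interoperability with graph viewers.
#'
#' @param graph A `chapter_network`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_edge_list <- function(graph, path) {
  stopifnot(inherits(graph, "chapter_network"))
  df <- data.frame(stratum = rep(stratum_label(graph$stratum), nrow(graph$edges)),
                   chapter1 = graph$edges$chapter1,
                   chapter2 = graph$edges$chapter2,
                   weight = formatC(graph$edges$weight, format = "f", digits = 6),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname export_edge_list
#' @export
export_graphml <- function(graph, path) {
  igraph::write_graph(as_igraph(graph), path, format = "graphml")
  invisible(path)
}
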