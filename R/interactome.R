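#' Protein-protein interactome
#'
#' An `interactome` is a simple undirected graph whose vertices are protein
#' accessions (typically UniProtKB). Self-interactions are excluded and each
#' unordered pair is stored once, so a protein's degree counts its distinct
#' neighbours.
#'
#' @param pairs two-column character matrix or data frame of interaction
#'   partners; order within a pair is irrelevant.
#' @return An object of class `interactome` wrapping an [igraph::graph] plus
#'   bookkeeping counts (`n_self_dropped`, `n_dup_dropped`).
#' @export
interactome <- function(pairs) {
  if (is.data.frame(pairs)) pairs <- as.matrix(pairs)
  if (length(pairs) == 0L) {
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    return(structure(list(graph = g, n_self_dropped = 0L, n_dup_dropped = 0L),
                     class = "interactome"))
  }
  if (!is.character(pairs)) storage.mode(pairs) <- "character"
  if (ncol(pairs) < 2L) stop("interaction pairs need two columns")
  a <- pairs[, 1L]; b <- pairs[, 2L]
  self <- a == b
  a <- a[!self]; b <- b[!self]
  # canonical order within the pair so A-B and B-A collapse
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  dup <- duplicated(key)
  g <- igraph::graph_from_edgelist(cbind(lo[!dup], hi[!dup]), directed = FALSE)
  structure(list(graph = g,
                 n_self_dropped = sum(self),
                 n_dup_dropped = sum(dup)),
            class = "interactome")
}

#' @export
print.interactome <- function(x, ...) {
  cat(sprintf("interactome: %d proteins, %d interactions\n",
              n_vertices(x), n_edges(x)))
  invisible(x)
}

#' Interactome accessors
#'
#' `interactome_vertices()` returns the accession set, `interactome_degree()`
#' the named degree index (distinct-neighbour counts), `n_vertices()` and
#' `n_edges()` the graph size.
#'
#' @param x an `interactome` or `subnetwork` object.
#' @return A character vector, a named integer vector, or a count.
#' @export
interactome_vertices <- function(x) {
  v <- igraph::V(graph_of(x))$name
  if (is.null(v)) character(0) else v
}

#' @rdname interactome_vertices
#' @export
interactome_degree <- function(x) {
  g <- graph_of(x)
  d <- igraph::degree(g)
  if (igraph::vcount(g) == 0L) d <- stats::setNames(integer(0), character(0))
  d
}

#' @rdname interactome_vertices
#' @export
n_vertices <- function(x) igraph::vcount(graph_of(x))

#' @rdname interactome_vertices
#' @export
n_edges <- function(x) igraph::ecount(graph_of(x))

graph_of <- function(x) {
  if (inherits(x, c("interactome", "subnetwork"))) x$graph
  else if (inherits(x, "igraph")) x
  else stop("not a graph-bearing object")
}
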