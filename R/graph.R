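#' Build the weighted herb co-occurrence graph
#'
#' An undirected edge joins two herbs iff at least one prescription contains
#' both; its weight is the number of such prescriptions (the co-occurrence
#' count). Herbs never co-prescribed with another herb remain as isolated,
#' degree-0 nodes, so the node order always equals the corpus vocabulary.
#'
#' @param corpus A non-empty \linkS4class{PrescriptionCorpus}.
#' @return A \linkS4class{CoOccurrenceGraph}.
#' @examples
#' g <- buildCooccurrenceGraph(exampleCorpus())
#' edgeTable(g)
#' @export
buildCooccurrenceGraph <- function(corpus) {
  if (!nPrescriptions(corpus)) stop("empty corpus")
  m <- binaryMatrix(corpus)
  cooc <- crossprod(m)               # herb x herb co-occurrence counts
  diag(cooc) <- 0
  vocab <- colnames(cooc)
  idx <- which(upper.tri(cooc) & cooc > 0, arr.ind = TRUE)
  edges <- data.frame(from = vocab[idx[, 1L]], to = vocab[idx[, 2L]],
                      weight = as.integer(cooc[idx]),
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), ]
  rownames(edges) <- NULL
  degree <- structure(as.numeric(rowSums(cooc)), names = vocab)
  new("CoOccurrenceGraph", nodes = vocab, edges = edges, degree = degree)
}

#' @describeIn vocabulary Node names of a co-occurrence graph.
#' @export
setMethod("vocabulary", "CoOccurrenceGraph", function(x) x@nodes)

#' @describeIn edgeTable Edge table of a co-occurrence graph.
#' @export
setMethod("edgeTable", "CoOccurrenceGraph", function(x) x@edges)

#' @describeIn nodeDegree Weighted degrees of a co-occurrence graph.
#' @export
setMethod("nodeDegree", "CoOccurrenceGraph", function(x) x@degree)

setMethod("show", "CoOccurrenceGraph", function(object) {
  cat("CoOccurrenceGraph with", length(object@nodes), "herbs and",
      nrow(object@edges), "edges\n")
  if (nrow(object@edges))
    cat("  weight range:", min(object@edges$weight), "-",
        max(object@edges$weight), "\n")
})

#' Convert a co-occurrence graph to an igraph object
#'
#' @param x A \linkS4class{CoOccurrenceGraph}.
#' @return An \code{igraph} undirected weighted graph (isolates retained).
#' @export
asIgraph <- function(x) {
  stopifnot(is(x, "CoOccurrenceGraph"))
  igraph::graph_from_data_frame(x@edges, directed = FALSE,
                                vertices = data.frame(name = x@nodes))
}

#' Export a graph as a weighted edge-list TSV or GraphML
#'
#' @param x A \linkS4class{CoOccurrenceGraph}.
#' @param path Output path; \code{.graphml} extension selects GraphML,
#'   anything else a three-column TSV.
#' @return Invisibly, the path.
#' @export
writeGraph <- function(x, path) {
  if (grepl("\\.graphml$", path, ignore.case = TRUE)) {
    igraph::write_graph(asIgraph(x), path, format = "graphml")
  } else {
    utils::write.table(x@edges, path, sep = "\t", row.names = FALSE,
                       quote = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}
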