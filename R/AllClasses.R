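#' @import methods
NULL

#' PrescriptionCorpus: a labeled collection of herb sets
#'
#' The central container of the package. Each prescription is an unordered set
#' of standardized herb names together with a group label
#' (\code{"anti_recurrence"} or \code{"general"}). Dosages are not modeled:
#' all downstream statistics are presence-based, so prescriptions are sets,
#' never multisets. The vocabulary is the sorted union of all herb sets, which
#' fixes a deterministic column order for the binary encoding and a node order
#' for the co-occurrence graph.
#'
#' @slot prescriptions A named list of character vectors; names are
#'   prescription ids (unique), each element a sorted set of herb names.
#' @slot group Character vector parallel to \code{prescriptions}, each entry
#'   one of \code{"anti_recurrence"} or \code{"general"}.
#' @slot vocabulary Sorted character vector: the union of all herb sets.
#'
#' @seealso \code{\link{readCorpus}}, \code{\link{binaryMatrix}},
#'   \code{\link{herbFrequency}}
#' @exportClass PrescriptionCorpus
setClass("PrescriptionCorpus",
  representation(
    prescriptions = "list",
    group = "character",
    vocabulary = "character"
  )
)

.validPrescriptionCorpus <- function(object) {
  msg <- character()
  p <- object@prescriptions
  if (length(p) != length(object@group))
    msg <- c(msg, "group labels must be parallel to prescriptions")
  if (length(p)) {
    if (is.null(names(p)) || anyDuplicated(names(p)))
      msg <- c(msg, "prescription ids must be present and unique")
    if (!all(object@group %in% c("anti_recurrence", "general")))
      msg <- c(msg, "group labels must be 'anti_recurrence' or 'general'")
    sizes <- lengths(p)
    if (any(sizes == 0L))
      msg <- c(msg, "every prescription must contain at least one herb")
    if (any(vapply(p, anyDuplicated, 0L) > 0L))
      msg <- c(msg, "duplicate herb within a prescription")
    herbs <- unique(unlist(p, use.names = FALSE))
    if (!setequal(herbs, object@vocabulary) ||
        is.unsorted(object@vocabulary, strictly = TRUE))
      msg <- c(msg, "vocabulary must be the sorted union of all herb sets")
  }
  if (length(msg)) msg else TRUE
}
setValidity("PrescriptionCorpus", .validPrescriptionCorpus)

#' HerbLexicon: raw-to-standard herb name mapping with herbal properties
#'
#' Maps raw herb names to standardized names and records the traditional
#' nature (cold/cool/neutral/warm/hot) and flavor categories of each herb.
#' Standardization against an external reference database happens outside the
#' package; the lexicon is a plain user-supplied table.
#'
#' @slot entries A data.frame with columns \code{raw_name},
#'   \code{standard_name}, \code{nature} (one of cold, cool, neutral, warm,
#'   hot, unknown) and \code{flavor} (a list column of character vectors over
#'   sour, bitter, sweet, pungent, salty, astringent, bland, unknown).
#'
#' @seealso \code{\link{readLexicon}}, \code{\link{standardizeHerbs}},
#'   \code{\link{propertyDistribution}}
#' @exportClass HerbLexicon
setClass("HerbLexicon", representation(entries = "data.frame"))

.natureLevels <- c("cold", "cool", "neutral", "warm", "hot", "unknown")
.flavorLevels <- c("sour", "bitter", "sweet", "pungent", "salty",
                   "astringent", "bland", "unknown")

.validHerbLexicon <- function(object) {
  e <- object@entries
  msg <- character()
  need <- c("raw_name", "standard_name", "nature", "flavor")
  if (!all(need %in% names(e)))
    return(paste("entries must have columns", paste(need, collapse = ", ")))
  if (nrow(e)) {
    if (anyDuplicated(e$raw_name))
      msg <- c(msg, "raw names must be unique")
    if (any(!nzchar(e$standard_name)))
      msg <- c(msg, "standard names must be non-empty")
    if (!all(e$nature %in% .natureLevels))
      msg <- c(msg, "unrecognized nature category")
    if (!is.list(e$flavor) ||
        !all(unlist(e$flavor, use.names = FALSE) %in% .flavorLevels))
      msg <- c(msg, "unrecognized flavor category")
  }
  if (length(msg)) msg else TRUE
}
setValidity("HerbLexicon", .validHerbLexicon)

#' CoOccurrenceGraph: weighted undirected herb co-occurrence graph
#'
#' Nodes are herbs; an edge joins two herbs iff at least one prescription
#' contains both, weighted by the number of such prescriptions. Herbs that
#' never co-occur with another herb are retained as degree-0 nodes, so the
#' node set always equals the corpus vocabulary.
#'
#' @slot nodes Ordered character vector of herb names.
#' @slot edges data.frame with columns \code{from}, \code{to} (herb names,
#'   \code{from < to} lexicographically) and \code{weight} (positive integer
#'   co-occurrence counts).
#' @slot degree Named numeric: weighted degree (sum of incident edge weights)
#'   per node.
#'
#' @seealso \code{\link{buildCooccurrenceGraph}}, \code{\link{gcnEmbed}}
#' @exportClass CoOccurrenceGraph
setClass("CoOccurrenceGraph",
  representation(nodes = "character", edges = "data.frame",
                 degree = "numeric")
)

.validCoOccurrenceGraph <- function(object) {
  msg <- character()
  e <- object@edges
  if (!all(c("from", "to", "weight") %in% names(e)))
    return("edges must have columns from, to, weight")
  if (nrow(e)) {
    if (!all(e$from %in% object@nodes) || !all(e$to %in% object@nodes))
      msg <- c(msg, "edge endpoints must be nodes")
    if (any(e$from == e$to)) msg <- c(msg, "self-edges are not allowed")
    if (any(e$weight <= 0) || any(e$weight != round(e$weight)))
      msg <- c(msg, "weights must be positive integers")
  }
  deg <- structure(numeric(length(object@nodes)), names = object@nodes)
  if (nrow(e)) {
    t1 <- tapply(e$weight, e$from, sum)
    t2 <- tapply(e$weight, e$to, sum)
    deg[names(t1)] <- deg[names(t1)] + t1
    deg[names(t2)] <- deg[names(t2)] + t2
  }
  if (!isTRUE(all.equal(deg[object@nodes],
                        object@degree[object@nodes], tolerance = 1e-9)))
    msg <- c(msg, "degree slot inconsistent with edge weights")
  if (length(msg)) msg else TRUE
}
setValidity("CoOccurrenceGraph", .validCoOccurrenceGraph)

#' HerbEmbedding: node embeddings from the graph-convolutional encoder
#'
#' @slot embedding Numeric matrix, one row per graph node (rownames = herb
#'   names), \code{out_dim} columns.
#' @slot lossTrace Numeric vector of per-epoch training losses.
#' @slot hyperparams List of the hyperparameters used (hidden_dim, out_dim,
#'   epochs, learning_rate, negatives_per_edge, seed, weighted_degree).
#'
#' @seealso \code{\link{gcnEmbed}}, \code{\link{clusterEmbeddings}}
#' @exportClass HerbEmbedding
setClass("HerbEmbedding",
  representation(embedding = "matrix", lossTrace = "numeric",
                 hyperparams = "list")
)

setValidity("HerbEmbedding", function(object) {
  msg <- character()
  if (is.null(rownames(object@embedding)))
    msg <- c(msg, "embedding rows must be named by herb")
  if (!all(is.finite(object@embedding)))
    msg <- c(msg, "embedding entries must be finite")
  if (length(msg)) msg else TRUE
})

#' ClusterAssignment: K-means labels over herb embeddings
#'
#' @slot k Integer number of clusters.
#' @slot labels Named integer vector mapping each herb to a cluster id in
#'   \code{1..k}; every cluster is non-empty.
#' @slot silhouette Mean silhouette width (Euclidean) of the assignment.
#' @slot silhouetteByK Named numeric of mean silhouette per candidate k when
#'   k was selected automatically (empty when k was fixed).
#'
#' @seealso \code{\link{clusterEmbeddings}}, \code{\link{scoreClusters}}
#' @exportClass ClusterAssignment
setClass("ClusterAssignment",
  representation(k = "integer", labels = "integer", silhouette = "numeric",
                 silhouetteByK = "numeric")
)

setValidity("ClusterAssignment", function(object) {
  msg <- character()
  if (is.null(names(object@labels)))
    msg <- c(msg, "labels must be named by herb")
  if (length(object@labels) &&
      !setequal(unique(object@labels), seq_len(object@k)))
    msg <- c(msg, "every cluster id in 1..k must be used")
  if (length(object@silhouette) != 1 ||
      object@silhouette < -1 || object@silhouette > 1)
    msg <- c(msg, "silhouette must be a scalar in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' ConsensusResult: agreement between the rule-mining and clustering arms
#'
#' Holds the candidate herb sets extracted from the association-rule arm and
#' the embedding-cluster arm, their intersection (the consensus core herb
#' spectrum), union, Venn counts, and per-herb evidence tags collected across
#' all four lines of evidence (rule mining, clustering, frequency banding,
#' random-forest importance).
#'
#' @slot ruleHerbs Character: herbs selected from the top association rules.
#' @slot clusterHerbs Character: herbs in the top-scoring cluster(s).
#' @slot intersection Character: herbs supported by both arms.
#' @slot union Character: herbs supported by either arm.
#' @slot vennCounts Named integer: \code{only_rules}, \code{only_cluster},
#'   \code{both}; they sum to \code{length(union)}.
#' @slot provenance data.frame with one row per herb in the union and logical
#'   columns \code{apriori}, \code{gcn}, \code{frequency_high}, \code{rf_top}.
#'
#' @seealso \code{\link{consensusCore}}, \code{\link{runPipeline}}
#' @exportClass ConsensusResult
setClass("ConsensusResult",
  representation(ruleHerbs = "character", clusterHerbs = "character",
                 intersection = "character", union = "character",
                 vennCounts = "integer", provenance = "data.frame")
)

setValidity("ConsensusResult", function(object) {
  msg <- character()
  if (!setequal(object@intersection,
                intersect(object@ruleHerbs, object@clusterHerbs)))
    msg <- c(msg, "intersection must equal ruleHerbs ∩ clusterHerbs")
  if (sum(object@vennCounts) != length(object@union))
    msg <- c(msg, "venn counts must sum to |union|")
  if (length(msg)) msg else TRUE
})
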