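#' Number of prescriptions in a corpus
#' @param x A \linkS4class{PrescriptionCorpus}.
#' @return Integer count.
#' @export
setGeneric("nPrescriptions", function(x) standardGeneric("nPrescriptions"))

#' Corpus vocabulary (sorted union of all herb sets)
#' @param x A \linkS4class{PrescriptionCorpus} or
#'   \linkS4class{CoOccurrenceGraph}.
#' @return Character vector of herb names.
#' @export
setGeneric("vocabulary", function(x) standardGeneric("vocabulary"))

#' Prescription ids
#' @param x A \linkS4class{PrescriptionCorpus}.
#' @return Character vector of unique ids.
#' @export
setGeneric("prescriptionIds", function(x) standardGeneric("prescriptionIds"))

#' Group labels per prescription
#' @param x A \linkS4class{PrescriptionCorpus}.
#' @return Character vector over \{anti_recurrence, general\}.
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))

#' Herb sets as a named list
#' @param x A \linkS4class{PrescriptionCorpus}.
#' @return Named list of character vectors (one per prescription).
#' @export
setGeneric("herbSets", function(x) standardGeneric("herbSets"))

#' Binary presence/absence encoding of a corpus
#'
#' Rows are prescriptions (ordered by id as stored), columns the sorted
#' vocabulary; a cell is 1 iff the herb occurs in the prescription. Row sums
#' therefore equal prescription sizes and column sums equal herb document
#' frequencies.
#'
#' @param x A \linkS4class{PrescriptionCorpus}.
#' @return Integer 0/1 matrix with dimnames (ids, herbs).
#' @examples
#' corp <- exampleCorpus()
#' m <- binaryMatrix(corp)
#' all(rowSums(m) == lengths(herbSets(corp)))
#' @export
setGeneric("binaryMatrix", function(x) standardGeneric("binaryMatrix"))

#' Edge table of a co-occurrence graph
#' @param x A \linkS4class{CoOccurrenceGraph}.
#' @return data.frame with columns from, to, weight.
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' Weighted node degrees
#' @param x A \linkS4class{CoOccurrenceGraph}.
#' @return Named numeric vector.
#' @export
setGeneric("nodeDegree", function(x) standardGeneric("nodeDegree"))

#' Cluster labels as a named vector
#' @param x A \linkS4class{ClusterAssignment}.
#' @return Named integer vector (herb -> cluster id in 1..k).
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
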