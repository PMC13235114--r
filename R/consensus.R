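#' Herbs supported by the top association rules
#'
#' Takes the union of antecedent and consequent herbs over the \code{topN}
#' highest-lift rules. The default \code{topN = 1} reads off the single
#' highest-lift rule; raising it widens the rule-arm candidate set.
#'
#' @param rules Ranked rule data.frame from \code{\link{deriveRules}}.
#' @param topN Number of leading rules to pool (default 1).
#' @return Sorted character vector of herbs (empty, with a warning, when no
#'   rules were supplied).
#' @export
selectRuleHerbs <- function(rules, topN = 1L) {
  stopifnot(topN >= 1L)
  if (!nrow(rules)) {
    warning("no rules supplied; returning an empty herb set")
    return(character())
  }
  top <- utils::head(rules, topN)
  sort(unique(unlist(strsplit(c(top$lhs, top$rhs), "|", fixed = TRUE))))
}

#' Herbs in the top-scoring cluster(s)
#'
#' @param scores Ranked cluster data.frame from \code{\link{scoreClusters}}.
#' @param nClusters Number of leading clusters to pool (default 1).
#' @return Sorted character vector of member herbs.
#' @export
selectClusterHerbs <- function(scores, nClusters = 1L) {
  stopifnot(nClusters >= 1L)
  top <- utils::head(scores, nClusters)
  sort(unique(unlist(strsplit(top$members, "|", fixed = TRUE))))
}

#' Consensus core herb spectrum with per-herb evidence tags
#'
#' Intersects the rule-derived and cluster-derived candidate sets into the
#' consensus core spectrum and annotates every herb in their union with the
#' evidence supporting it: \code{apriori} (in the rule set), \code{gcn} (in
#' the cluster set), \code{frequency_high} (high band and enriched in the
#' anti-recurrence group in the frequency differential), and \code{rf_top}
#' (within the leading \code{rfTopN} herbs of the random-forest mean
#' decrease accuracy ranking).
#'
#' @param ruleHerbs,clusterHerbs Character herb sets from the two arms.
#' @param differential Optional data.frame from
#'   \code{\link{frequencyDifferential}}.
#' @param forest Optional report from \code{\link{rfDifferential}}.
#' @param rfTopN Rank window for the \code{rf_top} tag (default 14).
#' @return A \linkS4class{ConsensusResult}.
#' @export
consensusCore <- function(ruleHerbs, clusterHerbs, differential = NULL,
                          forest = NULL, rfTopN = 14L) {
  ruleHerbs <- sort(unique(as.character(ruleHerbs)))
  clusterHerbs <- sort(unique(as.character(clusterHerbs)))
  inter <- intersect(ruleHerbs, clusterHerbs)
  uni <- sort(union(ruleHerbs, clusterHerbs))
  venn <- c(only_rules = length(setdiff(ruleHerbs, clusterHerbs)),
            only_cluster = length(setdiff(clusterHerbs, ruleHerbs)),
            both = length(inter))
  freqHigh <- character()
  if (!is.null(differential))
    freqHigh <- differential$herb[differential$band == "high" &
                                    differential$direction == "anti_enriched"]
  rfTop <- character()
  if (!is.null(forest))
    rfTop <- utils::head(forest$ranking, rfTopN)
  prov <- data.frame(
    herb = uni,
    apriori = uni %in% ruleHerbs,
    gcn = uni %in% clusterHerbs,
    frequency_high = uni %in% freqHigh,
    rf_top = uni %in% rfTop,
    stringsAsFactors = FALSE)
  prov$n_evidence <- rowSums(prov[, c("apriori", "gcn", "frequency_high",
                                      "rf_top")])
  new("ConsensusResult", ruleHerbs = ruleHerbs, clusterHerbs = clusterHerbs,
      intersection = inter, union = uni,
      vennCounts = structure(as.integer(venn), names = names(venn)),
      provenance = prov)
}

setMethod("show", "ConsensusResult", function(object) {
  v <- object@vennCounts
  cat("ConsensusResult\n")
  cat("  rule arm:", length(object@ruleHerbs), "herbs;",
      "cluster arm:", length(object@clusterHerbs), "herbs\n")
  cat("  venn: only_rules", v[["only_rules"]], "| both", v[["both"]],
      "| only_cluster", v[["only_cluster"]], "\n")
  cat("  core spectrum:", paste(object@intersection, collapse = ", "), "\n")
})

#' Rank consensus herbs by accumulated evidence
#'
#' Orders the herbs of a consensus result by their number of supporting
#' evidence tags, ties broken by the anti-recurrence frequency difference
#' (when a differential table is given) and then alphabetically.
#'
#' @param x A \linkS4class{ConsensusResult}.
#' @param differential Optional \code{\link{frequencyDifferential}} table
#'   for tie-breaking.
#' @param topHerbs Optional cap on the number of herbs returned.
#' @return data.frame: the provenance table in ranked order.
#' @export
rankConsensusHerbs <- function(x, differential = NULL, topHerbs = NULL) {
  stopifnot(is(x, "ConsensusResult"))
  prov <- x@provenance
  diffPts <- rep(0, nrow(prov))
  if (!is.null(differential)) {
    idx <- match(prov$herb, differential$herb)
    diffPts <- ifelse(is.na(idx), 0, differential$diff_points[idx])
  }
  prov <- prov[order(-prov$n_evidence, -diffPts, prov$herb), ]
  rownames(prov) <- NULL
  if (!is.null(topHerbs)) prov <- utils::head(prov, topHerbs)
  prov
}
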