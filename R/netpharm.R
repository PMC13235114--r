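# Compound/target screening and degree ranking on the compound-target
# bipartite network. The module consumes plain tables (database exports);
# it never queries the source databases itself. All thresholds are
# inclusive, as printed in the screening conventions they mirror
# (OB >= 30%, DL >= 0.18; SVM_score >= 0.8, RF_score >= 0.7).

#' Screen compounds on oral bioavailability and drug-likeness
#'
#' @param records data.frame with at least columns \code{ob} (percent) and
#'   \code{dl}; conventionally also \code{herb}, \code{compound_id},
#'   \code{compound_name}.
#' @param obMin Minimum oral bioavailability in percent (default 30,
#'   inclusive).
#' @param dlMin Minimum drug-likeness score (default 0.18, inclusive).
#' @return The surviving rows, input order preserved.
#' @export
filterCompounds <- function(records, obMin = 30, dlMin = 0.18) {
  stopifnot(all(c("ob", "dl") %in% names(records)), obMin >= 0, dlMin >= 0)
  out <- records[records$ob >= obMin & records$dl >= dlMin, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Screen compound-target links on SVM and RF prediction scores
#'
#' @param links data.frame with at least columns \code{svm_score} and
#'   \code{rf_score}; conventionally also \code{compound_id},
#'   \code{gene_symbol}.
#' @param svmMin Minimum SVM score (default 0.8, inclusive).
#' @param rfMin Minimum RF score (default 0.7, inclusive).
#' @return The surviving rows, input order preserved.
#' @export
filterTargets <- function(links, svmMin = 0.8, rfMin = 0.7) {
  stopifnot(all(c("svm_score", "rf_score") %in% names(links)),
            svmMin >= 0, svmMin <= 1, rfMin >= 0, rfMin <= 1)
  out <- links[links$svm_score >= svmMin & links$rf_score >= rfMin, ,
               drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compound-target bipartite network and degree rankings
#'
#' Restricts the link table to compounds that survived screening, collapses
#' duplicate (compound, target) pairs to single edges (multiplicity carries
#' no meaning here), and ranks both sides by degree -- the field's standard
#' way of nominating key active compounds and central targets. Links naming
#' compounds absent from the screened compound table are dropped and
#' counted.
#'
#' @param compounds Screened compound data.frame (needs
#'   \code{compound_id}).
#' @param links Screened link data.frame (needs \code{compound_id},
#'   \code{gene_symbol}).
#' @param topN How many of each ranking to return (default 10).
#' @return List with \code{edges} (data.frame compound_id, gene_symbol),
#'   \code{compound_degree} and \code{target_degree} (data.frames sorted by
#'   degree descending, ties lexicographic), \code{top_compounds},
#'   \code{top_targets} (the leading \code{topN} rows), and
#'   \code{n_dropped_links}.
#' @export
buildBipartiteRank <- function(compounds, links, topN = 10L) {
  stopifnot(topN >= 1L, "compound_id" %in% names(compounds),
            all(c("compound_id", "gene_symbol") %in% names(links)))
  known <- links$compound_id %in% compounds$compound_id
  nDropped <- sum(!known)
  edges <- unique(links[known, c("compound_id", "gene_symbol")])
  rownames(edges) <- NULL
  rankSide <- function(ids) {
    if (!length(ids))
      return(data.frame(id = character(), degree = integer(),
                        stringsAsFactors = FALSE))
    tab <- table(ids)
    df <- data.frame(id = names(tab), degree = as.integer(tab),
                     stringsAsFactors = FALSE)
    df <- df[order(-df$degree, df$id), ]
    rownames(df) <- NULL
    df
  }
  compDeg <- rankSide(edges$compound_id)
  names(compDeg)[1] <- "compound_id"
  targDeg <- rankSide(edges$gene_symbol)
  names(targDeg)[1] <- "gene_symbol"
  list(edges = edges, compound_degree = compDeg, target_degree = targDeg,
       top_compounds = utils::head(compDeg, topN),
       top_targets = utils::head(targDeg, topN),
       n_dropped_links = nDropped)
}
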