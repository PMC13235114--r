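# Two-group validation: frequency banding and a random-forest classifier.
# "Frequency variance" is the signed difference of the two group frequencies
# in percentage points -- the band labels only make sense on a bounded
# difference scale. The three stated ranges are read as a partition of the
# positive axis with half-open intervals: (20, Inf] high, (10, 20] moderate,
# (0, 10] slight, and a difference of exactly 0 is a balanced slight record.

.bandOf <- function(absPoints) {
  ifelse(absPoints > 20, "high",
         ifelse(absPoints > 10, "moderate", "slight"))
}

#' Per-herb frequency differential between the two prescription groups
#'
#' For every herb in the union vocabulary, computes its frequency in each
#' group (0 when absent), the signed difference in percentage points
#' (anti-recurrence minus general), the enrichment band, and the direction
#' of enrichment.
#'
#' @param corpusAnti,corpusGeneral Non-empty
#'   \linkS4class{PrescriptionCorpus} objects for the two groups.
#' @return data.frame sorted by absolute difference descending with columns
#'   \code{herb}, \code{freq_anti}, \code{freq_general}, \code{diff_points},
#'   \code{band} (high/moderate/slight), \code{direction}
#'   (anti_enriched/general_enriched/balanced).
#' @export
frequencyDifferential <- function(corpusAnti, corpusGeneral) {
  if (!nPrescriptions(corpusAnti) || !nPrescriptions(corpusGeneral))
    stop("both corpora must be non-empty")
  fa <- herbFrequency(corpusAnti)
  fg <- herbFrequency(corpusGeneral)
  herbs <- sort(union(fa$herb, fg$herb))
  freqA <- structure(rep(0, length(herbs)), names = herbs)
  freqG <- freqA
  freqA[fa$herb] <- fa$frequency
  freqG[fg$herb] <- fg$frequency
  diffPts <- 100 * (freqA - freqG)
  df <- data.frame(
    herb = herbs, freq_anti = unname(freqA), freq_general = unname(freqG),
    diff_points = unname(diffPts),
    band = .bandOf(abs(diffPts)),
    direction = ifelse(diffPts > 0, "anti_enriched",
                       ifelse(diffPts < 0, "general_enriched", "balanced")),
    stringsAsFactors = FALSE)
  df <- df[order(-abs(df$diff_points), df$herb), ]
  rownames(df) <- NULL
  df
}

#' Random-forest discrimination of the two prescription groups
#'
#' Trains a random-forest classifier on the stacked binary matrix (rows =
#' prescriptions of both groups, features = union vocabulary, outcome =
#' group label): bootstrap-resampled trees, sqrt(p) feature subsampling per
#' split, Gini splitting, unlimited depth. Reports the out-of-bag (OOB)
#' misclassification rate and both importance measures -- mean decrease in
#' accuracy (OOB permutation importance) and mean decrease in Gini impurity.
#' Inputs are canonicalized (vocabulary sorted, rows in corpus order), so
#' identical corpora and seed give an identical report regardless of how the
#' caller ordered herbs or prescriptions.
#'
#' @param corpusAnti,corpusGeneral The two group corpora, each with >= 2
#'   prescriptions.
#' @param nTrees Number of trees (default 1000).
#' @param seed Integer seed (default 123).
#' @param minCount Optional document-frequency floor: herbs occurring in
#'   fewer than \code{minCount} prescriptions overall are dropped from the
#'   predictors (default 1, i.e. the full union vocabulary).
#' @return List with \code{oob_error} (fraction), \code{importance}
#'   (data.frame herb, mean_decrease_accuracy, mean_decrease_gini, sorted by
#'   mean_decrease_accuracy descending), \code{ranking} (herb names in that
#'   order), \code{n_trees}, \code{seed}, \code{confusion}.
#' @export
rfDifferential <- function(corpusAnti, corpusGeneral, nTrees = 1000L,
                           seed = 123L, minCount = 1L) {
  if (nPrescriptions(corpusAnti) < 2L || nPrescriptions(corpusGeneral) < 2L)
    stop("each group needs at least 2 prescriptions")
  stopifnot(nTrees >= 1L)
  herbs <- sort(union(vocabulary(corpusAnti), vocabulary(corpusGeneral)))
  expand <- function(corpus) {
    m <- matrix(0L, nPrescriptions(corpus), length(herbs),
                dimnames = list(prescriptionIds(corpus), herbs))
    sets <- herbSets(corpus)
    ri <- rep(seq_along(sets), lengths(sets))
    m[cbind(ri, match(unlist(sets, use.names = FALSE), herbs))] <- 1L
    m
  }
  X <- rbind(expand(corpusAnti), expand(corpusGeneral))
  if (minCount > 1L) {
    keep <- colSums(X) >= minCount
    if (!any(keep)) stop("minCount filter removed every herb")
    X <- X[, keep, drop = FALSE]
  }
  y <- factor(c(rep("anti_recurrence", nPrescriptions(corpusAnti)),
                rep("general", nPrescriptions(corpusGeneral))))
  # randomForest treats syntactically invalid column names poorly; use
  # positional names and map back afterwards
  featNames <- colnames(X)
  colnames(X) <- sprintf("f%05d", seq_along(featNames))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  fit <- randomForest::randomForest(x = as.data.frame(X), y = y,
                                    ntree = nTrees, importance = TRUE)
  imp <- randomForest::importance(fit)
  df <- data.frame(
    herb = featNames,
    mean_decrease_accuracy = unname(imp[, "MeanDecreaseAccuracy"]),
    mean_decrease_gini = unname(imp[, "MeanDecreaseGini"]),
    stringsAsFactors = FALSE)
  df <- df[order(-df$mean_decrease_accuracy, df$herb), ]
  rownames(df) <- NULL
  oob <- unname(fit$err.rate[nTrees, "OOB"])
  list(oob_error = oob, importance = df, ranking = df$herb,
       n_trees = as.integer(nTrees), seed = as.integer(seed),
       confusion = fit$confusion)
}
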