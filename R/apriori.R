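# Level-wise Apriori over a binary prescription-by-herb matrix.
# Supports are fractional but thresholded on integer counts: an itemset is
# frequent iff count >= minSupport * N, compared with a small additive guard
# so that exact rational thresholds (e.g. 0.6 on N = 5) are not lost to
# floating-point representation.

.SUPPORT_EPS <- 1e-9

.itemsetKey <- function(items) paste(items, collapse = "\x1f")

.countItemsets <- function(mat, itemsets) {
  # itemsets: list of integer column-index vectors; returns integer counts
  vapply(itemsets, function(idx) {
    if (length(idx) == 1L) sum(mat[, idx])
    else sum(rowSums(mat[, idx, drop = FALSE]) == length(idx))
  }, 0L, USE.NAMES = FALSE)
}

#' Frequent itemsets by level-wise Apriori
#'
#' Enumerates exactly the herb itemsets (size >= 1) whose support -- the
#' fraction of prescriptions containing every member -- meets
#' \code{minSupport} (inclusive). Candidates of size k are generated by
#' joining frequent (k-1)-itemsets that share their first k-2 items and are
#' pruned by downward closure (every (k-1)-subset must itself be frequent)
#' before any support counting.
#'
#' @param mat Binary matrix from \code{\link{binaryMatrix}} (rows =
#'   prescriptions, columns = herbs, dimnames required).
#' @param minSupport Minimum support in (0, 1].
#' @param maxSize Optional cap on itemset size (default unbounded); a safety
#'   valve for adversarial corpora, not needed for real prescription data.
#' @return data.frame with columns \code{items} (herbs joined by
#'   \code{"|"}), \code{size}, \code{count}, \code{support}, ordered by size
#'   then lexicographically within size.
#' @examples
#' m <- binaryMatrix(exampleCorpus())
#' frequentItemsets(m, 0.6)
#' @export
frequentItemsets <- function(mat, minSupport, maxSize = Inf) {
  if (!is.matrix(mat) || nrow(mat) == 0L || ncol(mat) == 0L)
    stop("empty matrix")
  if (!(minSupport > 0 && minSupport <= 1))
    stop("minSupport must be in (0, 1]")
  n <- nrow(mat)
  minCount <- minSupport * n - .SUPPORT_EPS
  vocab <- colnames(mat)
  ord <- order(vocab)          # lexicographic item order drives generation
  mat <- mat[, ord, drop = FALSE]
  vocab <- vocab[ord]

  counts1 <- colSums(mat)
  keep <- which(counts1 >= minCount)
  level <- lapply(keep, identity)          # list of index vectors, size 1
  levelCounts <- as.integer(counts1[keep])
  allSets <- level
  allCounts <- levelCounts

  k <- 1L
  while (length(level) >= 2L && k < maxSize) {
    k <- k + 1L
    prevKeys <- vapply(level, .itemsetKey, "")
    # join step: pairs sharing the first k-2 items
    prefix <- vapply(level, function(s) .itemsetKey(s[-length(s)]), "")
    cand <- list()
    groups <- split(seq_along(level), prefix)
    for (g in groups) {
      if (length(g) < 2L) next
      for (a in seq_len(length(g) - 1L)) for (b in (a + 1L):length(g)) {
        s1 <- level[[g[a]]]; s2 <- level[[g[b]]]
        merged <- sort(unique(c(s1, s2)))
        if (length(merged) != k) next
        # prune: all (k-1)-subsets frequent
        ok <- all(vapply(seq_len(k), function(d)
          .itemsetKey(merged[-d]) %in% prevKeys, TRUE))
        if (ok) cand[[.itemsetKey(merged)]] <- merged
      }
    }
    if (!length(cand)) break
    cand <- unname(cand)
    cnt <- .countItemsets(mat, cand)
    hit <- cnt >= minCount
    level <- cand[hit]
    levelCounts <- as.integer(cnt[hit])
    allSets <- c(allSets, level)
    allCounts <- c(allCounts, levelCounts)
    if (!length(level)) break
  }

  items <- vapply(allSets, function(s) paste(vocab[s], collapse = "|"), "")
  df <- data.frame(items = items, size = lengths(allSets),
                   count = allCounts, support = allCounts / n,
                   stringsAsFactors = FALSE)
  df <- df[order(df$size, df$items), ]
  rownames(df) <- NULL
  df
}

#' Association rules from frequent itemsets
#'
#' For every frequent itemset of size >= 2, all partitions into a non-empty
#' antecedent (LHS) and a consequent (RHS) of exactly \code{rhsSize} herbs
#' are evaluated; rules whose confidence meets \code{minConfidence}
#' (inclusive) are returned. Confidence is support(LHS u RHS)/support(LHS)
#' and lift is confidence/support(RHS); rule support refers to the whole
#' itemset. Output is ranked by lift descending, with ties broken by
#' confidence, then support, then the LHS lexicographically.
#'
#' @param itemsets Output of \code{\link{frequentItemsets}} computed on the
#'   same matrix (the caller's contract).
#' @param mat The binary matrix the itemsets came from.
#' @param minConfidence Minimum confidence in (0, 1].
#' @param rhsSize Consequent size (default 1, the conventional
#'   single-consequent form).
#' @return data.frame with columns \code{lhs}, \code{rhs} (herbs joined by
#'   \code{"|"}), \code{support}, \code{confidence}, \code{lift},
#'   \code{count}.
#' @examples
#' m <- binaryMatrix(exampleCorpus())
#' deriveRules(frequentItemsets(m, 0.6), m, 0.8)
#' @export
deriveRules <- function(itemsets, mat, minConfidence, rhsSize = 1L) {
  stopifnot(rhsSize >= 1L)
  if (!(minConfidence > 0 && minConfidence <= 1))
    stop("minConfidence must be in (0, 1]")
  supp <- structure(itemsets$count, names = itemsets$items)
  n <- nrow(mat)
  out <- list()
  big <- itemsets[itemsets$size >= 2L & itemsets$size > rhsSize, ,
                  drop = FALSE]
  for (i in seq_len(nrow(big))) {
    items <- strsplit(big$items[i], "|", fixed = TRUE)[[1L]]
    cntAll <- big$count[i]
    rhsChoices <- utils::combn(items, rhsSize, simplify = FALSE)
    for (rhs in rhsChoices) {
      lhs <- setdiff(items, rhs)
      lhsKey <- paste(lhs, collapse = "|")
      rhsKey <- paste(rhs, collapse = "|")
      # subsets of a frequent itemset are frequent, so both lookups succeed
      cntLhs <- supp[[lhsKey]]
      cntRhs <- supp[[rhsKey]]
      conf <- cntAll / cntLhs
      if (conf >= minConfidence - .SUPPORT_EPS) {
        out[[length(out) + 1L]] <- data.frame(
          lhs = lhsKey, rhs = rhsKey,
          support = cntAll / n, confidence = conf,
          lift = conf / (cntRhs / n), count = cntAll,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(lhs = character(), rhs = character(),
                      support = numeric(), confidence = numeric(),
                      lift = numeric(), count = integer(),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  df <- df[order(-df$lift, -df$confidence, -df$support, df$lhs, df$rhs), ]
  rownames(df) <- NULL
  df
}

#' Support, confidence and lift of a single candidate rule
#'
#' Direct computation from the binary matrix, independent of any mined
#' itemsets: support = P(LHS u RHS), confidence = P(LHS u RHS)/P(LHS),
#' lift = confidence/P(RHS), with probabilities estimated as prescription
#' fractions.
#'
#' @param mat Binary matrix from \code{\link{binaryMatrix}}.
#' @param lhs,rhs Non-empty, disjoint character vectors of herbs, all present
#'   in the matrix columns.
#' @return List with \code{support}, \code{confidence}, \code{lift},
#'   \code{count}, and \code{no_support} (TRUE with NA metrics when the LHS
#'   never occurs, so that an undefined confidence is never reported as a
#'   number).
#' @examples
#' ruleMetrics(binaryMatrix(exampleCorpus()), "A", "C")
#' @export
ruleMetrics <- function(mat, lhs, rhs) {
  lhs <- unique(as.character(lhs)); rhs <- unique(as.character(rhs))
  if (!length(lhs) || !length(rhs)) stop("lhs and rhs must be non-empty")
  if (length(intersect(lhs, rhs))) stop("lhs and rhs must be disjoint")
  outside <- setdiff(c(lhs, rhs), colnames(mat))
  if (length(outside))
    stop("herb(s) not in vocabulary: ", paste(outside, collapse = ", "))
  n <- nrow(mat)
  has <- function(items) rowSums(mat[, items, drop = FALSE]) == length(items)
  cntLhs <- sum(has(lhs))
  if (cntLhs == 0L)
    return(list(support = 0, confidence = NA_real_, lift = NA_real_,
                count = 0L, no_support = TRUE))
  cntAll <- sum(has(lhs) & has(rhs))
  cntRhs <- sum(has(rhs))
  conf <- cntAll / cntLhs
  list(support = cntAll / n, confidence = conf,
       lift = conf / (cntRhs / n), count = as.integer(cntAll),
       no_support = FALSE)
}

#' Write mined rules or itemsets to CSV
#'
#' @param x data.frame from \code{\link{deriveRules}} or
#'   \code{\link{frequentItemsets}}.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeRules <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
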