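# Independent brute-force oracles for itemset and rule mining, plus small
# random-corpus generators. These deliberately share no code with the
# package's level-wise implementation: they enumerate every subset.

bruteItemsets <- function(mat, minSupport) {
  herbs <- sort(colnames(mat))
  n <- nrow(mat)
  rows <- list()
  for (k in seq_along(herbs)) {
    for (s in utils::combn(herbs, k, simplify = FALSE)) {
      cnt <- sum(rowSums(mat[, s, drop = FALSE]) == k)
      if (cnt >= minSupport * n - 1e-9)
        rows[[length(rows) + 1L]] <- data.frame(
          items = paste(s, collapse = "|"), size = k,
          count = cnt, support = cnt / n, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(items = character(), size = integer(),
                      count = integer(), support = numeric()))
  df <- do.call(rbind, rows)
  df[order(df$size, df$items), , drop = FALSE]
}

bruteRules <- function(mat, minSupport, minConfidence, rhsSize = 1L) {
  fi <- bruteItemsets(mat, minSupport)
  n <- nrow(mat)
  cnt <- function(s) sum(rowSums(mat[, s, drop = FALSE]) == length(s))
  rows <- list()
  for (i in which(fi$size >= 2 & fi$size > rhsSize)) {
    items <- strsplit(fi$items[i], "|", fixed = TRUE)[[1L]]
    for (rhs in utils::combn(items, rhsSize, simplify = FALSE)) {
      lhs <- setdiff(items, rhs)
      conf <- fi$count[i] / cnt(lhs)
      if (conf >= minConfidence - 1e-9)
        rows[[length(rows) + 1L]] <- data.frame(
          lhs = paste(lhs, collapse = "|"),
          rhs = paste(rhs, collapse = "|"),
          support = fi$count[i] / n, confidence = conf,
          lift = conf / (cnt(rhs) / n), count = fi$count[i],
          stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(lhs = character(), rhs = character(),
                      support = numeric(), confidence = numeric(),
                      lift = numeric(), count = integer()))
  do.call(rbind, rows)
}

# canonical sort for order-insensitive rule comparison
canonRules <- function(df) {
  df <- df[order(df$lhs, df$rhs), c("lhs", "rhs", "support",
                                    "confidence", "lift", "count")]
  rownames(df) <- NULL
  df
}

randomCorpus <- function(nHerbs, nPrescriptions, density = 0.4) {
  herbs <- LETTERS[seq_len(nHerbs)]
  sets <- list()
  i <- 0L
  while (length(sets) < nPrescriptions) {
    i <- i + 1L
    s <- herbs[runif(nHerbs) < density]
    if (!length(s)) next
    sets[[sprintf("P%03d", length(sets) + 1L)]] <- s
  }
  PrescriptionCorpus(sets, "anti_recurrence", deduplicate = FALSE)
}

# direct pairwise co-occurrence count by scanning prescriptions
scanCooccurrence <- function(corpus, a, b) {
  sum(vapply(herbSets(corpus),
             function(h) a %in% h && b %in% h, TRUE))
}

plantedSeparatorCorpora <- function(nPerGroup = 30L, nNoise = 15L,
                                    seed = 1L) {
  # herb "Marker" occurs in every anti-recurrence prescription and in no
  # general one; all other herbs are symmetric noise
  set.seed(seed)
  noise <- sprintf("Noise%02d", seq_len(nNoise))
  mk <- function(withMarker, prefix) {
    sets <- lapply(seq_len(nPerGroup), function(i) {
      s <- noise[runif(nNoise) < 0.3]
      if (withMarker) s <- c("Marker", s)
      if (!length(s)) s <- noise[1L]
      s
    })
    names(sets) <- paste0(prefix, seq_len(nPerGroup))
    sets
  }
  list(
    anti = PrescriptionCorpus(mk(TRUE, "A"), "anti_recurrence",
                              deduplicate = FALSE),
    general = PrescriptionCorpus(mk(FALSE, "G"), "general",
                                 deduplicate = FALSE))
}

twoBlobEmbedding <- function(nPer = 25L, dim = 16L, sep = 10, seed = 1L) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(nPer * dim), nPer, dim),
             matrix(rnorm(nPer * dim, mean = sep / sqrt(dim)), nPer, dim))
  rownames(X) <- sprintf("H%03d", seq_len(2L * nPer))
  list(X = X, labels = rep(1:2, each = nPer))
}
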