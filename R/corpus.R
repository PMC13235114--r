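#' Construct a PrescriptionCorpus
#'
#' Builds the corpus from a named list of herb vectors and parallel group
#' labels. Within each prescription, duplicate herb names are dropped (set
#' semantics) and the herbs sorted. Prescriptions sharing both group label
#' and herb set are collapsed to a single record, keeping the earliest id:
#' duplicate formulas with identical compositions carry no extra information
#' for presence-based mining. The collapse is group-scoped, so an identical
#' composition appearing in both groups is retained in each (the two-group
#' differential analysis needs it).
#'
#' @param prescriptions Named list of character vectors (names = ids).
#' @param group Character vector, one of \code{"anti_recurrence"} or
#'   \code{"general"} per prescription; a single value is recycled.
#' @param deduplicate Collapse identical (group, herb set) records
#'   (default TRUE).
#' @return A \linkS4class{PrescriptionCorpus}.
#' @examples
#' PrescriptionCorpus(list(P1 = c("A", "B"), P2 = "B"), "anti_recurrence")
#' @export
PrescriptionCorpus <- function(prescriptions, group,
                               deduplicate = TRUE) {
  if (length(group) == 1L) group <- rep(group, length(prescriptions))
  stopifnot(length(group) == length(prescriptions))
  if (is.null(names(prescriptions)) || !all(nzchar(names(prescriptions))))
    stop("every prescription must have an id (list name)")
  sets <- lapply(prescriptions, function(h) {
    h <- unique(as.character(h))
    h <- h[nzchar(h)]
    sort(h)
  })
  empty <- lengths(sets) == 0L
  if (any(empty))
    stop("prescription(s) with empty herb set: ",
         paste(names(sets)[empty], collapse = ", "))
  if (deduplicate) {
    key <- paste(group, vapply(sets, paste, "", collapse = "\x1f"),
                 sep = "\x1e")
    keep <- !duplicated(key)
    sets <- sets[keep]
    group <- group[keep]
  }
  if (anyDuplicated(names(sets)))
    stop("duplicate prescription id(s): ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  vocab <- sort(unique(unlist(sets, use.names = FALSE)))
  new("PrescriptionCorpus", prescriptions = sets,
      group = as.character(group), vocabulary = vocab)
}

#' @describeIn nPrescriptions Number of prescriptions in the corpus.
#' @export
setMethod("nPrescriptions", "PrescriptionCorpus",
          function(x) length(x@prescriptions))

#' @describeIn vocabulary Vocabulary of a corpus.
#' @export
setMethod("vocabulary", "PrescriptionCorpus", function(x) x@vocabulary)

#' @describeIn prescriptionIds Ids of a corpus.
#' @export
setMethod("prescriptionIds", "PrescriptionCorpus",
          function(x) names(x@prescriptions))

#' @describeIn groupLabels Group labels of a corpus.
#' @export
setMethod("groupLabels", "PrescriptionCorpus", function(x) x@group)

#' @describeIn herbSets Herb sets of a corpus.
#' @export
setMethod("herbSets", "PrescriptionCorpus", function(x) x@prescriptions)

setMethod("show", "PrescriptionCorpus", function(object) {
  n <- nPrescriptions(object)
  tab <- table(factor(object@group, c("anti_recurrence", "general")))
  cat("PrescriptionCorpus with", n, "prescriptions,",
      length(object@vocabulary), "herbs\n")
  cat("  anti_recurrence:", tab[["anti_recurrence"]],
      " general:", tab[["general"]], "\n")
  cat("  median prescription size:",
      stats::median(lengths(object@prescriptions)), "\n")
})

#' Subset a corpus by group label
#'
#' @param x A \linkS4class{PrescriptionCorpus}.
#' @param group \code{"anti_recurrence"} or \code{"general"}.
#' @return A \linkS4class{PrescriptionCorpus} with only that group.
#' @export
subsetByGroup <- function(x, group = c("anti_recurrence", "general")) {
  group <- match.arg(group)
  keep <- x@group == group
  if (!any(keep)) stop("no prescriptions with group '", group, "'")
  PrescriptionCorpus(x@prescriptions[keep], x@group[keep],
                     deduplicate = FALSE)
}

#' Read a prescription corpus from CSV/TSV
#'
#' Two dialects are accepted. \emph{Long}: one row per (prescription, herb)
#' with columns \code{prescription_id}, \code{group}, \code{herb}.
#' \emph{Wide}: one row per prescription with columns \code{prescription_id},
#' \code{group}, \code{herbs}, the latter a delimited list (default
#' delimiter \code{";"}). Field separator is inferred from the file
#' extension (\code{.tsv} = tab, otherwise comma) unless given. Herb sets are
#' deduplicated and identical (group, composition) records collapsed as in
#' \code{\link{PrescriptionCorpus}}.
#'
#' @param path File path.
#' @param format \code{"long"} or \code{"wide"}.
#' @param sep Field separator; default inferred from extension.
#' @param herbDelim List delimiter inside the wide-format \code{herbs} column.
#' @return A \linkS4class{PrescriptionCorpus}.
#' @export
readCorpus <- function(path, format = c("long", "wide"), sep = NULL,
                       herbDelim = ";") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "", fileEncoding = "UTF-8")
  need <- if (format == "long") c("prescription_id", "group", "herb")
          else c("prescription_id", "group", "herbs")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (format == "long") {
    ids <- unique(df$prescription_id)
    sets <- split(trimws(df$herb), factor(df$prescription_id, levels = ids))
    grp <- vapply(split(df$group, factor(df$prescription_id, levels = ids)),
                  function(g) as.character(g[[1L]]), "")
  } else {
    ids <- df$prescription_id
    if (anyDuplicated(ids))
      stop("duplicate prescription_id in wide-format file")
    sets <- lapply(strsplit(as.character(df$herbs), herbDelim, fixed = TRUE),
                   trimws)
    names(sets) <- ids
    grp <- as.character(df$group)
  }
  names(grp) <- NULL
  PrescriptionCorpus(sets, grp)
}

#' Write a corpus in the long CSV dialect
#'
#' @param x A \linkS4class{PrescriptionCorpus}.
#' @param path Output file path; separator inferred from extension as in
#'   \code{\link{readCorpus}}.
#' @return Invisibly, the path.
#' @export
writeCorpus <- function(x, path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- data.frame(
    prescription_id = rep(names(x@prescriptions), lengths(x@prescriptions)),
    group = rep(x@group, lengths(x@prescriptions)),
    herb = unlist(x@prescriptions, use.names = FALSE),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Construct a HerbLexicon
#'
#' @param entries data.frame with columns \code{raw_name},
#'   \code{standard_name}, \code{nature} and \code{flavor} (character vector
#'   list column, or \code{"|"}-separated strings).
#' @return A \linkS4class{HerbLexicon}.
#' @export
HerbLexicon <- function(entries = data.frame(raw_name = character(),
                                             standard_name = character(),
                                             nature = character())) {
  if (!"flavor" %in% names(entries))
    entries$flavor <- replicate(nrow(entries), "unknown", simplify = FALSE)
  if (!is.list(entries$flavor))
    entries$flavor <- strsplit(as.character(entries$flavor), "|", fixed = TRUE)
  entries$flavor <- lapply(entries$flavor, function(f) {
    f <- trimws(f)
    if (!length(f)) "unknown" else f
  })
  entries$raw_name <- as.character(entries$raw_name)
  entries$standard_name <- as.character(entries$standard_name)
  entries$nature <- as.character(entries$nature)
  rownames(entries) <- NULL
  new("HerbLexicon", entries = entries)
}

#' Read a herb lexicon from CSV
#'
#' Expected columns: \code{raw_name}, \code{standard_name}, \code{nature},
#' \code{flavor} (multi-valued, \code{"|"}-separated).
#'
#' @param path File path.
#' @param sep Field separator; default inferred from extension.
#' @return A \linkS4class{HerbLexicon}.
#' @export
readLexicon <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          fileEncoding = "UTF-8")
  HerbLexicon(df)
}

setMethod("show", "HerbLexicon", function(object) {
  cat("HerbLexicon with", nrow(object@entries), "entries\n")
})

#' Standardize herb names through a lexicon
#'
#' Replaces every raw name found in the lexicon by its standard name; names
#' absent from the lexicon pass through unchanged with a warning listing
#' them. Prescriptions are re-deduplicated after mapping (two raw names
#' mapping to one standard name collapse to a single herb, and prescriptions
#' that become compositionally identical within a group collapse to one).
#'
#' @param corpus A \linkS4class{PrescriptionCorpus}.
#' @param lexicon A \linkS4class{HerbLexicon}.
#' @return A standardized \linkS4class{PrescriptionCorpus}.
#' @export
standardizeHerbs <- function(corpus, lexicon) {
  e <- lexicon@entries
  if (!nrow(e)) return(corpus)
  map <- structure(e$standard_name, names = e$raw_name)
  unmapped <- setdiff(corpus@vocabulary, names(map))
  if (length(unmapped))
    warning("herb name(s) not in lexicon, passed through unchanged: ",
            paste(utils::head(unmapped, 10L), collapse = ", "),
            if (length(unmapped) > 10L) ", ...")
  sets <- lapply(corpus@prescriptions, function(h) {
    hit <- h %in% names(map)
    h[hit] <- map[h[hit]]
    h
  })
  PrescriptionCorpus(sets, corpus@group)
}

#' @describeIn binaryMatrix Binary encoding of a corpus.
#' @export
setMethod("binaryMatrix", "PrescriptionCorpus", function(x) {
  if (!nPrescriptions(x)) stop("empty corpus")
  vocab <- x@vocabulary
  m <- matrix(0L, nPrescriptions(x), length(vocab),
              dimnames = list(names(x@prescriptions), vocab))
  ri <- rep(seq_len(nPrescriptions(x)), lengths(x@prescriptions))
  ci <- match(unlist(x@prescriptions, use.names = FALSE), vocab)
  m[cbind(ri, ci)] <- 1L
  m
})

#' Per-herb document frequencies
#'
#' For each herb in the vocabulary, the number of prescriptions containing
#' it and that count as a fraction of all prescriptions.
#'
#' @param corpus A non-empty \linkS4class{PrescriptionCorpus}.
#' @return data.frame with columns \code{herb}, \code{count},
#'   \code{frequency}, sorted by count descending then herb.
#' @examples
#' herbFrequency(exampleCorpus())
#' @export
herbFrequency <- function(corpus) {
  if (!nPrescriptions(corpus)) stop("empty corpus")
  cnt <- table(unlist(corpus@prescriptions, use.names = FALSE))
  df <- data.frame(herb = names(cnt), count = as.integer(cnt),
                   frequency = as.numeric(cnt) / nPrescriptions(corpus),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$herb), ]
  rownames(df) <- NULL
  df
}

#' Distribution of herbal nature and flavor over a herb set
#'
#' Tallies the traditional nature and flavor categories of the given herbs
#' against a lexicon. Herbs absent from the lexicon (matched on standard
#' name, falling back to raw name) count as \code{unknown}; a multi-flavor
#' herb increments each of its flavor bins.
#'
#' @param herbs Character vector of herb names.
#' @param lexicon A \linkS4class{HerbLexicon}.
#' @return List with \code{nature_counts} (named integer over all nature
#'   levels), \code{flavor_counts}, \code{herbs_covered},
#'   \code{herbs_unknown}.
#' @export
propertyDistribution <- function(herbs, lexicon) {
  herbs <- unique(as.character(herbs))
  e <- lexicon@entries
  idx <- match(herbs, e$standard_name)
  fallback <- is.na(idx)
  idx[fallback] <- match(herbs[fallback], e$raw_name)
  nature <- rep("unknown", length(herbs))
  nature[!is.na(idx)] <- e$nature[idx[!is.na(idx)]]
  flavors <- lapply(seq_along(herbs), function(i)
    if (is.na(idx[i])) "unknown" else e$flavor[[idx[i]]])
  natureCounts <- table(factor(nature, .natureLevels))
  flavorCounts <- table(factor(unlist(flavors), .flavorLevels))
  list(
    nature_counts = structure(as.integer(natureCounts),
                              names = names(natureCounts)),
    flavor_counts = structure(as.integer(flavorCounts),
                              names = names(flavorCounts)),
    herbs_covered = sum(!is.na(idx)),
    herbs_unknown = sum(is.na(idx))
  )
}

#' Tiny built-in example corpus
#'
#' Three anti-recurrence prescriptions over herbs A, B, C; used in examples
#' and documentation.
#' @return A \linkS4class{PrescriptionCorpus}.
#' @export
exampleCorpus <- function() {
  PrescriptionCorpus(
    list(P1 = c("A", "B"), P2 = c("A", "B", "C"), P3 = c("B", "C")),
    "anti_recurrence")
}
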