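#' K-means clustering of herb embeddings with silhouette-based K selection
#'
#' Fits K-means (10 restarts per candidate K, a deterministic seed stream,
#' Euclidean geometry) to the embedding rows. With \code{k = "auto"} every K
#' in \code{kRange} is fitted and the assignment with the highest mean
#' silhouette width is returned (ties resolved toward the smaller K); with a
#' fixed integer K a single fit is made and its silhouette reported. K = 1
#' is rejected: the silhouette is undefined there.
#'
#' @param emb A \linkS4class{HerbEmbedding} or a numeric matrix with row
#'   names.
#' @param k \code{"auto"} or an integer >= 2.
#' @param kRange Candidate K values for automatic selection (default 2:10),
#'   truncated to at most (number of points - 1).
#' @param seed Integer seed for the restart stream.
#' @param nstart Restarts per K (default 10).
#' @return A \linkS4class{ClusterAssignment}.
#' @export
clusterEmbeddings <- function(emb, k = "auto", kRange = 2:10, seed = 1L,
                              nstart = 10L) {
  X <- if (is(emb, "HerbEmbedding")) emb@embedding else emb
  stopifnot(is.matrix(X), !is.null(rownames(X)))
  n <- nrow(X)
  auto <- identical(k, "auto")
  if (!auto) {
    k <- as.integer(k)
    if (k < 2L) stop("k must be at least 2 (silhouette undefined at k = 1)")
    if (k > n - 1L) stop("k must be at most number of points - 1")
    kRange <- k
  } else {
    if (n < 3L) stop("automatic K selection needs at least 3 points")
    kRange <- kRange[kRange >= 2L & kRange <= n - 1L]
    if (!length(kRange)) stop("kRange has no admissible values")
  }
  D <- stats::dist(X)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  sil <- structure(rep(NA_real_, length(kRange)), names = kRange)
  fits <- vector("list", length(kRange))
  nDistinct <- nrow(unique(X))
  for (i in seq_along(kRange)) {
    kk <- kRange[i]
    if (kk > nDistinct) next
    set.seed(.deriveSeed(seed, paste0("kmeans_k", kk)))
    km <- stats::kmeans(X, centers = kk, nstart = nstart, iter.max = 100L)
    sil[i] <- mean(cluster::silhouette(km$cluster, D)[, "sil_width"])
    fits[[i]] <- km
  }
  if (all(is.na(sil))) stop("no admissible K could be fitted")
  best <- which.max(sil)     # ties resolve to the first (smallest) K
  km <- fits[[best]]
  labels <- structure(as.integer(km$cluster), names = rownames(X))
  new("ClusterAssignment", k = as.integer(kRange[best]), labels = labels,
      silhouette = unname(sil[best]),
      silhouetteByK = if (auto) sil[!is.na(sil)] else stats::setNames(
        numeric(0), character(0)))
}

#' @describeIn clusterLabels Labels of a ClusterAssignment.
#' @export
setMethod("clusterLabels", "ClusterAssignment", function(x) x@labels)

setMethod("show", "ClusterAssignment", function(object) {
  cat("ClusterAssignment: k =", object@k,
      sprintf("(mean silhouette %.3f)\n", object@silhouette))
  print(table(cluster = object@labels))
})

#' Composite prioritization scores for herb clusters
#'
#' Scores every cluster of an assignment on three components: the mean
#' weighted degree of its members in the full co-occurrence graph; the
#' intra-cluster subgraph density, computed as total intra-cluster edge
#' weight divided by the member pair count (0 for singletons; weighted mass
#' can exceed 1, which the normalization absorbs); and coverage, the
#' fraction of prescriptions containing at least \code{minMembers} of its
#' members. Each component is min-max normalized across clusters (a
#' constant component maps to 0.5 everywhere) and the composite score is
#' the unweighted mean of the three normalized components, so it lies in
#' [0, 1]. Raw components are returned alongside so alternative
#' aggregations can be audited.
#'
#' @param graph The \linkS4class{CoOccurrenceGraph} the assignment was
#'   derived from.
#' @param corpus The \linkS4class{PrescriptionCorpus} behind the graph.
#' @param assignment A \linkS4class{ClusterAssignment} covering every graph
#'   node.
#' @param minMembers Members required for a prescription to count as
#'   covered (default 1).
#' @return data.frame sorted by composite descending with columns
#'   \code{cluster_id}, \code{n_members}, \code{members} (\code{"|"}-joined),
#'   \code{avg_degree}, \code{density}, \code{coverage}, \code{norm_degree},
#'   \code{norm_density}, \code{norm_coverage}, \code{composite}.
#' @export
scoreClusters <- function(graph, corpus, assignment, minMembers = 1L) {
  stopifnot(is(graph, "CoOccurrenceGraph"),
            is(assignment, "ClusterAssignment"))
  labels <- assignment@labels
  missing <- setdiff(names(labels), graph@nodes)
  if (length(missing))
    stop("assignment names node(s) absent from the graph: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  uncovered <- setdiff(graph@nodes, names(labels))
  if (length(uncovered))
    stop("assignment must cover every graph node; missing: ",
         paste(utils::head(uncovered, 5L), collapse = ", "))
  ids <- sort(unique(labels))
  ed <- graph@edges
  deg <- graph@degree
  sets <- herbSets(corpus)
  rows <- lapply(ids, function(cid) {
    members <- sort(names(labels)[labels == cid])
    sz <- length(members)
    avgDeg <- mean(deg[members])
    intra <- ed$from %in% members & ed$to %in% members
    density <- if (sz < 2L) 0 else sum(ed$weight[intra]) / (sz * (sz - 1) / 2)
    covered <- vapply(sets, function(h)
      sum(h %in% members) >= minMembers, TRUE)
    data.frame(cluster_id = cid, n_members = sz,
               members = paste(members, collapse = "|"),
               avg_degree = avgDeg, density = density,
               coverage = mean(covered), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  minmax <- function(v) {
    r <- range(v)
    if (r[1] == r[2]) rep(0.5, length(v)) else (v - r[1]) / (r[2] - r[1])
  }
  df$norm_degree <- minmax(df$avg_degree)
  df$norm_density <- minmax(df$density)
  df$norm_coverage <- minmax(df$coverage)
  df$composite <- (df$norm_degree + df$norm_density + df$norm_coverage) / 3
  df <- df[order(-df$composite, df$cluster_id), ]
  rownames(df) <- NULL
  df
}
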