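# Two-layer graph-convolutional encoder trained with a self-supervised
# link-prediction objective, implemented directly in dense linear algebra.
# Herb co-occurrence graphs are small (a few hundred nodes), so dense
# propagation is both simpler and faster than sparse machinery here.

.sigmoid <- function(x) 1 / (1 + exp(-x))

# numerically stable log(1 + exp(x))
.softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

.glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

.adamStep <- function(state, grad, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  state$w <- state$w - lr * mhat / (sqrt(vhat) + eps)
  state
}

#' Graph-convolutional herb embeddings via link prediction
#'
#' Learns one embedding vector per herb from the weighted co-occurrence
#' graph. The encoder is a two-layer graph convolution: features are
#' propagated through the symmetrically normalized weighted adjacency with
#' self-loops, through a \code{hiddenDim}-unit rectified layer and a linear
#' \code{outDim}-dimensional output layer. The initial node feature is the
#' standardized weighted degree (a scalar; set \code{weightedDegree = FALSE}
#' to use the unweighted degree instead). Training is self-supervised link
#' prediction on the whole graph: every observed edge is a positive example,
#' \code{negativesPerEdge} non-edges per edge are resampled uniformly each
#' epoch as negatives, pair scores are inner products of the endpoint
#' embeddings, and the binary cross-entropy of the logistic pair
#' probabilities is minimized by Adam. No train/validation edge split is
#' made: the embeddings themselves, not held-out link AUC, are the product.
#'
#' @param graph A \linkS4class{CoOccurrenceGraph} with >= 2 nodes and >= 1
#'   edge.
#' @param hiddenDim,outDim Layer widths (defaults 32 and 16).
#' @param epochs Training epochs (default 200).
#' @param learningRate Adam step size (default 0.01).
#' @param negativesPerEdge Negative samples per positive edge per epoch.
#' @param seed Integer seed; identical inputs and seed give identical
#'   embeddings.
#' @param weightedDegree Use the weighted degree as the input feature
#'   (default) or the plain edge count.
#' @return A \linkS4class{HerbEmbedding}.
#' @export
gcnEmbed <- function(graph, hiddenDim = 32L, outDim = 16L, epochs = 200L,
                     learningRate = 0.01, negativesPerEdge = 1L,
                     seed = 1L, weightedDegree = TRUE) {
  stopifnot(is(graph, "CoOccurrenceGraph"), hiddenDim >= 1, outDim >= 1,
            epochs >= 1, learningRate > 0, negativesPerEdge >= 1)
  nodes <- graph@nodes
  n <- length(nodes)
  if (n < 2L) stop("graph must have at least 2 nodes")
  ed <- graph@edges
  if (!nrow(ed)) stop("graph has no edges; embeddings are undefined")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(.deriveSeed(seed, "gcn_embed"))

  ei <- match(ed$from, nodes)
  ej <- match(ed$to, nodes)
  A <- matrix(0, n, n)
  A[cbind(ei, ej)] <- ed$weight
  A[cbind(ej, ei)] <- ed$weight

  # symmetric normalization with self-loops
  At <- A + diag(n)
  dInv <- 1 / sqrt(rowSums(At))
  S <- At * tcrossprod(dInv)

  deg <- if (weightedDegree) rowSums(A) else as.numeric(tabulate(
    c(ei, ej), nbins = n))
  sdDeg <- stats::sd(deg)
  x <- if (is.na(sdDeg) || sdDeg == 0) rep(0, n) else (deg - mean(deg)) / sdDeg
  X <- matrix(x, n, 1L)

  W1 <- .glorot(1L, hiddenDim)
  W2 <- .glorot(hiddenDim, outDim)
  st1 <- list(w = W1, m = W1 * 0, v = W1 * 0, t = 0L)
  st2 <- list(w = W2, m = W2 * 0, v = W2 * 0, t = 0L)

  # enumerate candidate non-edges once (graphs here are small)
  ut <- which(upper.tri(A), arr.ind = TRUE)
  isEdge <- A[ut] > 0
  nonEdges <- ut[!isEdge, , drop = FALSE]
  nNeg <- min(negativesPerEdge * nrow(ed), nrow(nonEdges))
  if (nNeg == 0L)
    warning("graph is complete; training on positive edges only")

  P <- S %*% X
  loss <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    negIdx <- if (nNeg > 0L)
      nonEdges[sample(nrow(nonEdges), nNeg), , drop = FALSE]
    else matrix(integer(), 0L, 2L)
    pi <- c(ei, negIdx[, 1L])
    pj <- c(ej, negIdx[, 2L])
    y <- c(rep(1, length(ei)), rep(0, nNeg))
    m <- length(y)

    Hpre <- P %*% st1$w
    H <- pmax(Hpre, 0)
    Q <- S %*% H
    Z <- Q %*% st2$w

    s <- rowSums(Z[pi, , drop = FALSE] * Z[pj, , drop = FALSE])
    loss[ep] <- mean(.softplus(s) - y * s)
    if (!is.finite(loss[ep]))
      stop("training diverged (non-finite loss) at epoch ", ep)

    g <- (.sigmoid(s) - y) / m
    Gm <- matrix(0, n, n)
    Gm[cbind(pi, pj)] <- g       # pair indices are unique within an epoch
    Gm <- Gm + t(Gm)
    dZ <- Gm %*% Z
    dW2 <- crossprod(Q, dZ)
    dQ <- dZ %*% t(st2$w)
    dH <- S %*% dQ
    dHpre <- dH * (Hpre > 0)
    dW1 <- crossprod(P, dHpre)

    st1 <- .adamStep(st1, dW1, learningRate)
    st2 <- .adamStep(st2, dW2, learningRate)
  }

  Hfinal <- pmax(P %*% st1$w, 0)
  Z <- (S %*% Hfinal) %*% st2$w
  rownames(Z) <- nodes
  new("HerbEmbedding", embedding = Z, lossTrace = loss,
      hyperparams = list(hidden_dim = hiddenDim, out_dim = outDim,
                         epochs = epochs, learning_rate = learningRate,
                         negatives_per_edge = negativesPerEdge, seed = seed,
                         weighted_degree = weightedDegree))
}

#' Embedding matrix accessor
#' @param x A \linkS4class{HerbEmbedding}.
#' @return Numeric matrix (herbs x dimensions).
#' @export
embeddingMatrix <- function(x) {
  stopifnot(is(x, "HerbEmbedding"))
  x@embedding
}

#' Training loss trace accessor
#' @param x A \linkS4class{HerbEmbedding}.
#' @return Numeric vector, one loss per epoch.
#' @export
lossTrace <- function(x) {
  stopifnot(is(x, "HerbEmbedding"))
  x@lossTrace
}

setMethod("show", "HerbEmbedding", function(object) {
  cat("HerbEmbedding:", nrow(object@embedding), "herbs x",
      ncol(object@embedding), "dimensions\n")
  n <- length(object@lossTrace)
  cat(sprintf("  loss %.4f (epoch 1) -> %.4f (epoch %d)\n",
              object@lossTrace[1], object@lossTrace[n], n))
})

#' Write embeddings as TSV (herb plus one column per dimension)
#' @param x A \linkS4class{HerbEmbedding}.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeEmbedding <- function(x, path) {
  df <- data.frame(herb = rownames(x@embedding), x@embedding,
                   stringsAsFactors = FALSE, check.names = FALSE)
  colnames(df) <- c("herb", paste0("dim", seq_len(ncol(x@embedding))))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
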