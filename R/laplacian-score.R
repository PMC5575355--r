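#' @include synthetic.R
NULL

#' Laplacian Score feature relevance
#'
#' Unsupervised relevance of each bin by its power of locality preserving
#' on a sample k-nearest-neighbour graph. Samples i and j are connected
#' when either is among the other's k nearest Euclidean neighbours, with
#' heat-kernel weight `S[i, j] = exp(-d[i, j]^2 / t)`. For each feature
#' column f, centred by the degree-weighted mean, the score is
#' `(f' L f) / (f' Deg f)` with graph Laplacian `L = Deg - S`. Lower scores
#' mark features varying smoothly over the graph (more relevant);
#' zero-variance features get the `Inf` sentinel.
#'
#' @param B a [ReadDepthMatrix-class] or numeric matrix (samples in rows).
#' @param kNeighbors neighbourhood size k (1 <= k < m; default 5).
#' @param bandwidth heat-kernel bandwidth t, or `"auto"` (default): the
#'   mean squared distance to the k nearest neighbours.
#' @return A [LaplacianScoreResult-class].
#' @seealso [selectFeatures()]
#' @export
laplacianScore <- function(B, kNeighbors = 5L, bandwidth = "auto") {
    Bv <- .coerceMatrix(B, "B")
    m <- nrow(Bv)
    kNeighbors <- as.integer(kNeighbors)
    if (is.na(kNeighbors) || kNeighbors < 1L || kNeighbors >= m)
        .stopInvalid("'kNeighbors' must satisfy 1 <= k < number of samples")
    d2 <- as.matrix(stats::dist(Bv))^2
    # k nearest neighbours of each sample (excluding self)
    nnIdx <- t(apply(d2, 1L, function(r) order(r)[2:(kNeighbors + 1L)]))
    adj <- matrix(FALSE, m, m)
    adj[cbind(rep(seq_len(m), kNeighbors), as.vector(nnIdx))] <- TRUE
    adj <- adj | t(adj)
    if (identical(bandwidth, "auto")) {
        t0 <- mean(d2[cbind(rep(seq_len(m), kNeighbors), as.vector(nnIdx))])
        if (t0 == 0) t0 <- 1  # degenerate: duplicated samples
    } else {
        t0 <- as.numeric(bandwidth)
        if (is.na(t0) || t0 <= 0) .stopInvalid("'bandwidth' must be positive")
    }
    S <- exp(-d2 / t0) * adj
    deg <- rowSums(S)

    wmean <- colSums(Bv * deg) / sum(deg)
    Fc <- sweep(Bv, 2L, wmean)
    den <- colSums(deg * Fc^2)
    num <- den - colSums(Fc * (S %*% Fc))  # f' L f = f' Deg f - f' S f
    scores <- ifelse(den > 0, pmax(num, 0) / den, Inf)
    colVar <- apply(Bv, 2L, stats::var)
    scores[colVar == 0] <- Inf
    new("LaplacianScoreResult", scores = as.numeric(scores),
        neighborCount = kNeighbors, bandwidth = t0,
        keptIndices = integer(0))
}

#' Retain the most relevant bins
#'
#' Keeps the `ceiling(keepFraction * n)` lowest-scoring bins in their
#' original order (ties broken toward the lower bin index).
#'
#' @param B the matrix that was scored.
#' @param result a [LaplacianScoreResult-class] from [laplacianScore()].
#' @param keepFraction fraction of bins to retain, in (0, 1].
#' @return list with `matrix` (filtered [ReadDepthMatrix-class]) and
#'   `result` (the score result with `keptIndices` filled in).
#' @export
selectFeatures <- function(B, result, keepFraction) {
    if (!is(result, "LaplacianScoreResult"))
        .stopInvalid("'result' must be a LaplacianScoreResult")
    if (length(keepFraction) != 1L || is.na(keepFraction) ||
        keepFraction <= 0 || keepFraction > 1)
        .stopInvalid("'keepFraction' must be in (0, 1]")
    if (!is(B, "ReadDepthMatrix")) B <- ReadDepthMatrix(.coerceMatrix(B))
    n <- length(result@scores)
    if (ncol(B@values) != n)
        .stopInvalid("'B' has a different number of bins than the scores")
    nKeep <- as.integer(ceiling(keepFraction * n))
    kept <- sort(order(result@scores, seq_len(n))[seq_len(nKeep)])
    filtered <- ReadDepthMatrix(B@values[, kept, drop = FALSE],
                                sampleIDs = B@sampleIDs,
                                binIDs = B@binIDs[kept])
    result@keptIndices <- kept
    list(matrix = filtered, result = result)
}
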