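#' @include laplacian-score.R
NULL

#' Baseline ordering: sort samples by total read depth
#'
#' The simple sorting scheme: samples are arranged by their row sum (total
#' aberration load), ascending or descending, with a stable sort so
#' equal-sum rows keep their input order.
#'
#' @param B a [ReadDepthMatrix-class] or numeric matrix.
#' @param direction `"ascending"` or `"descending"`.
#' @return A [SampleOrdering-class].
#' @export
quicksortOrdering <- function(B, direction = c("ascending", "descending")) {
    direction <- match.arg(direction)
    Bv <- .coerceMatrix(B, "B")
    key <- rowSums(Bv)
    if (direction == "descending") key <- -key
    SampleOrdering(order(key, seq_len(nrow(Bv))))
}

#' Baseline ordering: agglomerative hierarchical clustering
#'
#' Clusters samples on Euclidean distance, returns the dendrogram leaf
#' order as the sample arrangement and the `nClusters`-cut labels.
#'
#' @param B a [ReadDepthMatrix-class] or numeric matrix.
#' @param nClusters number of clusters to cut, in `1..m`.
#' @param linkage agglomeration method (default `"average"`).
#' @return list with `ordering` ([SampleOrdering-class]) and integer
#'   `labels`.
#' @export
hierarchicalOrdering <- function(B, nClusters, linkage = "average") {
    Bv <- .coerceMatrix(B, "B")
    m <- nrow(Bv)
    nClusters <- as.integer(nClusters)
    if (is.na(nClusters) || nClusters < 1L || nClusters > m)
        .stopInvalid("'nClusters' must be in 1..m")
    hc <- stats::hclust(stats::dist(Bv), method = linkage)
    labels <- unname(stats::cutree(hc, k = nClusters))
    list(ordering = SampleOrdering(hc$order), labels = labels)
}

#' Count contiguous label blocks along an ordering
#'
#' The number of maximal runs of identical labels when labels are read in
#' the given order; a perfect grouping of g groups gives exactly g.
#'
#' @param ordering a [SampleOrdering-class] or integer permutation.
#' @param labels per-sample labels (any atomic type).
#' @return integer block count.
#' @export
countLabelBlocks <- function(ordering, labels) {
    ord <- if (is(ordering, "SampleOrdering")) ordering@order
           else orderIndices(SampleOrdering(ordering))
    if (length(labels) != length(ord))
        .stopInvalid("'labels' must match the ordering length")
    length(rle(as.character(labels[ord]))$lengths)
}

#' Compare a predicted clustering against ground truth
#'
#' Adjusted Rand index plus the misclassification count under the optimal
#' cluster-to-truth label matching (linear assignment on the confusion
#' matrix), so the count is invariant to permutations of the predicted
#' label symbols.
#'
#' @param predicted,truth equal-length label vectors.
#' @return list with `adjustedRand` and `nMisclassified`.
#' @export
compareClusterings <- function(predicted, truth) {
    if (length(predicted) != length(truth))
        .stopInvalid("'predicted' and 'truth' must have equal length")
    ari <- mclust::adjustedRandIndex(predicted, truth)
    conf <- table(factor(predicted), factor(truth))
    k <- max(dim(conf))
    C <- matrix(0, k, k)  # pad to square; minimise negated matches
    C[seq_len(nrow(conf)), seq_len(ncol(conf))] <- -as.matrix(conf)
    assign <- .hungarianAssignment(C)
    matched <- -sum(C[cbind(seq_len(k), assign)])
    list(adjustedRand = ari,
         nMisclassified = as.integer(length(truth) - matched))
}

#' Evaluate a sample arrangement against ground-truth groups
#'
#' Reads the labels along the arrangement, counts contiguous blocks, and
#' scores the contiguous-run assignment (each maximal run becomes a
#' cluster) against the true labels.
#'
#' @param ordering a [SampleOrdering-class]: position -> original sample.
#' @param labels ground-truth label per original sample.
#' @param methodName name recorded in the report.
#' @return An [EvaluationReport-class].
#' @export
evaluateOrdering <- function(ordering, labels, methodName = "TCP") {
    ord <- if (is(ordering, "SampleOrdering")) ordering@order
           else orderIndices(SampleOrdering(ordering))
    if (length(labels) != length(ord))
        .stopInvalid("'labels' must match the ordering length")
    runs <- rle(as.character(labels[ord]))
    runClustersByPos <- rep(seq_along(runs$lengths), runs$lengths)
    runClusters <- integer(length(ord))
    runClusters[ord] <- runClustersByPos
    cmp <- compareClusterings(runClusters, labels)
    new("EvaluationReport", methodName = methodName,
        nLabelBlocks = length(runs$lengths),
        adjustedRand = cmp$adjustedRand,
        nMisclassified = cmp$nMisclassified)
}
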