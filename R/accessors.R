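#' @include AllGenerics.R
NULL

#' Construct a ReadDepthMatrix
#'
#' @param values numeric matrix, m samples (rows) x n bins (columns) of
#'   zero-centred read-depth values.
#' @param sampleIDs,binIDs optional identifier vectors; default to the
#'   dimnames of `values`, or to `cell_1..m` / `bin_1..n`.
#' @return A [ReadDepthMatrix-class].
#' @examples
#' rd <- ReadDepthMatrix(matrix(rnorm(12), 3, 4))
#' dim(rd)
#' @export
ReadDepthMatrix <- function(values, sampleIDs = NULL, binIDs = NULL) {
    if (!is.matrix(values) || !is.numeric(values))
        .stopInvalid("'values' must be a numeric matrix")
    if (is.null(sampleIDs))
        sampleIDs <- rownames(values)
    if (is.null(sampleIDs))
        sampleIDs <- sprintf("cell_%d", seq_len(nrow(values)))
    if (is.null(binIDs))
        binIDs <- colnames(values)
    if (is.null(binIDs))
        binIDs <- sprintf("bin_%d", seq_len(ncol(values)))
    dimnames(values) <- NULL
    new("ReadDepthMatrix", values = values,
        sampleIDs = as.character(sampleIDs), binIDs = as.character(binIDs))
}

#' @describeIn ReadDepthMatrix the numeric matrix.
#' @param x a `ReadDepthMatrix`.
#' @export
setMethod("rdValues", "ReadDepthMatrix", function(x) {
    v <- x@values
    dimnames(v) <- list(x@sampleIDs, x@binIDs)
    v
})

#' @describeIn ReadDepthMatrix sample identifiers.
#' @export
setMethod("sampleIDs", "ReadDepthMatrix", function(x) x@sampleIDs)

#' @describeIn ReadDepthMatrix bin identifiers.
#' @export
setMethod("binIDs", "ReadDepthMatrix", function(x) x@binIDs)

#' @export
setMethod("dim", "ReadDepthMatrix", function(x) dim(x@values))

setMethod("show", "ReadDepthMatrix", function(object) {
    d <- dim(object@values)
    cat("ReadDepthMatrix:", d[1L], "samples x", d[2L], "bins\n")
    cat("  samples:", paste(utils::head(object@sampleIDs, 4L),
        collapse = ", "), if (d[1L] > 4L) "..." else "", "\n")
    cat("  value range: [", format(min(object@values), digits = 4L), ", ",
        format(max(object@values), digits = 4L), "]\n", sep = "")
})

#' Construct a SampleOrdering
#'
#' @param order integer vector; a bijection on `1:m`. `order[pos]` names the
#'   source row placed at position `pos`.
#' @return A [SampleOrdering-class].
#' @examples
#' o <- SampleOrdering(c(2L, 1L, 3L))
#' applyOrdering(o, diag(3))
#' @export
SampleOrdering <- function(order) {
    new("SampleOrdering", order = as.integer(order))
}

#' @describeIn SampleOrdering the underlying index vector.
#' @param x a `SampleOrdering`.
#' @export
setMethod("orderIndices", "SampleOrdering", function(x) x@order)

#' @export
setMethod("length", "SampleOrdering", function(x) length(x@order))

#' @describeIn SampleOrdering the m x m binary matrix P with
#'   `P[pos, order[pos]] = 1`, so `P %*% M == M[order, ]`.
#' @export
setMethod("permutationMatrix", "SampleOrdering", function(x) {
    m <- length(x@order)
    P <- matrix(0, m, m)
    P[cbind(seq_len(m), x@order)] <- 1
    P
})

#' @describeIn SampleOrdering the inverse permutation.
#' @export
setMethod("inverseOrdering", "SampleOrdering", function(x) {
    SampleOrdering(order(x@order))
})

#' @describeIn SampleOrdering reorder the rows of a matrix or
#'   `ReadDepthMatrix`.
#' @param target matrix or `ReadDepthMatrix` with m rows.
#' @export
setMethod("applyOrdering", "SampleOrdering", function(x, target) {
    if (is(target, "ReadDepthMatrix")) {
        if (nrow(target@values) != length(x@order))
            .stopInvalid("ordering length does not match sample count")
        return(ReadDepthMatrix(target@values[x@order, , drop = FALSE],
                               sampleIDs = target@sampleIDs[x@order],
                               binIDs = target@binIDs))
    }
    if (!is.matrix(target) || nrow(target) != length(x@order))
        .stopInvalid("'target' must be a matrix with m rows")
    target[x@order, , drop = FALSE]
})

setMethod("show", "SampleOrdering", function(object) {
    cat("SampleOrdering of", length(object@order), "samples:",
        paste(utils::head(object@order, 10L), collapse = " "),
        if (length(object@order) > 10L) "..." else "", "\n")
})

#' Construct a TCPConfig
#'
#' @param alpha fidelity/regularisation trade-off (>= 0); `NA` (default)
#'   resolves at solve time to the median absolute adjacent-row difference
#'   of the input matrix.
#' @param gamma augmented-Lagrangian penalty (> 0).
#' @param maxIters iteration cap.
#' @param tol convergence tolerance.
#' @param stallWindow stop after this many iterations without an ordering
#'   change.
#' @param boundary `"circular"` (default; FFT X-step) or `"open"`.
#' @return A [TCPConfig-class].
#' @export
TCPConfig <- function(alpha = NA_real_, gamma = 1, maxIters = 1000L,
                      tol = 1e-6, stallWindow = 10L,
                      boundary = c("circular", "open")) {
    boundary <- match.arg(boundary)
    new("TCPConfig", alpha = as.numeric(alpha), gamma = as.numeric(gamma),
        maxIters = as.integer(maxIters), tol = as.numeric(tol),
        stallWindow = as.integer(stallWindow), boundary = boundary)
}

setMethod("show", "TCPConfig", function(object) {
    cat("TCPConfig: alpha =",
        if (is.na(object@alpha)) "auto (data-scaled)" else object@alpha,
        "| gamma =", object@gamma, "| boundary =", object@boundary, "\n")
    cat("  maxIters =", object@maxIters, "| tol =", object@tol,
        "| stallWindow =", object@stallWindow, "\n")
})

#' @describeIn TCPResult final solver state.
#' @param x a `TCPResult`.
#' @export
setMethod("solverState", "TCPResult", function(x) x@state)

#' @describeIn TCPResult did the solver converge before `maxIters`?
#' @export
setMethod("converged", "TCPResult", function(x) x@converged)

#' @describeIn TCPResult the recovered (denoised, reordered)
#'   `ReadDepthMatrix`.
#' @export
setMethod("recoveredMatrix", "TCPResult", function(x) x@recovered)

#' @describeIn TCPResult per-iteration trace data.frame.
#' @export
setMethod("solverTrace", "TCPResult", function(x) x@trace)

#' @describeIn TCPResult the seriation order: a [SampleOrdering-class]
#'   mapping each position of the recovered matrix to the original sample
#'   index (the inverse of the model's P).
#' @export
setMethod("sampleArrangement", "TCPResult", function(x) {
    inverseOrdering(x@state@ordering)
})

setMethod("show", "TCPResult", function(object) {
    st <- object@state
    cat("TCPResult:", if (object@converged) "converged" else "stopped",
        "after", st@iteration, "iterations\n")
    cat("  final objective:",
        format(st@objectiveHistory[length(st@objectiveHistory)],
               digits = 6L), "\n")
    cat("  final relative primal residual:",
        format(st@primalResidualHistory[length(st@primalResidualHistory)],
               digits = 4L), "\n")
})

#' @describeIn SyntheticDataset the observed matrix.
#' @param x a `SyntheticDataset`.
#' @export
setMethod("rdValues", "SyntheticDataset", function(x) rdValues(x@matrix))

#' @describeIn SyntheticDataset ground-truth group label per sample.
#' @export
setMethod("groupLabels", "SyntheticDataset", function(x) x@labels)

#' @describeIn SyntheticDataset ordering that undoes the shuffle.
#' @export
setMethod("trueOrder", "SyntheticDataset", function(x) x@trueOrder)

#' @describeIn SyntheticDataset logical mask of inserted irrelevant bins.
#' @export
setMethod("irrelevantMask", "SyntheticDataset", function(x) x@irrelevantMask)

#' @describeIn SyntheticDataset realised signal-to-noise ratio.
#' @export
setMethod("achievedSNR", "SyntheticDataset", function(x) x@achievedSNR)

setMethod("show", "SyntheticDataset", function(object) {
    d <- dim(object@matrix@values)
    cat("SyntheticDataset:", d[1L], "samples x", d[2L], "bins |",
        length(unique(object@labels)), "groups |",
        sum(object@irrelevantMask), "irrelevant bins\n")
    cat("  achieved SNR:", format(object@achievedSNR, digits = 4L), "\n")
})

#' @describeIn LaplacianScoreResult per-bin scores (lower = more relevant).
#' @param x a `LaplacianScoreResult`.
#' @export
setMethod("featureScores", "LaplacianScoreResult", function(x) x@scores)

#' @describeIn LaplacianScoreResult indices of retained bins.
#' @export
setMethod("keptIndices", "LaplacianScoreResult", function(x) x@keptIndices)

setMethod("show", "LaplacianScoreResult", function(object) {
    cat("LaplacianScoreResult:", length(object@scores), "features | k =",
        object@neighborCount, "| bandwidth =",
        format(object@bandwidth, digits = 4L), "\n")
    if (length(object@keptIndices))
        cat("  kept:", length(object@keptIndices), "features\n")
})

setMethod("show", "EvaluationReport", function(object) {
    cat("EvaluationReport [", object@methodName, "]\n", sep = "")
    cat("  label blocks:", object@nLabelBlocks,
        "| ARI:", format(object@adjustedRand, digits = 4L),
        "| misclassified:", object@nMisclassified, "\n")
})
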