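#' @include difference-operator.R
NULL

.coerceMatrix <- function(B, arg = "B") {
    if (is(B, "ReadDepthMatrix")) {
        v <- B@values
    } else if (is(B, "SyntheticDataset")) {
        v <- B@matrix@values
    } else if (is.matrix(B) && is.numeric(B)) {
        v <- B
        dimnames(v) <- NULL
    } else {
        .stopInvalid("'", arg, "' must be a numeric matrix or ReadDepthMatrix")
    }
    v
}

#' Column-wise total-variation norm of a matrix
#'
#' `||X||_{TV,l1} = sum_j sum_{i=2..m} |x[i,j] - x[i-1,j]|`, i.e. the l1 norm
#' of the first differences taken down each column (across samples). The
#' circular mode adds the wraparound term `|x[1,j] - x[m,j]|` per column,
#' matching the circulant difference operator used by the FFT solver.
#'
#' @param X numeric matrix (or `ReadDepthMatrix`) with at least 2 rows.
#' @param boundary `"circular"` or `"open"`.
#' @return Non-negative scalar; equals `sum(abs(D %*% X))` for the matching
#'   [buildDifferenceOperator()].
#' @examples
#' tvL1Norm(rbind(c(0, 0), c(1, 2), c(1, 2)), "open")     # 3
#' tvL1Norm(rbind(c(0, 0), c(1, 2), c(1, 2)), "circular") # 6
#' @export
tvL1Norm <- function(X, boundary = c("circular", "open")) {
    boundary <- match.arg(boundary)
    X <- .coerceMatrix(X, "X")
    if (nrow(X) < 2L) .stopInvalid("'X' must have at least 2 rows")
    if (!all(is.finite(X))) .stopInvalid("'X' must have finite entries")
    tv <- sum(abs(diff(X)))
    if (boundary == "circular")
        tv <- tv + sum(abs(X[1L, ] - X[nrow(X), ]))
    tv
}

#' Soft-thresholding (shrinkage) operator
#'
#' The proximal map of the l1 norm: `x - t` for `x > t`, `0` inside
#' `[-t, t]`, `x + t` for `x < -t`; applied element-wise to matrices.
#'
#' @param x numeric scalar, vector or matrix.
#' @param t non-negative threshold.
#' @export
softThreshold <- function(x, t) {
    if (length(t) != 1L || is.na(t) || t < 0)
        .stopInvalid("threshold 't' must be a single value >= 0")
    sign(x) * pmax(abs(x) - t, 0)
}

.fidelity <- function(order, X, B) sum((X[order, , drop = FALSE] - B)^2)

#' The TCP energy
#'
#' `||P X - B||^2_F + alpha * ||X||_{TV,l1}`, the objective minimised
#' jointly over the denoised matrix X and the permutation P.
#'
#' @param X numeric m x n matrix.
#' @param ordering [SampleOrdering-class] (or integer permutation vector);
#'   the index form of P, so `P X = X[order, ]`.
#' @param B observed m x n matrix.
#' @param alpha non-negative trade-off constant.
#' @param boundary boundary mode of the TV term.
#' @return Non-negative scalar energy.
#' @export
tcpObjective <- function(X, ordering, B, alpha,
                         boundary = c("circular", "open")) {
    boundary <- match.arg(boundary)
    X <- .coerceMatrix(X, "X")
    B <- .coerceMatrix(B, "B")
    if (!identical(dim(X), dim(B)))
        .stopInvalid("'X' and 'B' must have the same shape")
    if (length(alpha) != 1L || is.na(alpha) || alpha < 0)
        .stopInvalid("'alpha' must be a single value >= 0")
    ord <- if (is(ordering, "SampleOrdering")) ordering@order
           else orderIndices(SampleOrdering(ordering))
    if (length(ord) != nrow(X))
        .stopInvalid("ordering length must equal nrow(X)")
    .fidelity(ord, X, B) + alpha * tvL1Norm(X, boundary)
}
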