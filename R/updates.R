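#' @include norms.R
NULL

#' X-step: exact minimiser of the quadratic subproblem
#'
#' Solves `(2 I + gamma t(D) D) X = 2 t(P) B - t(D) lambda + gamma t(D) Y`.
#' For the circular boundary D is circulant, so the system is diagonalised
#' by a 1-D DFT along the sample axis applied independently to each column:
#' transform, divide by `2 + gamma |K|^2`, back-transform. For the open
#' boundary a dense symmetric solve is used.
#'
#' @param ordering [SampleOrdering-class] (index form of P).
#' @param B observed m x n matrix.
#' @param Y,dual current split variable and dual variable (m x n).
#' @param gamma penalty parameter (>= 0; the solver itself requires > 0).
#' @param D a [DifferenceOperator-class] of size m.
#' @return The m x n minimiser.
#' @export
updateX <- function(ordering, B, Y, dual, gamma, D) {
    B <- .coerceMatrix(B, "B")
    m <- nrow(B)
    if (!identical(dim(Y), dim(B)) || !identical(dim(dual), dim(B)))
        .stopInvalid("'B', 'Y' and 'dual' must share the same shape")
    if (length(gamma) != 1L || is.na(gamma) || gamma < 0)
        .stopInvalid("'gamma' must be a single value >= 0")
    if (D@size != m) .stopInvalid("'D' size does not match nrow(B)")
    ord <- if (is(ordering, "SampleOrdering")) ordering@order
           else orderIndices(SampleOrdering(ordering))
    PtB <- B[order(ord), , drop = FALSE]  # t(P) %*% B
    rhs <- 2 * PtB - .applyDt(D, dual) + gamma * .applyDt(D, Y)
    if (D@boundary == "circular") {
        denom <- 2 + gamma * Mod(D@spectrum)^2
        Xf <- stats::mvfft(rhs) / denom
        Xc <- stats::mvfft(Xf, inverse = TRUE) / m
        X <- Re(Xc)
        imagNorm <- sqrt(sum(Im(Xc)^2))
        if (imagNorm > 1e-8 * max(1, sqrt(sum(X^2))))
            stop("numerical-failure: imaginary residue after inverse FFT (",
                 format(imagNorm, digits = 4), ")", call. = FALSE)
    } else {
        A <- 2 * diag(m) + gamma * crossprod(D@matrixForm)
        X <- solve(A, rhs)
    }
    X
}

#' Y-step: element-wise soft thresholding
#'
#' `Y = S_{alpha/gamma}(D X + lambda / gamma)`, the exact minimiser of
#' `alpha ||Y||_1 + (gamma/2) ||Y - (D X + lambda/gamma)||^2_F`.
#'
#' @param X current m x n matrix.
#' @param dual dual variable (m x n).
#' @param alpha regularisation weight (>= 0).
#' @param gamma penalty parameter (> 0).
#' @param D a [DifferenceOperator-class].
#' @export
updateY <- function(X, dual, alpha, gamma, D) {
    if (length(gamma) != 1L || is.na(gamma) || gamma <= 0)
        .stopInvalid("'gamma' must be a single positive value")
    if (length(alpha) != 1L || is.na(alpha) || alpha < 0)
        .stopInvalid("'alpha' must be a single value >= 0")
    if (!identical(dim(X), dim(dual)))
        .stopInvalid("'X' and 'dual' must share the same shape")
    softThreshold(.applyD(D, X) + dual / gamma, alpha / gamma)
}

# Resolve ties reproducibly: where the diagonal entry has zero cost and
# taking it keeps the total optimal, prefer the identity mapping, so
# updateP(B, B) returns the identity ordering. Other ties are left to the
# (deterministic) assignment solver.
.canonicalizeOrder <- function(ord, C) {
    m <- length(ord)
    pos <- integer(m)
    pos[ord] <- seq_len(m)  # pos[k] = position holding source k
    scale <- max(C)
    zeroTol <- 1e-12 * max(1, scale)
    for (i in seq_len(m)) {
        k <- ord[i]
        if (k == i) next
        if (C[i, i] > zeroTol) next
        j <- pos[i]
        cur <- C[i, k] + C[j, i]
        swapped <- C[i, i] + C[j, k]
        if (swapped <= cur + 1e-9 * max(1, abs(cur))) {
            ord[i] <- i
            ord[j] <- k
            pos[i] <- i
            pos[k] <- j
        }
    }
    ord
}

#' P-step: optimal row assignment by the Kuhn-Munkres algorithm
#'
#' Minimises `||P X - B||^2_F` over permutation matrices. This is a linear
#' assignment problem on the cost `C[i, k] = ||X[k, ] - B[i, ]||^2` (source
#' row k of X placed at position i), solved exactly in O(m^3). Among tied
#' optima a canonicalisation pass prefers the identity mapping, so
#' `updateP(B, B)` returns the identity ordering.
#'
#' @param X candidate m x n matrix.
#' @param B observed m x n matrix.
#' @return The minimising [SampleOrdering-class].
#' @export
updateP <- function(X, B) {
    X <- .coerceMatrix(X, "X")
    B <- .coerceMatrix(B, "B")
    if (!identical(dim(X), dim(B)))
        .stopInvalid("'X' and 'B' must have the same shape")
    C <- outer(rowSums(B^2), rowSums(X^2), "+") - 2 * tcrossprod(B, X)
    C[C < 0] <- 0  # clip tiny negative round-off
    ord <- .hungarianAssignment(C)
    SampleOrdering(.canonicalizeOrder(ord, C))
}

#' Dual ascent step
#'
#' `lambda <- lambda + gamma (D X - Y)`, the standard augmented-Lagrangian
#' multiplier update for the constraint `Y = D X`.
#'
#' @param dual current dual variable (m x n).
#' @param X,Y current primal variables.
#' @param gamma penalty parameter.
#' @param D a [DifferenceOperator-class].
#' @export
updateDual <- function(dual, X, Y, gamma, D) {
    if (!identical(dim(X), dim(Y)) || !identical(dim(dual), dim(X)))
        .stopInvalid("'dual', 'X' and 'Y' must share the same shape")
    dual + gamma * (.applyD(D, X) - Y)
}
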