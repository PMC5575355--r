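#' @include accessors.R
NULL

#' Build the first-order difference operator along the sample axis
#'
#' Circular boundary gives the circulant D with rows
#' `(D X)[i, ] = X[i, ] - X[i - 1 mod m, ]`, whose DFT spectrum
#' `K_k = 1 - exp(-2 pi i k / m)` diagonalises it as `D = F^-1 diag(K) F`.
#' Open boundary zeroes the first row (no wraparound term), matching the
#' plain sum-over-`i = 2..m` definition of the total-variation norm.
#'
#' @param m number of samples (>= 2).
#' @param boundary `"circular"` or `"open"`.
#' @return A [DifferenceOperator-class].
#' @examples
#' D <- buildDifferenceOperator(3, "circular")
#' D@matrixForm
#' @export
buildDifferenceOperator <- function(m, boundary = c("circular", "open")) {
    boundary <- match.arg(boundary)
    m <- as.integer(m)
    if (is.na(m) || m < 2L)
        .stopInvalid("'m' must be an integer >= 2")
    D <- diag(m)
    idx <- seq_len(m)
    prev <- c(m, seq_len(m - 1L))
    D[cbind(idx, prev)] <- D[cbind(idx, prev)] - 1
    if (boundary == "open") {
        D[1L, ] <- 0
        spec <- complex(0)
    } else {
        spec <- stats::fft(D[, 1L])
    }
    new("DifferenceOperator", size = m, boundary = boundary,
        matrixForm = D, spectrum = spec)
}

setMethod("show", "DifferenceOperator", function(object) {
    cat("DifferenceOperator: m =", object@size,
        "| boundary =", object@boundary, "\n")
})

# D %*% X and t(D) %*% X without forming products column by column.
.applyD <- function(D, X) D@matrixForm %*% X
.applyDt <- function(D, X) crossprod(D@matrixForm, X)
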