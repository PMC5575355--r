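#' @include solver.R
NULL

#' Construct a SyntheticConfig
#'
#' @param nSamples number of samples (default 100).
#' @param nGroups number of groups (default 4).
#' @param groupSizes integer vector summing to `nSamples` (default equal
#'   split).
#' @param nBins number of true signal bins (default 300).
#' @param blockAmplitudes distinct per-group amplitudes (default `1:nGroups`).
#' @param targetSNR target linear SNR sd(signal)/sd(noise) (default 3.57);
#'   set to `NA` and give `noiseSD` to fix the noise level instead.
#' @param noiseSD noise standard deviation; exactly one of
#'   `targetSNR`/`noiseSD` may be non-NA.
#' @param nIrrelevant number of standard-normal irrelevant bins to insert.
#' @param withinGroupJitter relative per-sample amplitude jitter (default 0:
#'   rows within a group are identical before noise).
#' @param seed integer seed for all randomness, or NA.
#' @return A [SyntheticConfig-class].
#' @export
SyntheticConfig <- function(nSamples = 100L, nGroups = 4L,
                            groupSizes = NULL, nBins = 300L,
                            blockAmplitudes = NULL, targetSNR = 3.57,
                            noiseSD = NA_real_, nIrrelevant = 0L,
                            withinGroupJitter = 0,
                            seed = NA_integer_) {
    nSamples <- as.integer(nSamples)
    nGroups <- as.integer(nGroups)
    if (is.null(groupSizes)) {
        base <- nSamples %/% nGroups
        groupSizes <- rep(base, nGroups)
        extra <- nSamples - base * nGroups
        if (extra > 0L)
            groupSizes[seq_len(extra)] <- groupSizes[seq_len(extra)] + 1L
    }
    if (is.null(blockAmplitudes)) blockAmplitudes <- seq_len(nGroups)
    new("SyntheticConfig", nSamples = nSamples, nGroups = nGroups,
        groupSizes = as.integer(groupSizes), nBins = as.integer(nBins),
        blockAmplitudes = as.numeric(blockAmplitudes),
        targetSNR = as.numeric(targetSNR), noiseSD = as.numeric(noiseSD),
        nIrrelevant = as.integer(nIrrelevant),
        withinGroupJitter = as.numeric(withinGroupJitter),
        seed = as.integer(seed))
}

setMethod("show", "SyntheticConfig", function(object) {
    cat("SyntheticConfig:", object@nSamples, "samples in", object@nGroups,
        "groups |", object@nBins, "bins |",
        object@nIrrelevant, "irrelevant\n")
    cat("  noise:", if (!is.na(object@targetSNR))
        paste("target SNR", object@targetSNR) else
        paste("sd", object@noiseSD), "| seed:", object@seed, "\n")
})

#' Noise-free orthogonal block signal
#'
#' Partitions the bin axis into `nGroups` disjoint contiguous supports;
#' samples of group g carry `blockAmplitudes[g]` on support g and 0
#' elsewhere, so rows from different groups have exactly zero inner product
#' and rows within a group are identical (up to the optional jitter).
#'
#' @param config a [SyntheticConfig-class].
#' @return list with `matrix` (nSamples x nBins) and `labels` (character,
#'   `"group1"`, ...).
#' @export
makeBlockSignal <- function(config) {
    validObject(config)
    if (config@nBins < config@nGroups)
        .stopInvalid("'nBins' must be >= nGroups")
    g <- config@nGroups
    supportSizes <- rep(config@nBins %/% g, g)
    extra <- config@nBins - sum(supportSizes)
    if (extra > 0L)
        supportSizes[seq_len(extra)] <- supportSizes[seq_len(extra)] + 1L
    supportEnd <- cumsum(supportSizes)
    supportStart <- supportEnd - supportSizes + 1L
    M <- matrix(0, config@nSamples, config@nBins)
    labels <- character(config@nSamples)
    row <- 0L
    for (k in seq_len(g)) {
        cols <- supportStart[k]:supportEnd[k]
        for (s in seq_len(config@groupSizes[k])) {
            row <- row + 1L
            amp <- config@blockAmplitudes[k]
            if (config@withinGroupJitter > 0)
                amp <- amp * (1 + config@withinGroupJitter * stats::rnorm(1L))
            M[row, cols] <- amp
            labels[row] <- paste0("group", k)
        }
    }
    list(matrix = M, labels = labels)
}

#' Signal-to-noise ratio of a signal/noise pair
#'
#' Linear amplitude ratio `sd(signal entries) / sd(noise entries)`.
#' Returns `Inf` when the noise has zero spread, and 0 for a constant
#' signal.
#'
#' @param signal,noise numeric matrices of the same shape.
#' @export
computeSNR <- function(signal, noise) {
    if (!identical(dim(signal), dim(noise)))
        .stopInvalid("'signal' and 'noise' must have the same shape")
    sdN <- stats::sd(as.vector(noise))
    if (sdN == 0) return(Inf)
    stats::sd(as.vector(signal)) / sdN
}

#' Add i.i.d. zero-mean Gaussian noise at a target SNR
#'
#' When `targetSNR` is given, the noise standard deviation is set to
#' `sd(signal)/targetSNR`; the achieved SNR is then recomputed from the
#' realised draw. `noiseSD = 0` leaves the matrix unchanged with
#' `achievedSNR = Inf`.
#'
#' @param mat numeric matrix of noise-free signal.
#' @param targetSNR positive linear SNR, or NULL.
#' @param noiseSD noise standard deviation, or NULL; give exactly one of
#'   the two.
#' @param seed optional integer seed.
#' @return list with `matrix`, `achievedSNR`, `noiseSD`.
#' @export
addGaussianNoise <- function(mat, targetSNR = NULL, noiseSD = NULL,
                             seed = NULL) {
    if (!all(is.finite(mat))) .stopInvalid("'mat' must be finite")
    if (is.null(targetSNR) == is.null(noiseSD))
        .stopInvalid("give exactly one of 'targetSNR' or 'noiseSD'")
    if (!is.null(targetSNR)) {
        if (targetSNR <= 0) .stopInvalid("'targetSNR' must be positive")
        noiseSD <- stats::sd(as.vector(mat)) / targetSNR
    }
    if (noiseSD < 0) .stopInvalid("'noiseSD' must be >= 0")
    if (!is.null(seed)) set.seed(seed)
    if (noiseSD == 0)
        return(list(matrix = mat, achievedSNR = Inf, noiseSD = 0))
    noise <- matrix(stats::rnorm(length(mat), sd = noiseSD),
                    nrow(mat), ncol(mat))
    list(matrix = mat + noise, achievedSNR = computeSNR(mat, noise),
         noiseSD = noiseSD)
}

#' Insert irrelevant standard-normal read-depth columns
#'
#' Inserts `nIrrelevant` i.i.d. standard-normal columns at uniformly random
#' positions along the bin axis; original columns keep their relative
#' order. Removing the masked columns recovers the input exactly.
#'
#' @param mat numeric matrix.
#' @param nIrrelevant non-negative count of columns to insert.
#' @param seed optional integer seed.
#' @return list with `matrix` (n + nIrrelevant columns) and logical `mask`
#'   marking inserted columns.
#' @export
insertIrrelevantFeatures <- function(mat, nIrrelevant, seed = NULL) {
    nIrrelevant <- as.integer(nIrrelevant)
    if (is.na(nIrrelevant) || nIrrelevant < 0L)
        .stopInvalid("'nIrrelevant' must be >= 0")
    if (nIrrelevant == 0L)
        return(list(matrix = mat, mask = logical(ncol(mat))))
    if (!is.null(seed)) set.seed(seed)
    nTotal <- ncol(mat) + nIrrelevant
    mask <- logical(nTotal)
    mask[sample.int(nTotal, nIrrelevant)] <- TRUE
    out <- matrix(0, nrow(mat), nTotal)
    out[, !mask] <- mat
    out[, mask] <- stats::rnorm(nrow(mat) * nIrrelevant)
    list(matrix = out, mask = mask)
}

#' Shuffle sample rows, recording the inverse permutation
#'
#' @param mat numeric matrix.
#' @param labels per-row labels (same length as `nrow(mat)`).
#' @param seed optional integer seed.
#' @return list with `matrix`, `labels` (both shuffled) and `trueOrder`, a
#'   [SampleOrdering-class] such that applying it to the shuffled matrix
#'   restores the input row order exactly.
#' @export
shuffleSamples <- function(mat, labels, seed = NULL) {
    m <- nrow(mat)
    if (length(labels) != m)
        .stopInvalid("'labels' must have one entry per row")
    if (!is.null(seed)) set.seed(seed)
    perm <- sample.int(m)
    list(matrix = mat[perm, , drop = FALSE], labels = labels[perm],
         trueOrder = SampleOrdering(order(perm)))
}

#' Generate a full synthetic benchmark dataset
#'
#' Runs the pipeline block signal -> Gaussian noise -> irrelevant-feature
#' insertion -> row shuffle, all seeded by `config@seed`, and wraps the
#' result with ground truth for evaluation.
#'
#' @param config a [SyntheticConfig-class].
#' @return A [SyntheticDataset-class].
#' @examples
#' sim <- simulateReadDepth(SyntheticConfig(seed = 7L))
#' sim
#' @export
simulateReadDepth <- function(config) {
    validObject(config)
    if (!is.na(config@seed)) set.seed(config@seed)
    sig <- makeBlockSignal(config)
    noisy <- if (!is.na(config@targetSNR))
        addGaussianNoise(sig$matrix, targetSNR = config@targetSNR)
    else
        addGaussianNoise(sig$matrix, noiseSD = config@noiseSD)
    expanded <- insertIrrelevantFeatures(noisy$matrix, config@nIrrelevant)
    shuffled <- shuffleSamples(expanded$matrix, sig$labels)

    nTotal <- ncol(expanded$matrix)
    binIDs <- character(nTotal)
    binIDs[!expanded$mask] <- sprintf("bin_%04d", seq_len(config@nBins))
    if (config@nIrrelevant > 0L)
        binIDs[expanded$mask] <- sprintf("irr_%05d",
                                         seq_len(config@nIrrelevant))
    rd <- ReadDepthMatrix(shuffled$matrix,
        sampleIDs = sprintf("cell_%03d", seq_len(config@nSamples)),
        binIDs = binIDs)
    new("SyntheticDataset", matrix = rd, labels = shuffled$labels,
        trueOrder = shuffled$trueOrder, irrelevantMask = expanded$mask,
        achievedSNR = noisy$achievedSNR)
}
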