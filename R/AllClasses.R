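#' @include TCPermute-package.R
NULL

.stopInvalid <- function(...) stop("invalid-input: ", ..., call. = FALSE)

#' Read-depth matrix of samples by genomic bins
#'
#' An m x n numeric matrix of zero-centred copy-number read-depth values
#' (two copies map to 0 after normalisation), with unique sample and bin
#' identifiers. Samples are rows; bins are columns.
#'
#' @slot values numeric matrix, m samples x n bins.
#' @slot sampleIDs character vector of m unique sample identifiers.
#' @slot binIDs character vector of n unique bin identifiers.
#'
#' @seealso [ReadDepthMatrix()] for the constructor, [solveTCP()].
#' @exportClass ReadDepthMatrix
setClass("ReadDepthMatrix",
    representation(values = "matrix", sampleIDs = "character",
                   binIDs = "character"))

setValidity("ReadDepthMatrix", function(object) {
    v <- object@values
    if (!is.numeric(v)) return("'values' must be a numeric matrix")
    if (nrow(v) < 2L) return("at least 2 samples (rows) are required")
    if (ncol(v) < 1L) return("at least 1 bin (column) is required")
    if (!all(is.finite(v))) return("all read-depth values must be finite")
    if (length(object@sampleIDs) != nrow(v))
        return("length of 'sampleIDs' must equal the number of rows")
    if (length(object@binIDs) != ncol(v))
        return("length of 'binIDs' must equal the number of columns")
    if (anyDuplicated(object@sampleIDs)) return("'sampleIDs' must be unique")
    if (anyDuplicated(object@binIDs)) return("'binIDs' must be unique")
    TRUE
})

#' Sample ordering (row permutation)
#'
#' A permutation of the m sample indices, interchangeable with its m x m
#' binary permutation-matrix form P. `order[pos]` gives the source row to
#' place at position `pos`, so applying the ordering to a matrix M yields
#' `M[order, ]`.
#'
#' @slot order integer vector; a bijection on `1:m`.
#'
#' @seealso [SampleOrdering()], [permutationMatrix()], [applyOrdering()].
#' @exportClass SampleOrdering
setClass("SampleOrdering", representation(order = "integer"))

setValidity("SampleOrdering", function(object) {
    o <- object@order
    if (length(o) < 1L) return("'order' must be non-empty")
    if (anyNA(o)) return("'order' must not contain NA")
    if (!identical(sort(o), seq_along(o)))
        return("'order' must be a bijection on 1..m")
    TRUE
})

#' First-order difference operator along the sample axis
#'
#' The m x m matrix D with `(D X)[i, ] = X[i, ] - X[i - 1, ]`. With circular
#' boundary D is circulant (row i wraps to row m when i = 1) and is
#' diagonalised by the discrete Fourier transform, `D = F^-1 diag(K) F`; the
#' diagonal K is stored in `spectrum`. With open boundary the first row of D
#' is zero, embedding the (m-1)-row difference as m x m so that all split
#' variables keep the same shape.
#'
#' @slot size integer m.
#' @slot boundary `"circular"` or `"open"`.
#' @slot matrixForm the dense m x m matrix D.
#' @slot spectrum complex vector of m DFT coefficients (circular only;
#'   length 0 for open boundary).
#'
#' @seealso [buildDifferenceOperator()].
#' @exportClass DifferenceOperator
setClass("DifferenceOperator",
    representation(size = "integer", boundary = "character",
                   matrixForm = "matrix", spectrum = "complex"))

setValidity("DifferenceOperator", function(object) {
    if (object@size < 2L) return("'size' must be >= 2")
    if (!object@boundary %in% c("circular", "open"))
        return("'boundary' must be 'circular' or 'open'")
    if (!identical(dim(object@matrixForm),
                   c(object@size, object@size)))
        return("'matrixForm' must be size x size")
    if (object@boundary == "circular" &&
        length(object@spectrum) != object@size)
        return("'spectrum' must have length 'size' for circular boundary")
    TRUE
})

#' Solver configuration for the TCP model
#'
#' @slot alpha numeric >= 0; trade-off between data fidelity and the
#'   (TV, l1) regulariser. `NA` means a data-scaled default, the median
#'   absolute adjacent-row difference of the input matrix.
#' @slot gamma positive numeric; augmented-Lagrangian penalty parameter.
#' @slot maxIters positive integer; iteration cap.
#' @slot tol positive numeric; convergence tolerance on the relative primal
#'   residual and relative objective change.
#' @slot stallWindow positive integer; the solver also stops once the sample
#'   ordering has been unchanged for this many consecutive iterations.
#' @slot boundary `"circular"` (FFT X-step) or `"open"` (dense X-step).
#'
#' @seealso [TCPConfig()], [solveTCP()].
#' @exportClass TCPConfig
setClass("TCPConfig",
    representation(alpha = "numeric", gamma = "numeric",
                   maxIters = "integer", tol = "numeric",
                   stallWindow = "integer", boundary = "character"))

setValidity("TCPConfig", function(object) {
    if (length(object@alpha) != 1L ||
        (!is.na(object@alpha) && object@alpha < 0))
        return("'alpha' must be a single value >= 0 (or NA for data-scaled)")
    if (length(object@gamma) != 1L || is.na(object@gamma) ||
        object@gamma <= 0)
        return("'gamma' must be a single positive value")
    if (object@maxIters < 1L) return("'maxIters' must be >= 1")
    if (is.na(object@tol) || object@tol <= 0)
        return("'tol' must be positive")
    if (object@stallWindow < 1L) return("'stallWindow' must be >= 1")
    if (!object@boundary %in% c("circular", "open"))
        return("'boundary' must be 'circular' or 'open'")
    TRUE
})

#' State of the alternating TCP solver
#'
#' Holds the current denoised matrix X, the split variable Y (tracking D X),
#' the dual variable lambda, the current sample ordering, and per-iteration
#' histories. Histories have length `iteration + 1`: entry 1 records the
#' initial state.
#'
#' @slot X,Y,dual numeric m x n matrices.
#' @slot ordering a [SampleOrdering-class].
#' @slot iteration non-negative integer.
#' @slot objectiveHistory numeric; energy value per iteration.
#' @slot primalResidualHistory numeric; relative primal residual
#'   `||DX - Y||_F / max(||DX||_F, ||Y||_F, 1)` per iteration.
#' @slot stableIterations integer; consecutive iterations with an unchanged
#'   ordering.
#'
#' @exportClass SolverState
setClass("SolverState",
    representation(X = "matrix", Y = "matrix", dual = "matrix",
                   ordering = "SampleOrdering", iteration = "integer",
                   objectiveHistory = "numeric",
                   primalResidualHistory = "numeric",
                   stableIterations = "integer"))

setValidity("SolverState", function(object) {
    d <- dim(object@X)
    if (!identical(dim(object@Y), d) || !identical(dim(object@dual), d))
        return("X, Y and dual must share the same shape")
    if (length(object@ordering@order) != d[1L])
        return("ordering length must equal nrow(X)")
    if (object@iteration < 0L) return("'iteration' must be >= 0")
    if (length(object@objectiveHistory) != object@iteration + 1L ||
        length(object@primalResidualHistory) != object@iteration + 1L)
        return("histories must have length iteration + 1")
    TRUE
})

#' Result of a TCP solve
#'
#' @slot state final [SolverState-class].
#' @slot converged logical; `TRUE` when the convergence criterion (or the
#'   ordering-stall rule) fired before `maxIters`.
#' @slot recovered [ReadDepthMatrix-class]; the final X with sample
#'   identifiers rearranged into the recovered order.
#' @slot trace data.frame with one row per recorded iteration: iteration,
#'   objective, fidelity, tv, primalResidual, orderingChanged,
#'   fidelityBeforeP, fidelityAfterP.
#' @slot config the [TCPConfig-class] used (alpha resolved to its numeric
#'   value).
#'
#' @exportClass TCPResult
setClass("TCPResult",
    representation(state = "SolverState", converged = "logical",
                   recovered = "ReadDepthMatrix", trace = "data.frame",
                   config = "TCPConfig"))

#' Configuration of the synthetic block-signal generator
#'
#' Defaults reproduce the benchmark design: 100 samples in four equal groups
#' with mutually orthogonal block patterns over 300 bins, amplitudes 1..4,
#' Gaussian noise targeting SNR 3.57.
#'
#' @slot nSamples,nGroups,nBins integers.
#' @slot groupSizes integer vector summing to `nSamples`.
#' @slot blockAmplitudes numeric; pairwise-distinct per-group amplitudes.
#' @slot targetSNR,noiseSD exactly one is non-NA. SNR is the linear ratio
#'   sd(signal) / sd(noise) over all matrix entries.
#' @slot nIrrelevant non-negative integer; standard-normal columns inserted
#'   at random positions.
#' @slot withinGroupJitter non-negative numeric; relative amplitude jitter
#'   per sample (0 = identical rows within a group before noise).
#' @slot seed integer (or NA); seeds all randomness of the generator.
#'
#' @seealso [SyntheticConfig()], [simulateReadDepth()].
#' @exportClass SyntheticConfig
setClass("SyntheticConfig",
    representation(nSamples = "integer", nGroups = "integer",
                   groupSizes = "integer", nBins = "integer",
                   blockAmplitudes = "numeric", targetSNR = "numeric",
                   noiseSD = "numeric", nIrrelevant = "integer",
                   withinGroupJitter = "numeric", seed = "integer"))

setValidity("SyntheticConfig", function(object) {
    if (object@nGroups < 1L) return("'nGroups' must be >= 1")
    if (length(object@groupSizes) != object@nGroups)
        return("'groupSizes' must have length nGroups")
    if (any(object@groupSizes < 1L)) return("all group sizes must be >= 1")
    if (sum(object@groupSizes) != object@nSamples)
        return("'groupSizes' must sum to nSamples")
    if (object@nBins < object@nGroups)
        return("'nBins' must be >= nGroups")
    if (length(object@blockAmplitudes) != object@nGroups)
        return("'blockAmplitudes' must have length nGroups")
    if (anyDuplicated(object@blockAmplitudes))
        return("'blockAmplitudes' must be pairwise distinct")
    if (is.na(object@targetSNR) == is.na(object@noiseSD))
        return("exactly one of 'targetSNR' / 'noiseSD' must be set")
    if (!is.na(object@targetSNR) && object@targetSNR <= 0)
        return("'targetSNR' must be positive")
    if (!is.na(object@noiseSD) && object@noiseSD < 0)
        return("'noiseSD' must be >= 0")
    if (object@nIrrelevant < 0L) return("'nIrrelevant' must be >= 0")
    if (object@withinGroupJitter < 0)
        return("'withinGroupJitter' must be >= 0")
    TRUE
})

#' A generated synthetic dataset
#'
#' @slot matrix [ReadDepthMatrix-class]; the observed (noisy, expanded,
#'   shuffled) matrix handed to the solver.
#' @slot labels character; ground-truth group label per sample, aligned with
#'   the rows of `matrix`.
#' @slot trueOrder [SampleOrdering-class]; applying it to `matrix` restores
#'   the pre-shuffle row order.
#' @slot irrelevantMask logical per bin; `TRUE` marks inserted
#'   standard-normal columns.
#' @slot achievedSNR numeric; realised sd(signal)/sd(noise) (Inf when no
#'   noise was added).
#'
#' @exportClass SyntheticDataset
setClass("SyntheticDataset",
    representation(matrix = "ReadDepthMatrix", labels = "character",
                   trueOrder = "SampleOrdering", irrelevantMask = "logical",
                   achievedSNR = "numeric"))

setValidity("SyntheticDataset", function(object) {
    m <- nrow(object@matrix@values)
    n <- ncol(object@matrix@values)
    if (length(object@labels) != m)
        return("'labels' must have one entry per sample")
    if (length(object@trueOrder@order) != m)
        return("'trueOrder' must have length m")
    if (length(object@irrelevantMask) != n)
        return("'irrelevantMask' must have one entry per bin")
    TRUE
})

#' Laplacian-Score feature relevance result
#'
#' Lower scores mark features that better preserve locality on the sample
#' nearest-neighbour graph (more relevant); a zero-variance feature gets the
#' `Inf` sentinel (maximally irrelevant).
#'
#' @slot scores numeric, one non-negative score (or Inf) per bin.
#' @slot neighborCount integer k used for the kNN graph.
#' @slot bandwidth numeric; the heat-kernel bandwidth t actually used.
#' @slot keptIndices sorted integer indices of retained bins (filled by
#'   [selectFeatures()]; empty until then).
#'
#' @exportClass LaplacianScoreResult
setClass("LaplacianScoreResult",
    representation(scores = "numeric", neighborCount = "integer",
                   bandwidth = "numeric", keptIndices = "integer"))

setValidity("LaplacianScoreResult", function(object) {
    if (any(object@scores < 0, na.rm = TRUE))
        return("'scores' must be non-negative")
    if (length(object@keptIndices) &&
        (is.unsorted(object@keptIndices, strictly = TRUE) ||
         min(object@keptIndices) < 1L ||
         max(object@keptIndices) > length(object@scores)))
        return("'keptIndices' must be strictly increasing indices into scores")
    TRUE
})

#' Block-recovery evaluation report
#'
#' @slot methodName character.
#' @slot nLabelBlocks integer; maximal runs of identical labels along the
#'   ordering.
#' @slot adjustedRand numeric in [-1, 1].
#' @slot nMisclassified non-negative integer under optimal cluster-to-truth
#'   matching.
#'
#' @exportClass EvaluationReport
setClass("EvaluationReport",
    representation(methodName = "character", nLabelBlocks = "integer",
                   adjustedRand = "numeric", nMisclassified = "integer"))
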