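test_that("duplicated rows are grouped contiguously on noiseless data", {
    fix <- twoGroupShuffled()
    fit <- solveTCP(fix$matrix, TCPConfig(maxIters = 200))
    arr <- sampleArrangement(fit)
    expect_equal(countLabelBlocks(arr, fix$labels), 2L)
    # fidelity at the solution is no worse than the identity arrangement
    X <- unname(rdValues(recoveredMatrix(fit)))
    ordIdx <- orderIndices(solverState(fit)@ordering)
    expect_lte(sum((X[ordIdx, ] - fix$matrix)^2),
               sum((X - fix$matrix)^2) + 1e-9)
})

test_that("alpha = 0 on sorted noiseless data converges to X = t(P) B", {
    sig <- makeBlockSignal(SyntheticConfig(nSamples = 12L, nGroups = 3L,
        groupSizes = c(4L, 4L, 4L), nBins = 9L,
        blockAmplitudes = c(1, 2, 3), noiseSD = 0, targetSNR = NA))
    fit <- solveTCP(sig$matrix, TCPConfig(alpha = 0, maxIters = 100))
    expect_true(converged(fit))
    st <- solverState(fit)
    expect_lt(st@primalResidualHistory[st@iteration + 1L], 1e-6)
    ordIdx <- orderIndices(st@ordering)
    expect_equal(st@X, sig$matrix[order(ordIdx), ], tolerance = 1e-8)
})

test_that("degenerate inputs are handled", {
    # all-zero matrix: immediate convergence to X = 0, identity ordering
    fit <- solveTCP(matrix(0, 4, 3), TCPConfig())
    expect_true(converged(fit))
    expect_equal(unname(rdValues(recoveredMatrix(fit))), matrix(0, 4, 3))
    expect_equal(orderIndices(solverState(fit)@ordering), 1:4)
    # m = 2 and n = 1
    fit2 <- solveTCP(matrix(c(1, -1), 2, 1), TCPConfig(maxIters = 50))
    expect_equal(dim(solverState(fit2)@X), c(2L, 1L))
    fit3 <- solveTCP(matrix(rnorm(6), 6, 1), TCPConfig(maxIters = 50))
    expect_equal(dim(solverState(fit3)@X), c(6L, 1L))
    expect_error(solveTCP(matrix(0, 4, 3), config = "nope"), "TCPConfig")
})

test_that("checkConvergence follows residual, objective and stall rules", {
    mkState <- function(objs, ress, stable) {
        m <- 3L
        new("SolverState", X = matrix(0, m, 2), Y = matrix(0, m, 2),
            dual = matrix(0, m, 2), ordering = SampleOrdering(1:3),
            iteration = length(objs) - 1L, objectiveHistory = objs,
            primalResidualHistory = ress, stableIterations = stable)
    }
    expect_true(checkConvergence(mkState(c(10, 10), c(1, 0), 0L),
                                 1e-6, 10L))
    expect_false(checkConvergence(mkState(c(10, 8), c(1, 0.5), 0L),
                                  1e-6, 10L))
    # stalled ordering wins regardless of residual
    expect_true(checkConvergence(mkState(c(10, 8), c(1, 0.9), 10L),
                                 1e-6, 10L))
    expect_false(checkConvergence(mkState(10, 1, 0L), 1e-6, 10L))
})

test_that("P-step monotonicity holds at every recorded iteration", {
    for (seed in c(3L, 7L)) {
        sim <- simulateReadDepth(SyntheticConfig(nSamples = 30L,
            nGroups = 3L, groupSizes = c(10L, 10L, 10L), nBins = 60L,
            blockAmplitudes = c(1, 2, 3), targetSNR = 3, seed = seed))
        fit <- solveTCP(sim@matrix, TCPConfig(maxIters = 150))
        tr <- solverTrace(fit)
        tr <- tr[-1L, ]  # iteration 0 has no P-step
        expect_true(all(tr$fidelityAfterP <=
                        tr$fidelityBeforeP + 1e-8 * pmax(1, tr$fidelityBeforeP)))
    }
})

test_that("the final ordering is a valid permutation", {
    sim <- simulateReadDepth(SyntheticConfig(nSamples = 25L, nGroups = 2L,
        groupSizes = c(12L, 13L), nBins = 40L, blockAmplitudes = c(1, 2),
        targetSNR = 4, seed = 9L))
    fit <- solveTCP(sim@matrix, TCPConfig(maxIters = 120))
    ordIdx <- orderIndices(solverState(fit)@ordering)
    expect_setequal(ordIdx, seq_along(ordIdx))
    P <- permutationMatrix(solverState(fit)@ordering)
    expect_equal(crossprod(P, P), diag(length(ordIdx)))
})

test_that("the solver is deterministic for a fixed input and config", {
    sim <- simulateReadDepth(SyntheticConfig(nSamples = 20L, nGroups = 2L,
        groupSizes = c(10L, 10L), nBins = 30L, blockAmplitudes = c(1, 3),
        targetSNR = 3, seed = 4L))
    f1 <- solveTCP(sim@matrix, TCPConfig(maxIters = 80))
    f2 <- solveTCP(sim@matrix, TCPConfig(maxIters = 80))
    expect_identical(orderIndices(sampleArrangement(f1)),
                     orderIndices(sampleArrangement(f2)))
    expect_identical(rdValues(recoveredMatrix(f1)),
                     rdValues(recoveredMatrix(f2)))
    expect_identical(solverTrace(f1), solverTrace(f2))
})

test_that("trace bookkeeping matches the iteration count", {
    fit <- solveTCP(twoGroupShuffled()$matrix, TCPConfig(maxIters = 60))
    st <- solverState(fit)
    expect_equal(nrow(solverTrace(fit)), st@iteration + 1L)
    expect_length(st@objectiveHistory, st@iteration + 1L)
    expect_length(st@primalResidualHistory, st@iteration + 1L)
})

test_that("the open-boundary solve also recovers grouped duplicates", {
    fix <- twoGroupShuffled(seed = 13L)
    fit <- solveTCP(fix$matrix,
                    TCPConfig(boundary = "open", maxIters = 200))
    expect_equal(countLabelBlocks(sampleArrangement(fit), fix$labels), 2L)
})
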