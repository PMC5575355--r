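test_that("block signals have disjoint supports and orthogonal groups", {
    # 4 groups, 4 bins, unit-distinct amplitudes: one bin per group
    cfg <- SyntheticConfig(nSamples = 4L, nGroups = 4L,
        groupSizes = rep(1L, 4L), nBins = 4L,
        blockAmplitudes = c(1, 2, 3, 4), noiseSD = 0, targetSNR = NA)
    sig <- makeBlockSignal(cfg)
    expect_equal(sig$matrix != 0, diag(4) == 1)
    expect_true(all(tcrossprod(sig$matrix)[upper.tri(diag(4))] == 0))

    # standard design: 100 x 300 with 4 disjoint 75-bin supports
    sig2 <- makeBlockSignal(SyntheticConfig())
    expect_equal(dim(sig2$matrix), c(100L, 300L))
    supports <- lapply(unique(sig2$labels), function(g)
        which(colSums(sig2$matrix[sig2$labels == g, , drop = FALSE]) != 0))
    expect_true(all(lengths(supports) == 75L))
    expect_equal(length(Reduce(union, supports)), 300L)
    # Gram matrix of group-mean rows is diagonal
    means <- t(vapply(unique(sig2$labels), function(g)
        colMeans(sig2$matrix[sig2$labels == g, , drop = FALSE]),
        numeric(300L)))
    G <- tcrossprod(means)
    expect_true(all(G[upper.tri(G)] == 0))
})

test_that("computeSNR is the linear sd ratio", {
    M <- matrix(rnorm(100), 10, 10)
    expect_equal(computeSNR(M, M), 1)
    expect_equal(computeSNR(M, 2 * M), 0.5)
    expect_equal(computeSNR(matrix(1, 5, 5), M[1:5, 1:5]), 0)
    expect_equal(computeSNR(M, matrix(0, 10, 10)), Inf)
})

test_that("Gaussian noise hits the target SNR and is seed-stable", {
    sig <- makeBlockSignal(SyntheticConfig())
    out0 <- addGaussianNoise(sig$matrix, noiseSD = 0)
    expect_identical(out0$matrix, sig$matrix)
    expect_identical(out0$achievedSNR, Inf)

    out <- addGaussianNoise(sig$matrix, targetSNR = 3.57, seed = 31L)
    expect_lt(abs(out$achievedSNR - 3.57) / 3.57, 0.05)
    out2 <- addGaussianNoise(sig$matrix, targetSNR = 3.57, seed = 31L)
    expect_identical(out$matrix, out2$matrix)
    expect_error(addGaussianNoise(sig$matrix, targetSNR = -1), "positive")
    expect_error(addGaussianNoise(sig$matrix), "exactly one")
})

test_that("achieved SNR is calibrated within 2% on average over seeds", {
    sig <- makeBlockSignal(SyntheticConfig())
    snrs <- vapply(1:20, function(s)
        addGaussianNoise(sig$matrix, targetSNR = 3.57, seed = s)$achievedSNR,
        numeric(1))
    expect_lt(abs(mean(snrs) - 3.57) / 3.57, 0.02)
})

test_that("irrelevant features insert, mask and round-trip correctly", {
    M <- matrix(rnorm(30), 3, 10)
    out0 <- insertIrrelevantFeatures(M, 0L)
    expect_identical(out0$matrix, M)
    expect_identical(out0$mask, logical(10))

    sig <- makeBlockSignal(SyntheticConfig())
    out <- insertIrrelevantFeatures(sig$matrix, 1000L, seed = 8L)
    expect_equal(dim(out$matrix), c(100L, 1300L))
    expect_equal(sum(out$mask), 1000L)
    expect_identical(out$matrix[, !out$mask], sig$matrix)
})

test_that("shuffling records the exact inverse ordering", {
    M <- matrix(rnorm(40), 8, 5)
    labs <- letters[1:8]
    out <- shuffleSamples(M, labs, seed = 3L)
    expect_identical(applyOrdering(out$trueOrder, out$matrix), M)
    expect_identical(out$labels[orderIndices(out$trueOrder)], labs)
    out2 <- shuffleSamples(M, labs, seed = 3L)
    expect_identical(out$matrix, out2$matrix)
    one <- shuffleSamples(M[1, , drop = FALSE], "a")
    expect_equal(orderIndices(one$trueOrder), 1L)
})

test_that("the full pipeline is byte-identical for a fixed seed", {
    cfg <- SyntheticConfig(nIrrelevant = 50L, seed = 77L)
    s1 <- simulateReadDepth(cfg)
    s2 <- simulateReadDepth(cfg)
    expect_identical(rdValues(s1), rdValues(s2))
    expect_identical(groupLabels(s1), groupLabels(s2))
    expect_identical(orderIndices(trueOrder(s1)), orderIndices(trueOrder(s2)))
    expect_identical(irrelevantMask(s1), irrelevantMask(s2))
    expect_identical(achievedSNR(s1), achievedSNR(s2))
    expect_equal(sum(irrelevantMask(s1)), 50L)
    expect_lt(abs(achievedSNR(s1) - 3.57) / 3.57, 0.05)
})
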