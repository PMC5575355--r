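test_that("quicksort ordering sorts by row sum with stable ties", {
    B <- rbind(c(2, 1), c(1, 0), c(1.5, 0.5))   # sums 3, 1, 2
    expect_equal(orderIndices(quicksortOrdering(B)), c(2L, 3L, 1L))
    expect_equal(orderIndices(quicksortOrdering(B, "descending")),
                 rev(c(2L, 3L, 1L)))
    Btie <- rbind(c(1, 1), c(2, 0), c(0, 2), c(0, 1))  # sums 2, 2, 2, 1
    expect_equal(orderIndices(quicksortOrdering(Btie)),
                 c(4L, 1L, 2L, 3L))
})

test_that("hierarchical ordering separates distant duplicate pairs", {
    B <- rbind(c(0, 0), c(0.1, 0), c(50, 50), c(50.1, 50))
    out <- hierarchicalOrdering(B, nClusters = 2L)
    arr <- orderIndices(out$ordering)
    expect_equal(countLabelBlocks(out$ordering, out$labels), 2L)
    expect_equal(out$labels[1], out$labels[2])
    expect_equal(out$labels[3], out$labels[4])
    expect_false(out$labels[1] == out$labels[3])

    expect_equal(length(unique(hierarchicalOrdering(B, 4L)$labels)), 4L)
    expect_equal(length(unique(hierarchicalOrdering(B, 1L)$labels)), 1L)
    expect_error(hierarchicalOrdering(B, 5L), "nClusters")
})

test_that("countLabelBlocks counts maximal runs and ignores label names", {
    expect_equal(countLabelBlocks(1:4, c("A", "A", "B", "B")), 2L)
    expect_equal(countLabelBlocks(1:4, c("A", "B", "A", "B")), 4L)
    g <- rep(c("x", "y", "z"), times = c(3, 4, 2))
    expect_equal(countLabelBlocks(seq_along(g), g), 3L)
    relabelled <- as.integer(factor(g, levels = c("z", "x", "y")))
    expect_equal(countLabelBlocks(seq_along(g), relabelled), 3L)
    expect_error(countLabelBlocks(1:3, c("A", "B")), "labels")
})

test_that("compareClusterings scores agreement under optimal matching", {
    truth <- rep(c("a", "b"), each = 10L)
    same <- compareClusterings(truth, truth)
    expect_equal(same$adjustedRand, 1)
    expect_equal(same$nMisclassified, 0L)

    moved <- truth
    moved[1L] <- "b"
    out <- compareClusterings(moved, truth)
    expect_equal(out$nMisclassified, 1L)

    # invariance to permuting predicted label symbols
    flipped <- ifelse(moved == "a", "q", "p")
    expect_equal(compareClusterings(flipped, truth)$nMisclassified, 1L)
})

test_that("random labelings score near-zero adjusted Rand", {
    truth <- rep(c(1L, 2L), each = 25L)
    aris <- vapply(1:50, function(s) {
        set.seed(600 + s)
        compareClusterings(sample(truth), truth)$adjustedRand
    }, numeric(1))
    expect_lt(median(abs(aris)), 0.2)
})

test_that("evaluateOrdering summarises contiguous-run recovery", {
    labs <- rep(c("A", "B"), each = 4L)
    rep1 <- evaluateOrdering(1:8, labs, "identity")
    expect_equal(rep1@nLabelBlocks, 2L)
    expect_equal(rep1@adjustedRand, 1)
    expect_equal(rep1@nMisclassified, 0L)
    shuffled <- c(1L, 5L, 2L, 6L, 3L, 7L, 4L, 8L)
    rep2 <- evaluateOrdering(shuffled, labs, "interleaved")
    expect_equal(rep2@nLabelBlocks, 8L)
    expect_lt(rep2@adjustedRand, 0.2)
})
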