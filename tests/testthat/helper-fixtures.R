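# Shared fixtures: everything is generated in code at test time.

# all permutations of 1..n (n small), as a list of integer vectors
allPermutations <- function(n) {
    if (n == 1L) return(list(1L))
    do.call(c, lapply(seq_len(n), function(i) {
        lapply(allPermutations(n - 1L), function(p) {
            rest <- setdiff(seq_len(n), i)
            c(i, rest[p])
        })
    }))
}

# noiseless two-group instance with duplicated rows in shuffled order
twoGroupShuffled <- function(seed = 11L) {
    set.seed(seed)
    rowA <- c(2, 2, 0, 0)
    rowB <- c(0, 0, 3, 3)
    M <- rbind(rowA, rowB, rowA, rowB, rowA, rowB, rowA, rowB)
    rownames(M) <- NULL
    labels <- rep(c("A", "B"), 4L)
    perm <- sample.int(8L)
    list(matrix = M[perm, ], labels = labels[perm])
}

# standard benchmark dataset at a given SNR
standardSim <- function(seed, snr = 3.57, nIrrelevant = 0L) {
    simulateReadDepth(SyntheticConfig(targetSNR = snr,
                                      nIrrelevant = as.integer(nIrrelevant),
                                      seed = as.integer(seed)))
}
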