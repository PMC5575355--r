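# TCPermute

Seriation of noisy single-cell copy-number profiles by **total-variation
constrained permutation (TCP)**: given a read-depth matrix *B* (cells ×
genomic bins, normalised so two copies map to 0), the package jointly
estimates a row permutation *P* and a denoised matrix *X* by minimising

```
|| P X − B ||²_F  +  α · || X ||_{TV,ℓ1},      || X ||_{TV,ℓ1} = Σ_j Σ_i |x_{i,j} − x_{i−1,j}|
```

so that similar cells are stacked into contiguous blocks and shared
copy-number patterns become visible directly in the matrix. The energy is
minimised by an ADMM-style alternation: an FFT-diagonalised exact X-step, a
soft-thresholding Y-step, a Kuhn–Munkres linear-assignment P-step with a
segment-relocation refinement, and a dual ascent — see the methods
vignette (`vignettes/tcp-methods.Rmd`) for the algorithm and the design
choices.

It is aimed at anyone exploring sub-population structure in single-cell
DNA-sequencing read depth (tumour heterogeneity, ploidy groups) who wants
an ordering of cells rather than only a clustering: the recovered matrix
keeps every cell's profile, denoised and arranged.

The package also ships:

* a **synthetic benchmark generator** (`simulateReadDepth()`): 100 cells in
  four orthogonal block groups over 300 bins, Gaussian noise at a target
  SNR (the studied levels are 3.57 / 2.82 / 1.55), optional standard-normal
  irrelevant bins, shuffled rows with ground truth;
* a **Laplacian-Score feature pre-filter** (`laplacianScore()`,
  `selectFeatures()`) to remove irrelevant read-depth signals before TCP;
* **baseline orderings** (`quicksortOrdering()`, `hierarchicalOrdering()`)
  and **evaluation metrics** (`countLabelBlocks()`, `compareClusterings()`,
  `evaluateOrdering()`);
* TSV/CSV readers and writers and a command-line interface
  (`tcpCLI()`; thin wrapper in `inst/scripts/tcp.R`).

## A worked example

```r
library(TCPermute)

sim <- simulateReadDepth(SyntheticConfig(seed = 1L))  # 100 x 300, SNR 3.57
sim
#> SyntheticDataset: 100 samples x 300 bins | 4 groups | 0 irrelevant bins
#>   achieved SNR: 3.557

fit <- solveTCP(sim@matrix, TCPConfig())
fit
#> TCPResult: converged after 64 iterations
#>   final objective: 50851.5
#>   final relative primal residual: 0.7364

evaluateOrdering(sampleArrangement(fit), groupLabels(sim))
#> EvaluationReport [TCP]
#>   label blocks: 4 | ARI: 1 | misclassified: 0
```

`label blocks: 4` means the 100 shuffled cells were rearranged into exactly
four contiguous ground-truth blocks (the ideal for this design), and the
adjusted Rand index of 1 means the contiguous runs coincide perfectly with
the true groups. The same workflow from a shell:

```sh
Rscript inst/scripts/tcp.R simulate --out-dir sim --seed 1
Rscript inst/scripts/tcp.R run --input sim/matrix.tsv --out-dir fit
Rscript inst/scripts/tcp.R evaluate --ordering fit/ordering.tsv --labels sim/labels.tsv
```

With thousands of irrelevant bins, filter first:

```r
sim <- simulateReadDepth(SyntheticConfig(nIrrelevant = 1000L, seed = 1L))
sc  <- laplacianScore(sim@matrix, kNeighbors = 5)
sel <- selectFeatures(sim@matrix, sc, keepFraction = 300 / 1300)
fit <- solveTCP(sel$matrix, TCPConfig())
```

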