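Package: tilegam
Title: Genome-Wide Negative Binomial P-Spline Models on Overlapping Tiles
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits smooth occupancy and log-fold-change tracks to base-pair
    resolution ChIP-seq coverage using penalized cubic B-spline negative
    binomial generalized additive models under factorial designs. Models are
    fitted independently on overlapping genomic tiles with a sparse
    Newton-Raphson solver, pointwise standard errors are obtained with a
    sparse Cholesky factorization and the Takahashi sparse inverse subset
    recursion, smoothing and dispersion hyperparameters are selected by
    blocked k-fold cross-validation on representative tiles, and per-tile
    fits are assembled genome-wide by joining at overlap midpoints with
    optional chunked HDF5-backed storage. Includes a synthetic-data
    generator producing known smooths, size factors and negative binomial
    counts at base resolution, with fragment-level BAM output.
License: GPL-2
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    splines,
    Matrix,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    parallel,
    Rsamtools,
    GenomicAlignments
Suggests:
    testthat (>= 3.0.0),
    rhdf5,
    rtracklayer,
    DESeq2,
    optparse,
    jsonlite
biocViews: ChIPSeq, Coverage, Regression, DifferentialPeakCalling
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
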