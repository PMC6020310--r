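#' Read and validate a sample table
#'
#' The sample table is a tab-separated file with a header containing
#' `sample_id`, `bam` (path, may be empty when counts are supplied
#' directly), and one 0/1 indicator column per smooth stating which smooth
#' functions contribute to each sample's mean (the rows of the experimental
#' design matrix `Z`).
#'
#' @param path path to the TSV file.
#' @return A `data.frame` with validated columns; the design indicator
#'   columns can be extracted with [designMatrix()].
#' @export
readSampleTable <- function(path) {
    tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                             check.names = FALSE)
    validateSampleTable(tab)
    tab
}

validateSampleTable <- function(tab) {
    if (!all(c("sample_id", "bam") %in% names(tab)))
        stop("sample table needs 'sample_id' and 'bam' columns")
    Z <- designMatrix(tab)
    invisible(tab)
}

#' Extract the experimental design matrix Z from a sample table
#'
#' @param tab data.frame as returned by [readSampleTable()].
#' @return Binary matrix, samples x smooths, with sample ids as row names.
#' @export
designMatrix <- function(tab) {
    cols <- setdiff(names(tab), c("sample_id", "bam"))
    if (length(cols) == 0L) stop("invalid design: no smooth columns")
    Z <- as.matrix(tab[, cols, drop = FALSE])
    storage.mode(Z) <- "double"
    rownames(Z) <- tab$sample_id
    checkDesign(Z)
    Z
}

checkDesign <- function(Z) {
    if (nrow(Z) == 0L) stop("invalid design: need at least one sample")
    if (ncol(Z) == 0L) stop("invalid design: need at least one smooth")
    if (!all(Z %in% c(0, 1)))
        stop("invalid design: indicator entries must be 0 or 1")
    if (any(colSums(Z) == 0))
        stop("invalid design: every smooth needs at least one sample")
    invisible(Z)
}

#' Build the full tile design matrix X = Z %x% Xk
#'
#' Rows are sample-major: all positions of sample 1 first, then sample 2,
#' and so on; columns are smooth-major (all coefficients of smooth 1, then
#' smooth 2, ...). Entry `((j,i),(k,r))` equals `Z[j,k] * Xk[i,r]`.
#'
#' @param Z binary design matrix, samples x smooths.
#' @param Xk sparse per-smooth basis matrix from [basisMatrix()].
#' @return Sparse `dgCMatrix` of dimension
#'   `(nrow(Z)*nrow(Xk)) x (ncol(Z)*ncol(Xk))`.
#' @export
buildDesign <- function(Z, Xk) {
    checkDesign(Z)
    X <- Matrix::kronecker(methods::as(Z, "CsparseMatrix"), Xk)
    methods::as(methods::as(X, "CsparseMatrix"), "generalMatrix")
}

#' Median-of-ratios size factors
#'
#' Estimates per-sample sequencing-depth size factors from a matrix of
#' binned fragment counts: each sample's factor is the median across bins
#' of its count divided by the per-bin geometric mean over samples. Factors
#' are then centered to have geometric mean one, so that the log offsets
#' are mean zero across samples.
#'
#' @param binned numeric matrix, bins x samples.
#' @return Numeric vector of size factors, one per sample.
#' @export
computeSizeFactors <- function(binned) {
    binned <- as.matrix(binned)
    keep <- rowSums(binned > 0) == ncol(binned)
    if (!any(keep))
        stop("normalization undefined: no bin has positive counts in all samples")
    lc <- log(binned[keep, , drop = FALSE])
    logRatios <- lc - rowMeans(lc)
    sf <- exp(apply(logRatios, 2L, stats::median))
    sf <- sf / exp(mean(log(sf)))
    names(sf) <- colnames(binned)
    sf
}

#' Bin a per-base count matrix for size-factor estimation
#'
#' @param counts per-base counts, positions x samples.
#' @param binSize bin width in bp (default 1000).
#' @return Matrix of binned counts, bins x samples.
#' @export
binCounts <- function(counts, binSize = 1000) {
    counts <- as.matrix(counts)
    bin <- (seq_len(nrow(counts)) - 1L) %/% binSize
    rowsum(counts, group = bin, reorder = TRUE)
}

#' Expand per-sample size factors into per-data-point offsets
#'
#' Offsets are natural-log size factors, laid out sample-major to match the
#' row order of [buildDesign()].
#'
#' @param sizeFactors per-sample size factors.
#' @param nPositions number of modelled positions per sample.
#' @return Numeric offset vector of length
#'   `length(sizeFactors) * nPositions`.
#' @export
offsetsFromSizeFactors <- function(sizeFactors, nPositions) {
    if (any(!is.finite(log(sizeFactors))))
        stop("size factors must be positive and finite")
    rep(log(sizeFactors), each = nPositions)
}
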