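#' @import methods
#' @importClassesFrom Matrix dgCMatrix dsCMatrix dtCMatrix
NULL

#' Cubic B-spline basis over a genomic interval
#'
#' Holds the knot vector of a uniform cubic B-spline basis spanning a
#' half-open genomic interval `[start, end)` (0-based coordinates). Inner
#' knots are placed every `spacing` bp starting at `start`; the last inner
#' knot is the first multiple of `spacing` at or beyond `end`. Three
#' uniformly spaced extension knots are added beyond each boundary so that
#' all basis functions retain the uniform B-spline shape; consequently the
#' basis dimension is `length(knots) - 4`.
#'
#' @slot start,end interval boundaries in bp (0-based, half-open).
#' @slot spacing distance in bp between adjacent inner knots.
#' @slot knots full knot vector including the 3 extension knots per side.
#' @export
setClass("SplineBasis",
    representation(start = "numeric", end = "numeric",
                   spacing = "numeric", knots = "numeric"))

setValidity("SplineBasis", function(object) {
    if (length(object@spacing) != 1L || !is.finite(object@spacing) ||
        object@spacing <= 0)
        return("'spacing' must be a single positive number")
    if (object@end - object@start < object@spacing)
        return("interval must span at least one knot spacing")
    if (is.unsorted(object@knots, strictly = TRUE))
        return("knots must be strictly increasing")
    if (length(object@knots) < 8L)
        return("need at least 8 knots for a cubic basis")
    TRUE
})

#' Overlapping tile layout for one chromosome
#'
#' Tiles are overlapping intervals advancing by `tileSize - overlap`; the
#' last tile is right-anchored at the chromosome end. Each tile owns a
#' disjoint *chunk*, delimited by the midpoints of the overlaps with its
#' neighbours (terminal chunks are extended to the chromosome boundaries),
#' so that the chunks partition `[0, chromLength)` exactly.
#'
#' @slot chromLength chromosome length in bp.
#' @slot tileSize,overlap tiling parameters in bp.
#' @slot tileStart,tileEnd,chunkStart,chunkEnd 0-based half-open interval
#'   bounds, one entry per tile.
#' @export
setClass("TileLayout",
    representation(chromLength = "numeric", tileSize = "numeric",
                   overlap = "numeric", tileStart = "numeric",
                   tileEnd = "numeric", chunkStart = "numeric",
                   chunkEnd = "numeric"))

setValidity("TileLayout", function(object) {
    n <- length(object@tileStart)
    if (n == 0L) return("layout must contain at least one tile")
    if (length(object@tileEnd) != n || length(object@chunkStart) != n ||
        length(object@chunkEnd) != n)
        return("tile and chunk vectors must have equal length")
    if (sum(object@chunkEnd - object@chunkStart) != object@chromLength)
        return("chunks must partition the chromosome")
    TRUE
})

#' Per-tile penalized negative binomial spline model
#'
#' Bundles everything needed to evaluate the penalized NB log-likelihood on
#' one tile: the sample-major response vector `y` (all positions of sample
#' 1, then sample 2, ...), matching log size-factor offsets, the full
#' sparse design `X = Z %x% Xk`, the block-diagonal second-order difference
#' penalty (one block per smooth), and the hyperparameters.
#'
#' @slot y counts, sample-major.
#' @slot offsets per-data-point offsets (natural log of size factors).
#' @slot X sparse full design matrix.
#' @slot S block-diagonal penalty matrix (without the ridge term).
#' @slot basis the [SplineBasis] shared by all smooths.
#' @slot Z experimental design indicator matrix (samples x smooths).
#' @slot positions 0-based genomic positions modelled (one copy; rows of
#'   `X` repeat them per sample).
#' @slot lambda,theta,epsilon smoothing weight, NB dispersion, ridge weight.
#' @export
setClass("TileModel",
    representation(y = "numeric", offsets = "numeric", X = "dgCMatrix",
                   S = "dsCMatrix", basis = "SplineBasis", Z = "matrix",
                   positions = "numeric", lambda = "numeric",
                   theta = "numeric", epsilon = "numeric"))

setValidity("TileModel", function(object) {
    n <- length(object@y)
    if (length(object@offsets) != n) return("offsets must match y")
    if (nrow(object@X) != n) return("nrow(X) must match length(y)")
    if (ncol(object@X) != nrow(object@S)) return("penalty dimension mismatch")
    if (any(object@y < 0)) return("counts must be non-negative")
    if (object@theta <= 0) return("'theta' must be positive")
    if (object@lambda < 0 || object@epsilon < 0)
        return("'lambda' and 'epsilon' must be non-negative")
    if (nrow(object@X) != nrow(object@Z) * length(object@positions))
        return("row count must equal n_samples * n_positions")
    TRUE
})

#' Result of a Newton-Raphson fit on one tile
#'
#' @slot beta estimated spline coefficients (concatenated per smooth).
#' @slot mu fitted means, sample-major like the model response.
#' @slot loglik penalized objective at `beta`.
#' @slot gradNorm max-norm of the penalized gradient at `beta`.
#' @slot iterations Newton iterations performed.
#' @slot converged whether a convergence criterion was met.
#' @slot model the [TileModel] that was fitted.
#' @export
setClass("TileFit",
    representation(beta = "numeric", mu = "numeric", loglik = "numeric",
                   gradNorm = "numeric", iterations = "integer",
                   converged = "logical", model = "TileModel"))

#' Sparse Cholesky factorization with fill-reducing permutation
#'
#' Represents `P A P' = L L'` for a symmetric positive definite `A`, where
#' `P` is the fill-reducing permutation (stored as the 1-based index vector
#' `perm`, i.e. `(P x)[i] = x[perm[i]]`) and `L` is lower triangular with
#' positive diagonal.
#'
#' @slot L lower-triangular sparse factor.
#' @slot perm 1-based permutation vector.
#' @export
setClass("SparseCholesky",
    representation(L = "dtCMatrix", perm = "integer"))

#' Entries of a matrix inverse on a sparse pattern
#'
#' Values of `H^-1` (for the negative definite penalized Hessian `H`) on
#' the sparsity pattern of the Cholesky factor of `-H`, a superset of the
#' nonzero pattern of `H` itself. Produced by the Takahashi sparse inverse
#' subset recursion; entries of the true inverse outside the pattern are
#' provably not needed for pointwise smooth variances.
#'
#' @slot values sparse symmetric matrix holding the inverse entries on the
#'   pattern (structural zeros elsewhere).
#' @slot ops number of multiply operations spent in the recursion (used to
#'   verify the linear scaling of the algorithm).
#' @export
setClass("InverseSubset",
    representation(values = "dgCMatrix", ops = "numeric"))

#' Assembled genome-wide fit
#'
#' Per-base fitted log-rate and standard error for each smooth, assembled
#' from independent tile fits by overlap-midpoint ownership, together with
#' per-tile convergence diagnostics and provenance.
#'
#' @slot chrom chromosome name.
#' @slot chromLength chromosome length in bp.
#' @slot smoothNames names of the fitted smooth functions.
#' @slot backend `"memory"` or `"hdf5"`.
#' @slot fit,se per-base matrices (length x smooths) when the memory
#'   backend is active, otherwise 0x0 placeholders.
#' @slot h5file path of the backing HDF5 file (hdf5 backend).
#' @slot layout the [TileLayout] used.
#' @slot hyper list with elements `lambda`, `theta`, `epsilon`.
#' @slot diagnostics one row per tile: convergence flag, iterations,
#'   objective, gradient norm.
#' @slot provenance list describing inputs and package version.
#' @export
setClass("GenomeFit",
    representation(chrom = "character", chromLength = "numeric",
                   smoothNames = "character", backend = "character",
                   fit = "matrix", se = "matrix", h5file = "character",
                   layout = "TileLayout", hyper = "list",
                   diagnostics = "data.frame", provenance = "list"))

#' Configuration of a synthetic ChIP-seq-like dataset
#'
#' Truth smooths are sums of Gaussian bumps on a log scale (deliberately
#' outside the spline family), combined through a design matrix `Z` and
#' per-sample size factors into NB means at base resolution.
#'
#' @slot length genome (chromosome) length in bp.
#' @slot smooths list, one element per smooth, each a list with numeric
#'   fields `centers`, `widths`, `heights` (log-scale bump parameters) and
#'   scalar `baseline` (log-scale constant).
#' @slot Z design indicator matrix, samples x smooths.
#' @slot theta true NB dispersion (variance `mu + mu^2/theta`).
#' @slot sizeFactors true per-sample size factors.
#' @slot seed RNG seed (mandatory; all draws are reproducible from it).
#' @export
setClass("SimConfig",
    representation(length = "numeric", smooths = "list", Z = "matrix",
                   theta = "numeric", sizeFactors = "numeric",
                   seed = "integer"))

setValidity("SimConfig", function(object) {
    if (object@theta <= 0) return("'theta' must be positive")
    if (length(object@seed) != 1L || is.na(object@seed))
        return("'seed' is mandatory")
    if (ncol(object@Z) != length(object@smooths))
        return("ncol(Z) must equal the number of smooths")
    if (nrow(object@Z) != length(object@sizeFactors))
        return("nrow(Z) must equal the number of size factors")
    if (any(object@sizeFactors <= 0)) return("size factors must be positive")
    TRUE
})

#' Simulated dataset with known truth
#'
#' @slot truth per-base true smooth values (length x smooths, log scale).
#' @slot mu per-base NB means (length x samples).
#' @slot counts per-base simulated counts (length x samples).
#' @slot config the generating [SimConfig].
#' @export
setClass("SimulatedData",
    representation(truth = "matrix", mu = "matrix", counts = "matrix",
                   config = "SimConfig"))
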