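#' Construct a uniform cubic B-spline basis for a genomic interval
#'
#' Places inner knots every `spacing` bp from `start` up to the first knot
#' at or beyond `end`, then extends the knot vector by three uniformly
#' spaced knots on each side. With cubic (order 4) splines the resulting
#' basis has `length(knots) - 4` functions; each genomic position inside
#' the interval is covered by at most 4 basis functions (5 including
#' closed-support boundaries at knots).
#'
#' @param start,end interval in bp, 0-based half-open.
#' @param spacing inner knot spacing in bp (default 20).
#' @return A [SplineBasis-class] object.
#' @examples
#' b <- splineBasis(0, 100, 20)
#' basisDim(b)  # 8
#' @export
splineBasis <- function(start, end, spacing = 20) {
    if (!is.finite(spacing) || spacing <= 0)
        stop("invalid argument: 'spacing' must be positive")
    if (!is.finite(end - start) || end - start < spacing)
        stop("invalid argument: interval must span at least one knot spacing")
    nInner <- ceiling((end - start) / spacing) + 1L
    inner <- start + (seq_len(nInner) - 1) * spacing
    knots <- c(start - (3:1) * spacing, inner,
               inner[nInner] + (1:3) * spacing)
    new("SplineBasis", start = start, end = end, spacing = spacing,
        knots = knots)
}

#' Number of basis functions
#' @param x a [SplineBasis-class] object.
#' @return Integer basis dimension.
#' @export
basisDim <- function(x) length(x@knots) - 4L

#' Inner knot range covered by the basis
#'
#' Positions inside this closed range can be evaluated; the range always
#' contains `[start, end)`.
#' @param x a [SplineBasis-class] object.
#' @return Numeric length-2 vector.
#' @export
innerRange <- function(x) c(x@knots[4L], x@knots[length(x@knots) - 3L])

setMethod("show", "SplineBasis", function(object) {
    cat("SplineBasis over [", object@start, ", ", object@end, ") bp\n",
        "  knot spacing: ", object@spacing, " bp\n",
        "  basis dimension: ", basisDim(object), "\n", sep = "")
})

#' Evaluate the B-spline basis at genomic positions
#'
#' Returns the sparse design matrix `Xk` with entry `(i, r)` equal to the
#' r-th cubic B-spline evaluated at `positions[i]`. Rows form a partition
#' of unity over the inner knot range; entries below `1e-14` are stored as
#' structural zeros so the declared sparsity pattern is exact.
#'
#' @param basis a [SplineBasis-class] object.
#' @param positions ordered vector of positions in bp (0-based).
#' @return A sparse `dgCMatrix` with `length(positions)` rows and
#'   `basisDim(basis)` columns.
#' @export
basisMatrix <- function(basis, positions) {
    rng <- innerRange(basis)
    if (any(positions < rng[1L] | positions > rng[2L]))
        stop("out of domain: positions must lie within the inner knot range")
    M <- splines::splineDesign(basis@knots, positions, ord = 4L,
                               sparse = TRUE)
    M <- as(as(M, "CsparseMatrix"), "generalMatrix")
    M@x[abs(M@x) < 1e-14] <- 0
    Matrix::drop0(M)
}

#' Second-order difference penalty matrix
#'
#' Builds `S = D'D` where `D` is the `(p-2) x p` second-difference
#' operator, the P-spline penalty approximating the integrated squared
#' second derivative of the smooth. `S` is symmetric positive
#' semi-definite with null space spanned by constant and linear coefficient
#' vectors, and has at most 5 nonzeros per row.
#'
#' @param p basis dimension (`>= 3`).
#' @return Sparse symmetric `dsCMatrix`.
#' @examples
#' penaltyMatrix(5)[3, ]  # 1 -4 6 -4 1
#' @export
penaltyMatrix <- function(p) {
    if (p < 3) stop("invalid argument: 'p' must be at least 3")
    D <- Matrix::sparseMatrix(
        i = rep(seq_len(p - 2L), 3L),
        j = c(seq_len(p - 2L), seq_len(p - 2L) + 1L, seq_len(p - 2L) + 2L),
        x = rep(c(1, -2, 1), each = p - 2L),
        dims = c(p - 2L, p))
    Matrix::forceSymmetric(Matrix::crossprod(D))
}
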