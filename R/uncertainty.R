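#' Sparse Cholesky factorization with fill-reducing permutation
#'
#' Factorizes a symmetric positive definite sparse matrix as
#' `P A P' = L L'` using CHOLMOD with an approximate-minimum-degree
#' permutation. The permutation is returned as the 1-based index vector
#' `perm`, so that `(P x)[i] = x[perm[i]]`.
#'
#' @param A sparse symmetric positive definite matrix.
#' @return A [SparseCholesky-class] object.
#' @export
sparseCholesky <- function(A) {
    A <- Matrix::forceSymmetric(methods::as(A, "CsparseMatrix"))
    ## simplicial factor: its stored pattern is the exact symbolic fill,
    ## which the inverse-subset recursion relies on
    ch <- tryCatch(
        Matrix::Cholesky(A, LDL = FALSE, perm = TRUE, super = FALSE),
        error = function(e) stop("factorization failure: matrix is not ",
                                 "positive definite (",
                                 conditionMessage(e), ")"))
    L <- methods::as(Matrix::expand1(ch, "L"), "CsparseMatrix")
    new("SparseCholesky", L = methods::as(L, "triangularMatrix"),
        perm = as.integer(ch@perm) + 1L)
}

setMethod("show", "SparseCholesky", function(object) {
    cat("SparseCholesky of a", nrow(object@L), "x", nrow(object@L),
        "matrix;", length(object@L@x), "nonzeros in L\n")
})

#' Takahashi sparse inverse subset
#'
#' Given `P A P' = L L'` for symmetric positive definite `A`, computes the
#' entries of `A^-1` on the sparsity pattern of `L + L'` (which contains
#' the nonzero pattern of `A`) by the Takahashi recursion, proceeding from
#' the last column backwards over the fill pattern. No dense inverse is
#' ever formed; the cost is linear in the matrix dimension for the banded
#' matrices arising from local-support spline bases.
#'
#' The recursion uses the root-free form `A = L1 D L1'` (with `L1` unit
#' lower triangular and `D = diag(L)^2`):
#' `Z[i,j] = (i == j)/d_i - sum_{k > i} L1[k,i] Z[k,j]`,
#' evaluated for the upper-triangular pattern entries `(i, j)` (`i <= j`,
#' `L[j,i] != 0`) of each column `j`, from the last column backwards and
#' within a column in decreasing row order. Every `Z[k,j]` the sum touches
#' then lies on the filled pattern: `j` and `k` are both off-diagonal
#' entries of column `i` of `L`, so the symbolic factorization places fill
#' at `(max(j,k), min(j,k))`.
#'
#' @param chol a [SparseCholesky-class] object.
#' @return An [InverseSubset-class] holding the entries of `A^-1` on the
#'   (permutation-unscrambled) pattern, plus the multiply-operation count.
#' @export
takahashiInverse <- function(chol) {
    L <- chol@L
    n <- nrow(L)
    Lp <- L@p; Li <- L@i; Lx <- L@x
    dL <- numeric(n)
    ## per-column pattern (1-based rows, diagonal first) and unit-L values
    colRows <- vector("list", n)
    colVals <- vector("list", n)
    for (j in seq_len(n)) {
        idx <- (Lp[j] + 1L):Lp[j + 1L]
        r <- Li[idx] + 1L
        v <- Lx[idx]
        stopifnot(r[1L] == j)
        dL[j] <- v[1L]
        colRows[[j]] <- r
        colVals[[j]] <- v / v[1L]   # unit lower-triangular column
    }
    d <- dL^2
    ## row patterns of L = upper-triangular pattern per column of Z
    Lt <- methods::as(Matrix::t(L), "CsparseMatrix")
    Tp <- Lt@p; Ti <- Lt@i
    rowPat <- vector("list", n)
    for (j in seq_len(n))
        rowPat[[j]] <- Ti[(Tp[j] + 1L):Tp[j + 1L]] + 1L  # ascending, last = j
    zvals <- vector("list", n)
    ops <- 0
    for (j in rev(seq_len(n))) {
        rp <- rowPat[[j]]
        m <- length(rp)
        z <- numeric(m)
        for (idx in rev(seq_len(m))) {
            i <- rp[idx]
            ri <- colRows[[i]]
            s <- 0
            if (length(ri) > 1L) {
                ki <- ri[-1L]                 # k > i on column i's pattern
                li <- colVals[[i]][-1L]
                le <- ki <= j
                if (any(le)) {
                    pos <- match(ki[le], rp)
                    if (anyNA(pos))
                        stop("internal consistency error: Cholesky fill ",
                             "pattern is not closed")
                    s <- s + sum(li[le] * z[pos])
                }
                if (any(!le)) {               # Z[k,j] = Z[j,k], column k
                    kk <- ki[!le]
                    zv <- vapply(kk, function(k) {
                        pkk <- match(j, rowPat[[k]])
                        if (is.na(pkk))
                            stop("internal consistency error: Cholesky ",
                                 "fill pattern is not closed")
                        zvals[[k]][pkk]
                    }, numeric(1L))
                    s <- s + sum(li[!le] * zv)
                }
                ops <- ops + length(ki)
            }
            z[idx] <- (if (i == j) 1 / d[i] else 0) - s
        }
        zvals[[j]] <- z
    }
    ## scatter back to original (unpermuted) indices, symmetrically
    nnzL <- length(Li)
    ii <- integer(2L * nnzL); jj <- integer(2L * nnzL)
    xx <- numeric(2L * nnzL)
    pos <- 0L
    perm <- chol@perm
    for (j in seq_len(n)) {
        r <- rowPat[[j]]
        z <- zvals[[j]]
        m <- length(r)
        oI <- perm[r]; oJ <- perm[rep.int(j, m)]
        ii[pos + seq_len(m)] <- oI
        jj[pos + seq_len(m)] <- oJ
        xx[pos + seq_len(m)] <- z
        pos <- pos + m
        if (m > 1L) {                         # mirror off-diagonals
            k <- m - 1L
            ii[pos + seq_len(k)] <- oJ[-m]
            jj[pos + seq_len(k)] <- oI[-m]
            xx[pos + seq_len(k)] <- z[-m]
            pos <- pos + k
        }
    }
    V <- Matrix::sparseMatrix(i = ii[seq_len(pos)], j = jj[seq_len(pos)],
                              x = xx[seq_len(pos)], dims = c(n, n))
    new("InverseSubset", values = methods::as(V, "generalMatrix"),
        ops = ops)
}

setMethod("show", "InverseSubset", function(object) {
    cat("InverseSubset:", nrow(object@values), "x", ncol(object@values),
        "with", length(object@values@x), "pattern entries\n")
})

#' Inverse subset of a negative definite Hessian
#'
#' Convenience wrapper: factorizes `A = -H` (positive definite for
#' `lambda, epsilon > 0`), runs the Takahashi recursion, and negates so the
#' returned values are entries of `H^-1` (negative on the diagonal).
#'
#' @param H sparse negative definite penalized Hessian.
#' @return An [InverseSubset-class] of `H^-1`.
#' @export
hessianInverseSubset <- function(H) {
    sub <- takahashiInverse(sparseCholesky(-H))
    sub@values <- -sub@values
    sub
}

## indices of the coefficient block of smooth k
smoothBlock <- function(pk, k) ((k - 1L) * pk + 1L):(k * pk)

#' Pointwise variances of a smooth from the inverse subset
#'
#' Computes `sigma^2_i = diag(Xk Hk^-1 Xk')` for smooth `k`, where `Hk^-1`
#' is the block of `H^-1` for that smooth's coefficients, restricted to the
#' computed pattern. The index pairs `(l, j)` with
#' `Xk[i,l] Xk[i,j] != 0` all lie in the nonzero pattern of `H` (they
#' appear in `t(X) W X`), so the restriction is exact. Only the first
#' product `Xk %*% Hk^-1` is formed; it is multiplied elementwise with
#' `Xk` and summed over columns, so no dense p x p or n x n matrix ever
#' materializes.
#'
#' @param subset an [InverseSubset-class] of `H^-1` (for instance from
#'   [hessianInverseSubset()]).
#' @param Xk sparse basis matrix rows at the positions of interest.
#' @param k smooth index (block of the coefficient vector).
#' @return Numeric vector of strictly positive variances.
#' @export
smoothVariances <- function(subset, Xk, k = 1L) {
    pk <- ncol(Xk)
    blk <- smoothBlock(pk, k)
    if (max(blk) > nrow(subset@values))
        stop("internal consistency error: smooth block outside pattern")
    Mk <- -subset@values[blk, blk, drop = FALSE]   # block of (-H)^-1
    v <- Matrix::rowSums((Xk %*% Mk) * Xk)
    if (any(v <= 0))
        stop("invalid variance: non-positive variance encountered")
    as.vector(v)
}

#' Pointwise variances by the indirect Cholesky method
#'
#' Independent route to the same variances: with `P A P' = L L'` for
#' `A = -H`, `sigma^2_i = sum_j ((X P' L^-1)[i,j])^2`, evaluated by
#' triangular solves in row batches to bound memory. Used as a
#' cross-method oracle and optional fallback; the Takahashi route is the
#' default because it scales linearly rather than quadratically.
#'
#' @param chol a [SparseCholesky-class] of `-H`.
#' @param Xk sparse basis matrix rows at the positions of interest.
#' @param k smooth index.
#' @param K total number of smooths (block count of the full coefficient
#'   vector).
#' @param batch rows per triangular solve (default 512).
#' @return Numeric vector of variances.
#' @export
indirectVariances <- function(chol, Xk, k = 1L, K = 1L, batch = 512L) {
    p <- nrow(chol@L)
    pk <- ncol(Xk)
    n <- nrow(Xk)
    blk <- smoothBlock(pk, k)
    if (max(blk) > p) stop("smooth block exceeds factor dimension")
    ## embed Xk into the full coefficient space, then permute columns
    T3 <- methods::as(Xk, "TsparseMatrix")
    Xfull <- Matrix::sparseMatrix(i = T3@i + 1L, j = blk[T3@j + 1L],
                                  x = T3@x, dims = c(n, p))
    Xp <- Xfull[, chol@perm, drop = FALSE]  # column j of X P' is X[, perm[j]]
    out <- numeric(n)
    for (s in seq(1L, n, by = batch)) {
        e <- min(s + batch - 1L, n)
        B <- Matrix::t(Xp[s:e, , drop = FALSE])
        Tm <- Matrix::solve(chol@L, B)
        out[s:e] <- Matrix::colSums(Tm^2)
    }
    out
}

#' Verify pattern sufficiency for variance computation
#'
#' Checks the structural claim underpinning [smoothVariances()]: every
#' index pair `(l, j)` with `X[i,l] X[i,j] != 0` for some row `i` lies in
#' the nonzero pattern of `H` (and hence of the computed inverse subset).
#'
#' @param X sparse design matrix.
#' @param pattern sparse matrix whose nonzero pattern is tested (e.g. `H`
#'   or `subset@values`).
#' @return `TRUE` if the pattern covers all needed pairs, else `FALSE`.
#' @export
patternCovers <- function(X, pattern) {
    P <- methods::as(methods::as(pattern, "CsparseMatrix"), "generalMatrix")
    X <- methods::as(X, "CsparseMatrix")
    Xt <- Matrix::t(X)
    for (i in seq_len(nrow(X))) {
        ci <- Xt@i[(Xt@p[i] + 1L):Xt@p[i + 1L]] + 1L
        if (Xt@p[i + 1L] == Xt@p[i]) next
        sub <- P[ci, ci, drop = FALSE]
        need <- length(ci)^2
        if (length(methods::as(sub, "TsparseMatrix")@x) < need) {
            ## structural zeros present: check explicitly
            patOK <- matrix(FALSE, length(ci), length(ci))
            Tp <- methods::as(sub, "TsparseMatrix")
            patOK[cbind(Tp@i + 1L, Tp@j + 1L)] <- TRUE
            if (!all(patOK)) return(FALSE)
        }
    }
    TRUE
}

#' Pointwise z-scores and two-sided Gaussian p-values
#'
#' @param f fitted smooth values.
#' @param sigma2 pointwise variances (must be strictly positive).
#' @return A `data.frame` with columns `z` and `p`.
#' @export
pointwisePvalues <- function(f, sigma2) {
    if (any(sigma2 <= 0)) stop("invalid variance: sigma2 must be positive")
    z <- f / sqrt(sigma2)
    data.frame(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Variances of the first derivative of a smooth
#'
#' Same covariance contraction as [smoothVariances()] but with the basis
#' rows replaced by their first derivatives, yielding pointwise variances
#' of `d f_k / dx`.
#'
#' @param subset an [InverseSubset-class] of `H^-1`.
#' @param basis the [SplineBasis-class] of the fit.
#' @param positions positions at which to evaluate.
#' @param k smooth index.
#' @return Numeric vector of derivative variances.
#' @export
derivativeVariances <- function(subset, basis, positions, k = 1L) {
    rng <- innerRange(basis)
    if (any(positions < rng[1L] | positions > rng[2L]))
        stop("out of domain: positions must lie within the inner knot range")
    Dk <- splines::splineDesign(basis@knots, positions, ord = 4L,
                                derivs = rep(1L, length(positions)),
                                sparse = TRUE)
    Dk <- methods::as(methods::as(Dk, "CsparseMatrix"), "generalMatrix")
    pk <- basisDim(basis)
    blk <- smoothBlock(pk, k)
    Mk <- -subset@values[blk, blk, drop = FALSE]
    v <- Matrix::rowSums((Dk %*% Mk) * Dk)
    as.vector(v)
}
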