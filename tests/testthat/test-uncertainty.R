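test_that("sparse Cholesky reconstructs the permuted matrix", {
    ## identity
    ch <- sparseCholesky(Matrix::Diagonal(4))
    expect_equal(as.matrix(ch@L), diag(4))

    ## hand example: with identity permutation L = ((2,0),(1,sqrt(2)))
    A <- Matrix::Matrix(c(4, 2, 2, 3), 2, 2, sparse = TRUE)
    ch <- sparseCholesky(A)
    if (identical(ch@perm, 1:2))
        expect_equal(as.matrix(ch@L),
                     rbind(c(2, 0), c(1, sqrt(2))), tolerance = 1e-12)
    R <- ch@L %*% Matrix::t(ch@L)
    expect_equal(as.matrix(R),
                 as.matrix(A)[ch@perm, ch@perm], tolerance = 1e-12)

    ## random banded SPD reconstruction
    for (seed in c(1, 2)) {
        A <- randomBandedSPD(seed, 400)
        ch <- sparseCholesky(A)
        R <- as.matrix(ch@L %*% Matrix::t(ch@L))
        expect_lt(max(abs(R - as.matrix(A)[ch@perm, ch@perm])), 1e-8)
    }

    ## non-SPD input fails loudly
    B <- Matrix::Matrix(c(1, 2, 2, 1), 2, 2, sparse = TRUE)
    suppressWarnings(expect_error(sparseCholesky(B),
                                  "factorization failure"))
})

test_that("Takahashi recursion equals the dense inverse on its pattern", {
    ## 2x2 analytic inverse
    A <- Matrix::Matrix(c(2, 1, 1, 2), 2, 2, sparse = TRUE)
    sub <- takahashiInverse(sparseCholesky(A))
    expect_equal(as.matrix(sub@values),
                 rbind(c(2/3, -1/3), c(-1/3, 2/3)), tolerance = 1e-12)

    ## identity
    subI <- takahashiInverse(sparseCholesky(Matrix::Diagonal(5)))
    expect_equal(as.matrix(subI@values), diag(5))

    ## random banded SPD: match dense inverse restricted to the pattern
    for (seed in 3:5) {
        p <- sample(100:300, 1)
        A <- randomBandedSPD(seed, p)
        sub <- takahashiInverse(sparseCholesky(A))
        dense <- solve(as.matrix(A))
        Tm <- methods::as(sub@values, "TsparseMatrix")
        expect_lt(max(abs(Tm@x - dense[cbind(Tm@i + 1L, Tm@j + 1L)])),
                  1e-8)
        ## symmetry of the subset
        expect_lt(max(abs(sub@values - Matrix::t(sub@values))), 1e-10)
    }
})

test_that("inverse subset of the Hessian has negative diagonal", {
    m <- randomTileModel(21, nPos = 100L, spacing = 20)
    fit <- newtonFit(m)
    H <- nbHessian(m, coef(fit))
    sub <- hessianInverseSubset(H)
    expect_true(all(Matrix::diag(sub@values) < 0))
})

test_that("smooth variances agree across all three computation routes", {
    for (seed in c(31, 32)) {
        K <- if (seed %% 2 == 0) 2L else 1L
        m <- randomTileModel(seed, nPos = 150L, spacing = 15, K = K)
        fit <- newtonFit(m)
        H <- nbHessian(m, coef(fit))
        sub <- hessianInverseSubset(H)
        ch <- sparseCholesky(-H)
        Xk <- basisMatrix(m@basis, m@positions)
        Hinv <- solve(as.matrix(-H))
        pk <- ncol(Xk)
        for (k in seq_len(K)) {
            blk <- ((k - 1L) * pk + 1L):(k * pk)
            dense <- diag(as.matrix(Xk) %*% Hinv[blk, blk] %*%
                          t(as.matrix(Xk)))
            v1 <- smoothVariances(sub, Xk, k)
            v2 <- indirectVariances(ch, Xk, k, K)
            expect_lt(max(abs(v1 - dense) / dense), 1e-8)
            expect_lt(max(abs(v2 - dense) / dense), 1e-8)
            expect_lt(max(abs(v1 - v2) / v1), 1e-6)
            expect_true(all(v1 > 0))
        }
    }
})

test_that("pattern covers every index pair the variance sum needs", {
    for (seed in 41:44) {
        m <- randomTileModel(seed, nPos = 80L, spacing = 10,
                             K = sample(1:2, 1))
        H <- nbHessian(m, rep(0, ncol(m@X)))
        expect_true(patternCovers(m@X, H))
        sub <- hessianInverseSubset(H)
        expect_true(patternCovers(m@X, sub@values))
        ## computed pattern contains NZ(H) (structural containment)
        Ht <- methods::as(methods::as(H, "generalMatrix"),
                          "TsparseMatrix")
        Vt <- methods::as(sub@values, "TsparseMatrix")
        p <- nrow(H)
        hKeys <- (as.numeric(Ht@i)) * p + Ht@j
        vKeys <- (as.numeric(Vt@i)) * p + Vt@j
        expect_true(all(hKeys %in% vKeys))
    }
})

test_that("variances do not depend on the fill-reducing permutation", {
    m <- randomTileModel(51, nPos = 120L, spacing = 12)
    fit <- newtonFit(m)
    H <- nbHessian(m, coef(fit))
    Xk <- basisMatrix(m@basis, m@positions)
    v1 <- smoothVariances(hessianInverseSubset(H), Xk, 1)
    ## natural-ordering factorization (no permutation)
    chNat <- Matrix::Cholesky(Matrix::forceSymmetric(-H), LDL = FALSE,
                              perm = FALSE, super = FALSE)
    L <- methods::as(Matrix::expand1(chNat, "L"), "CsparseMatrix")
    cholNat <- new("SparseCholesky",
                   L = methods::as(L, "triangularMatrix"),
                   perm = seq_len(nrow(L)))
    subNat <- takahashiInverse(cholNat)
    subNat@values <- -subNat@values
    v2 <- smoothVariances(subNat, Xk, 1)
    expect_lt(max(abs(v1 - v2) / v1), 1e-8)
})

test_that("replicating every observation shrinks the variances", {
    m <- randomTileModel(61, nPos = 100L, spacing = 20)
    fit <- newtonFit(m)
    H1 <- nbHessian(m, coef(fit))
    Xk <- basisMatrix(m@basis, m@positions)
    v1 <- smoothVariances(hessianInverseSubset(H1), Xk, 1)
    ## duplicate all data points: information doubles
    m2 <- m
    m2@y <- c(m@y, m@y)
    m2@offsets <- c(m@offsets, m@offsets)
    m2@X <- rbind(m@X, m@X)
    m2@Z <- rbind(m@Z, m@Z)
    fit2 <- newtonFit(m2)
    H2 <- nbHessian(m2, coef(fit2))
    v2 <- smoothVariances(hessianInverseSubset(H2), Xk, 1)
    expect_true(all(v2 < v1))
})

test_that("pointwise p-values follow the Gaussian z rule", {
    res <- pointwisePvalues(c(0, 1.959964, -1.959964), rep(1, 3))
    expect_equal(res$p[1], 1)
    expect_equal(res$p[2], 0.05, tolerance = 1e-6)
    expect_equal(res$p[2], res$p[3])
    expect_error(pointwisePvalues(1, 0), "invalid variance")
})

test_that("derivative variances match a dense derivative oracle", {
    m <- randomTileModel(71, nPos = 80L, spacing = 16)
    fit <- newtonFit(m)
    H <- nbHessian(m, coef(fit))
    sub <- hessianInverseSubset(H)
    pos <- m@positions[10:60]
    v <- derivativeVariances(sub, m@basis, pos, 1)
    Dk <- splines::splineDesign(m@basis@knots, pos, ord = 4,
                                derivs = rep(1L, length(pos)))
    dense <- diag(Dk %*% solve(as.matrix(-H)) %*% t(Dk))
    expect_lt(max(abs(v - dense) / dense), 1e-8)
})
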