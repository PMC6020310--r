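## Independent oracles used across the test suite. These deliberately
## avoid the package's own code paths: scalar Cox-de Boor recursion for
## basis values, dense base-R linear algebra for fitting and inversion,
## and central finite differences for derivatives.

## scalar Cox-de Boor recursion: value of the r-th B-spline of order `ord`
## (degree ord-1) on knot vector `kn` at point x
deBoorValue <- function(kn, r, ord, x) {
    if (ord == 1L)
        return(as.numeric(x >= kn[r] && x < kn[r + 1L]))
    denom1 <- kn[r + ord - 1L] - kn[r]
    denom2 <- kn[r + ord] - kn[r + 1L]
    t1 <- if (denom1 > 0) (x - kn[r]) / denom1 *
        deBoorValue(kn, r, ord - 1L, x) else 0
    t2 <- if (denom2 > 0) (kn[r + ord] - x) / denom2 *
        deBoorValue(kn, r + 1L, ord - 1L, x) else 0
    t1 + t2
}

## dense basis matrix via the scalar recursion
deBoorMatrix <- function(kn, positions) {
    p <- length(kn) - 4L
    out <- matrix(0, length(positions), p)
    for (i in seq_along(positions))
        for (r in seq_len(p))
            out[i, r] <- deBoorValue(kn, r, 4L, positions[i])
    out
}

## dense second-difference penalty oracle
densePenalty <- function(p) {
    D <- diff(diag(p), differences = 2)
    t(D) %*% D
}

## dense penalized NB objective/gradient/Hessian in base R
denseObjective <- function(y, o, X, Sp, lambda, theta, beta) {
    mu <- exp(o + as.vector(X %*% beta))
    sum(dnbinom(y, size = theta, mu = mu, log = TRUE)) -
        lambda * sum(beta * (Sp %*% beta))
}

denseGradient <- function(y, o, X, Sp, lambda, theta, beta) {
    mu <- exp(o + as.vector(X %*% beta))
    u <- y - (y + theta) * mu / (mu + theta)
    as.vector(t(X) %*% u) - 2 * lambda * as.vector(Sp %*% beta)
}

denseHessian <- function(y, o, X, Sp, lambda, theta, beta) {
    mu <- exp(o + as.vector(X %*% beta))
    w <- -theta * mu * (y + theta) / (mu + theta)^2
    t(X) %*% (w * X) - 2 * lambda * Sp
}

## dense Newton oracle with step halving, entirely in base R
denseNewtonFit <- function(y, o, X, Sp, lambda, theta, beta0,
                           tol = 1e-10, maxIter = 100L) {
    beta <- beta0
    obj <- denseObjective(y, o, X, Sp, lambda, theta, beta)
    for (t in seq_len(maxIter)) {
        g <- denseGradient(y, o, X, Sp, lambda, theta, beta)
        if (max(abs(g)) <= tol) break
        H <- denseHessian(y, o, X, Sp, lambda, theta, beta)
        delta <- solve(-H, g)
        step <- 1
        repeat {
            cand <- beta + step * delta
            cobj <- denseObjective(y, o, X, Sp, lambda, theta, cand)
            if (is.finite(cobj) && cobj >= obj - 1e-12) break
            step <- step / 2
            if (step < 1e-8) break
        }
        beta <- beta + step * delta
        obj <- denseObjective(y, o, X, Sp, lambda, theta, beta)
    }
    beta
}

## central finite differences of a scalar function
numGradient <- function(f, x, h = 1e-5) {
    vapply(seq_along(x), function(i) {
        e <- numeric(length(x)); e[i] <- h
        (f(x + e) - f(x - e)) / (2 * h)
    }, numeric(1L))
}

numJacobian <- function(g, x, h = 1e-5) {
    p <- length(x)
    out <- matrix(0, p, p)
    for (i in seq_len(p)) {
        e <- numeric(p); e[i] <- h
        out[, i] <- (g(x + e) - g(x - e)) / (2 * h)
    }
    (out + t(out)) / 2
}

## random small tile model with NB counts from a bumpy truth, seeded
randomTileModel <- function(seed, nPos = 300L, spacing = 20, K = 1L,
                            lambda = NULL, theta = NULL, epsilon = 1e-3,
                            baseline = log(5)) {
    set.seed(seed)
    if (is.null(lambda)) lambda <- exp(runif(1, log(5), log(500)))
    if (is.null(theta)) theta <- exp(runif(1, log(1), log(20)))
    basis <- tilegam::splineBasis(0, nPos, spacing)
    x <- 0:(nPos - 1L)
    Z <- if (K == 1L) matrix(1, 1, 1) else rbind(c(1, 0), c(1, 1))
    nS <- nrow(Z)
    truth <- vapply(seq_len(K), function(k) {
        nb <- sample(1:3, 1)
        f <- rep(if (k == 1L) baseline else 0, nPos)
        for (b in seq_len(nb))
            f <- f + runif(1, -1, 1.5) *
                exp(-(x - runif(1, 0, nPos))^2 / (2 * runif(1, 20, 60)^2))
        f
    }, numeric(nPos))
    mu <- exp(truth %*% t(Z))
    counts <- matrix(rnbinom(length(mu), size = theta, mu = mu),
                     nrow = nPos, ncol = nS)
    tilegam::tileModel(counts, Z, basis, lambda = lambda, theta = theta,
                       epsilon = epsilon)
}

## dense penalty including ridge, matching a TileModel
modelDensePenalty <- function(model) {
    as.matrix(model@S) + model@epsilon * diag(ncol(model@X))
}

## random banded SPD matrix, seeded
randomBandedSPD <- function(seed, p, band = 4L) {
    set.seed(seed)
    B <- matrix(0, p, p)
    for (d in 0:band) {
        v <- runif(p - d, -1, 1)
        B[cbind(seq_len(p - d), seq_len(p - d) + d)] <- v
    }
    A <- B %*% t(B) + diag(p) * (band + 1)
    Matrix::forceSymmetric(Matrix::drop0(methods::as(
        methods::as(A, "CsparseMatrix"), "generalMatrix"), 1e-14))
}
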