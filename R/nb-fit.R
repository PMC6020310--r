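#' Assemble a per-tile penalized NB spline model
#'
#' Builds the sparse design `X = Z %x% Xk` for the tile positions, the
#' block-diagonal second-order difference penalty (one identical block per
#' smooth), and stores counts and offsets sample-major.
#'
#' @param counts per-base counts for the tile, positions x samples (a
#'   vector is treated as a single sample).
#' @param Z binary experimental design matrix, samples x smooths.
#' @param basis [SplineBasis-class] covering the tile.
#' @param positions 0-based positions modelled; default all bases of the
#'   basis interval `[start, end)`.
#' @param sizeFactors per-sample size factors (default all 1).
#' @param lambda,theta,epsilon hyperparameters: smoothing weight,
#'   NB dispersion, ridge weight (the penalty is
#'   `lambda * t(beta) (S + epsilon I) beta`).
#' @return A [TileModel-class] object.
#' @export
tileModel <- function(counts, Z, basis, positions = NULL,
                      sizeFactors = NULL, lambda, theta, epsilon = 1e-3) {
    counts <- as.matrix(counts)
    checkDesign(Z)
    if (is.null(positions))
        positions <- seq(basis@start, basis@end - 1)
    if (nrow(counts) != length(positions))
        stop("counts rows must match positions")
    if (ncol(counts) != nrow(Z))
        stop("counts columns must match design rows")
    if (is.null(sizeFactors)) sizeFactors <- rep(1, nrow(Z))
    Xk <- basisMatrix(basis, positions)
    X <- buildDesign(Z, Xk)
    pk <- ncol(Xk)
    S <- methods::as(Matrix::forceSymmetric(Matrix::bdiag(
        rep(list(penaltyMatrix(pk)), ncol(Z)))), "CsparseMatrix")
    new("TileModel", y = as.vector(counts),
        offsets = offsetsFromSizeFactors(sizeFactors, length(positions)),
        X = X, S = methods::as(S, "symmetricMatrix"), basis = basis,
        Z = Z, positions = as.numeric(positions),
        lambda = lambda, theta = theta, epsilon = epsilon)
}

## penalty including the ridge term, as used by the objective
penaltyWithRidge <- function(model) {
    model@S + model@epsilon * Matrix::Diagonal(ncol(model@X))
}

linearPredictor <- function(model, beta) {
    eta <- model@offsets + as.vector(model@X %*% beta)
    if (any(abs(eta) > 50)) {
        warning("linear predictor clipped at +/- 50 to avoid overflow")
        eta <- pmin(pmax(eta, -50), 50)
    }
    eta
}

#' Penalized negative binomial log-likelihood
#'
#' Evaluates `sum_i log NB(y_i; mu_i, theta) - lambda t(beta) (S + eps I)
#' beta` with `mu = exp(offsets + X beta)` and the NB parameterized so that
#' the variance is `mu + mu^2/theta`. The linear predictor is clipped at
#' +/- 50 (with a warning) to guard against overflow.
#'
#' @param model a [TileModel-class] object.
#' @param beta coefficient vector.
#' @return Scalar objective value.
#' @export
penalizedLogLik <- function(model, beta) {
    mu <- exp(linearPredictor(model, beta))
    ll <- sum(stats::dnbinom(model@y, size = model@theta, mu = mu,
                             log = TRUE))
    pen <- model@lambda *
        (sum(beta * as.vector(model@S %*% beta)) +
         model@epsilon * sum(beta^2))
    ll - pen
}

#' Gradient of the penalized log-likelihood
#'
#' `t(X) u - 2 lambda (S + eps I) beta` with
#' `u_i = y_i - (y_i + theta) mu_i / (mu_i + theta)`, the derivative of the
#' NB log-likelihood with respect to the linear predictor.
#'
#' @inheritParams penalizedLogLik
#' @return Numeric gradient vector.
#' @export
nbGradient <- function(model, beta) {
    mu <- exp(linearPredictor(model, beta))
    u <- model@y - (model@y + model@theta) * mu / (mu + model@theta)
    as.vector(Matrix::crossprod(model@X, u)) -
        2 * model@lambda *
            (as.vector(model@S %*% beta) + model@epsilon * beta)
}

#' Sparse Hessian of the penalized log-likelihood
#'
#' `H = t(X) W X - 2 lambda (S + eps I)` with diagonal curvature weights
#' `W_ii = -theta mu_i (y_i + theta) / (mu_i + theta)^2`, the exact second
#' derivative of the NB log-likelihood in the linear predictor (full
#' Newton, not the Fisher-scoring expectation). `H` is negative definite
#' whenever `lambda, epsilon > 0`, and banded because the splines have
#' local support.
#'
#' @inheritParams penalizedLogLik
#' @return Sparse symmetric `dsCMatrix`.
#' @export
nbHessian <- function(model, beta) {
    mu <- exp(linearPredictor(model, beta))
    w <- -model@theta * mu * (model@y + model@theta) / (mu + model@theta)^2
    XtWX <- Matrix::crossprod(model@X,
                              Matrix::Diagonal(x = w) %*% model@X)
    Matrix::forceSymmetric(XtWX - 2 * model@lambda * penaltyWithRidge(model))
}

#' Fit a tile model by sparse Newton-Raphson
#'
#' Maximizes the penalized NB log-likelihood with Newton steps
#' `beta <- beta - H^-1 g`, each linear system solved by a sparse Cholesky
#' factorization of `-H` with a fill-reducing permutation (the inverse is
#' never formed). Step halving enforces a monotone objective. The
#' iteration stops when the gradient max-norm falls below `tol` or the
#' relative objective change falls below `tolObj`, whichever happens
#' first.
#'
#' @param model a [TileModel-class] object.
#' @param beta0 starting coefficients; by default a ridged least-squares
#'   fit of `log(y + 1) - offsets` onto `X`.
#' @param tol gradient max-norm tolerance (default `1e-6`).
#' @param tolObj relative objective change tolerance (default `1e-8`).
#' @param maxIter maximum Newton iterations (default 50).
#' @return A [TileFit-class] object; `converged(fit)` is `FALSE` when
#'   `maxIter` was exhausted.
#' @export
newtonFit <- function(model, beta0 = NULL, tol = 1e-6, tolObj = 1e-8,
                      maxIter = 50L) {
    if (tol <= 0) stop("'tol' must be positive")
    p <- ncol(model@X)
    if (is.null(beta0)) {
        M <- Matrix::forceSymmetric(
            Matrix::crossprod(model@X) +
            2 * model@lambda * penaltyWithRidge(model) +
            1e-6 * Matrix::Diagonal(p))
        rhs <- as.vector(Matrix::crossprod(model@X,
                                           log(model@y + 1) - model@offsets))
        beta0 <- as.vector(Matrix::solve(Matrix::Cholesky(M, LDL = FALSE,
                                                          perm = TRUE), rhs))
    }
    beta <- beta0
    obj <- penalizedLogLik(model, beta)
    converged <- FALSE
    iter <- 0L
    g <- nbGradient(model, beta)
    for (t in seq_len(maxIter)) {
        if (max(abs(g)) <= tol) { converged <- TRUE; break }
        H <- nbHessian(model, beta)
        ch <- tryCatch(
            Matrix::Cholesky(Matrix::forceSymmetric(-H), LDL = FALSE,
                             perm = TRUE),
            error = function(e) stop("numerical failure: Hessian is not ",
                                     "negative definite (",
                                     conditionMessage(e), ")"))
        delta <- as.vector(Matrix::solve(ch, g))
        step <- 1
        accepted <- FALSE
        for (h in seq_len(21L)) {
            cand <- beta + step * delta
            candObj <- penalizedLogLik(model, cand)
            if (is.finite(candObj) && candObj >= obj - 1e-12) {
                accepted <- TRUE; break
            }
            step <- step / 2
        }
        iter <- t
        if (!accepted) break
        relChange <- abs(candObj - obj) / (abs(obj) + 1e-10)
        beta <- cand
        obj <- candObj
        g <- nbGradient(model, beta)
        if (relChange < tolObj) { converged <- TRUE; break }
    }
    if (max(abs(g)) <= tol) converged <- TRUE
    new("TileFit", beta = beta, mu = exp(linearPredictor(model, beta)),
        loglik = obj, gradNorm = max(abs(g)), iterations = iter,
        converged = converged, model = model)
}

#' @describeIn newtonFit estimated coefficients.
#' @param object a [TileFit-class] object.
#' @param ... ignored.
#' @export
setMethod("coef", "TileFit", function(object, ...) object@beta)

#' @describeIn newtonFit fitted means, sample-major.
#' @export
setMethod("fitted", "TileFit", function(object, ...) object@mu)

#' Convergence flag of a tile fit
#' @param fit a [TileFit-class] object.
#' @export
converged <- function(fit) fit@converged

setMethod("show", "TileFit", function(object) {
    cat("TileFit: p =", length(object@beta),
        "| iterations:", object@iterations,
        "| converged:", object@converged,
        "\n  penalized log-likelihood:", format(object@loglik),
        "| max |grad|:", format(object@gradNorm), "\n")
})

#' Per-position smooth values of a tile fit
#'
#' Evaluates `f_k(x) = Xk beta^(k)` for every smooth at the model
#' positions.
#'
#' @param fit a [TileFit-class] object.
#' @param positions optional positions (default: model positions).
#' @return Matrix, positions x smooths.
#' @export
smoothEstimates <- function(fit, positions = NULL) {
    model <- fit@model
    if (is.null(positions)) positions <- model@positions
    Xk <- basisMatrix(model@basis, positions)
    pk <- ncol(Xk)
    K <- ncol(model@Z)
    out <- vapply(seq_len(K), function(k) {
        idx <- ((k - 1L) * pk + 1L):(k * pk)
        as.vector(Xk %*% fit@beta[idx])
    }, numeric(length(positions)))
    matrix(out, nrow = length(positions), ncol = K,
           dimnames = list(NULL, colnames(model@Z)))
}
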