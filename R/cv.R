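## evaluate an expression with a locally-set RNG seed, restoring the
## caller's RNG state afterwards
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(expr)
}

#' Select representative tiles for cross-validation
#'
#' Samples `nTiles` tiles without replacement with probability proportional
#' to their total fragment count, so that hyperparameters are tuned on
#' tiles carrying signal. If fewer than `nTiles` tiles have positive
#' counts, the remainder is drawn uniformly from the zero-count tiles.
#'
#' @param layout a [TileLayout-class] object.
#' @param counts per-base counts, positions x samples (or a vector).
#' @param nTiles number of tiles to select (default 20).
#' @param seed RNG seed; selection is reproducible from it.
#' @return Integer vector of selected tile indices.
#' @export
selectCVTiles <- function(layout, counts, nTiles = 20L, seed = 1L) {
    counts <- as.matrix(counts)
    nT <- length(layout)
    if (nTiles > nT) stop("invalid argument: nTiles exceeds tile count")
    perBase <- rowSums(counts)
    w <- vapply(seq_len(nT), function(t) {
        sum(perBase[(layout@tileStart[t] + 1L):layout@tileEnd[t]])
    }, numeric(1L))
    if (all(w == 0)) stop("no signal: all tiles have zero counts")
    withSeed(seed, {
        pos <- which(w > 0)
        if (length(pos) >= nTiles) {
            sel <- sample(pos, nTiles, prob = w[pos])
        } else {
            rest <- setdiff(seq_len(nT), pos)
            sel <- c(sample(pos, length(pos), prob = w[pos]),
                     sample(rest, nTiles - length(pos)))
        }
        sel
    })
}

#' Blocked fold assignment for positions of a tile
#'
#' Positions are grouped into consecutive blocks of `blockBp` bases;
#' blocks are dealt to folds round-robin after a seeded random shuffle of
#' the fold order. Held-out positions are therefore short blocks flanked
#' by training data, so cross-validation scores interpolation quality
#' rather than memorization.
#'
#' @param n number of positions in the tile.
#' @param nFolds number of folds (default 10).
#' @param blockBp block length in bp (default 20).
#' @param seed RNG seed.
#' @return Integer vector of fold labels in `1..nFolds`, length `n`.
#' @export
makeFolds <- function(n, nFolds = 10L, blockBp = 20L, seed = 1L) {
    if (nFolds < 2L || blockBp < 1L)
        stop("invalid argument: need nFolds >= 2 and blockBp >= 1")
    if (n < nFolds * blockBp)
        stop("invalid argument: tile too short for ", nFolds,
             " folds of ", blockBp, " bp blocks")
    nBlocks <- ceiling(n / blockBp)
    withSeed(seed, {
        ord <- sample.int(nFolds)
        blockFold <- ord[((seq_len(nBlocks) - 1L) %% nFolds) + 1L]
        rep(blockFold, each = blockBp)[seq_len(n)]
    })
}

## rebuild a TileModel restricted to a subset of positions (rows across
## all samples), reusing the basis and design
restrictModel <- function(model, keepPos, lambda, theta) {
    nPos <- length(model@positions)
    nS <- nrow(model@Z)
    rows <- as.vector(outer(keepPos, (seq_len(nS) - 1L) * nPos, "+"))
    Xk <- basisMatrix(model@basis, model@positions[keepPos])
    X <- buildDesign(model@Z, Xk)
    new("TileModel", y = model@y[rows], offsets = model@offsets[rows],
        X = X, S = model@S, basis = model@basis, Z = model@Z,
        positions = model@positions[keepPos],
        lambda = lambda, theta = theta, epsilon = model@epsilon)
}

#' Out-of-fold log-likelihood for one tile
#'
#' For each fold, the model is refitted on the remaining positions only
#' (held-out rows are dropped, not zeroed) and the unpenalized NB
#' log-likelihood of the held-out positions is evaluated at the refitted
#' coefficients; contributions are summed over folds.
#'
#' @param model a [TileModel-class] object (its `lambda`/`theta` are
#'   overridden by the arguments).
#' @param folds fold labels from [makeFolds()], one per model position.
#' @param lambda,theta hyperparameters to evaluate.
#' @return Scalar out-of-fold log-likelihood; `-Inf` (with a warning) if
#'   any fold fails to converge.
#' @export
cvObjective <- function(model, folds, lambda, theta) {
    nPos <- length(model@positions)
    if (length(folds) != nPos) stop("fold labels must match positions")
    nS <- nrow(model@Z)
    total <- 0
    for (f in sort(unique(folds))) {
        trainPos <- which(folds != f)
        testPos <- which(folds == f)
        if (length(testPos) == 0L) next
        sub <- restrictModel(model, trainPos, lambda, theta)
        fit <- tryCatch(newtonFit(sub), error = function(e) NULL)
        if (is.null(fit) || !fit@converged) {
            warning("fold ", f, " did not converge; objective is -Inf")
            return(-Inf)
        }
        rows <- as.vector(outer(testPos, (seq_len(nS) - 1L) * nPos, "+"))
        Xk <- basisMatrix(model@basis, model@positions[testPos])
        Xtest <- buildDesign(model@Z, Xk)
        eta <- model@offsets[rows] + as.vector(Xtest %*% fit@beta)
        eta <- pmin(pmax(eta, -50), 50)
        total <- total + sum(stats::dnbinom(model@y[rows], size = theta,
                                            mu = exp(eta), log = TRUE))
    }
    total
}

#' Cross-validated selection of smoothing and dispersion parameters
#'
#' Maximizes the summed out-of-fold log-likelihood over `(log lambda,
#' log theta)` by Nelder-Mead from several seeded starting points drawn
#' log-uniformly from the search ranges. When both ranges are degenerate
#' (a single point) the objective is evaluated there and that point is
#' returned.
#'
#' @param models list of [TileModel-class] objects (the representative
#'   tiles).
#' @param nFolds folds per tile (default 10).
#' @param blockBp fold block length in bp (default 20).
#' @param seed RNG seed controlling folds and starting points.
#' @param nStarts number of Nelder-Mead starts (default 3).
#' @param maxEval maximum objective evaluations per start (default 50).
#' @param lambdaRange,thetaRange search ranges (log-uniform sampling of
#'   starts).
#' @return A list with `lambda`, `theta`, `value` (objective at the
#'   optimum), `evaluations` (data.frame log of all evaluations) and
#'   `nFits` (number of per-fold model fits performed).
#' @export
optimizeHyperparams <- function(models, nFolds = 10L, blockBp = 20L,
                                seed = 1L, nStarts = 3L, maxEval = 50L,
                                lambdaRange = c(1e-1, 1e5),
                                thetaRange = c(0.1, 100)) {
    if (length(models) == 0L) stop("need at least one tile model")
    foldsList <- lapply(seq_along(models), function(t)
        makeFolds(length(models[[t]]@positions), nFolds, blockBp,
                  seed + t))
    log <- new.env()
    log$tab <- list()
    log$nFits <- 0L
    evalPoint <- function(par) {
        lambda <- exp(par[1L]); theta <- exp(par[2L])
        val <- 0
        for (t in seq_along(models)) {
            v <- suppressWarnings(
                cvObjective(models[[t]], foldsList[[t]], lambda, theta))
            log$nFits <- log$nFits + nFolds
            if (!is.finite(v)) { val <- -Inf; break }
            val <- val + v
        }
        log$tab[[length(log$tab) + 1L]] <-
            data.frame(lambda = lambda, theta = theta, objective = val)
        val
    }
    single <- diff(range(lambdaRange)) == 0 && diff(range(thetaRange)) == 0
    if (single) {
        par <- log(c(lambdaRange[1L], thetaRange[1L]))
        val <- evalPoint(par)
        best <- list(par = par, value = val)
    } else {
        starts <- withSeed(seed, {
            s <- cbind(stats::runif(nStarts, log(lambdaRange[1L]),
                                    log(lambdaRange[2L])),
                       stats::runif(nStarts, log(thetaRange[1L]),
                                    log(thetaRange[2L])))
            s[1L, ] <- c(mean(log(lambdaRange)), mean(log(thetaRange)))
            s
        })
        best <- NULL
        for (s in seq_len(nStarts)) {
            opt <- stats::optim(starts[s, ],
                                fn = function(p) -evalPoint(p),
                                method = "Nelder-Mead",
                                control = list(maxit = maxEval))
            cand <- list(par = opt$par, value = -opt$value)
            if (is.null(best) || cand$value > best$value) best <- cand
        }
        if (!is.finite(best$value))
            stop("optimization failure: all hyperparameter evaluations ",
                 "were -Inf")
    }
    tab <- do.call(rbind, log$tab)
    ## report the best point actually evaluated (Nelder-Mead's final par
    ## is always among them)
    ix <- which.max(tab$objective)
    list(lambda = tab$lambda[ix], theta = tab$theta[ix],
         value = tab$objective[ix], evaluations = tab, nFits = log$nFits)
}
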