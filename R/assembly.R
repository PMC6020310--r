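## fit one tile and return everything assembly needs
fitOneTile <- function(t, counts, Z, layout, knotSpacing, sizeFactors,
                       lambda, theta, epsilon) {
    ts <- layout@tileStart[t]; te <- layout@tileEnd[t]
    basis <- splineBasis(ts, te, knotSpacing)
    tileCounts <- counts[(ts + 1L):te, , drop = FALSE]
    model <- tileModel(tileCounts, Z, basis, sizeFactors = sizeFactors,
                       lambda = lambda, theta = theta, epsilon = epsilon)
    fit <- newtonFit(model)
    K <- ncol(Z)
    cs <- layout@chunkStart[t]; ce <- layout@chunkEnd[t]
    chunkPos <- seq(cs, ce - 1)
    fitVals <- seVals <- matrix(NA_real_, length(chunkPos), K)
    if (fit@converged) {
        H <- nbHessian(model, fit@beta)
        sub <- hessianInverseSubset(H)
        Xk <- basisMatrix(basis, chunkPos)
        pk <- ncol(Xk)
        for (k in seq_len(K)) {
            idx <- smoothBlock(pk, k)
            fitVals[, k] <- as.vector(Xk %*% fit@beta[idx])
            seVals[, k] <- sqrt(smoothVariances(sub, Xk, k))
        }
    }
    list(tile = t, chunkStart = cs, chunkEnd = ce, fit = fitVals,
         se = seVals, converged = fit@converged,
         iterations = fit@iterations, loglik = fit@loglik,
         gradNorm = fit@gradNorm)
}

#' Fit a genome-wide model tile by tile
#'
#' Fits the penalized NB spline model independently on every tile of the
#' layout, computes pointwise standard errors by the sparse inverse subset
#' algorithm, and assembles per-base tracks by overlap-midpoint chunk
#' ownership. Tile computations share no mutable state, so they can be
#' dispatched to parallel workers; results are written serially in tile
#' order, making the output independent of worker count. Non-converged
#' tiles are recorded in the diagnostics and their chunks masked with
#' `NA`.
#'
#' @param counts per-base counts, chromLength x samples.
#' @param Z binary design matrix, samples x smooths.
#' @param layout a [TileLayout-class]; default tiles of 24 kb with 3 kb
#'   overlap.
#' @param knotSpacing inner knot spacing in bp (default 20).
#' @param sizeFactors per-sample size factors; estimated by
#'   median-of-ratios on 1 kb bins when `NULL`.
#' @param lambda,theta,epsilon hyperparameters (e.g. from
#'   [optimizeHyperparams()]).
#' @param chrom chromosome name for the output.
#' @param backend `"memory"` (default) or `"hdf5"` (chunk-wise writes to a
#'   pre-initialized HDF5 file; requires the rhdf5 package).
#' @param h5file path for the HDF5 backend (default: temp file).
#' @param workers number of parallel workers for tile fitting (forked via
#'   the parallel package when > 1; output is identical for any worker
#'   count).
#' @return A [GenomeFit-class] object.
#' @export
fitGenome <- function(counts, Z, layout = NULL, knotSpacing = 20,
                      sizeFactors = NULL, lambda, theta, epsilon = 1e-3,
                      chrom = "chr", backend = c("memory", "hdf5"),
                      h5file = NULL, workers = 1L) {
    backend <- match.arg(backend)
    counts <- as.matrix(counts)
    checkDesign(Z)
    chromLength <- nrow(counts)
    if (is.null(layout)) layout <- makeTiles(chromLength)
    if (layout@chromLength != chromLength)
        stop("layout chromosome length does not match counts")
    if (is.null(sizeFactors))
        sizeFactors <- computeSizeFactors(binCounts(counts))
    K <- ncol(Z)
    smoothNames <- colnames(Z)
    if (is.null(smoothNames)) smoothNames <- paste0("s", seq_len(K))
    nT <- length(layout)
    runTile <- function(t) fitOneTile(t, counts, Z, layout, knotSpacing,
                                      sizeFactors, lambda, theta, epsilon)
    results <- if (workers > 1L) {
        parallel::mclapply(seq_len(nT), runTile, mc.cores = workers)
    } else {
        lapply(seq_len(nT), runTile)
    }
    ## serialized writing, one owner chunk per base
    useH5 <- backend == "hdf5"
    if (useH5) {
        if (!requireNamespace("rhdf5", quietly = TRUE))
            stop("the hdf5 backend requires the rhdf5 package")
        if (is.null(h5file)) h5file <- tempfile(fileext = ".h5")
        if (file.exists(h5file)) file.remove(h5file)
        rhdf5::h5createFile(h5file)
        chunkLen <- min(chromLength, max(layout@chunkEnd - layout@chunkStart))
        for (ds in c("fit", "se"))
            rhdf5::h5createDataset(h5file, ds, dims = c(chromLength, K),
                                   chunk = c(chunkLen, 1L),
                                   storage.mode = "double", fillValue = NA_real_)
        fitMat <- matrix(numeric(0), 0, 0)
        seMat <- matrix(numeric(0), 0, 0)
    } else {
        h5file <- character(0)
        fitMat <- matrix(NA_real_, chromLength, K,
                         dimnames = list(NULL, smoothNames))
        seMat <- fitMat
    }
    for (res in results) {
        rows <- (res$chunkStart + 1L):res$chunkEnd
        if (useH5) {
            rhdf5::h5write(res$fit, h5file, "fit",
                           index = list(rows, seq_len(K)))
            rhdf5::h5write(res$se, h5file, "se",
                           index = list(rows, seq_len(K)))
        } else {
            fitMat[rows, ] <- res$fit
            seMat[rows, ] <- res$se
        }
    }
    diag <- data.frame(
        tile = vapply(results, `[[`, numeric(1L), "tile"),
        converged = vapply(results, `[[`, logical(1L), "converged"),
        iterations = vapply(results, `[[`, integer(1L), "iterations"),
        loglik = vapply(results, `[[`, numeric(1L), "loglik"),
        gradNorm = vapply(results, `[[`, numeric(1L), "gradNorm"))
    if (!all(diag$converged))
        warning(sum(!diag$converged), " tile(s) did not converge; ",
                "their chunks are masked with NA")
    new("GenomeFit", chrom = chrom, chromLength = chromLength,
        smoothNames = smoothNames, backend = backend, fit = fitMat,
        se = seMat, h5file = h5file, layout = layout,
        hyper = list(lambda = lambda, theta = theta, epsilon = epsilon),
        diagnostics = diag,
        provenance = list(package = "tilegam",
                          version = as.character(utils::packageVersion("tilegam")),
                          knotSpacing = knotSpacing,
                          sizeFactors = sizeFactors,
                          samples = nrow(Z), smooths = K))
}

#' Join per-tile fits into per-base tracks
#'
#' Each base takes its value from the unique tile whose chunk contains it
#' (hard ownership at overlap midpoints, no blending).
#'
#' @param tileFits list of [TileFit-class] objects, one per tile of the
#'   layout, fitted on the corresponding tile intervals.
#' @param layout the [TileLayout-class] that produced the tiles.
#' @return Matrix of per-base smooth values, chromLength x smooths.
#' @export
joinTiles <- function(tileFits, layout) {
    nT <- length(layout)
    if (length(tileFits) != nT)
        stop("assembly error: need one fit per tile")
    K <- ncol(tileFits[[1L]]@model@Z)
    out <- matrix(NA_real_, layout@chromLength, K)
    for (t in seq_len(nT)) {
        fit <- tileFits[[t]]
        if (is.null(fit)) stop("assembly error: missing tile ", t)
        cs <- layout@chunkStart[t]; ce <- layout@chunkEnd[t]
        chunkPos <- seq(cs, ce - 1)
        out[(cs + 1L):ce, ] <- smoothEstimates(fit, chunkPos)
    }
    out
}

setMethod("show", "GenomeFit", function(object) {
    cat("GenomeFit on", object@chrom, "(", object@chromLength, "bp )\n",
        " smooths:", paste(object@smoothNames, collapse = ", "), "\n",
        " backend:", object@backend,
        "| tiles:", length(object@layout),
        "| converged:", sum(object@diagnostics$converged), "/",
        nrow(object@diagnostics), "\n",
        " lambda:", object@hyper$lambda, " theta:", object@hyper$theta,
        "\n")
})

readTrack <- function(fit, what, smooth) {
    k <- if (is.character(smooth)) match(smooth, fit@smoothNames)
         else as.integer(smooth)
    if (is.na(k) || k < 1L || k > length(fit@smoothNames))
        stop("unknown smooth: ", smooth)
    if (fit@backend == "hdf5") {
        as.vector(rhdf5::h5read(fit@h5file, what,
                                index = list(seq_len(fit@chromLength), k)))
    } else {
        slot(fit, what)[, k]
    }
}

#' Per-base fitted track of a smooth
#' @param fit a [GenomeFit-class] object.
#' @param smooth smooth index or name.
#' @return Numeric vector of length `chromLength`.
#' @export
fittedTrack <- function(fit, smooth = 1L) readTrack(fit, "fit", smooth)

#' Per-base standard error track of a smooth
#' @inheritParams fittedTrack
#' @export
seTrack <- function(fit, smooth = 1L) readTrack(fit, "se", smooth)

#' Export assembled tracks
#'
#' Writes the per-smooth fitted log-rate and standard error tracks.
#' Formats: `"tsv"` (one row per base: chrom, 0-based position, fit and se
#' per smooth), `"hdf5"` (datasets `fit` and `se`), `"bigwig"` (one pair
#' of files per smooth via rtracklayer), and `"bed"` (0-based intervals of
#' the bases whose two-sided pointwise Gaussian p-value is below
#' `pThreshold`, one line per base).
#'
#' @param fit a [GenomeFit-class] object.
#' @param format one of `"tsv"`, `"hdf5"`, `"bigwig"`, `"bed"`.
#' @param file output path (used as a prefix for bigwig).
#' @param smooth smooth index or name for the bed export.
#' @param pThreshold p-value cutoff for the bed export (default 0.05).
#' @return Invisibly, the path(s) written.
#' @export
exportTracks <- function(fit, format = c("tsv", "hdf5", "bigwig", "bed"),
                         file, smooth = 1L, pThreshold = 0.05) {
    format <- match.arg(format)
    K <- length(fit@smoothNames)
    if (format == "tsv") {
        df <- data.frame(chrom = fit@chrom,
                         pos = seq_len(fit@chromLength) - 1L)
        for (k in seq_len(K)) {
            df[[paste0("fit_", fit@smoothNames[k])]] <- fittedTrack(fit, k)
            df[[paste0("se_", fit@smoothNames[k])]] <- seTrack(fit, k)
        }
        utils::write.table(df, file, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        return(invisible(file))
    }
    if (format == "hdf5") {
        if (!requireNamespace("rhdf5", quietly = TRUE))
            stop("hdf5 export requires the rhdf5 package")
        if (file.exists(file)) file.remove(file)
        rhdf5::h5createFile(file)
        fitM <- vapply(seq_len(K), function(k) fittedTrack(fit, k),
                       numeric(fit@chromLength))
        seM <- vapply(seq_len(K), function(k) seTrack(fit, k),
                      numeric(fit@chromLength))
        rhdf5::h5write(fitM, file, "fit")
        rhdf5::h5write(seM, file, "se")
        rhdf5::h5closeAll()
        return(invisible(file))
    }
    if (format == "bigwig") {
        if (!requireNamespace("rtracklayer", quietly = TRUE))
            stop("bigwig export requires the rtracklayer package")
        paths <- character(0)
        for (k in seq_len(K)) {
            for (what in c("fit", "se")) {
                v <- readTrack(fit, what, k)
                gr <- GenomicRanges::GRanges(
                    fit@chrom,
                    IRanges::IRanges(seq_len(fit@chromLength),
                                     width = 1L),
                    score = v)
                GenomeInfoDb::seqlengths(gr) <- fit@chromLength
                path <- paste0(file, ".", fit@smoothNames[k], ".", what,
                               ".bw")
                rtracklayer::export.bw(gr, path)
                paths <- c(paths, path)
            }
        }
        return(invisible(paths))
    }
    ## bed
    f <- fittedTrack(fit, smooth)
    s <- seTrack(fit, smooth)
    ok <- !is.na(f) & !is.na(s) & s > 0
    p <- rep(NA_real_, length(f))
    p[ok] <- pointwisePvalues(f[ok], s[ok]^2)$p
    hit <- which(!is.na(p) & p < pThreshold)
    df <- data.frame(chrom = fit@chrom, start = hit - 1L, end = hit,
                     name = paste0("p", seq_along(hit)),
                     score = round(-10 * log10(pmax(p[hit], 1e-30))))
    utils::write.table(df, file, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(file)
}
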