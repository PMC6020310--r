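#' Configure a synthetic ChIP-seq-like dataset
#'
#' The true smooths are sums of Gaussian bumps plus a baseline, on the log
#' scale — deliberately outside the spline family so that estimator
#' recovery is never trivially exact. Defaults emulate a two-condition
#' comparison (control occupancy plus a treatment/control log-fold-change
#' smooth carried only by the treatment samples) at moderate coverage and
#' overdispersion.
#'
#' @param length chromosome length in bp (default 30000).
#' @param smooths list of per-smooth bump specs (`centers`, `widths`,
#'   `heights`, `baseline`); default: a control occupancy smooth with
#'   three bumps and baseline `log(5)`, and a log-fold-change smooth with
#'   two signed bumps and baseline 0.
#' @param Z binary design matrix; default the 2-sample control/treatment
#'   layout `rbind(c(1, 0), c(1, 1))`.
#' @param theta true NB dispersion (default 5).
#' @param sizeFactors true per-sample size factors (default `c(0.9, 1.1)`,
#'   mild depth imbalance).
#' @param seed mandatory RNG seed.
#' @return A [SimConfig-class] object.
#' @export
simConfig <- function(length = 30000,
                      smooths = NULL, Z = NULL, theta = 5,
                      sizeFactors = NULL, seed) {
    if (missing(seed)) stop("'seed' is mandatory")
    if (is.null(smooths))
        smooths <- list(
            control = list(
                centers = length * c(0.2, 0.5, 0.8),
                widths = length * c(0.02, 0.03, 0.015),
                heights = c(1.5, 2.0, 1.0), baseline = log(5)),
            treatment_vs_control = list(
                centers = length * c(0.35, 0.7),
                widths = length * c(0.02, 0.025),
                heights = c(1.2, -0.8), baseline = 0))
    if (is.null(Z)) {
        Z <- rbind(control = c(1, 0), treatment = c(1, 1))
        colnames(Z) <- names(smooths)[seq_len(ncol(Z))]
    }
    if (is.null(sizeFactors)) sizeFactors <- c(0.9, 1.1)[seq_len(nrow(Z))]
    if (is.null(sizeFactors) || length(sizeFactors) != nrow(Z))
        sizeFactors <- rep(1, nrow(Z))
    new("SimConfig", length = length, smooths = smooths,
        Z = as.matrix(Z), theta = theta, sizeFactors = sizeFactors,
        seed = as.integer(seed))
}

## evaluate a bump-sum smooth at 0-based positions
evalSmooth <- function(spec, x) {
    f <- rep(spec$baseline, length(x))
    for (b in seq_along(spec$centers))
        f <- f + spec$heights[b] *
            exp(-(x - spec$centers[b])^2 / (2 * spec$widths[b]^2))
    f
}

#' Simulate negative binomial count tracks
#'
#' Draws per-base counts `y ~ NB(mu, theta)` (variance `mu + mu^2/theta`)
#' with `mu = exp(log sizeFactor_j + sum_k Z[j,k] f_k(x))`, reproducibly
#' from the config seed.
#'
#' @param config a [SimConfig-class] object.
#' @return A [SimulatedData-class] object with truth, means and counts.
#' @export
simulateCounts <- function(config) {
    x <- seq(0, config@length - 1)
    K <- base::length(config@smooths)
    truth <- vapply(config@smooths, evalSmooth, numeric(config@length),
                    x = x)
    truth <- matrix(truth, ncol = K,
                    dimnames = list(NULL, names(config@smooths)))
    nS <- nrow(config@Z)
    mu <- exp(sweep(truth %*% t(config@Z), 2L,
                    log(config@sizeFactors), "+"))
    counts <- withSeed(config@seed, {
        matrix(stats::rnbinom(base::length(mu), size = config@theta,
                              mu = mu),
               nrow = config@length, ncol = nS)
    })
    rownames(config@Z) -> nm
    colnames(mu) <- colnames(counts) <- nm
    new("SimulatedData", truth = truth, mu = mu, counts = counts,
        config = config)
}

setMethod("show", "SimulatedData", function(object) {
    cat("SimulatedData:", nrow(object@counts), "bp x",
        ncol(object@counts), "sample(s),",
        base::length(object@config@smooths), "smooth(s)\n",
        " theta:", object@config@theta,
        " total counts:", sum(object@counts), "\n")
})

#' Write simulated fragments as SAM/BAM files
#'
#' For every count at base `x` a fragment of length `fragmentLength`
#' centered at `x` is emitted, so that ingesting the file with
#' [centerFragments()] + [computeCoverage()] reproduces the count track
#' exactly. Fragments that would overhang the chromosome are shifted
#' inward (and counted in the returned summary); their centers move
#' accordingly. One file per sample is written; in `"bam"` format the
#' files are coordinate-sorted and indexed.
#'
#' @param sim a [SimulatedData-class] object.
#' @param fragmentLength fragment length in bp (default 200).
#' @param paired emit proper read pairs (default) or single-end forward
#'   reads.
#' @param readLength aligned read length (default 50, capped at the
#'   fragment length).
#' @param dir output directory (default: a temp directory).
#' @param chrom chromosome name (default `"chrS"`).
#' @param format `"bam"` (default) or `"sam"`.
#' @return List with `files` (per-sample paths) and `shifted` (number of
#'   boundary-shifted fragments per sample).
#' @export
simulateFragments <- function(sim, fragmentLength = 200, paired = TRUE,
                              readLength = 50, dir = tempfile("simbam"),
                              chrom = "chrS", format = c("bam", "sam")) {
    format <- match.arg(format)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    L <- sim@config@length
    rl <- min(readLength, fragmentLength)
    cig <- paste0(rl, "M")
    files <- character(ncol(sim@counts))
    shifted <- integer(ncol(sim@counts))
    header <- c("@HD\tVN:1.6\tSO:coordinate",
                paste0("@SQ\tSN:", chrom, "\tLN:", L))
    for (j in seq_len(ncol(sim@counts))) {
        cnt <- sim@counts[, j]
        centers <- rep.int(seq_along(cnt) - 1L, cnt)
        start0 <- centers - fragmentLength %/% 2L
        lo <- start0 < 0
        hi <- start0 + fragmentLength > L
        start0[lo] <- 0L
        start0[hi] <- L - fragmentLength
        shifted[j] <- sum(lo | hi)
        ord <- order(start0)
        start0 <- start0[ord]
        nfrag <- length(start0)
        qname <- sprintf("frag%08d", seq_len(nfrag))
        if (paired && nfrag > 0L) {
            p1 <- start0 + 1L
            p2 <- start0 + fragmentLength - rl + 1L
            rec1 <- paste(qname, 99L, chrom, p1, 60L, cig, "=", p2,
                          fragmentLength, "*", "*", sep = "\t")
            rec2 <- paste(qname, 147L, chrom, p2, 60L, cig, "=", p1,
                          -fragmentLength, "*", "*", sep = "\t")
            recs <- c(rec1, rec2)[order(c(p1, p2), c(seq_len(nfrag),
                                                     seq_len(nfrag)))]
        } else if (nfrag > 0L) {
            recs <- paste(qname, 0L, chrom, start0 + 1L, 60L, cig, "*",
                          0L, 0L, "*", "*", sep = "\t")
        } else {
            recs <- character(0)
        }
        nm <- if (is.null(colnames(sim@counts))) paste0("sample", j)
              else colnames(sim@counts)[j]
        samPath <- file.path(dir, paste0(nm, ".sam"))
        writeLines(c(header, recs), samPath)
        if (format == "bam") {
            bamPath <- Rsamtools::asBam(samPath,
                                        file.path(dir, nm),
                                        overwrite = TRUE,
                                        indexDestination = TRUE)
            file.remove(samPath)
            files[j] <- bamPath
        } else {
            files[j] <- samPath
        }
    }
    names(files) <- colnames(sim@counts)
    list(files = files, shifted = shifted, chrom = chrom, dir = dir)
}

#' Write simulated count tracks as TSV
#'
#' Plain-text companion to [simulateFragments()]: columns `chrom`, `pos`
#' (0-based) and one count column per sample.
#'
#' @param sim a [SimulatedData-class] object.
#' @param file output path.
#' @param chrom chromosome name.
#' @return Invisibly, the path written.
#' @export
writeCountsTSV <- function(sim, file, chrom = "chrS") {
    df <- data.frame(chrom = chrom,
                     pos = seq_len(nrow(sim@counts)) - 1L)
    cn <- colnames(sim@counts)
    if (is.null(cn)) cn <- paste0("sample", seq_len(ncol(sim@counts)))
    for (j in seq_len(ncol(sim@counts))) df[[cn[j]]] <- sim@counts[, j]
    utils::write.table(df, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}

#' Read a per-base count track TSV
#'
#' @param file path written by [writeCountsTSV()] (columns `chrom`, `pos`,
#'   then one column per sample).
#' @return Matrix of counts, positions x samples.
#' @export
readCountsTSV <- function(file) {
    df <- utils::read.delim(file, sep = "\t", check.names = FALSE)
    as.matrix(df[, setdiff(names(df), c("chrom", "pos")), drop = FALSE])
}
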