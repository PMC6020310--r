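#' Read a BAM file and compute fragment center positions
#'
#' For paired-end data the fragment is the span between the outermost
#' aligned bases of a proper pair and the center is its midpoint. For
#' single-end data the center is the 5' start of the read shifted by
#' `fragmentLength/2` in the read orientation. Each fragment contributes
#' one center (mates are never double-counted). Unmapped, secondary and
#' supplementary records are skipped; duplicates are retained unless
#' `dropDuplicates` is set. Coordinates are 0-based.
#'
#' @param bam path to a coordinate-sorted, indexed BAM file.
#' @param fragmentLength fragment length in bp; required for single-end
#'   data, ignored for paired-end.
#' @param chrom optional chromosome name to restrict to.
#' @param paired logical; autodetected from the first records if `NULL`.
#' @param dropDuplicates drop records flagged as PCR/optical duplicates.
#' @return A list with `centers` (integer vector of 0-based positions) and
#'   `qc` (list with counts of retained fragments and skipped records).
#' @export
centerFragments <- function(bam, fragmentLength = NULL, chrom = NULL,
                            paired = NULL, dropDuplicates = FALSE) {
    if (!file.exists(bam)) stop("I/O error: BAM file not found: ", bam)
    bai <- paste0(bam, ".bai")
    if (!file.exists(bai) && !file.exists(sub("\\.bam$", ".bai", bam)))
        stop("I/O error: BAM index (.bai) not found for ", bam)
    if (is.null(paired))
        paired <- suppressMessages(Rsamtools::testPairedEndBam(bam))
    flag <- Rsamtools::scanBamFlag(
        isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
        isSupplementaryAlignment = FALSE,
        isDuplicate = if (dropDuplicates) FALSE else NA)
    param <- if (is.null(chrom)) {
        Rsamtools::ScanBamParam(flag = flag)
    } else {
        hdr <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
        if (!chrom %in% names(hdr)) stop("chromosome not in BAM header: ", chrom)
        Rsamtools::ScanBamParam(flag = flag,
            which = GenomicRanges::GRanges(chrom,
                IRanges::IRanges(1L, hdr[[chrom]])))
    }
    total <- Rsamtools::countBam(bam)$records
    if (paired) {
        gp <- GenomicAlignments::readGAlignmentPairs(bam, param = param)
        gr <- GenomicRanges::granges(gp)
        start0 <- GenomicRanges::start(gr) - 1L
        centers <- start0 + GenomicRanges::width(gr) %/% 2L
        used <- 2L * length(gp)
    } else {
        if (is.null(fragmentLength))
            stop("'fragmentLength' is required for single-end data")
        ga <- GenomicAlignments::readGAlignments(bam, param = param)
        fwd <- as.vector(GenomicAlignments::strand(ga) != "-")
        start0 <- GenomicAlignments::start(ga) - 1L
        end0 <- GenomicAlignments::end(ga) - 1L
        shift <- fragmentLength %/% 2L
        centers <- ifelse(fwd, start0 + shift, end0 - shift)
        used <- length(ga)
    }
    list(centers = as.integer(centers),
         qc = list(fragments = length(centers),
                   recordsTotal = total, recordsUsed = used,
                   recordsSkipped = total - used, paired = paired))
}

#' Per-base coverage from fragment centers
#'
#' `counts[x + 1]` is the number of fragment centers at 0-based position
#' `x`. Centers falling outside `[0, chromLength)` are clipped to the
#' nearest boundary and counted in the `clipped` attribute.
#'
#' @param centers integer vector of 0-based center positions.
#' @param chromLength chromosome length in bp.
#' @return Integer vector of length `chromLength` with attribute
#'   `clipped` (number of clipped centers).
#' @export
computeCoverage <- function(centers, chromLength) {
    out <- centers < 0 | centers >= chromLength
    if (any(out))
        centers <- pmin(pmax(centers, 0L), chromLength - 1L)
    counts <- tabulate(centers + 1L, nbins = chromLength)
    attr(counts, "clipped") <- sum(out)
    counts
}

#' Lay out overlapping tiles and disjoint chunks over a chromosome
#'
#' Tiles advance by `tileSize - overlap`; the last tile is right-anchored
#' so it ends exactly at `chromLength`. Chunk boundaries sit at the
#' midpoints of the actual overlap between consecutive tiles, and the
#' first/last chunks are extended to the chromosome boundaries, so the
#' chunks partition the chromosome exactly.
#'
#' @param chromLength chromosome length in bp.
#' @param tileSize tile width in bp (default 24000).
#' @param overlap overlap between consecutive tiles in bp (default 3000).
#' @return A [TileLayout-class] object.
#' @examples
#' makeTiles(10000, 4000, 1000)
#' @export
makeTiles <- function(chromLength, tileSize = 24000, overlap = 3000) {
    if (overlap >= tileSize || overlap <= 0)
        stop("invalid argument: need 0 < overlap < tileSize")
    if (chromLength <= tileSize) {
        return(new("TileLayout", chromLength = chromLength,
                   tileSize = tileSize, overlap = overlap,
                   tileStart = 0, tileEnd = chromLength,
                   chunkStart = 0, chunkEnd = chromLength))
    }
    step <- tileSize - overlap
    n <- ceiling((chromLength - tileSize) / step) + 1L
    tileStart <- (seq_len(n) - 1) * step
    tileEnd <- tileStart + tileSize
    tileStart[n] <- chromLength - tileSize
    tileEnd[n] <- chromLength
    bnd <- floor((tileStart[-1L] + tileEnd[-n]) / 2)
    chunkStart <- c(0, bnd)
    chunkEnd <- c(bnd, chromLength)
    new("TileLayout", chromLength = chromLength, tileSize = tileSize,
        overlap = overlap, tileStart = tileStart, tileEnd = tileEnd,
        chunkStart = chunkStart, chunkEnd = chunkEnd)
}

#' Number of tiles in a layout
#' @param x a [TileLayout-class] object.
#' @export
setMethod("length", "TileLayout", function(x) length(x@tileStart))

setMethod("show", "TileLayout", function(object) {
    cat("TileLayout:", length(object), "tile(s) over",
        object@chromLength, "bp\n  tileSize:", object@tileSize,
        " overlap:", object@overlap, "\n")
})

#' Tile or chunk intervals as GRanges
#'
#' Converts the internal 0-based half-open bounds to 1-based closed
#' `GRanges` coordinates.
#'
#' @param layout a [TileLayout-class] object.
#' @param chrom chromosome name for the ranges.
#' @param what `"tiles"` or `"chunks"`.
#' @return A `GRanges` object.
#' @export
tileRanges <- function(layout, chrom = "chr", what = c("tiles", "chunks")) {
    what <- match.arg(what)
    if (what == "tiles")
        GenomicRanges::GRanges(chrom,
            IRanges::IRanges(layout@tileStart + 1L, layout@tileEnd))
    else
        GenomicRanges::GRanges(chrom,
            IRanges::IRanges(layout@chunkStart + 1L, layout@chunkEnd))
}
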