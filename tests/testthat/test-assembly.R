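test_that("a single-tile genome reproduces the direct tile fit", {
    cfg <- simConfig(length = 3000, smooths = list(
        occ = list(centers = 1500, widths = 200, heights = 1.5,
                   baseline = log(6))),
        Z = matrix(1, 1, 1, dimnames = list("s1", "occ")),
        sizeFactors = 1, seed = 201)
    sim <- simulateCounts(cfg)
    lay <- makeTiles(3000, 4000, 1000)
    gf <- fitGenome(sim@counts, cfg@Z, lay, sizeFactors = 1,
                    lambda = 50, theta = 5)
    b <- splineBasis(0, 3000, 20)
    m <- tileModel(sim@counts, cfg@Z, b, lambda = 50, theta = 5)
    fit <- newtonFit(m)
    expect_equal(fittedTrack(gf, 1), unname(smoothEstimates(fit)[, 1]),
                 tolerance = 1e-12)
    H <- nbHessian(m, coef(fit))
    v <- smoothVariances(hessianInverseSubset(H),
                         basisMatrix(b, 0:2999), 1)
    expect_equal(seTrack(gf, 1), sqrt(v), tolerance = 1e-10)
})

test_that("joined tracks take each base from its owning chunk", {
    lay <- makeTiles(10000, 4000, 1000)
    set.seed(77)
    Z <- matrix(1, 1, 1)
    fits <- lapply(seq_len(length(lay)), function(t) {
        b <- splineBasis(lay@tileStart[t], lay@tileEnd[t], 20)
        ## different constant level per tile makes ownership visible
        y <- matrix(rpois(4000, 5 * t), 4000, 1)
        newtonFit(tileModel(y, Z, b, lambda = 10, theta = 5))
    })
    out <- joinTiles(fits, lay)
    expect_equal(nrow(out), 10000)
    expect_true(all(is.finite(out)))
    ## base 3499 owned by tile 1, base 3500 by tile 2 (0-based)
    expect_equal(out[3500, 1], smoothEstimates(fits[[1]], 3499)[1, 1])
    expect_equal(out[3501, 1], smoothEstimates(fits[[2]], 3500)[1, 1])
    ## identical fitted functions join seamlessly
    ## epsilon = 0 so a constant fit is exactly in the penalty null space
    cst <- lapply(seq_len(length(lay)), function(t) {
        b <- splineBasis(lay@tileStart[t], lay@tileEnd[t], 20)
        newtonFit(tileModel(matrix(7L, 4000, 1), Z, b, lambda = 10,
                            theta = 5, epsilon = 0))
    })
    joined <- joinTiles(cst, lay)
    expect_lt(max(abs(diff(joined[, 1]))), 1e-7)
    expect_error(joinTiles(fits[1:2], lay), "assembly error")
})

test_that("worker count does not change the assembled fit", {
    cfg <- simConfig(length = 6000, smooths = list(
        occ = list(centers = c(2000, 4500), widths = c(250, 300),
                   heights = c(1.5, 1.0), baseline = log(5))),
        Z = matrix(1, 1, 1, dimnames = list("s1", "occ")),
        sizeFactors = 1, seed = 211)
    sim <- simulateCounts(cfg)
    lay <- makeTiles(6000, 4000, 1000)
    g1 <- fitGenome(sim@counts, cfg@Z, lay, sizeFactors = 1,
                    lambda = 50, theta = 5, workers = 1L)
    g2 <- fitGenome(sim@counts, cfg@Z, lay, sizeFactors = 1,
                    lambda = 50, theta = 5, workers = 2L)
    expect_identical(g1@fit, g2@fit)
    expect_identical(g1@se, g2@se)
})

test_that("hdf5 backend matches the in-memory backend exactly", {
    cfg <- simConfig(length = 5000, smooths = list(
        occ = list(centers = 2500, widths = 300, heights = 1.2,
                   baseline = log(4))),
        Z = matrix(1, 1, 1, dimnames = list("s1", "occ")),
        sizeFactors = 1, seed = 221)
    sim <- simulateCounts(cfg)
    lay <- makeTiles(5000, 3000, 1000)
    gm <- fitGenome(sim@counts, cfg@Z, lay, sizeFactors = 1,
                    lambda = 50, theta = 5, backend = "memory")
    h5 <- tempfile(fileext = ".h5")
    gh <- fitGenome(sim@counts, cfg@Z, lay, sizeFactors = 1,
                    lambda = 50, theta = 5, backend = "hdf5",
                    h5file = h5)
    expect_equal(fittedTrack(gh, 1), unname(fittedTrack(gm, 1)))
    expect_equal(seTrack(gh, 1), unname(seTrack(gm, 1)))
    expect_true(file.exists(h5))
})

test_that("exports round-trip through tsv, hdf5, bigwig and bed", {
    cfg <- simConfig(length = 4000, smooths = list(
        occ = list(centers = 2000, widths = 250, heights = 1.5,
                   baseline = log(5))),
        Z = matrix(1, 1, 1, dimnames = list("s1", "occ")),
        sizeFactors = 1, seed = 231)
    sim <- simulateCounts(cfg)
    gf <- fitGenome(sim@counts, cfg@Z, makeTiles(4000, 3000, 1000),
                    sizeFactors = 1, lambda = 50, theta = 5,
                    chrom = "chrS")
    ## tsv
    tsv <- tempfile(fileext = ".tsv")
    exportTracks(gf, "tsv", tsv)
    df <- read.delim(tsv)
    expect_equal(df$fit_occ, unname(fittedTrack(gf, 1)))
    expect_equal(df$se_occ, unname(seTrack(gf, 1)))
    ## hdf5: bit-identical arrays
    h5 <- tempfile(fileext = ".h5")
    exportTracks(gf, "hdf5", h5)
    back <- rhdf5::h5read(h5, "fit")
    expect_identical(as.vector(back[, 1]), unname(fittedTrack(gf, 1)))
    ## bigwig: probed values equal stored within format precision
    bw <- exportTracks(gf, "bigwig", tempfile())
    imp <- rtracklayer::import(bw[1], as = "NumericList")[[1]]
    expect_lt(max(abs(imp - fittedTrack(gf, 1))), 1e-6)
    ## bed: line count equals the direct per-base count
    bed <- tempfile(fileext = ".bed")
    exportTracks(gf, "bed", bed, smooth = 1, pThreshold = 0.05)
    p <- pointwisePvalues(fittedTrack(gf, 1), seTrack(gf, 1)^2)$p
    expect_equal(length(readLines(bed)), sum(p < 0.05))
    expect_error(exportTracks(gf, "vcf", tempfile()))
})

test_that("mismatched layouts are rejected", {
    counts <- matrix(rpois(2000, 4), 2000, 1)
    expect_error(fitGenome(counts, matrix(1, 1, 1),
                           makeTiles(3000, 2000, 500),
                           lambda = 10, theta = 5),
                 "does not match")
})
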