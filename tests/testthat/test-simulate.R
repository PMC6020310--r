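test_that("simulated counts follow the NB mean-variance law", {
    ## Poisson limit: huge theta
    cfgP <- simConfig(length = 1e5, smooths = list(
        s = list(centers = 0, widths = 1, heights = 0,
                 baseline = log(4))),
        Z = matrix(1, 1, 1), theta = 1e8, sizeFactors = 1, seed = 301)
    y <- simulateCounts(cfgP)@counts[, 1]
    expect_gt(var(y) / mean(y), 0.97)
    expect_lt(var(y) / mean(y), 1.03)

    ## overdispersed: variance mu + mu^2/theta = 4 + 16/2 = 12
    cfgN <- simConfig(length = 1e5, smooths = list(
        s = list(centers = 0, widths = 1, heights = 0,
                 baseline = log(4))),
        Z = matrix(1, 1, 1), theta = 2, sizeFactors = 1, seed = 302)
    y2 <- simulateCounts(cfgN)@counts[, 1]
    expect_lt(abs(var(y2) - 12) / 12, 0.03)

    ## zero-height smooths: constant mean exp(baseline)
    expect_lt(abs(mean(y) - 4) / 4, 0.05)

    ## reproducibility and provenance
    expect_identical(simulateCounts(cfgN)@counts[, 1], y2)
    expect_equal(simulateCounts(cfgN)@config@seed, 302L)
})

test_that("means compose truth, design and size factors exactly", {
    cfg <- simConfig(length = 500, theta = 5, seed = 303)
    sim <- simulateCounts(cfg)
    expect_equal(sim@mu,
                 exp(sweep(sim@truth %*% t(cfg@Z), 2,
                           log(cfg@sizeFactors), "+")),
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_true(all(sim@counts >= 0))
    expect_true(all(sim@counts == floor(sim@counts)))
    expect_error(simConfig(length = 100, theta = -1, seed = 1))
    expect_error(simConfig(length = 100, theta = 5))   # seed mandatory
})

test_that("fragment round trip reproduces interior counts exactly", {
    ## signal confined to the interior so no fragment is boundary-shifted
    cfg <- simConfig(length = 4000, smooths = list(
        s = list(centers = c(1500, 2500), widths = c(150, 200),
                 heights = c(4, 3.5), baseline = -8)),
        Z = matrix(1, 2, 1), theta = 5, sizeFactors = c(1, 1),
        seed = 311)
    sim <- simulateCounts(cfg)
    expect_gt(sum(sim@counts), 0)
    expect_equal(sum(sim@counts[c(1:200, 3801:4000), ]), 0)

    ## paired-end
    fr <- simulateFragments(sim, fragmentLength = 200, dir = tempfile())
    expect_equal(fr$shifted, c(0L, 0L))
    for (j in 1:2) {
        cf <- centerFragments(fr$files[[j]])
        cov <- computeCoverage(cf$centers, 4000)
        expect_identical(as.integer(cov), as.integer(sim@counts[, j]))
    }
    ## mate coordinates consistent with the fragment span
    aln <- GenomicAlignments::readGAlignmentPairs(fr$files[[1]])
    gr <- GenomicRanges::granges(aln)
    expect_true(all(GenomicRanges::width(gr) == 200))

    ## single-end
    frS <- simulateFragments(sim, fragmentLength = 200, paired = FALSE,
                             dir = tempfile())
    cfS <- centerFragments(frS$files[[1]], fragmentLength = 200,
                           paired = FALSE)
    covS <- computeCoverage(cfS$centers, 4000)
    expect_identical(as.integer(covS), as.integer(sim@counts[, 1]))
})

test_that("zero counts produce a valid empty BAM", {
    cfg <- simConfig(length = 1000, smooths = list(
        s = list(centers = 500, widths = 50, heights = 0,
                 baseline = -30)),
        Z = matrix(1, 1, 1), theta = 5, sizeFactors = 1, seed = 321)
    sim <- simulateCounts(cfg)
    expect_equal(sum(sim@counts), 0)
    fr <- simulateFragments(sim, dir = tempfile())
    expect_equal(Rsamtools::countBam(fr$files[[1]])$records, 0)
    hdr <- Rsamtools::scanBamHeader(fr$files[[1]])[[1]]$targets
    expect_equal(unname(hdr["chrS"]), 1000L, ignore_attr = TRUE)
})

test_that("TSV count tracks round-trip", {
    cfg <- simConfig(length = 300, theta = 5, seed = 331)
    sim <- simulateCounts(cfg)
    f <- tempfile(fileext = ".tsv")
    writeCountsTSV(sim, f)
    back <- readCountsTSV(f)
    expect_equal(unname(back), unname(sim@counts))
})

test_that("log-fold-change recovery improves with coverage", {
    rmse <- vapply(c(1, 8, 64), function(base) {
        L <- 2000
        cfg <- simConfig(length = L, smooths = list(
            control = list(centers = L * c(0.3, 0.7),
                           widths = L * c(0.06, 0.05),
                           heights = c(1.2, 0.8), baseline = log(base)),
            lfc = list(centers = L * 0.5, widths = L * 0.06,
                       heights = 1.0, baseline = 0)),
            Z = rbind(c(1, 0), c(1, 1)), theta = 5,
            sizeFactors = c(1, 1), seed = 401)
        sim <- simulateCounts(cfg)
        b <- splineBasis(0, L, 20)
        m <- tileModel(sim@counts, cfg@Z, b, sizeFactors = c(1, 1),
                       lambda = 100, theta = 5)
        fit <- newtonFit(m)
        est <- smoothEstimates(fit)
        sqrt(mean((est[, 2] - sim@truth[, 2])^2))
    }, numeric(1))
    expect_true(all(diff(rmse) < 0))
})
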