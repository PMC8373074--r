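test_that("gene placement is deterministic, non-overlapping and capacity-checked", {
    gg <- genGenomeAndGenes(1, 1e6, 50, minSpacing = 2000, seed = 7)
    expect_length(gg$genes, 50L)
    expect_identical(gg$genes, genGenomeAndGenes(1, 1e6, 50,
                                                 minSpacing = 2000, seed = 7)$genes)
    # pairwise non-overlap with at least the configured spacing between genes
    o <- order(start(gg$genes))
    gaps <- start(gg$genes)[o][-1] - end(gg$genes)[o][-50]
    expect_true(all(gaps > 2000))
    # strand counts are fixed by the seeded stream (run-once regression fixture)
    expect_equal(as.vector(table(as.character(strand(gg$genes)))[c("+", "-")]),
                 c(24L, 26L))
    expect_error(genGenomeAndGenes(1, 1e3, 500, seed = 1), "cannot place")
})

test_that("genes spread over multiple chromosomes on both strands", {
    gg <- genGenomeAndGenes(3, c(4e5, 2e5, 2e5), 60, seed = 3)
    expect_setequal(as.character(GenomeInfoDb::seqnames(gg$genome)),
                    c("chr1", "chr2", "chr3"))
    expect_length(gg$genes, 60L)
    expect_true(all(c("+", "-") %in% as.character(strand(gg$genes))))
})

test_that("planted landscape follows the Gaussian valley formula", {
    g <- one_gene()
    genome <- tiny_genome(chr1 = 50000L)
    ls <- plantCompactionLandscape(genome, g, baseline = 0.8,
                                   valleyDepth = 0.8, valleyWidth = 100)
    v <- landscapeValues(ls)$chr1
    tss <- 20001L
    expect_equal(as.numeric(v[tss]), 0)                       # center reaches baseline - depth
    expect_equal(as.numeric(v[tss + 100L]),
                 0.8 - 0.8 * exp(-0.5), tolerance = 1e-12)    # value at one sigma
    expect_equal(as.numeric(v[1]), 0.8)                       # far away: baseline
    flat <- plantCompactionLandscape(genome, g, baseline = 0.8,
                                     valleyDepth = 0, valleyWidth = 100)
    expect_equal(unique(as.numeric(S4Vectors::runValue(landscapeValues(flat)$chr1))), 0.8)
    expect_error(plantCompactionLandscape(genome, g, baseline = 0.5,
                                          valleyDepth = 0.9),
                 "depths must lie")
})

test_that("expression link has the stated closed form and monotonicity", {
    genome <- tiny_genome(chr1 = 50000L)
    g <- one_gene()
    # c(TSS) = 1: fully compact, tpm floors at 0
    lsC <- plantCompactionLandscape(genome, g, baseline = 1, valleyDepth = 0)
    e1 <- simulateExpression(g, lsC, interceptA = 2.5, slopeB = 2.5,
                             noiseSd = 0, seed = 1)
    expect_equal(e1$tpm, 0)
    # c(TSS) = 0: fully open
    lsO <- plantCompactionLandscape(genome, g, baseline = 0.8, valleyDepth = 0.8)
    e0 <- simulateExpression(g, lsO, interceptA = 2.5, slopeB = 2.5,
                             noiseSd = 0, seed = 1)
    expect_equal(e0$tpm, 10^2.5 - 1, tolerance = 1e-12)
    # noise-free monotonicity: more open TSS transcribes at least as much
    gg <- genGenomeAndGenes(1, 2e5, 20, seed = 5)
    ls <- plantCompactionLandscape(gg$genome, gg$genes,
                                   depthRange = c(0.1, 0.8), seed = 5)
    ex <- simulateExpression(gg$genes, ls, noiseSd = 0, seed = 5)
    cT <- compactionAt(ls, gg$genes)
    expect_true(all(diff(ex$tpm[order(cT)]) <= 1e-9))
})

test_that("sedimentation model is a proper monotone categorical family", {
    m <- binomialSedimentation()
    grid <- seq(0, 1, by = 0.01)
    p <- fractionProbabilities(m, grid)
    expect_equal(rowSums(p), rep(1, length(grid)))
    expect_true(all(p >= 0))
    expect_true(all(diff(expectedFraction(m, grid)) > 0))
    expect_equal(expectedFraction(m, c(0, 0.5, 1)), c(1, 3, 5))
    # endpoint determinism
    expect_equal(fractionProbabilities(m, 0)[1, ], c(1, 0, 0, 0, 0),
                 ignore_attr = TRUE)
    expect_equal(fractionProbabilities(m, 1)[1, ], c(0, 0, 0, 0, 1),
                 ignore_attr = TRUE)
    # a broken model is rejected by the validity method
    expect_error(methods::validObject(methods::new("SedimentationModel",
        name = "bad",
        probFun = function(c) matrix(0.3, nrow = length(c), ncol = 5))),
        "sum to 1")
})

test_that("fragments at landscape extremes land in the extreme fractions", {
    genome <- tiny_genome(chr1 = 20000L)
    g <- one_gene(20000L, 5001L, 8000L)
    open <- plantCompactionLandscape(genome, g, baseline = 0, valleyDepth = 0)
    fo <- simulateFractionFragments(genome, open, nFragments = 2000, seed = 2)
    expect_true(all(fo$fraction == 1L))
    compact <- plantCompactionLandscape(genome, g, baseline = 1, valleyDepth = 0)
    fc <- simulateFractionFragments(genome, compact, nFragments = 2000, seed = 2)
    expect_true(all(fc$fraction == 5L))
})

test_that("fragment simulation conserves counts, bounds, lengths and seed", {
    genome <- tiny_genome(chr1 = 50000L)
    g <- one_gene()
    ls <- plantCompactionLandscape(genome, g, valleyDepth = 0.5)
    fr <- simulateFractionFragments(genome, ls, nFragments = 5000,
                                    lengthRange = c(300, 500), seed = 9)
    expect_length(fr, 5000L)                     # conservation before thinning
    expect_true(all(start(fr) >= 1L & end(fr) <= 50000L))
    expect_true(all(width(fr) >= 300L & width(fr) <= 500L))
    expect_true(all(fr$fraction %in% 1:5))
    expect_identical(fr, simulateFractionFragments(genome, ls,
                                                   nFragments = 5000,
                                                   lengthRange = c(300, 500),
                                                   seed = 9))
    # thinning removes only fragments of the biased fractions
    thin <- simulateFractionFragments(genome, ls, nFragments = 5000,
                                      recoveryBias = c(1, 1, 1, 1, 0.2),
                                      seed = 9)
    expect_lt(length(thin), 5000L)
})

test_that("planted compaction is recoverable from fraction proportions", {
    # ML inverse of the binomial model at a fixed position:
    # c_hat = (mean fraction - 1) / 4, within 3 * sqrt(c(1-c)/(4n))
    genome <- tiny_genome(chr1 = 30000L)
    g <- one_gene(30000L, 10001L, 13000L)
    for (cc in c(0.3, 0.7)) {
        ls <- plantCompactionLandscape(genome, g, baseline = cc, valleyDepth = 0)
        fr <- simulateFractionFragments(genome, ls, nFragments = 50000, seed = 4)
        cover <- fr[start(fr) <= 15000 & end(fr) >= 15000]
        n <- length(cover)
        chat <- (mean(cover$fraction) - 1) / 4
        expect_lt(abs(chat - cc), 3 * sqrt(cc * (1 - cc) / (4 * n)))
    }
})

test_that("MNase occupancy plants exact valleys and recoverable NFR depths", {
    genome <- tiny_genome(chr1 = 50000L)
    g <- one_gene()
    mn <- simulateMnaseOccupancy(genome, g, baselineOcc = 0.8, nfrDepth = 0.6,
                                 valleyWidth = 60, noiseSd = 0, seed = 1)
    expect_equal(as.numeric(mn$track$chr1[20001L]), 0.2)   # baseline - depth at center
    flat <- simulateMnaseOccupancy(genome, g, baselineOcc = 0.8, nfrDepth = 0,
                                   noiseSd = 0, seed = 1)
    expect_equal(unique(as.numeric(S4Vectors::runValue(flat$track$chr1))), 0.8)
    # downstream nfrDepth recovers the planted depth (noise 0: up to Gaussian tails)
    w <- anchorWindows(g, "TSS")
    expect_equal(nfrDepth(mn$track, w)$nfrDepth, 0.6, tolerance = 1e-3)
    expect_error(simulateMnaseOccupancy(genome, g, baselineOcc = 0.5,
                                        nfrDepth = 0.9, seed = 1),
                 "depths must lie")
})

test_that("RNAP track peaks at TSSs with height increasing with openness", {
    gg <- genGenomeAndGenes(1, 3e5, 10, seed = 2)
    ls <- plantCompactionLandscape(gg$genome, gg$genes,
                                   depthRange = c(0.1, 0.8), seed = 2)
    tr <- simulateRnapTrack(gg$genome, gg$genes, ls, noiseSd = 0)
    w <- anchorWindows(gg$genes, "TSS")
    lev <- regionStats(tr, w)$meanValue
    cT <- compactionAt(ls, gg$genes)[match(w$gene_id, gg$genes$gene_id)]
    expect_lt(cor(lev, cT), -0.9)   # open TSSs bind more polymerase
})

test_that("repeats and TADs respect genome bounds; TADs tile each chromosome", {
    genome <- tiny_genome(chr1 = 1e5L, chr2 = 5e4L)
    rep <- simulateRepeats(genome, nRepeats = 200, seed = 6)
    expect_true(all(start(rep) >= 1L))
    expect_true(all(end(rep) <= GenomeInfoDb::seqlengths(genome)[
        as.character(GenomicRanges::seqnames(rep))]))
    tads <- simulateTads(genome, nTads = 5, seed = 6)
    for (chr in c("chr1", "chr2")) {
        tt <- tads[GenomicRanges::seqnames(tads) == chr]
        expect_length(tt, 5L)
        expect_equal(sum(width(tt)),
                     unname(GenomeInfoDb::seqlengths(genome)[chr]))
        expect_true(all(start(tt)[-1] == end(tt)[-5] + 1L))
    }
})
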