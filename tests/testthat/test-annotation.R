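test_that("TSS/TES windows follow the strand-aware upstream convention", {
    # + strand gene at BED start 10000: TSS window is BED [9750, 10000)
    gp <- one_gene(50000L, 10001L, 12000L, "+")
    w <- anchorWindows(gp, "TSS")
    expect_equal(start(w), 9751L)
    expect_equal(end(w), 10000L)
    # - strand gene ending at BED 20000: TSS window is BED [20000, 20250)
    gm <- one_gene(50000L, 18001L, 20000L, "-")
    wm <- anchorWindows(gm, "TSS")
    expect_equal(start(wm), 20001L)
    expect_equal(end(wm), 20250L)
    # TES windows mirror the rule downstream of transcription
    expect_equal(c(start(anchorWindows(gp, "TES")), end(anchorWindows(gp, "TES"))),
                 c(12001L, 12250L))
    expect_equal(c(start(anchorWindows(gm, "TES")), end(anchorWindows(gm, "TES"))),
                 c(17751L, 18000L))
    # window running off the chromosome start is clipped with a warning
    gEdge <- one_gene(50000L, 101L, 2000L, "+")
    expect_warning(wc <- anchorWindows(gEdge, "TSS"), "clipped")
    expect_equal(c(start(wc), end(wc)), c(1L, 100L))
    gStar <- gp
    strand(gStar) <- "*"
    expect_error(anchorWindows(gStar, "TSS"), "strand")
})

test_that("repeat filtering equals the brute-force all-pairs overlap test", {
    # printed example: repeat [250,260) removes only the second window
    w <- GRanges("chr1", IRanges(c(1, 201), c(100, 300)), gene_id = c("a", "b"))
    rep <- GRanges("chr1", IRanges(251, 260))
    expect_equal(filterRepeatOverlap(w, rep)$gene_id, "a")
    # empty repeat set: identity
    expect_identical(filterRepeatOverlap(w, rep[0]), w)
    # half-open convention: abutting intervals share no base
    wAb <- GRanges("chr1", IRanges(1, 100), gene_id = "a")
    repAb <- GRanges("chr1", IRanges(101, 110))
    expect_length(filterRepeatOverlap(wAb, repAb), 1L)
    # randomized equivalence with a vectorized O(n*m) oracle
    set.seed(13)
    for (i in 1:3) {
        n <- 1000; m <- 1000
        ws <- sample.int(1e5, n); rs <- sample.int(1e5, m)
        wg <- GRanges("chr1", IRanges(ws, width = sample(50:500, n, TRUE)),
                      gene_id = as.character(seq_len(n)))
        rg <- GRanges("chr1", IRanges(rs, width = sample(50:500, m, TRUE)))
        hit <- outer(start(wg), end(rg), "<=") & outer(end(wg), start(rg), ">=")
        keepOracle <- rowSums(hit) == 0
        expect_equal(filterRepeatOverlap(wg, rg)$gene_id,
                     as.character(which(keepOracle)))
    }
})

test_that("region stats give window means and rcpm by definition", {
    tr <- mk_track(chr1 = c(1, 1, 2, 1, 0))
    # window BED [1,4): bases 2..4 in 1-based coordinates
    w <- GRanges("chr1", IRanges(2, 4))
    expect_equal(regionStats(tr, w)$meanValue, 4 / 3)
    # constant track: mean is the constant for any window
    trc <- mk_track(chr1 = rep(2.5, 100))
    expect_equal(regionStats(trc, GRanges("chr1", IRanges(11, 60)))$meanValue, 2.5)
    # rcpm: overlapping fragments per million mapped
    frags <- GRanges("chr1", IRanges(c(1, 2, 90), c(3, 5, 95)))
    rc <- regionStats(mk_track(chr1 = rep(0, 100)),
                      GRanges("chr1", IRanges(2, 4)),
                      fragments = frags, totalMapped = 1e6)
    expect_equal(rc$rcpm, 2.0)
    expect_error(regionStats(tr, GRanges("chr1", IRanges(5, 4))), "zero-length")
})

test_that("window-mean scores are invariant under coordinate mirroring", {
    # reversing the chromosome and flipping strands must not change
    # any TSS/TES window mean
    set.seed(21)
    L <- 10000L
    vals <- runif(L)
    genome <- tiny_genome(chr1 = L)
    gg <- genGenomeAndGenes(1, L, 3, geneLengthRange = c(500, 800),
                            minSpacing = 600, seed = 8)
    tr <- mk_track(chr1 = vals)
    w <- anchorWindows(gg$genes, "TSS")
    m <- regionStats(tr, w)$meanValue
    # mirrored system: position p -> L + 1 - p, strands flipped
    gmir <- GRanges("chr1", IRanges(L + 1L - end(gg$genes),
                                    L + 1L - start(gg$genes)),
                    strand = ifelse(as.character(strand(gg$genes)) == "+",
                                    "-", "+"),
                    gene_id = gg$genes$gene_id)
    GenomeInfoDb::seqlengths(gmir) <- L
    trmir <- mk_track(chr1 = rev(vals))
    wmir <- anchorWindows(gmir, "TSS")
    mmir <- regionStats(trmir, wmir)$meanValue
    expect_equal(mmir, m, tolerance = 1e-12)
})

test_that("metagene proportions are normalized, symmetric and scale-free", {
    gg <- genGenomeAndGenes(1, 1e5, 5, geneLengthRange = c(1000, 2000),
                            minSpacing = 2500, seed = 15)
    set.seed(15)
    base <- runif(1e5) + 0.5
    # five identical tracks: every proportion must be exactly 1/5
    tracks <- lapply(1:5, function(f) mk_track(chr1 = base))
    mp <- metageneProfile(tracks, gg$genes, flankBp = 1000, bodyBins = 20,
                          flankBins = 10)
    pp <- profileProportions(mp)
    expect_equal(dim(pp), c(5L, 40L))
    expect_true(all(abs(pp - 0.2) < 1e-12))
    # distinct tracks: columns with signal sum to one
    tracks2 <- lapply(1:5, function(f) mk_track(chr1 = base * f + f))
    mp2 <- metageneProfile(tracks2, gg$genes, flankBp = 1000, bodyBins = 20,
                           flankBins = 10)
    expect_equal(colSums(profileProportions(mp2)), rep(1, 40))
    # common rescaling of all five tracks changes nothing
    tracks3 <- lapply(tracks2, function(t) t * 7)
    mp3 <- metageneProfile(tracks3, gg$genes, flankBp = 1000, bodyBins = 20,
                           flankBins = 10)
    expect_equal(profileProportions(mp3), profileProportions(mp2),
                 tolerance = 1e-12)
})

test_that("metagene skips genes shorter than the bin resolution", {
    genome <- tiny_genome(chr1 = 50000L)
    short <- GRanges("chr1", IRanges(c(10001, 20001), c(10030, 22000)),
                     strand = "+", gene_id = c("s", "l"),
                     tpm = c(1, 1))
    GenomeInfoDb::seqlengths(short) <- 50000L
    tracks <- lapply(1:5, function(f) mk_track(chr1 = rep(1, 50000)))
    expect_message(mp <- metageneProfile(tracks, short, bodyBins = 100),
                   "skipped")
    expect_equal(mp@nGenes, 1L)
})
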