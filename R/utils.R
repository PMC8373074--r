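# Internal helpers shared across modules.

# Check two RleList tracks describe the same genome (names and lengths).
.checkSameGenome <- function(a, b) {
    if (!identical(names(a), names(b)) ||
        !identical(as.numeric(lengths(a)), as.numeric(lengths(b))))
        stop("tracks cover different chromosomes or lengths")
    invisible(TRUE)
}

# Genome-wide total signal of a track.
.totalSignal <- function(track) {
    sum(vapply(track, function(v) sum(as.numeric(runValue(v)) *
                                      as.numeric(runLength(v))), numeric(1)))
}

# Apply an RleViews summary (viewMeans/viewMins/viewMaxs) over the windows of
# a GRanges, preserving input order. Windows must lie within the track.
.trackViews <- function(track, gr, fun) {
    sn <- as.character(GenomicRanges::seqnames(gr))
    if (!all(sn %in% names(track)))
        stop("windows reference chromosomes absent from the track")
    out <- numeric(length(gr))
    for (chr in unique(sn)) {
        i <- which(sn == chr)
        len <- length(track[[chr]])
        if (any(start(gr)[i] < 1L) || any(end(gr)[i] > len))
            stop("window outside track bounds on ", chr)
        v <- Views(track[[chr]], start = start(gr)[i], end = end(gr)[i])
        out[i] <- fun(v)
    }
    out
}

.trackMeans <- function(track, gr) .trackViews(track, gr, viewMeans)

# Decode one chromosome of a track and return c(0, cumsum(values)), so the
# mean over [s, e] (1-based, closed) is (cs[e + 1] - cs[s]) / (e - s + 1).
.cumsumTrack <- function(rle) c(0, cumsum(as.numeric(rle)))

.intervalMeans <- function(cs, s, e) (cs[e + 1] - cs[s]) / (e - s + 1)

# Strand-aware TSS base (1-based) of each gene.
.tssPosition <- function(genes) {
    st <- as.character(strand(genes))
    if (any(!st %in% c("+", "-")))
        stop("gene strand must be '+' or '-'")
    ifelse(st == "+", start(genes), end(genes))
}

# Plant Gaussian valleys on a constant-baseline per-chromosome vector set.
# Overlapping valleys combine by pointwise maximum deficit, which keeps the
# result within [baseline - max depth, baseline].
.plantValleys <- function(genome, centers, chroms, baseline, depths, width) {
    lens <- GenomeInfoDb::seqlengths(genome)
    vecs <- lapply(lens, function(L) rep(baseline, L))
    half <- ceiling(6 * width)
    for (i in seq_along(centers)) {
        chr <- chroms[i]
        L <- lens[[chr]]
        lo <- max(1L, centers[i] - half)
        hi <- min(L, centers[i] + half)
        idx <- lo:hi
        deficit <- depths[i] * exp(-((idx - centers[i])^2) / (2 * width^2))
        vecs[[chr]][idx] <- pmin(vecs[[chr]][idx], baseline - deficit)
    }
    as(lapply(vecs, Rle), "RleList")
}

# Derive n well-separated stage seeds from one master seed. Consecutive
# integer seeds give noticeably correlated Mersenne-Twister streams, so
# stage seeds are drawn from a master stream instead.
.stageSeeds <- function(seed, n) {
    withr::with_seed(as.integer(seed),
                     sample.int(.Machine$integer.max - 1L, n))
}

# Empty zero track over a genome.
.zeroTrack <- function(genome) {
    lens <- GenomeInfoDb::seqlengths(genome)
    as(lapply(lens, function(L) Rle(0, L)), "RleList")
}
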