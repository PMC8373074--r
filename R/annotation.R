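#' Strand-aware TSS/TES anchor windows
#'
#' TSS windows cover the \code{size} bases immediately upstream of, and
#' excluding, the transcription start base: for a + strand gene starting at
#' BED coordinate s the window is [s-250, s) (0-based half-open), mirrored
#' for - strand genes. TES windows apply the same rule reflected at the
#' transcription end: the \code{size} bases immediately downstream of the
#' last transcribed base. Windows running off a chromosome end are clipped
#' with a warning; windows clipped to zero width are dropped.
#'
#' @param genes gene \code{GRanges} with strand + or - and a \code{gene_id}
#'   column; \code{seqlengths} must be set for clipping.
#' @param kind \code{"TSS"} or \code{"TES"}.
#' @param size window width in bp (default 250).
#' @return a \code{GRanges} of windows with \code{gene_id} and
#'   \code{anchor} metadata columns, parallel to \code{genes} up to dropped
#'   zero-width windows.
#' @examples
#' gn <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10001, 12000),
#'                              strand = "+", gene_id = "g1")
#' GenomeInfoDb::seqlengths(gn) <- 50000
#' anchorWindows(gn, "TSS")   # chr1:9751-10000, i.e. BED [9750, 10000)
#' @export
anchorWindows <- function(genes, kind = c("TSS", "TES"), size = 250L) {
    kind <- match.arg(kind)
    st <- as.character(strand(genes))
    if (any(!st %in% c("+", "-")))
        stop("gene strand must be '+' or '-'")
    w <- if (kind == "TSS")
        suppressWarnings(promoters(genes, upstream = size, downstream = 0L))
    else
        suppressWarnings(flank(genes, width = size, start = FALSE))
    mcols(w) <- DataFrame(gene_id = genes$gene_id, anchor = kind)
    trimmed <- suppressWarnings(trim(w))
    nClipped <- sum(width(trimmed) < size)
    if (nClipped > 0)
        warning(nClipped, " ", kind,
                " window(s) clipped at chromosome bounds")
    trimmed[width(trimmed) > 0L]
}

#' Drop windows overlapping repeats
#'
#' Keeps a window if and only if it shares no base with any repeat interval
#' (the half-open overlap test of \code{intersectBed -v}): abutting
#' intervals do not overlap.
#'
#' @param windows a \code{GRanges} of windows.
#' @param repeats a \code{GRanges} of repeat intervals.
#' @return the surviving windows, original order preserved.
#' @export
filterRepeatOverlap <- function(windows, repeats) {
    subsetByOverlaps(windows, repeats, invert = TRUE, ignore.strand = TRUE)
}

#' Window statistics on a track
#'
#' For each window returns the arithmetic mean track value over its bases
#' and, when fragments are supplied, the read count per million mapped
#' (rcpm): the number of fragments overlapping the window, scaled by 1e6
#' over the total mapped fragment count.
#'
#' @param track an \code{RleList} (depth or score).
#' @param windows a \code{GRanges}; zero-width windows are an error.
#' @param fragments optional \code{GRanges} of all mapped fragments.
#' @param totalMapped total mapped fragment count for the rcpm denominator;
#'   defaults to \code{length(fragments)}.
#' @return a \code{DataFrame} with \code{gene_id} (if present),
#'   \code{meanValue} and \code{rcpm} (NA without fragments).
#' @export
regionStats <- function(track, windows, fragments = NULL,
                        totalMapped = length(fragments)) {
    if (any(width(windows) == 0L))
        stop("zero-length window")
    m <- .trackMeans(track, windows)
    rcpm <- rep(NA_real_, length(windows))
    if (!is.null(fragments)) {
        if (totalMapped <= 0) stop("totalMapped must be positive")
        rcpm <- countOverlaps(windows, fragments,
                              ignore.strand = TRUE) * 1e6 / totalMapped
    }
    out <- DataFrame(meanValue = m, rcpm = rcpm)
    if (!is.null(windows$gene_id))
        out <- DataFrame(gene_id = windows$gene_id, out)
    out
}

#' Metagene fractional-proportion profile over gene bodies
#'
#' Averages the five normalized fraction tracks over a metagene axis: a
#' fixed-scale upstream flank, the gene body linearly rescaled to
#' \code{bodyBins} bins, and a fixed-scale downstream flank, oriented so the
#' TSS is always on the left. Per bin, the fractional proportion of each
#' fraction is its mean depth divided by the sum over the five fractions,
#' so columns with signal sum to 1; multiplying all tracks by a common
#' constant leaves the profile unchanged. Genes shorter than
#' \code{bodyBins} bases are skipped (count reported via \code{message}).
#'
#' @param tracks list of five \code{RleList} depth tracks (Fr-1..Fr-5),
#'   normalized per fraction.
#' @param genes gene \code{GRanges}.
#' @param flankBp flank width in bp (default 2000).
#' @param bodyBins,flankBins bin counts for the body and each flank.
#' @return a \code{\linkS4class{MetageneProfile}}.
#' @export
metageneProfile <- function(tracks, genes, flankBp = 2000L,
                            bodyBins = 100L, flankBins = 40L) {
    stopifnot(length(tracks) == 5L)
    for (f in 2:5) .checkSameGenome(tracks[[1]], tracks[[f]])
    st <- as.character(strand(genes))
    if (any(!st %in% c("+", "-")))
        stop("gene strand must be '+' or '-'")
    keep <- width(genes) >= bodyBins
    if (any(!keep))
        message(sum(!keep), " gene(s) shorter than ", bodyBins,
                " bp skipped in metagene profile")
    genes <- genes[keep]
    st <- st[keep]
    if (length(genes) == 0L) stop("no gene long enough to profile")
    B <- as.integer(bodyBins + 2L * flankBins)
    lens <- GenomeInfoDb::seqlengths(seqinfo(genes))
    cs <- lapply(names(lens)[names(lens) %in% as.character(seqnames(genes))],
                 function(chr) lapply(tracks, function(t) .cumsumTrack(t[[chr]])))
    names(cs) <- names(lens)[names(lens) %in% as.character(seqnames(genes))]
    depth <- matrix(0, nrow = 5L, ncol = B)
    sn <- as.character(seqnames(genes))
    for (i in seq_along(genes)) {
        L <- lens[[sn[i]]]
        s <- start(genes)[i]; e <- end(genes)[i]
        # bin edges in genomic coordinates, 5' flank / body / 3' flank
        upEdges <- floor(seq(s - 1L - flankBp, s - 1L, length.out = flankBins + 1L))
        bodyEdges <- floor(seq(s - 1L, e, length.out = bodyBins + 1L))
        dnEdges <- floor(seq(e, e + flankBp, length.out = flankBins + 1L))
        edges <- c(upEdges, bodyEdges[-1L], dnEdges[-1L])
        bs <- edges[-length(edges)] + 1L
        be <- edges[-1L]
        ok <- bs >= 1L & be <= L & be >= bs
        if (st[i] == "-") {
            # reverse genomic bin order so the TSS sits on the left
            bs <- rev(bs); be <- rev(be); ok <- rev(ok)
        }
        cc <- cs[[sn[i]]]
        for (f in 1:5) {
            mv <- rep(0, B)
            mv[ok] <- .intervalMeans(cc[[f]], bs[ok], be[ok])
            depth[f, ] <- depth[f, ] + mv
        }
    }
    depth <- depth / length(genes)
    tot <- colSums(depth)
    prop <- sweep(depth, 2L, tot, "/")
    prop[, tot <= 0] <- NA_real_
    rownames(prop) <- rownames(depth) <- paste0("Fr-", 1:5)
    new("MetageneProfile", proportions = prop, meanDepth = depth,
        bodyBins = as.integer(bodyBins), flankBins = as.integer(flankBins),
        flankBp = as.integer(flankBp), nGenes = length(genes))
}

#' @describeIn metageneProfile the 5 x bins proportion matrix.
#' @param x a \code{MetageneProfile}.
#' @export
setMethod("profileProportions", "MetageneProfile",
    function(x) x@proportions)
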