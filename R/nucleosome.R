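#' Nucleosome-free-region depth at TSS windows
#'
#' The NFR depth of a gene is the distance between the lowest and highest
#' nucleosome occupancy within its TSS window (-250 bp to 0): simply
#' max - min of the per-base occupancy values, with no smoothing. Adding a
#' constant to the track leaves it unchanged; scaling the track scales it
#' linearly.
#'
#' @param occupancy an \code{RleList} MNase occupancy track (normalized
#'   upstream; units are arbitrary).
#' @param windows TSS window \code{GRanges} (see
#'   \code{\link{anchorWindows}}); zero-width windows are an error.
#' @return a \code{DataFrame} with \code{gene_id} (if present),
#'   \code{minOcc}, \code{maxOcc} and \code{nfrDepth = maxOcc - minOcc}.
#' @export
nfrDepth <- function(occupancy, windows) {
    if (any(width(windows) == 0L))
        stop("zero-length window")
    mn <- .trackViews(occupancy, windows, viewMins)
    mx <- .trackViews(occupancy, windows, viewMaxs)
    out <- DataFrame(minOcc = mn, maxOcc = mx, nfrDepth = mx - mn)
    if (!is.null(windows$gene_id))
        out <- DataFrame(gene_id = windows$gene_id, out)
    out
}

#' Mean occupancy curve around TSSs
#'
#' Averages occupancy over [TSS - flank, TSS + flank) across genes,
#' strand-aware (transcription always runs left to right), in \code{nBins}
#' equal-width bins. Genes whose window would run outside the chromosome
#' are skipped with a warning.
#'
#' @param occupancy an \code{RleList} occupancy track.
#' @param genes gene \code{GRanges}.
#' @param flank half-window in bp (default 1000).
#' @param nBins number of bins across the 2*flank window.
#' @return numeric vector of per-bin mean occupancy, with bin-center
#'   offsets relative to the TSS as names.
#' @export
tssOccupancyCurve <- function(occupancy, genes, flank = 1000L,
                              nBins = 100L) {
    st <- as.character(strand(genes))
    if (any(!st %in% c("+", "-")))
        stop("gene strand must be '+' or '-'")
    if ((2L * flank) %% nBins != 0L)
        stop("2*flank must be a multiple of nBins")
    bw <- (2L * flank) %/% nBins
    tss <- .tssPosition(genes)
    sn <- as.character(seqnames(genes))
    lens <- GenomeInfoDb::seqlengths(seqinfo(genes))
    inside <- tss - flank >= 1L & tss + flank - 1L <= lens[sn]
    if (any(!inside))
        warning(sum(!inside), " gene(s) with out-of-bounds TSS window skipped")
    if (!any(inside)) stop("no usable gene")
    genes <- genes[inside]; st <- st[inside]; tss <- tss[inside]; sn <- sn[inside]
    cs <- lapply(unique(sn), function(chr) .cumsumTrack(occupancy[[chr]]))
    names(cs) <- unique(sn)
    acc <- numeric(nBins)
    for (i in seq_along(genes)) {
        bs <- tss[i] - flank + bw * (seq_len(nBins) - 1L)
        be <- bs + bw - 1L
        mv <- .intervalMeans(cs[[sn[i]]], bs, be)
        if (st[i] == "-") mv <- rev(mv)
        acc <- acc + mv
    }
    curve <- acc / length(genes)
    names(curve) <- -flank + bw * (seq_len(nBins) - 1L) + bw / 2
    curve
}
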