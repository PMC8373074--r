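#' Per-base coverage from fragment intervals
#'
#' Depth at base p is the number of fragments whose interval contains p.
#'
#' @param fragments a \code{GRanges}, optionally with a \code{fraction}
#'   metadata column.
#' @param genome a \code{Seqinfo} fixing chromosome names and lengths.
#' @param fraction if given, restrict to fragments of this gradient
#'   fraction (1..5) before computing coverage.
#' @return an \code{RleList} with one full-length vector per chromosome.
#' @export
coverageFromFragments <- function(fragments, genome, fraction = NULL) {
    if (!is.null(fraction)) {
        if (is.null(fragments$fraction))
            stop("fragments carry no 'fraction' column")
        fragments <- fragments[fragments$fraction == fraction]
    }
    lens <- GenomeInfoDb::seqlengths(genome)
    sn <- as.character(seqnames(fragments))
    if (!all(sn %in% names(lens)))
        stop("fragments reference chromosomes absent from the genome")
    bad <- which(start(fragments) < 1L | end(fragments) > lens[sn])
    if (length(bad))
        stop("fragment out of chromosome bounds: record ", bad[1L], " (",
             sn[bad[1L]], ":", start(fragments)[bad[1L]], "-",
             end(fragments)[bad[1L]], ")")
    seqinfo(fragments) <- genome
    coverage(fragments)
}

#' Normalize a coverage track to a target wigsum
#'
#' Rescales the track so its genome-wide total signal equals the configured
#' wigsum, then multiplies by the fraction's recovery factor (the amount of
#' DNA recovered from that gradient fraction). Both steps are linear and
#' applied in this order. A track with no signal is returned unchanged with
#' a warning.
#'
#' @param track an \code{RleList} coverage track.
#' @param params a \code{\link{normalizationParams}} object.
#' @param fraction which fraction's recovery factor to apply (1..5).
#' @return the normalized \code{RleList}.
#' @export
normalizeTrack <- function(track, params = normalizationParams(),
                           fraction = 1L) {
    stopifnot(is(params, "NormalizationParams"),
              fraction %in% 1:5)
    total <- .totalSignal(track)
    if (total <= 0) {
        warning("track has no signal; returned unchanged")
        return(track)
    }
    track * (params@wigsum / total * params@recovery[fraction])
}

#' Fr-5/Fr-1 compaction score track
#'
#' The central statistic: per base,
#' \deqn{score(p) = \log_2\frac{d_5(p) + \epsilon}{d_1(p) + \epsilon}}
#' where \eqn{d_1, d_5} are the normalized Fr-1 and Fr-5 depths and
#' \eqn{\epsilon} (default 0.001) keeps the ratio finite where either track
#' is zero. Very negative scores mark locally open chromatin; scores near
#' zero (equal representation in both fractions) mark compact chromatin.
#' Swapping the inputs negates the score at every base.
#'
#' @param fr1,fr5 normalized \code{RleList} depth tracks covering identical
#'   chromosomes.
#' @param epsilon positive offset applied once to each track.
#' @return an \code{RleList} of per-base scores, finite everywhere.
#' @export
compactionScore <- function(fr1, fr5, epsilon = 0.001) {
    stopifnot(epsilon > 0)
    .checkSameGenome(fr1, fr5)
    log2((fr5 + epsilon) / (fr1 + epsilon))
}

#' Five-class compaction binning of a score track
#'
#' Assigns every base to one of five classes delimited by the four bin
#' edges: class 1 (most open) holds scores below the first edge, class 5
#' (most compact) scores at or above the last; class k covers
#' [edge_{k-1}, edge_k). Also reports the percentage of the genome scoring
#' strictly above \code{openThreshold} (default -3.5), the conventional cut
#' separating the broadly compact genome from locally open chromatin.
#'
#' @param score an \code{RleList} score track.
#' @param bins a \code{\link{compactionBins}} object.
#' @param openThreshold score threshold for the compact-genome percentage.
#' @return list with \code{classes} (integer \code{RleList}),
#'   \code{percentages} (named length-5 numeric summing to 100),
#'   \code{pctAboveThreshold} and \code{threshold}.
#' @export
classifyCompaction <- function(score, bins = compactionBins(),
                               openThreshold = -3.5) {
    stopifnot(is(bins, "CompactionBins"))
    edges <- bins@edges
    counts <- numeric(5)
    above <- 0
    total <- 0
    classes <- lapply(score, function(r) {
        v <- runValue(r)
        cl <- findInterval(v, edges) + 1L
        rl <- as.numeric(runLength(r))
        for (k in 1:5)
            counts[k] <<- counts[k] + sum(rl[cl == k])
        above <<- above + sum(rl[v > openThreshold])
        total <<- total + sum(rl)
        Rle(cl, runLength(r))
    })
    pct <- 100 * counts / total
    names(pct) <- binLabels(bins)
    list(classes = as(classes, "RleList"), percentages = pct,
         pctAboveThreshold = 100 * above / total, threshold = openThreshold)
}

#' @describeIn compactionBins human-readable labels of the five classes,
#'   most open first.
#' @param x a \code{CompactionBins} object.
#' @export
setMethod("binLabels", "CompactionBins", function(x) {
    e <- x@edges
    c(sprintf("<%g", e[1]),
      sprintf("[%g,%g)", e[1], e[2]),
      sprintf("[%g,%g)", e[2], e[3]),
      sprintf("[%g,%g)", e[3], e[4]),
      sprintf(">=%g", e[4]))
})
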