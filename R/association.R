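#' Expression categories on the log10(TPM + 1) scale
#'
#' Partitions genes by transcription level using the printed thresholds:
#' Low when \eqn{y < 0.15}, Mid when \eqn{0.5 < y \le 1.5}, High when
#' \eqn{y > 2.0}, with \eqn{y = \log_{10}(TPM + 1)}. Values falling in the
#' gaps (0.15, 0.5] and (1.5, 2.0] get class \code{none} and are excluded
#' from class-grouped analyses (but retained in scatter analyses).
#'
#' @param tpm nonnegative numeric vector of TPM values.
#' @param config an \code{\link{expressionCategories}} object.
#' @return factor with levels Low, Mid, High, none.
#' @examples
#' categorizeExpression(c(0, 9, 2))   # Low, Mid, none
#' @export
categorizeExpression <- function(tpm, config = expressionCategories()) {
    if (any(is.na(tpm)) || any(tpm < 0))
        stop("tpm must be nonnegative and non-missing")
    y <- log10(tpm + 1)
    cls <- rep("none", length(y))
    cls[y < config@lowMax] <- "Low"
    cls[y > config@midMin & y <= config@midMax] <- "Mid"
    cls[y > config@highMin] <- "High"
    factor(cls, levels = c("Low", "Mid", "High", "none"))
}

#' Qualification filter on TSS/TES coverage
#'
#' Keeps a gene record iff its rcpm is strictly greater than the threshold
#' at both the TSS and the TES window, so that the score's logarithm never
#' rests on empty coverage.
#'
#' @param records a data.frame-like with \code{rcpmTss} and \code{rcpmTes}.
#' @param config a \code{\link{qualificationParams}} object.
#' @return the surviving records.
#' @export
qualifyGenes <- function(records, config = qualificationParams()) {
    stopifnot(all(c("rcpmTss", "rcpmTes") %in% colnames(records)))
    keep <- records$rcpmTss > config@rcpmMin & records$rcpmTes > config@rcpmMin
    records[keep, , drop = FALSE]
}

#' Pearson correlation with least-squares approximation line
#'
#' Sample Pearson r plus the ordinary least-squares line
#' \eqn{y = a + b x} (the "approximation line" drawn through scatter
#' plots), and the two-sided p-value of the correlation test. No
#' multiple-testing adjustment is applied.
#'
#' @param x,y numeric vectors of equal length, n >= 3, neither constant.
#' @return list with \code{r}, \code{slope}, \code{intercept}, \code{p},
#'   \code{n}.
#' @export
pearsonFit <- function(x, y) {
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3L) stop("need at least 3 complete pairs")
    if (sd(x) == 0 || sd(y) == 0)
        stop("undefined correlation: constant input")
    slope <- cov(x, y) / var(x)
    list(r = cor(x, y), slope = slope,
         intercept = mean(y) - slope * mean(x),
         p = cor.test(x, y)$p.value, n = length(x))
}

#' Per-fraction relative abundance as log2 ratio to the mean
#'
#' Summarizes a vector of per-fraction amounts (e.g. recovered DNA, blot
#' intensity, or region coverage per fraction) as
#' \eqn{\log_2(\mathrm{amount}_f / \mathrm{mean})}, the conventional way of
#' displaying fraction compositions relative to their average. Zero amounts
#' receive a small offset (with a warning) before the ratio, mirroring the
#' score's epsilon. Scaling all amounts by a common factor leaves the
#' result unchanged.
#'
#' @param amounts nonnegative numeric, at least one positive.
#' @param epsilon offset applied to all amounts when any is zero.
#' @return numeric vector of log2 ratios to the mean.
#' @examples
#' fractionRelativeAbundance(c(1, 1, 1, 1, 1, 3))
#' @export
fractionRelativeAbundance <- function(amounts, epsilon = 0.001) {
    if (any(amounts < 0)) stop("amounts must be nonnegative")
    if (all(amounts == 0)) stop("at least one amount must be positive")
    if (any(amounts == 0)) {
        warning("zero amount(s); applying offset ", epsilon)
        amounts <- amounts + epsilon
    }
    log2(amounts / mean(amounts))
}

#' Per-TAD score summaries and boundary openness
#'
#' Per TAD: mean and standard deviation of the per-base Fr-5/Fr-1 score.
#' Per boundary (TAD start and end points): the mean score over a symmetric
#' window (default 2 kb) around the boundary, labeled open when below
#' \code{openThreshold} (default -2.5, the cut for relatively open
#' chromatin). Also reports the Pearson fit of TAD length versus TAD mean
#' score.
#'
#' @param score an \code{RleList} score track.
#' @param tads a \code{GRanges} of TAD intervals.
#' @param openThreshold boundary openness threshold.
#' @param boundaryWindow total boundary window width in bp.
#' @return list with \code{tads} (DataFrame: chrom, start, end, length,
#'   meanScore, sdScore), \code{boundaries} (DataFrame: chrom, pos,
#'   meanScore, open), \code{openBoundaryFraction} and
#'   \code{lengthScoreFit} (NULL when degenerate).
#' @export
tadSummary <- function(score, tads, openThreshold = -2.5,
                       boundaryWindow = 2000L) {
    if (length(tads) == 0L)
        return(list(tads = DataFrame(), boundaries = DataFrame(),
                    openBoundaryFraction = NA_real_, lengthScoreFit = NULL))
    m <- .trackMeans(score, tads)
    m2 <- .trackMeans(score * score, tads)
    n <- width(tads)
    sdv <- sqrt(pmax(0, (m2 - m^2) * n / pmax(1, n - 1)))
    tadDf <- DataFrame(chrom = as.character(seqnames(tads)),
                       start = start(tads), end = end(tads),
                       length = n, meanScore = m, sdScore = sdv)
    # boundaries: unique start/end points per chromosome
    bchr <- rep(as.character(seqnames(tads)), 2L)
    bpos <- c(start(tads), end(tads))
    keep <- !duplicated(paste(bchr, bpos))
    bchr <- bchr[keep]; bpos <- bpos[keep]
    half <- boundaryWindow %/% 2L
    lens <- vapply(score, length, numeric(1))
    bs <- pmax(1L, bpos - half)
    be <- pmin(as.integer(lens[bchr]), bpos + half - 1L)
    bgr <- GRanges(bchr, IRanges(bs, be))
    bm <- .trackMeans(score, bgr)
    bDf <- DataFrame(chrom = bchr, pos = bpos, meanScore = bm,
                     open = bm < openThreshold)
    fit <- tryCatch(pearsonFit(as.numeric(n), m), error = function(e) NULL)
    list(tads = tadDf, boundaries = bDf,
         openBoundaryFraction = mean(bDf$open), lengthScoreFit = fit)
}

#' RNA-polymerase binding versus TSS compaction
#'
#' Per gene, the RNAP binding level is the mean ChIP track value over the
#' TSS window; the function returns the joined table and the Pearson fit
#' against the TSS Fr-5/Fr-1 score. A degenerate correlation (constant
#' input) is surfaced as a warning while the table is still returned.
#'
#' @param rnapTrack an \code{RleList} RNAP binding track.
#' @param tssWindows TSS window \code{GRanges} with \code{gene_id}.
#' @param tssScores per-gene TSS Fr-5/Fr-1 scores, parallel to
#'   \code{tssWindows}.
#' @return list with \code{table} (DataFrame: gene_id, rnapLevel,
#'   tssScore) and \code{fit} (NULL when degenerate).
#' @export
rnapAssociation <- function(rnapTrack, tssWindows, tssScores) {
    stopifnot(length(tssWindows) == length(tssScores))
    lev <- .trackMeans(rnapTrack, tssWindows)
    tab <- DataFrame(gene_id = tssWindows$gene_id, rnapLevel = lev,
                     tssScore = tssScores)
    fit <- tryCatch(pearsonFit(tssScores, lev), error = function(e) {
        warning("correlation undefined: ", conditionMessage(e))
        NULL
    })
    list(table = tab, fit = fit)
}

#' Gene-level association table
#'
#' Joins, per gene: TSS and TES window-mean Fr-5/Fr-1 scores,
#' log10(TPM+1), expression class, rcpm at both anchors with the qualified
#' flag, and optionally NFR depth and RNAP binding level.
#'
#' @param genes gene \code{GRanges} with \code{gene_id} and \code{tpm}.
#' @param scoreTrack Fr-5/Fr-1 \code{RleList}.
#' @param fragments all mapped fragments (for rcpm).
#' @param occupancy optional MNase \code{RleList} for NFR depth.
#' @param rnapTrack optional RNAP \code{RleList}.
#' @param windowSize anchor window width, bp.
#' @param qual a \code{\link{qualificationParams}} object.
#' @param cats an \code{\link{expressionCategories}} object.
#' @return a \code{DataFrame}, one row per gene whose TSS and TES windows
#'   survived boundary clipping.
#' @export
geneAssociationTable <- function(genes, scoreTrack, fragments,
                                 occupancy = NULL, rnapTrack = NULL,
                                 windowSize = 250L,
                                 qual = qualificationParams(),
                                 cats = expressionCategories()) {
    tssW <- anchorWindows(genes, "TSS", windowSize)
    tesW <- anchorWindows(genes, "TES", windowSize)
    ids <- intersect(tssW$gene_id, tesW$gene_id)
    genes <- genes[match(ids, genes$gene_id)]
    tssW <- tssW[match(ids, tssW$gene_id)]
    tesW <- tesW[match(ids, tesW$gene_id)]
    tssStats <- regionStats(scoreTrack, tssW, fragments)
    tesStats <- regionStats(scoreTrack, tesW, fragments)
    out <- DataFrame(gene_id = ids,
                     tssScore = tssStats$meanValue,
                     tesScore = tesStats$meanValue,
                     log10Tpm = log10(genes$tpm + 1),
                     class = categorizeExpression(genes$tpm, cats),
                     rcpmTss = tssStats$rcpm,
                     rcpmTes = tesStats$rcpm)
    out$qualified <- out$rcpmTss > qual@rcpmMin & out$rcpmTes > qual@rcpmMin
    if (!is.null(occupancy))
        out$nfrDepth <- nfrDepth(occupancy, tssW)$nfrDepth
    if (!is.null(rnapTrack))
        out$rnapLevel <- .trackMeans(rnapTrack, tssW)
    out
}
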