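#' Sedimentation model: from local compaction to a fraction distribution
#'
#' Maps the mean compaction \eqn{\bar c \in [0,1]} of a chromatin fragment to
#' a categorical distribution over the five sucrose-gradient fractions
#' Fr-1..Fr-5. The default model (\code{\link{binomialSedimentation}}) draws
#' the fraction index as \eqn{1 + \mathrm{Binomial}(4, \bar c)}, which maps
#' the endpoints exactly (fully open fragments stay in Fr-1, fully compact
#' ones sediment to Fr-5) and has mean fraction index \eqn{1 + 4\bar c},
#' monotone in compaction.
#'
#' @slot name identifier of the model.
#' @slot probFun function taking a numeric vector of compaction values and
#'   returning an \code{n x 5} matrix of fraction probabilities.
#' @exportClass SedimentationModel
setClass("SedimentationModel",
    representation(name = "character", probFun = "function"))

setValidity("SedimentationModel", function(object) {
    grid <- c(0, 0.25, 0.5, 0.75, 1)
    p <- object@probFun(grid)
    if (!is.matrix(p) || nrow(p) != length(grid) || ncol(p) != 5L)
        return("probFun must return an n x 5 matrix")
    if (any(p < -1e-12))
        return("probFun returned negative probabilities")
    if (any(abs(rowSums(p) - 1) > 1e-8))
        return("fraction probabilities must sum to 1 for every compaction value")
    ef <- drop(p %*% seq_len(5))
    if (any(diff(ef) < -1e-9))
        return("expected fraction index must be monotone nondecreasing in compaction")
    TRUE
})

#' Planted compaction landscape
#'
#' Per-base compaction parameter \eqn{c \in [0,1]} (0 = fully open, 1 = fully
#' compact) used as ground truth by the simulator: a constant baseline with
#' Gaussian-shaped valleys centered on gene TSSs, so that downstream scoring
#' can be checked against a known landscape.
#'
#' @slot values \code{RleList}, one run-length encoded vector per chromosome.
#' @slot baseline baseline compaction level.
#' @slot valleyWidth Gaussian sigma of the TSS valleys, in bp.
#' @slot tssDepth named numeric, planted valley depth per gene id.
#' @exportClass CompactionLandscape
setClass("CompactionLandscape",
    representation(values = "RleList", baseline = "numeric",
                   valleyWidth = "numeric", tssDepth = "numeric"))

setValidity("CompactionLandscape", function(object) {
    lo <- min(vapply(object@values, function(v) min(runValue(v)), numeric(1)))
    hi <- max(vapply(object@values, function(v) max(runValue(v)), numeric(1)))
    if (lo < -1e-9 || hi > 1 + 1e-9)
        return("compaction values must lie in [0, 1]")
    if (length(object@baseline) != 1L || object@baseline < 0 || object@baseline > 1)
        return("baseline must be a single value in [0, 1]")
    if (any(object@tssDepth < -1e-9) || any(object@tssDepth > object@baseline + 1e-9))
        return("valley depths must lie in [0, baseline]")
    TRUE
})

#' Normalization parameters for fraction coverage tracks
#'
#' Coverage tracks are first rescaled so their genome-wide total signal
#' equals the target \code{wigsum} (default 8.5e9, the conventional value for
#' a human-genome scale track), then multiplied by a per-fraction recovery
#' factor reflecting the amount of DNA recovered from each fraction. The
#' \code{epsilon} offset (default 0.001) is added to both tracks before the
#' ratio so the logarithm is finite everywhere.
#'
#' @slot wigsum target genome-wide total signal.
#' @slot recovery numeric of length 5, unitless per-fraction multipliers.
#' @slot epsilon offset added before the ratio.
#' @exportClass NormalizationParams
setClass("NormalizationParams",
    representation(wigsum = "numeric", recovery = "numeric", epsilon = "numeric"))

setValidity("NormalizationParams", function(object) {
    if (length(object@wigsum) != 1L || object@wigsum <= 0)
        return("wigsum must be a single positive number")
    if (length(object@recovery) != 5L || any(object@recovery <= 0))
        return("recovery must be 5 positive factors (Fr-1..Fr-5)")
    if (length(object@epsilon) != 1L || object@epsilon <= 0)
        return("epsilon must be a single positive number")
    TRUE
})

#' @rdname NormalizationParams-class
#' @param wigsum,recovery,epsilon see slot documentation.
#' @return a \code{NormalizationParams} object.
#' @export
normalizationParams <- function(wigsum = 8.5e9, recovery = rep(1, 5),
                                epsilon = 0.001) {
    new("NormalizationParams", wigsum = as.numeric(wigsum),
        recovery = as.numeric(recovery), epsilon = as.numeric(epsilon))
}

#' Five-class compaction binning
#'
#' Four ascending score edges split the Fr-5/Fr-1 score axis into five
#' classes, from most open (lowest scores) to most compact. Defaults
#' (-4.5, -3.5, -2.5, -1.5) bracket the two thresholds used in practice:
#' -3.5 separating the broadly compact genome and -2.5 marking relatively
#' open chromatin at TAD boundaries.
#'
#' @slot edges strictly increasing numeric of length 4.
#' @exportClass CompactionBins
setClass("CompactionBins", representation(edges = "numeric"))

setValidity("CompactionBins", function(object) {
    if (length(object@edges) != 4L || any(diff(object@edges) <= 0))
        return("edges must be 4 strictly increasing values")
    TRUE
})

#' @rdname CompactionBins-class
#' @param edges strictly increasing numeric of length 4.
#' @return a \code{CompactionBins} object.
#' @export
compactionBins <- function(edges = c(-4.5, -3.5, -2.5, -1.5)) {
    new("CompactionBins", edges = as.numeric(edges))
}

#' Expression category thresholds on the log10(TPM + 1) scale
#'
#' Genes are grouped as Low (\eqn{y < 0.15}), Mid (\eqn{0.5 < y \le 1.5}) or
#' High (\eqn{y > 2.0}) with \eqn{y = \log_{10}(\mathrm{TPM}+1)}. The gaps
#' (0.15, 0.5] and (1.5, 2.0] deliberately carry no class: such genes are
#' excluded from class-grouped analyses but kept in scatter analyses.
#'
#' @slot lowMax,midMin,midMax,highMin the four thresholds.
#' @exportClass ExpressionCategories
setClass("ExpressionCategories",
    representation(lowMax = "numeric", midMin = "numeric",
                   midMax = "numeric", highMin = "numeric"))

setValidity("ExpressionCategories", function(object) {
    th <- c(object@lowMax, object@midMin, object@midMax, object@highMin)
    if (length(th) != 4L || any(diff(th) <= 0))
        return("thresholds must satisfy lowMax < midMin < midMax < highMin")
    TRUE
})

#' @rdname ExpressionCategories-class
#' @param lowMax,midMin,midMax,highMin thresholds on the log10(TPM+1) scale.
#' @return an \code{ExpressionCategories} object.
#' @export
expressionCategories <- function(lowMax = 0.15, midMin = 0.5,
                                 midMax = 1.5, highMin = 2.0) {
    new("ExpressionCategories", lowMax = lowMax, midMin = midMin,
        midMax = midMax, highMin = highMin)
}

#' Gene qualification threshold
#'
#' A gene qualifies for score-based analyses when its read count per million
#' mapped (rcpm) is strictly greater than \code{rcpmMin} at both the TSS and
#' the TES window, so that neither window rests on essentially zero coverage.
#'
#' @slot rcpmMin minimum rcpm (strict), default 0.05.
#' @exportClass QualificationParams
setClass("QualificationParams", representation(rcpmMin = "numeric"))

setValidity("QualificationParams", function(object) {
    if (length(object@rcpmMin) != 1L || object@rcpmMin < 0)
        return("rcpmMin must be a single nonnegative number")
    TRUE
})

#' @rdname QualificationParams-class
#' @param rcpmMin strict lower bound on rcpm at TSS and TES.
#' @return a \code{QualificationParams} object.
#' @export
qualificationParams <- function(rcpmMin = 0.05) {
    new("QualificationParams", rcpmMin = as.numeric(rcpmMin))
}

#' Metagene fractional-proportion profile
#'
#' Matrix of fractional proportions over a metagene axis: upstream flank at
#' native scale, gene body linearly rescaled to a fixed number of bins,
#' downstream flank at native scale, with the TSS always on the left.
#' Each column holding signal sums to 1 across the five fractions.
#'
#' @slot proportions 5 x B matrix, rows Fr-1..Fr-5.
#' @slot meanDepth 5 x B matrix of mean normalized depth per bin.
#' @slot bodyBins,flankBins bin counts.
#' @slot flankBp flank width in bp.
#' @slot nGenes number of genes averaged.
#' @exportClass MetageneProfile
setClass("MetageneProfile",
    representation(proportions = "matrix", meanDepth = "matrix",
                   bodyBins = "integer", flankBins = "integer",
                   flankBp = "integer", nGenes = "integer"))

setValidity("MetageneProfile", function(object) {
    B <- object@bodyBins + 2L * object@flankBins
    if (!identical(dim(object@proportions), c(5L, B)))
        return("proportions must be a 5 x (bodyBins + 2*flankBins) matrix")
    if (!identical(dim(object@meanDepth), dim(object@proportions)))
        return("meanDepth must match proportions in shape")
    TRUE
})

setMethod("show", "SedimentationModel", function(object) {
    cat("SedimentationModel:", object@name, "\n")
    p <- fractionProbabilities(object, c(0, 0.5, 1))
    rownames(p) <- c("c=0", "c=0.5", "c=1")
    colnames(p) <- paste0("Fr-", 1:5)
    print(round(p, 4))
})

setMethod("show", "CompactionLandscape", function(object) {
    cat("CompactionLandscape on", length(object@values), "chromosome(s),",
        sum(as.numeric(lengths(object@values))), "bp\n")
    cat("  baseline:", object@baseline,
        " valley sigma:", object@valleyWidth, "bp\n")
    cat("  planted TSS valleys:", length(object@tssDepth))
    if (length(object@tssDepth))
        cat(" (depth range ", round(min(object@tssDepth), 3), "..",
            round(max(object@tssDepth), 3), ")", sep = "")
    cat("\n")
})

setMethod("show", "NormalizationParams", function(object) {
    cat("NormalizationParams: wigsum =", format(object@wigsum),
        " epsilon =", object@epsilon, "\n  recovery (Fr-1..Fr-5):",
        paste(object@recovery, collapse = " "), "\n")
})

setMethod("show", "CompactionBins", function(object) {
    cat("CompactionBins with edges:", paste(object@edges, collapse = ", "),
        "\n  classes:", paste(binLabels(object), collapse = " | "), "\n")
})

setMethod("show", "MetageneProfile", function(object) {
    cat("MetageneProfile:", object@nGenes, "genes,",
        ncol(object@proportions), "bins (",
        object@flankBins, "flank +", object@bodyBins, "body +",
        object@flankBins, "flank )\n")
})
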