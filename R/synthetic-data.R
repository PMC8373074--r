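#' Binomial sedimentation model
#'
#' The default generative rule linking local compaction to sedimentation: a
#' fragment with mean compaction \eqn{\bar c} lands in fraction
#' \eqn{1 + \mathrm{Binomial}(4, \bar c)}. Fully open fragments
#' (\eqn{\bar c = 0}) always stay in Fr-1, fully compact ones always reach
#' Fr-5, and the expected fraction index \eqn{1 + 4\bar c} grows linearly
#' with compaction. The maximum-likelihood inverse
#' \eqn{\hat c = (\bar f - 1)/4} makes the planted landscape recoverable in
#' closed form.
#'
#' @return a \code{\linkS4class{SedimentationModel}}.
#' @examples
#' m <- binomialSedimentation()
#' fractionProbabilities(m, 0.5)   # Binomial(4, 1/2) pmf: 1/16 4/16 6/16 ...
#' @export
binomialSedimentation <- function() {
    pf <- function(cbar) {
        p <- vapply(0:4, function(k) dbinom(k, 4, cbar),
                    numeric(length(cbar)))
        if (is.null(dim(p))) p <- matrix(p, nrow = 1L)
        p
    }
    new("SedimentationModel", name = "binomial4", probFun = pf)
}

#' @describeIn binomialSedimentation probabilities over Fr-1..Fr-5 for each
#'   compaction value; rows sum to 1.
#' @param model a \code{SedimentationModel}.
#' @param cbar numeric vector of mean compaction values in [0, 1].
#' @export
setMethod("fractionProbabilities", "SedimentationModel",
    function(model, cbar) {
        if (any(cbar < 0 | cbar > 1)) stop("compaction values must be in [0, 1]")
        p <- model@probFun(cbar)
        dimnames(p) <- list(NULL, paste0("Fr-", 1:5))
        p
    })

#' @describeIn binomialSedimentation expected fraction index, monotone
#'   nondecreasing in compaction.
#' @export
setMethod("expectedFraction", "SedimentationModel",
    function(model, cbar) drop(fractionProbabilities(model, cbar) %*% (1:5)))

#' @describeIn binomialSedimentation draw one fraction label per compaction
#'   value from the model (consumes the current RNG stream; seed upstream).
#' @export
setMethod("assignFractions", "SedimentationModel",
    function(model, cbar) {
        p <- fractionProbabilities(model, cbar)
        cp1 <- p[, 1L]
        cp2 <- cp1 + p[, 2L]
        cp3 <- cp2 + p[, 3L]
        cp4 <- cp3 + p[, 4L]
        u <- runif(length(cbar))
        1L + (u > cp1) + (u > cp2) + (u > cp3) + (u > cp4)
    })

#' Generate a toy genome and non-overlapping gene models
#'
#' Places \code{nGenes} genes of uniformly drawn length on a genome of
#' \code{nChroms} chromosomes, with at least \code{minSpacing} bp between
#' neighbouring genes and random strands. Gene placement consumes a single
#' seeded stream, so a fixed seed gives identical output.
#'
#' @param nChroms number of chromosomes.
#' @param chromLen chromosome length(s) in bp, recycled to \code{nChroms}.
#' @param nGenes total number of genes.
#' @param geneLengthRange min/max gene length in bp.
#' @param minSpacing minimum gap between genes (and to chromosome ends), bp.
#' @param seed integer seed.
#' @return list with \code{genome} (a \code{Seqinfo}) and \code{genes}
#'   (a \code{GRanges} with \code{gene_id}, \code{tpm} = NA).
#' @export
genGenomeAndGenes <- function(nChroms = 1L, chromLen = 1e6, nGenes = 200L,
                              geneLengthRange = c(1000L, 2500L),
                              minSpacing = 2000L, seed = 1L) {
    chromLen <- rep(as.integer(chromLen), length.out = nChroms)
    if (nGenes * (max(geneLengthRange) + minSpacing) > sum(as.numeric(chromLen)))
        stop("cannot place ", nGenes, " genes: genome too small for ",
             "gene length ", max(geneLengthRange), " + spacing ", minSpacing)
    chromNames <- paste0("chr", seq_len(nChroms))
    genome <- GenomeInfoDb::Seqinfo(seqnames = chromNames,
                                    seqlengths = chromLen)
    # genes per chromosome, proportional to length (remainder to the largest)
    kPer <- floor(nGenes * chromLen / sum(as.numeric(chromLen)))
    rest <- nGenes - sum(kPer)
    if (rest > 0) {
        ord <- order(chromLen, decreasing = TRUE)
        kPer[ord[seq_len(rest)]] <- kPer[ord[seq_len(rest)]] + 1L
    }
    withr::with_seed(seed, {
        grl <- lapply(seq_len(nChroms), function(ci) {
            k <- kPer[ci]
            if (k == 0L) return(NULL)
            L <- chromLen[ci]
            lens <- geneLengthRange[1] +
                sample.int(diff(geneLengthRange) + 1L, k, replace = TRUE) - 1L
            slack <- L - sum(lens) - (k + 1L) * minSpacing
            if (slack < 0)
                stop("cannot place ", k, " genes on ", chromNames[ci],
                     ": insufficient length")
            cuts <- diff(c(0, sort(runif(k)), 1))
            gaps <- minSpacing + floor(slack * cuts)
            starts <- cumsum(gaps[seq_len(k)]) + cumsum(c(0L, lens[-k]))
            GRanges(chromNames[ci],
                    IRanges(start = starts + 1L, width = lens),
                    strand = sample(c("+", "-"), k, replace = TRUE))
        })
        genes <- suppressWarnings(do.call(c, grl[!vapply(grl, is.null, logical(1))]))
        seqinfo(genes) <- genome
        genes$gene_id <- sprintf("g%04d", seq_along(genes))
        genes$tpm <- NA_real_
        list(genome = genome, genes = genes)
    })
}

#' Plant a compaction landscape with Gaussian TSS valleys
#'
#' Builds the ground-truth per-base compaction track: constant at
#' \code{baseline} except for Gaussian valleys of standard deviation
#' \code{valleyWidth} centered on each gene's TSS, reaching
#' \code{baseline - depth} at the center. Overlapping valleys combine by the
#' deeper deficit, keeping all values in [0, 1].
#'
#' @param genome a \code{Seqinfo}.
#' @param genes gene \code{GRanges} (strand determines the TSS base).
#' @param baseline baseline compaction in [0, 1].
#' @param valleyDepth per-gene valley depth(s), recycled; each must lie in
#'   [0, baseline]. Ignored when \code{depthRange} is given.
#' @param depthRange optional length-2 range; depths are then drawn
#'   uniformly per gene under \code{seed}.
#' @param valleyWidth Gaussian sigma in bp. The default (250 bp) makes the
#'   open domain around an active TSS span roughly 0.5-1 kb, wide enough
#'   that 300-500 bp fragments centered there have low mean compaction and
#'   sediment to the top fractions, as active TSS regions do.
#' @param seed integer seed (used only when \code{depthRange} is given).
#' @return a \code{\linkS4class{CompactionLandscape}}.
#' @export
plantCompactionLandscape <- function(genome, genes, baseline = 0.8,
                                     valleyDepth = 0.6, depthRange = NULL,
                                     valleyWidth = 250, seed = 1L) {
    n <- length(genes)
    depths <- if (!is.null(depthRange)) {
        stopifnot(length(depthRange) == 2L)
        withr::with_seed(seed, runif(n, depthRange[1], depthRange[2]))
    } else rep(valleyDepth, length.out = n)
    if (any(depths < 0) || any(depths > baseline))
        stop("valley depths must lie in [0, baseline]")
    centers <- .tssPosition(genes)
    vals <- .plantValleys(genome, centers,
                          as.character(seqnames(genes)),
                          baseline, depths, valleyWidth)
    names(depths) <- genes$gene_id
    new("CompactionLandscape", values = vals, baseline = baseline,
        valleyWidth = valleyWidth, tssDepth = depths)
}

#' @describeIn plantCompactionLandscape the per-chromosome \code{RleList} of
#'   compaction values.
#' @param x a \code{CompactionLandscape}.
#' @export
setMethod("landscapeValues", "CompactionLandscape", function(x) x@values)

#' @describeIn plantCompactionLandscape the baseline compaction level.
#' @export
setMethod("baselineCompaction", "CompactionLandscape", function(x) x@baseline)

#' @describeIn plantCompactionLandscape named vector of planted valley
#'   depths (ground truth for recovery checks).
#' @export
setMethod("plantedDepths", "CompactionLandscape", function(x) x@tssDepth)

#' @describeIn plantCompactionLandscape compaction value at the TSS base of
#'   each gene (strand-aware).
#' @export
setMethod("compactionAt", "CompactionLandscape", function(x, genes) {
    pos <- .tssPosition(genes)
    sn <- as.character(seqnames(genes))
    vapply(seq_along(genes), function(i)
        as.numeric(x@values[[sn[i]]][pos[i]]), numeric(1))
})

#' Simulate expression coupled to TSS openness
#'
#' Sets per-gene TPM so that \eqn{\log_{10}(TPM+1) =
#' \max(0,\; a - b\,c(TSS) + N(0, \sigma))}: open TSSs (low compaction)
#' transcribe more, planting the inverse compaction-expression relation the
#' scoring pipeline is expected to recover. The floor at zero mirrors TPM
#' nonnegativity.
#'
#' @param genes gene \code{GRanges}.
#' @param landscape a \code{CompactionLandscape}.
#' @param interceptA,slopeB nonnegative link coefficients.
#' @param noiseSd standard deviation of the Gaussian noise on the
#'   log10(TPM+1) scale.
#' @param seed integer seed.
#' @return \code{genes} with the \code{tpm} metadata column filled in.
#' @export
simulateExpression <- function(genes, landscape, interceptA = 2.5,
                               slopeB = 2.5, noiseSd = 0.4, seed = 1L) {
    stopifnot(interceptA >= 0, slopeB >= 0, noiseSd >= 0)
    cT <- compactionAt(landscape, genes)
    y <- withr::with_seed(seed,
        pmax(0, interceptA - slopeB * cT + rnorm(length(genes), 0, noiseSd)))
    genes$tpm <- 10^y - 1
    genes
}

#' Simulate per-fraction sequencing fragments
#'
#' Drops \code{nFragments} fragments uniformly on the genome with lengths
#' uniform in \code{lengthRange}, computes each fragment's mean compaction
#' over the planted landscape, and draws its gradient fraction from the
#' sedimentation model. Optional per-fraction \code{recoveryBias}
#' (probabilities in (0, 1]) thins fragments after assignment, emulating
#' uneven DNA recovery across fractions.
#'
#' @param genome a \code{Seqinfo}.
#' @param landscape a \code{CompactionLandscape}.
#' @param model a \code{SedimentationModel}.
#' @param nFragments number of fragments before thinning.
#' @param lengthRange min/max fragment length in bp (sonicated chromatin
#'   runs around 300-500 bp).
#' @param recoveryBias numeric length 5 in (0, 1]; keep probability per
#'   fraction. Default 1 (no thinning).
#' @param seed integer seed.
#' @return sorted \code{GRanges} with an integer \code{fraction} column.
#' @export
simulateFractionFragments <- function(genome, landscape,
                                      model = binomialSedimentation(),
                                      nFragments = 1e6,
                                      lengthRange = c(300L, 500L),
                                      recoveryBias = rep(1, 5), seed = 1L) {
    stopifnot(length(recoveryBias) == 5L,
              all(recoveryBias > 0), all(recoveryBias <= 1),
              lengthRange[1] > 0, lengthRange[1] <= lengthRange[2])
    lens <- GenomeInfoDb::seqlengths(genome)
    if (lengthRange[2] > min(lens))
        stop("fragment length exceeds the shortest chromosome")
    n <- as.integer(nFragments)
    cs <- lapply(names(lens), function(chr)
        .cumsumTrack(landscapeValues(landscape)[[chr]]))
    names(cs) <- names(lens)
    withr::with_seed(seed, {
        fragLen <- lengthRange[1] +
            sample.int(diff(lengthRange) + 1L, n, replace = TRUE) - 1L
        ci <- sample.int(length(lens), n, replace = TRUE,
                         prob = as.numeric(lens))
        starts <- 1L + floor(runif(n) * (as.numeric(lens)[ci] - fragLen + 1))
        ends <- starts + fragLen - 1L
        cbar <- numeric(n)
        for (k in seq_along(lens)) {
            i <- which(ci == k)
            if (length(i))
                cbar[i] <- .intervalMeans(cs[[k]], starts[i], ends[i])
        }
        # numeric fuzz from the cumsum trick can leave values a hair outside [0,1]
        cbar <- pmin(1, pmax(0, cbar))
        fraction <- assignFractions(model, cbar)
        keep <- if (any(recoveryBias < 1))
            runif(n) < recoveryBias[fraction] else rep(TRUE, n)
        gr <- GRanges(names(lens)[ci[keep]],
                      IRanges(start = starts[keep], end = ends[keep]),
                      fraction = fraction[keep])
        seqinfo(gr) <- genome
        sort(gr)
    })
}

#' Simulate an MNase nucleosome-occupancy track
#'
#' Constant baseline occupancy with Gaussian nucleosome-free-region (NFR)
#' valleys at gene TSSs and optional truncated-at-zero Gaussian noise. NFR
#' depths are configurable independently of the compaction landscape, so the
#' generator can emulate either coupled or null occupancy-compaction
#' relations.
#'
#' @param genome a \code{Seqinfo}.
#' @param genes gene \code{GRanges}.
#' @param baselineOcc baseline occupancy (arbitrary units).
#' @param nfrDepth per-gene valley depth(s) in [0, baselineOcc], recycled.
#'   Ignored when \code{depthRange} is given.
#' @param depthRange optional length-2 range for uniform per-gene depths.
#' @param valleyWidth Gaussian sigma in bp.
#' @param noiseSd per-base truncated Gaussian noise sd.
#' @param seed integer seed.
#' @return list with \code{track} (\code{RleList}) and \code{depths}
#'   (named numeric, the planted NFR depth per gene).
#' @export
simulateMnaseOccupancy <- function(genome, genes, baselineOcc = 0.8,
                                   nfrDepth = 0.6, depthRange = NULL,
                                   valleyWidth = 60, noiseSd = 0,
                                   seed = 1L) {
    n <- length(genes)
    withr::with_seed(seed, {
        depths <- if (!is.null(depthRange))
            runif(n, depthRange[1], depthRange[2])
        else rep(nfrDepth, length.out = n)
        if (any(depths < 0) || any(depths > baselineOcc))
            stop("NFR depths must lie in [0, baselineOcc]")
        centers <- .tssPosition(genes)
        vals <- .plantValleys(genome, centers, as.character(seqnames(genes)),
                              baselineOcc, depths, valleyWidth)
        if (noiseSd > 0) {
            vals <- as(lapply(vals, function(v) {
                Rle(pmax(0, as.numeric(v) + rnorm(length(v), 0, noiseSd)))
            }), "RleList")
        }
        names(depths) <- genes$gene_id
        list(track = vals, depths = depths)
    })
}

#' Simulate an RNA-polymerase binding track coupled to TSS openness
#'
#' Gaussian binding peaks at TSSs whose height grows with local openness
#' (\eqn{1 - c(TSS)}) over a small uniform background, emulating a ChIP
#' signal in which polymerase binds open promoters more frequently.
#'
#' @param genome a \code{Seqinfo}.
#' @param genes gene \code{GRanges}.
#' @param landscape a \code{CompactionLandscape}.
#' @param peakScale peak height multiplier.
#' @param peakWidth Gaussian sigma of the binding peak, bp.
#' @param background uniform background level.
#' @param noiseSd truncated Gaussian per-base noise sd.
#' @param seed integer seed.
#' @return an \code{RleList} track.
#' @export
simulateRnapTrack <- function(genome, genes, landscape, peakScale = 1,
                              peakWidth = 200, background = 0.01,
                              noiseSd = 0, seed = 1L) {
    heights <- peakScale * (1 - compactionAt(landscape, genes))
    centers <- .tssPosition(genes)
    lens <- GenomeInfoDb::seqlengths(genome)
    vecs <- lapply(lens, function(L) rep(background, L))
    half <- ceiling(6 * peakWidth)
    sn <- as.character(seqnames(genes))
    for (i in seq_along(genes)) {
        L <- lens[[sn[i]]]
        idx <- max(1L, centers[i] - half):min(L, centers[i] + half)
        vecs[[sn[i]]][idx] <- vecs[[sn[i]]][idx] +
            heights[i] * exp(-((idx - centers[i])^2) / (2 * peakWidth^2))
    }
    if (noiseSd > 0)
        vecs <- withr::with_seed(seed, lapply(vecs, function(v)
            pmax(0, v + rnorm(length(v), 0, noiseSd))))
    as(lapply(vecs, Rle), "RleList")
}

#' Simulate a repeat annotation
#'
#' Uniformly placed repeat intervals (lengths uniform in \code{lengthRange});
#' repeats may overlap each other and genes, as real repeat annotations do.
#'
#' @param genome a \code{Seqinfo}.
#' @param nRepeats number of intervals.
#' @param lengthRange min/max repeat length, bp.
#' @param seed integer seed.
#' @return a sorted \code{GRanges}.
#' @export
simulateRepeats <- function(genome, nRepeats = 300L,
                            lengthRange = c(150L, 800L), seed = 1L) {
    lens <- GenomeInfoDb::seqlengths(genome)
    withr::with_seed(seed, {
        rl <- lengthRange[1] +
            sample.int(diff(lengthRange) + 1L, nRepeats, replace = TRUE) - 1L
        ci <- sample.int(length(lens), nRepeats, replace = TRUE,
                         prob = as.numeric(lens))
        starts <- 1L + floor(runif(nRepeats) * (as.numeric(lens)[ci] - rl + 1))
        gr <- GRanges(names(lens)[ci], IRanges(start = starts, width = rl))
        seqinfo(gr) <- genome
        sort(gr)
    })
}

#' Simulate a TAD partition
#'
#' Partitions each chromosome into \code{nTads} contiguous topologically
#' associating domains by drawing internal breakpoints uniformly; adjacent
#' TADs share a boundary point.
#'
#' @param genome a \code{Seqinfo}.
#' @param nTads TADs per chromosome.
#' @param seed integer seed.
#' @return a \code{GRanges} tiling each chromosome.
#' @export
simulateTads <- function(genome, nTads = 20L, seed = 1L) {
    lens <- GenomeInfoDb::seqlengths(genome)
    withr::with_seed(seed, {
        grl <- lapply(names(lens), function(chr) {
            L <- lens[[chr]]
            bp <- sort(sample.int(L - 1L, nTads - 1L))
            starts <- c(1L, bp + 1L)
            ends <- c(bp, L)
            GRanges(chr, IRanges(start = starts, end = ends))
        })
        gr <- suppressWarnings(do.call(c, grl))
        seqinfo(gr) <- genome
        gr
    })
}
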