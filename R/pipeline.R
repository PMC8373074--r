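#' Default demonstration configuration
#'
#' The standard synthetic study: one 1 Mb chromosome carrying 200
#' non-overlapping genes, a compaction landscape at baseline 0.8 with
#' Gaussian TSS valleys of depth uniform in [0.2, 0.8] (sigma 250 bp),
#' expression inversely coupled to TSS compaction, one million 300-500 bp
#' fragments assigned to fractions by the binomial sedimentation model
#' (normalized to a wigsum of 2.75e6, preserving the canonical
#' wigsum-to-genome-length ratio of ~2.7 on the 1 Mb toy genome so the
#' epsilon offset plays the same role as on a full-size track), an
#' MNase track whose NFR depths are drawn independently of both compaction
#' and expression (the null configuration), an RNAP track coupled to TSS
#' openness, plus random repeats and a 20-TAD partition.
#'
#' @param seed global integer seed; stage seeds are derived from it.
#' @param outdir output directory for \code{\link{runPipeline}}.
#' @return a named config list.
#' @export
demoConfig <- function(seed = 101L, outdir = tempfile("fracscore_run")) {
    list(
        seed = as.integer(seed),
        outdir = outdir,
        genome = list(nChroms = 1L, chromLen = 1e6L),
        genes = list(n = 200L, lengthRange = c(1000L, 2500L),
                     minSpacing = 2000L),
        landscape = list(baseline = 0.8, depthRange = c(0.2, 0.8),
                         valleyWidth = 250),
        expression = list(interceptA = 2.5, slopeB = 2.5, noiseSd = 0.4),
        fragments = list(n = 1e6, lengthRange = c(300L, 500L),
                         recoveryBias = rep(1, 5)),
        mnase = list(baselineOcc = 0.8, depthRange = c(0.1, 0.7),
                     valleyWidth = 60, noiseSd = 0.02),
        rnap = list(peakScale = 1, peakWidth = 200, background = 0.01,
                    noiseSd = 0.005),
        repeats = list(n = 300L, lengthRange = c(150L, 800L)),
        tads = list(n = 20L),
        normalization = list(wigsum = 2.75e6, epsilon = 0.001,
                             recovery = rep(1, 5)),
        bins = list(edges = c(-4.5, -3.5, -2.5, -1.5),
                    openThreshold = -3.5),
        windows = list(size = 250L),
        metagene = list(flankBp = 2000L, bodyBins = 100L, flankBins = 40L),
        tadSummary = list(openThreshold = -2.5, boundaryWindow = 2000L)
    )
}

#' Run the full simulate-score-associate pipeline
#'
#' Orchestrates generator, scoring, annotation, nucleosome and association
#' stages as a pure function of (config, seed): identical configs and seeds
#' give byte-identical output files. Emits per-fraction BEDs, the score and
#' auxiliary bedGraph tracks, the gene association table, metagene and
#' occupancy-curve TSVs, the NFR table, TAD summaries, class percentages
#' and a machine-readable JSON manifest. Progress is logged to the console
#' and to \code{run.log} in the output directory.
#'
#' @param config a config list as returned by \code{\link{demoConfig}}, or
#'   the path of a YAML file with the same structure.
#' @param outdir overrides \code{config$outdir} when given.
#' @return invisibly, a list with all in-memory results: \code{genome},
#'   \code{genes}, \code{landscape}, \code{fragments}, \code{tracks},
#'   \code{score}, \code{classification}, \code{association} (qualified
#'   flag included), fitted correlations (\code{fitRecovery},
#'   \code{fitTssExpression}, \code{fitTesExpression}, \code{fitNfrTpm},
#'   \code{fitNfrScore}, \code{rnap}), \code{metagene},
#'   \code{occupancyCurves}, \code{tadSummary} and \code{files}.
#' @export
runPipeline <- function(config, outdir = NULL) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    if (!is.null(outdir)) config$outdir <- outdir
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    logFile <- file.path(config$outdir, "run.log")
    cat("", file = logFile)
    logmsg <- function(...) {
        line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
        message(line)
        cat(line, "\n", file = logFile, append = TRUE)
    }
    seed <- config$seed
    sseed <- .stageSeeds(seed, 8L)
    stage <- function(name, expr) {
        t0 <- Sys.time()
        out <- tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE))
        logmsg(sprintf("%-12s %.1fs", name,
                       as.numeric(difftime(Sys.time(), t0, units = "secs"))))
        out
    }

    gg <- stage("genome", genGenomeAndGenes(
        nChroms = config$genome$nChroms, chromLen = config$genome$chromLen,
        nGenes = config$genes$n, geneLengthRange = config$genes$lengthRange,
        minSpacing = config$genes$minSpacing, seed = sseed[1]))
    genome <- gg$genome

    landscape <- stage("landscape", plantCompactionLandscape(
        genome, gg$genes, baseline = config$landscape$baseline,
        depthRange = config$landscape$depthRange,
        valleyWidth = config$landscape$valleyWidth, seed = sseed[2]))

    genes <- stage("expression", simulateExpression(
        gg$genes, landscape, interceptA = config$expression$interceptA,
        slopeB = config$expression$slopeB,
        noiseSd = config$expression$noiseSd, seed = sseed[3]))

    fragments <- stage("fragments", simulateFractionFragments(
        genome, landscape, nFragments = config$fragments$n,
        lengthRange = config$fragments$lengthRange,
        recoveryBias = config$fragments$recoveryBias, seed = sseed[4]))

    mnase <- stage("mnase", simulateMnaseOccupancy(
        genome, genes, baselineOcc = config$mnase$baselineOcc,
        depthRange = config$mnase$depthRange,
        valleyWidth = config$mnase$valleyWidth,
        noiseSd = config$mnase$noiseSd, seed = sseed[5]))

    rnap <- stage("rnap", simulateRnapTrack(
        genome, genes, landscape, peakScale = config$rnap$peakScale,
        peakWidth = config$rnap$peakWidth,
        background = config$rnap$background,
        noiseSd = config$rnap$noiseSd, seed = sseed[6]))

    repeats <- stage("repeats", simulateRepeats(
        genome, nRepeats = config$repeats$n,
        lengthRange = config$repeats$lengthRange, seed = sseed[7]))

    tads <- stage("tads", simulateTads(genome, nTads = config$tads$n,
                                       seed = sseed[8]))

    nparams <- normalizationParams(wigsum = config$normalization$wigsum,
                                   recovery = config$normalization$recovery,
                                   epsilon = config$normalization$epsilon)
    tracks <- stage("coverage", lapply(1:5, function(f)
        normalizeTrack(coverageFromFragments(fragments, genome, f),
                       nparams, f)))

    score <- stage("score", compactionScore(tracks[[1]], tracks[[5]],
                                            nparams@epsilon))

    classification <- stage("classify", classifyCompaction(
        score, compactionBins(config$bins$edges),
        openThreshold = config$bins$openThreshold))

    assoc <- stage("associate", {
        tab <- geneAssociationTable(genes, score, fragments,
                                    occupancy = mnase$track,
                                    rnapTrack = rnap,
                                    windowSize = config$windows$size)
        tssW <- anchorWindows(genes, "TSS", config$windows$size)
        kept <- filterRepeatOverlap(tssW, repeats)
        logmsg(sprintf("  TSS windows: %d of %d survive repeat filter",
                       length(kept), length(tssW)))
        tab$repeatFree <- tab$gene_id %in% kept$gene_id
        tab
    })
    qual <- assoc[assoc$qualified, ]
    logmsg(sprintf("  genes qualified: %d of %d", nrow(qual), nrow(assoc)))

    plantedC <- compactionAt(landscape, genes)
    names(plantedC) <- genes$gene_id
    fitRecovery <- pearsonFit(plantedC[qual$gene_id], qual$tssScore)
    fitTssExpression <- pearsonFit(qual$tssScore, qual$log10Tpm)
    fitTesExpression <- pearsonFit(qual$tesScore, qual$log10Tpm)
    fitNfrTpm <- pearsonFit(qual$nfrDepth, qual$log10Tpm)
    fitNfrScore <- pearsonFit(qual$nfrDepth, qual$tssScore)
    tssW <- anchorWindows(genes, "TSS", config$windows$size)
    tssW <- tssW[match(qual$gene_id, tssW$gene_id)]
    rnapAssoc <- rnapAssociation(rnap, tssW, qual$tssScore)

    metagene <- stage("metagene", {
        byClass <- split(seq_len(nrow(assoc)), assoc$class, drop = FALSE)
        lapply(byClass[c("Low", "Mid", "High")], function(i) {
            if (length(i) < 2L) return(NULL)
            g <- genes[match(assoc$gene_id[i], genes$gene_id)]
            metageneProfile(tracks, g, flankBp = config$metagene$flankBp,
                            bodyBins = config$metagene$bodyBins,
                            flankBins = config$metagene$flankBins)
        })
    })

    occCurves <- stage("occupancy", {
        byClass <- split(seq_len(nrow(assoc)), assoc$class, drop = FALSE)
        lapply(byClass[c("Low", "Mid", "High")], function(i) {
            if (length(i) < 2L) return(NULL)
            g <- genes[match(assoc$gene_id[i], genes$gene_id)]
            suppressWarnings(tssOccupancyCurve(mnase$track, g))
        })
    })

    tadSum <- stage("tadSummary", tadSummary(
        score, tads, openThreshold = config$tadSummary$openThreshold,
        boundaryWindow = config$tadSummary$boundaryWindow))

    files <- stage("write", {
        od <- config$outdir
        f <- c(exportFractionBeds(fragments, od))
        f["score"] <- exportBedGraph(score, file.path(od, "score.bedGraph"))
        f["landscape"] <- exportBedGraph(landscapeValues(landscape),
                                         file.path(od, "landscape.bedGraph"))
        f["mnase"] <- exportBedGraph(mnase$track,
                                     file.path(od, "mnase.bedGraph"))
        f["rnap"] <- exportBedGraph(rnap, file.path(od, "rnap.bedGraph"))
        rtracklayer::export(repeats, file.path(od, "repeats.bed"),
                            format = "BED")
        f["repeats"] <- file.path(od, "repeats.bed")
        rtracklayer::export(tads, file.path(od, "tads.bed"), format = "BED")
        f["tads"] <- file.path(od, "tads.bed")
        f["genes"] <- writeGenesTsv(genes, file.path(od, "genes.tsv"))
        write.table(as.data.frame(assoc), file.path(od, "association.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        f["association"] <- file.path(od, "association.tsv")
        for (cl in names(metagene)) {
            if (is.null(metagene[[cl]])) next
            p <- file.path(od, sprintf("metagene_%s.tsv", cl))
            write.table(profileProportions(metagene[[cl]]), p, sep = "\t",
                        quote = FALSE, col.names = NA)
            f[paste0("metagene_", cl)] <- p
        }
        nfrTab <- DataFrame(gene_id = assoc$gene_id,
                            nfrDepth = assoc$nfrDepth)
        write.table(as.data.frame(nfrTab), file.path(od, "nfr.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        f["nfr"] <- file.path(od, "nfr.tsv")
        write.table(as.data.frame(tadSum$tads), file.path(od, "tad_summary.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        f["tad_summary"] <- file.path(od, "tad_summary.tsv")
        pctDf <- data.frame(class = names(classification$percentages),
                            percent = unname(classification$percentages))
        write.table(pctDf, file.path(od, "class_percentages.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        f["class_percentages"] <- file.path(od, "class_percentages.tsv")
        f
    })

    formats <- ifelse(grepl("\\.bed$", files), "BED",
               ifelse(grepl("\\.bedGraph$", files), "bedGraph", "TSV"))
    manifest <- list(package = "fracscore",
                     version = as.character(packageVersion("fracscore")),
                     seed = seed, config = config,
                     files = as.list(stats::setNames(
                         paste(basename(files), formats, sep = ":"),
                         names(files))))
    jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    files["manifest"] <- file.path(config$outdir, "manifest.json")
    logmsg("done")

    invisible(list(genome = genome, genes = genes, landscape = landscape,
                   fragments = fragments, tracks = tracks, score = score,
                   classification = classification, association = assoc,
                   qualified = qual, plantedCompaction = plantedC,
                   fitRecovery = fitRecovery,
                   fitTssExpression = fitTssExpression,
                   fitTesExpression = fitTesExpression,
                   fitNfrTpm = fitNfrTpm, fitNfrScore = fitNfrScore,
                   rnap = rnapAssoc, metagene = metagene,
                   occupancyCurves = occCurves, tadSummary = tadSum,
                   mnase = mnase, files = files))
}
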