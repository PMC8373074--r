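#' Export a track as bedGraph
#'
#' Adjacent equal values are run-length merged into single bedGraph lines
#' (the \code{RleList} representation compresses them already).
#'
#' @param track an \code{RleList}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
exportBedGraph <- function(track, path) {
    gr <- as(track, "GRanges")
    rtracklayer::export(gr, path, format = "bedGraph")
    invisible(path)
}

#' Import a bedGraph as a full-length track
#'
#' @param path bedGraph file.
#' @param genome a \code{Seqinfo} fixing chromosome lengths; bases not
#'   covered by the file get value 0.
#' @return an \code{RleList}.
#' @export
importBedGraph <- function(path, genome) {
    gr <- rtracklayer::import(path, format = "bedGraph")
    seqinfo(gr) <- genome[intersect(GenomeInfoDb::seqlevels(genome),
                                    GenomeInfoDb::seqlevels(gr))]
    cov <- coverage(gr, weight = "score")
    lens <- GenomeInfoDb::seqlengths(genome)
    # chromosomes absent from the file come back as zero tracks
    as(lapply(names(lens), function(chr) {
        if (chr %in% names(cov)) cov[[chr]] else Rle(0, lens[[chr]])
    }), "RleList") |> stats::setNames(names(lens))
}

#' Export per-fraction fragment BED files
#'
#' One BED file per gradient fraction, 0-based half-open coordinates.
#'
#' @param fragments \code{GRanges} with a \code{fraction} column.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return named character vector of the five paths, invisibly.
#' @export
exportFractionBeds <- function(fragments, dir, prefix = "fragments") {
    if (is.null(fragments$fraction))
        stop("fragments carry no 'fraction' column")
    paths <- vapply(1:5, function(f) {
        p <- file.path(dir, sprintf("%s_fr%d.bed", prefix, f))
        gr <- fragments[fragments$fraction == f]
        mcols(gr) <- NULL
        rtracklayer::export(gr, p, format = "BED")
        p
    }, character(1))
    names(paths) <- paste0("Fr-", 1:5)
    invisible(paths)
}

#' Write/read gene models as 6-column TSV
#'
#' Columns: gene_id, chrom, strand, start, end (0-based half-open, BED
#' convention), tpm.
#'
#' @param genes gene \code{GRanges} with \code{gene_id} and \code{tpm}.
#' @param path TSV file path.
#' @return \code{path}, invisibly.
#' @export
writeGenesTsv <- function(genes, path) {
    df <- data.frame(gene_id = genes$gene_id,
                     chrom = as.character(seqnames(genes)),
                     strand = as.character(strand(genes)),
                     start = start(genes) - 1L,
                     end = end(genes),
                     tpm = genes$tpm)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeGenesTsv
#' @param genome a \code{Seqinfo} for the returned \code{GRanges}.
#' @export
readGenesTsv <- function(path, genome = NULL) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    gr <- GRanges(df$chrom, IRanges(start = df$start + 1L, end = df$end),
                  strand = df$strand, gene_id = df$gene_id, tpm = df$tpm)
    if (!is.null(genome)) seqinfo(gr) <- genome
    gr
}
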