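library(GenomicRanges)

# Build an RleList track from named numeric vectors.
mk_track <- function(...) {
    vs <- list(...)
    as(lapply(vs, S4Vectors::Rle), "RleList")
}

tiny_genome <- function(...) {
    lens <- c(...)
    GenomeInfoDb::Seqinfo(seqnames = names(lens), seqlengths = unname(lens))
}

# One gene on a small chromosome, TSS well inside.
one_gene <- function(chromLen = 50000L, start = 20001L, end = 23000L,
                     strand = "+", id = "g1") {
    g <- GRanges("chr1", IRanges(start, end), strand = strand,
                 gene_id = id, tpm = NA_real_)
    GenomeInfoDb::seqlengths(g) <- chromLen
    g
}

# The standard demonstration run, computed once per session and shared by
# the tests that assert its statistical properties.
.demo_cache <- new.env(parent = emptyenv())
demo_run <- function(seed = 101L) {
    key <- paste0("s", seed)
    if (!exists(key, envir = .demo_cache)) {
        res <- suppressMessages(suppressWarnings(
            runPipeline(demoConfig(seed = seed,
                                   outdir = file.path(tempdir(),
                                                      paste0("demo_", seed))))))
        assign(key, res, envir = .demo_cache)
    }
    get(key, envir = .demo_cache)
}

# Scaled-down pipeline config for fast structural tests.
small_config <- function(seed = 11L, outdir = tempfile("small_run")) {
    cfg <- demoConfig(seed = seed, outdir = outdir)
    cfg$genome$chromLen <- 3e5L
    cfg$genes$n <- 50L
    cfg$fragments$n <- 1e5
    cfg$repeats$n <- 100L
    cfg$tads$n <- 8L
    cfg
}
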