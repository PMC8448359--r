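#' @importFrom Biostrings DNAString DNAStringSet DNAStringSetList
#'   writeXStringSet readDNAStringSet reverseComplement subseq PDict
#'   vcountPDict width DNA_BASES
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges findOverlaps overlapsAny coverage
#' @importFrom S4Vectors queryHits subjectHits Rle runValue runLength
NULL

randomDna <- function(n) {
    paste(sample(Biostrings::DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Generate a synthetic reference: chromosomes, repeat mask, plasmid
#'
#' Builds \code{nChromosomes} random chromosomes, stamps exact-duplication
#' repeat blocks (a single repeat unit copied verbatim at non-overlapping
#' positions covering ~\code{repeatFraction} of each chromosome) and draws a
#' plasmid sequence sharing no 31-mer with the chromosomes on either strand.
#' Because the repeat copies are exact, any mapper must assign reads
#' originating inside them mapping quality 0; the truth-based alignment
#' emitter does the same.
#'
#' @param config A \code{\link{SimConfig}}.
#' @param repeatUnitLength Repeat block length in bp (default 1000, longer
#'   than the discordant clustering window so repeat flanks are genuinely
#'   unmappable).
#' @param plasmidName Contig name used for the plasmid.
#' @return A \code{\link{ReferenceSet}}. Deterministic for a fixed
#'   \code{config@seed}.
#' @examples
#' ref <- generateReference(SimConfig(seed = 1, chromosomeLength = 50000L))
#' ref
#' @export
generateReference <- function(config, repeatUnitLength = 1000L,
                              plasmidName = "plasmid") {
    validObject(config)
    L <- config@chromosomeLength
    nrep <- as.integer(round(config@repeatFraction * L / repeatUnitLength))
    if (config@repeatFraction > 0 && nrep >= 1L &&
        L < (nrep + 2L) * repeatUnitLength)
        stop("chromosome_length too small to place requested repeat blocks")
    withSeed(config@seed, {
        unit <- randomDna(repeatUnitLength)
        chrNames <- paste0("chr", seq_len(config@nChromosomes))
        seqs <- character(config@nChromosomes)
        maskStart <- integer(0); maskChrom <- character(0)
        for (ci in seq_len(config@nChromosomes)) {
            s <- randomDna(L)
            if (nrep > 0L) {
                starts <- placeBlocks(L, nrep, repeatUnitLength)
                for (st in starts)      # st 0-based
                    substr(s, st + 1L, st + repeatUnitLength) <- unit
                maskStart <- c(maskStart, starts)
                maskChrom <- c(maskChrom, rep(chrNames[ci], length(starts)))
            }
            seqs[ci] <- s
        }
        chromosomes <- DNAStringSet(seqs)
        names(chromosomes) <- chrNames
        plas <- drawPlasmid(chromosomes, config@plasmidLength)
        names(plas) <- plasmidName
        mask <- GRanges(maskChrom,
                        IRanges(start = maskStart + 1L,
                                width = repeatUnitLength))
        new("ReferenceSet", chromosomes = chromosomes, plasmid = plas,
            repeatMask = sort(mask), plasmidName = plasmidName)
    })
}

## non-overlapping 0-based block starts, separated by >= one block length
placeBlocks <- function(L, n, unit) {
    starts <- integer(0)
    tries <- 0L
    while (length(starts) < n) {
        tries <- tries + 1L
        if (tries > 1000L * n)
            stop("chromosome_length too small to place requested repeat blocks")
        cand <- sample.int(L - 2L * unit, 1L)  # keep off the ends
        if (all(abs(cand - starts) >= 2L * unit))
            starts <- c(starts, cand)
    }
    sort(starts)
}

## plasmid sequence with no shared 31-mer (either strand) with chromosomes
drawPlasmid <- function(chromosomes, len, k = 31L) {
    for (i in 1:20) {
        p <- DNAStringSet(randomDna(len))
        if (sharedKmers(p[[1]], chromosomes, k) == 0L)
            return(p)
    }
    stop("failed to draw a plasmid with no shared ", k, "-mers")
}

## number of k-mers of 'query' (both strands) present in 'subjects'
sharedKmers <- function(query, subjects, k = 31L) {
    n <- length(query)
    if (n < k) return(0L)
    kmers <- DNAStringSet(query,
                          start = seq_len(n - k + 1L), width = k)
    pd <- PDict(c(kmers, reverseComplement(kmers)))
    sum(vcountPDict(pd, subjects))
}

#' Write a ReferenceSet to disk
#'
#' Writes the combined reference FASTA (chromosomes followed by the plasmid
#' contig) and the repeat mask as BED (0-based half-open, as BED requires).
#'
#' @param ref A \code{\link{ReferenceSet}}.
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named character vector of the written paths.
#' @export
writeReference <- function(ref, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    fasta <- file.path(dir, "reference.fasta")
    writeXStringSet(c(ref@chromosomes, ref@plasmid), fasta)
    bed <- file.path(dir, "repeats.bed")
    m <- ref@repeatMask
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(m)),
                     start = GenomicRanges::start(m) - 1L,
                     end = GenomicRanges::end(m))
    utils::write.table(df, bed, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(c(fasta = fasta, repeats = bed))
}
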