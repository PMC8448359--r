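## Discordant-pair collection, soft-clip evidence table, per-base depth.

#' Calling parameters
#'
#' Bundles the structural-variant caller's tunables. Defaults:
#' \code{mapqMin} 20 (alignments below it feed only the repeat-flank
#' diagnosis); \code{minSupport} 2 pairs per cluster; \code{windowBp}
#' fragmentMean + 3 fragmentSd; \code{maxPairDistance} 200 kb (above the
#' largest junction deletion expected); \code{duplicationCap} 1000 bp
#' (target-site duplications beyond it are flagged unknown);
#' \code{minClip} 5 bp minimum soft-clip considered junction evidence.
#'
#' @param config A \code{\link{SimConfig}} (fragment statistics).
#' @param mapqMin,minSupport,windowBp,maxPairDistance,duplicationCap,minClip
#'   See description.
#' @return Named list of parameters.
#' @export
svParams <- function(config, mapqMin = 20L, minSupport = 2L,
                     windowBp = NULL, maxPairDistance = 200000L,
                     duplicationCap = 1000L, minClip = 5L) {
    if (is.null(windowBp))
        windowBp <- as.integer(config@fragmentMean + 3 * config@fragmentSd)
    list(mapqMin = as.integer(mapqMin), minSupport = as.integer(minSupport),
         windowBp = as.integer(windowBp),
         maxPairDistance = as.integer(maxPairDistance),
         duplicationCap = as.integer(duplicationCap),
         minClip = as.integer(minClip),
         fragmentMean = config@fragmentMean,
         fragmentSd = config@fragmentSd,
         readLength = config@readLength)
}

#' Partition read pairs into discordant classes
#'
#' A pair is discordant iff its mates map to different contigs, or to the
#' same contig with non-facing orientation, or with an implied fragment
#' length outside fragmentMean +/- 3 fragmentSd. Discordant pairs are
#' partitioned into plasmid-paired (one mate on the plasmid contig),
#' interchromosomal and intrachromosomal-aberrant sets. Pairs whose
#' chromosomal mate falls below \code{mapqMin} are excluded from clustering
#' but retained in a side channel used for the repeat-flank diagnosis.
#'
#' @param pairs Pair table (\code{\link{emitAlignments}} or
#'   \code{\link{readAlignments}}).
#' @param plasmidContig Name of the plasmid contig.
#' @param params \code{\link{svParams}} list.
#' @return List with elements \code{plasmid_paired} (chromosomal-anchor
#'   table), \code{interchromosomal}, \code{intrachromosomal_aberrant}
#'   (two-anchor tables), \code{lowmapq} (side channel), and \code{skipped}
#'   (count of pairs with missing mate information).
#' @export
collectDiscordantPairs <- function(pairs, plasmidContig, params) {
    both <- pairs$mapped1 & pairs$mapped2
    skipped <- sum(!both)
    p <- pairs[both, , drop = FALSE]
    isP1 <- p$contig1 == plasmidContig
    isP2 <- p$contig2 == plasmidContig
    plasmid <- xor(isP1, isP2)
    diffContig <- p$contig1 != p$contig2
    lo <- params$fragmentMean - 3 * params$fragmentSd
    hi <- params$fragmentMean + 3 * params$fragmentSd
    implied <- pmax(p$end1, p$end2) - pmin(p$start1, p$start2)
    facing <- p$strand1 != p$strand2 &
        ifelse(p$strand1 == "+", p$start1 <= p$start2,
               p$start2 <= p$start1)
    aberrant <- !diffContig & !(isP1 & isP2) &
        (!facing | implied < lo | implied > hi)

    ## plasmid-paired: normalize to the chromosomal anchor
    pp <- p[plasmid & diffContig, , drop = FALSE]
    chromIs1 <- pp$contig2 == plasmidContig
    anchor <- data.frame(
        read_id = pp$read_id,
        chrom = ifelse(chromIs1, pp$contig1, pp$contig2),
        astart = ifelse(chromIs1, pp$start1, pp$start2),
        aend = ifelse(chromIs1, pp$end1, pp$end2),
        strand = ifelse(chromIs1, pp$strand1, pp$strand2),
        mapq = ifelse(chromIs1, pp$mapq1, pp$mapq2),
        stringsAsFactors = FALSE)
    anchor$side <- ifelse(anchor$strand == "+", "left", "right")
    ppOK <- anchor[anchor$mapq >= params$mapqMin, , drop = FALSE]
    ppLow <- anchor[anchor$mapq < params$mapqMin, , drop = FALSE]

    ## genome-genome discordant pairs, both anchors kept
    gg <- p[(diffContig & !plasmid) | aberrant, , drop = FALSE]
    ggOK <- gg[pmin(gg$mapq1, gg$mapq2) >= params$mapqMin, , drop = FALSE]
    list(plasmid_paired = ppOK,
         interchromosomal =
             ggOK[ggOK$contig1 != ggOK$contig2, , drop = FALSE],
         intrachromosomal_aberrant =
             ggOK[ggOK$contig1 == ggOK$contig2, , drop = FALSE],
         lowmapq = ppLow,
         skipped = skipped)
}

#' Soft-clip evidence table
#'
#' One row per sufficiently long soft-clip on a well-mapped mate: the
#' reference coordinate of the junction the clip marks (alignment end for
#' right clips, alignment start for left clips, 0-based).
#'
#' @param pairs Pair table.
#' @param params \code{\link{svParams}} list.
#' @return data.frame with contig, coord, type ("end" or "start").
#' @export
clipTable <- function(pairs, params) {
    rows <- list()
    for (mate in 1:2) {
        g <- function(f) pairs[[paste0(f, mate)]]
        ok <- g("mapped") & g("mapq") >= params$mapqMin
        re <- ok & g("clipR") >= params$minClip
        le <- ok & g("clipL") >= params$minClip
        rows[[length(rows) + 1L]] <- data.frame(
            contig = g("contig")[re], coord = g("end")[re],
            type = rep("end", sum(re)), stringsAsFactors = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
            contig = g("contig")[le], coord = g("start")[le],
            type = rep("start", sum(le)), stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
}

#' In-read deletion gap table
#'
#' Extracts per-read deletion operations (CIGAR D) from well-mapped mates.
#'
#' @param pairs Pair table.
#' @param params \code{\link{svParams}} list.
#' @return data.frame with contig, delPos (0-based), delLen.
#' @export
gapTable <- function(pairs, params) {
    rows <- list()
    for (mate in 1:2) {
        g <- function(f) pairs[[paste0(f, mate)]]
        ok <- g("mapped") & g("mapq") >= params$mapqMin &
            !is.na(g("delLen")) & g("delLen") > 0L
        rows[[length(rows) + 1L]] <- data.frame(
            contig = g("contig")[ok], delPos = g("delPos")[ok],
            delLen = g("delLen")[ok], stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
}

#' Per-base depth from a pair table
#'
#' Coverage of the aligned portions of all mapped mates (soft-clipped bases
#' and in-read deletion gaps excluded), per contig.
#'
#' @param pairs Pair table.
#' @param contigLengths Named integer vector of contig lengths.
#' @return A named list of \code{Rle} per contig.
#' @export
computeDepth <- function(pairs, contigLengths) {
    out <- list()
    for (ct in names(contigLengths)) {
        irs <- list()
        for (mate in 1:2) {
            g <- function(f) pairs[[paste0(f, mate)]]
            ok <- g("mapped") & g("contig") == ct
            s <- g("start")[ok]; e <- g("end")[ok]
            dp <- g("delPos")[ok]; dl <- g("delLen")[ok]
            hasD <- !is.na(dl) & dl > 0L
            ## split at deletion ops so the gap itself gets no depth
            s2 <- c(s[!hasD], s[hasD], dp[hasD] + dl[hasD])
            e2 <- c(e[!hasD], dp[hasD], e[hasD])
            keep <- e2 > s2
            irs[[mate]] <- IRanges::IRanges(s2[keep] + 1L, e2[keep])
        }
        ir <- c(irs[[1]], irs[[2]])
        out[[ct]] <- IRanges::coverage(ir, width = contigLengths[[ct]])
    }
    out
}

## mean depth over 0-based [s, e)
depthMean <- function(depth, chrom, s, e) {
    if (is.null(depth[[chrom]]) || e <= s) return(NA_real_)
    n <- length(depth[[chrom]])
    s1 <- max(s + 1L, 1L); e1 <- min(e, n)
    if (e1 < s1) return(NA_real_)
    mean(S4Vectors::window(depth[[chrom]], s1, e1))
}
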