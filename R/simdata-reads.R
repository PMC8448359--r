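## Fragment sampling, truth-based alignment emission, FASTQ output, SAM IO.

#' Sample sequencing fragments from a mutant genome
#'
#' Fragment count is round(coverage * genome_length / (2 * read_length));
#' fragments are uniform over the mutated genome with lengths
#' Normal(fragmentMean, fragmentSd) truncated at [2 * readLength, Inf).
#'
#' @param mutant A \code{\link{MutantGenome}}.
#' @param config A \code{\link{SimConfig}}.
#' @param seed Integer seed.
#' @return data.frame with columns chrom (mutated chromosome), start
#'   (0-based, mutated coordinates), len.
#' @export
simulateFragments <- function(mutant, config, seed) {
    lens <- mutatedLengths(mutant)
    G <- sum(lens)
    nPairs <- as.integer(round(config@coverage * G /
                                   (2 * config@readLength)))
    withSeed(seed, {
        fl <- round(stats::rnorm(nPairs, config@fragmentMean,
                                 config@fragmentSd))
        fl <- pmax(fl, 2 * config@readLength)
        chrom <- sample(names(lens), nPairs, replace = TRUE,
                        prob = lens / G)
        maxStart <- pmax(lens[chrom] - fl, 0)
        fl <- pmin(fl, lens[chrom])
        start <- floor(stats::runif(nPairs) * (maxStart + 1))
        data.frame(chrom = chrom, start = as.integer(start),
                   len = as.integer(fl), stringsAsFactors = FALSE)
    })
}

## ---------------------------------------------------------------------------
## mapping mutated-genome intervals back to the reference
## ---------------------------------------------------------------------------

## Map read intervals [s, e) on one mutated chromosome to reference
## alignments. Returns a data.frame with contig, start, end (0-based
## half-open on the reference), strand, clipL, clipR (in reference
## orientation), delPos, delLen, mapped.
mapIntervals <- function(segs, s, e, mutStrand, readDelMax = 100L,
                         minSeed = 20L) {
    w <- segs$end - segs$start
    mstart <- cumsum(c(0L, w[-length(w)]))
    n <- length(s)
    i <- findInterval(s, mstart)
    j <- findInterval(e - 1L, mstart)
    contig <- character(n); rstart <- integer(n); rend <- integer(n)
    strand <- character(n); clipL <- integer(n); clipR <- integer(n)
    delPos <- rep(NA_integer_, n); delLen <- rep(NA_integer_, n)
    mapped <- rep(TRUE, n)

    mapSimple <- function(idx, seg, ps, pe) {
        ## map sub-interval [ps, pe) lying wholly inside segment 'seg'
        off1 <- ps - mstart[seg]
        off2 <- pe - mstart[seg]
        if (segs$strand[seg] == "+") {
            list(contig = segs$src[seg],
                 start = segs$start[seg] + off1,
                 end = segs$start[seg] + off2,
                 flip = FALSE)
        } else {
            list(contig = segs$src[seg],
                 start = segs$end[seg] - off2,
                 end = segs$end[seg] - off1,
                 flip = TRUE)
        }
    }

    simple <- which(i == j)
    if (length(simple)) {
        seg <- i[simple]
        off1 <- s[simple] - mstart[seg]
        off2 <- e[simple] - mstart[seg]
        plus <- segs$strand[seg] == "+"
        contig[simple] <- segs$src[seg]
        rstart[simple] <- ifelse(plus, segs$start[seg] + off1,
                                 segs$end[seg] - off2)
        rend[simple] <- ifelse(plus, segs$start[seg] + off2,
                               segs$end[seg] - off1)
        strand[simple] <- ifelse(plus == (mutStrand[simple] == "+"),
                                 "+", "-")
    }

    for (k in which(i != j)) {
        ## read spans >= 1 junction: portions per touched segment
        segIdx <- i[k]:j[k]
        ps <- pmax(s[k], mstart[segIdx])
        pe <- pmin(e[k], mstart[segIdx] + w[segIdx])
        plen <- pe - ps
        merged <- FALSE
        if (length(segIdx) == 2L) {
            a <- segIdx[1]; b <- segIdx[2]
            colinear <- segs$src[a] == segs$src[b] &&
                segs$strand[a] == "+" && segs$strand[b] == "+"
            gap <- if (colinear) segs$start[b] - segs$end[a] else -1L
            if (colinear && gap >= 0L && gap <= readDelMax &&
                all(plen >= minSeed)) {
                rs <- segs$start[a] + (ps[1] - mstart[a])
                contig[k] <- segs$src[a]
                rstart[k] <- rs
                rend[k] <- rs + plen[1] + gap + plen[2]
                strand[k] <- if (mutStrand[k] == "+") "+" else "-"
                if (gap > 0L) {
                    delPos[k] <- rs + plen[1]
                    delLen[k] <- gap
                }
                merged <- TRUE
            }
        }
        if (!merged) {
            best <- which.max(plen)  # leftmost wins ties
            if (plen[best] < minSeed) { mapped[k] <- FALSE; next }
            m <- mapSimple(k, segIdx[best], ps[best], pe[best])
            contig[k] <- m$contig
            rstart[k] <- m$start
            rend[k] <- m$end
            before <- ps[best] - s[k]
            after <- e[k] - pe[best]
            if (!m$flip) {
                clipL[k] <- before; clipR[k] <- after
                strand[k] <- if (mutStrand[k] == "+") "+" else "-"
            } else {
                clipL[k] <- after; clipR[k] <- before
                strand[k] <- if (mutStrand[k] == "+") "-" else "+"
            }
        }
    }
    data.frame(contig = contig, start = rstart, end = rend,
               strand = strand, clipL = clipL, clipR = clipR,
               delPos = delPos, delLen = delLen, mapped = mapped,
               stringsAsFactors = FALSE)
}

#' Emit truth-based alignments for a simulated mutant
#'
#' Places every mate at its true reference origin by mapping fragment
#' coordinates through the mutant's segment map (standing in for an
#' off-the-shelf aligner, which is deliberately not re-implemented).
#' Junction-spanning reads are soft-clipped at the breakpoint; reads
#' crossing a colinear gap of at most \code{readDelMax} bp on the same
#' contig receive an in-read deletion operation instead, mirroring a banded
#' aligner. Reads originating in repeat blocks get mapping quality 0; all
#' others 60. Proper-pair flags are set only for concordant pairs (same
#' contig, facing orientation, implied fragment within fragmentMean +/- 3
#' fragmentSd).
#'
#' @param mutant A \code{\link{MutantGenome}}.
#' @param reference The \code{\link{ReferenceSet}}.
#' @param config A \code{\link{SimConfig}}.
#' @param seed Integer seed (used if \code{fragments} is NULL).
#' @param fragments Optional fragment table from
#'   \code{\link{simulateFragments}} (retained provenance).
#' @param readDelMax Largest colinear gap represented as an in-read
#'   deletion op (bp).
#' @param minSeed Smallest mappable read portion (bp); junction-spanning
#'   reads with no portion this long are recorded unmapped.
#' @return data.frame of read pairs (one row per pair): per-mate contig,
#'   start, end (0-based half-open), strand, mapq, clipL, clipR, delPos,
#'   delLen, mapped, plus a proper flag.
#' @export
emitAlignments <- function(mutant, reference, config, seed = 1L,
                           fragments = NULL, readDelMax = 100L,
                           minSeed = 20L) {
    if (is.null(fragments))
        fragments <- simulateFragments(mutant, config, seed)
    rl <- config@readLength
    pairs <- NULL
    for (ch in names(mutant@segments)) {
        fr <- fragments[fragments$chrom == ch, , drop = FALSE]
        if (nrow(fr) == 0L) next
        segs <- mutant@segments[[ch]]
        m1 <- mapIntervals(segs, fr$start, fr$start + rl,
                           rep("+", nrow(fr)), readDelMax, minSeed)
        m2 <- mapIntervals(segs, fr$start + fr$len - rl,
                           fr$start + fr$len,
                           rep("-", nrow(fr)), readDelMax, minSeed)
        df <- data.frame(
            read_id = sprintf("%s_%s_%06d", mutant@mutantId, ch,
                              seq_len(nrow(fr))),
            contig1 = m1$contig, start1 = m1$start, end1 = m1$end,
            strand1 = m1$strand, clipL1 = m1$clipL, clipR1 = m1$clipR,
            delPos1 = m1$delPos, delLen1 = m1$delLen, mapped1 = m1$mapped,
            contig2 = m2$contig, start2 = m2$start, end2 = m2$end,
            strand2 = m2$strand, clipL2 = m2$clipL, clipR2 = m2$clipR,
            delPos2 = m2$delPos, delLen2 = m2$delLen, mapped2 = m2$mapped,
            stringsAsFactors = FALSE)
        pairs <- rbind(pairs, df)
    }
    if (is.null(pairs)) return(emptyPairTable())
    pairs$mapq1 <- alignMapq(pairs$contig1, pairs$start1, pairs$end1,
                             pairs$mapped1, reference)
    pairs$mapq2 <- alignMapq(pairs$contig2, pairs$start2, pairs$end2,
                             pairs$mapped2, reference)
    pairs$proper <- properPair(pairs, config)
    rownames(pairs) <- NULL
    pairs
}

emptyPairTable <- function() {
    data.frame(read_id = character(0), contig1 = character(0),
               start1 = integer(0), end1 = integer(0),
               strand1 = character(0), clipL1 = integer(0),
               clipR1 = integer(0), delPos1 = integer(0),
               delLen1 = integer(0), mapped1 = logical(0),
               contig2 = character(0), start2 = integer(0),
               end2 = integer(0), strand2 = character(0),
               clipL2 = integer(0), clipR2 = integer(0),
               delPos2 = integer(0), delLen2 = integer(0),
               mapped2 = logical(0), mapq1 = integer(0),
               mapq2 = integer(0), proper = logical(0),
               stringsAsFactors = FALSE)
}

alignMapq <- function(contig, start, end, mapped, reference) {
    mq <- ifelse(mapped, 60L, 0L)
    m <- reference@repeatMask
    if (length(m) == 0L) return(mq)
    idx <- which(mapped)
    if (length(idx) == 0L) return(mq)
    q <- GenomicRanges::GRanges(contig[idx],
                                IRanges::IRanges(start[idx] + 1L,
                                                 pmax(end[idx], start[idx] + 1L)))
    hit <- IRanges::overlapsAny(q, m)
    mq[idx[hit]] <- 0L
    mq
}

properPair <- function(p, config) {
    lo <- config@fragmentMean - 3 * config@fragmentSd
    hi <- config@fragmentMean + 3 * config@fragmentSd
    implied <- pmax(p$end1, p$end2) - pmin(p$start1, p$start2)
    fwdFirst <- ifelse(p$strand1 == "+", p$start1 <= p$start2,
                       p$start2 <= p$start1)
    p$mapped1 & p$mapped2 & p$contig1 == p$contig2 &
        p$strand1 != p$strand2 & fwdFirst &
        implied >= lo & implied <= hi
}

#' Write paired FASTQ for a simulated mutant
#'
#' Reconstructs the mutated genome, extracts each fragment's terminal
#' \code{readLength} bases (/1 forward, /2 reverse-complemented) and
#' applies uniform substitution errors at \code{baseErrorRate}.
#'
#' @inheritParams emitAlignments
#' @param outPrefix Path prefix; writes \code{<prefix>_1.fastq} and
#'   \code{<prefix>_2.fastq}.
#' @return Invisibly, the two file paths; the fragment table is attached
#'   as attribute \code{"fragments"}.
#' @export
simulateReads <- function(mutant, reference, config, seed = 1L,
                          outPrefix = tempfile("reads"),
                          fragments = NULL) {
    if (is.null(fragments))
        fragments <- simulateFragments(mutant, config, seed)
    rl <- config@readLength
    seqs <- mutantSequences(mutant, reference)
    r1 <- r2 <- character(nrow(fragments))
    ids <- character(nrow(fragments))
    for (ch in names(seqs)) {
        idx <- which(fragments$chrom == ch)
        if (!length(idx)) next
        st <- fragments$start[idx]
        fl <- fragments$len[idx]
        v1 <- Biostrings::extractAt(
            seqs[[ch]], IRanges::IRanges(st + 1L, st + rl))
        v2 <- Biostrings::extractAt(
            seqs[[ch]], IRanges::IRanges(st + fl - rl + 1L, st + fl))
        r1[idx] <- as.character(v1)
        r2[idx] <- as.character(reverseComplement(v2))
        ids[idx] <- sprintf("%s_%s_%06d", mutant@mutantId, ch,
                            seq_along(idx))
    }
    if (config@baseErrorRate > 0)
        withSeed(subSeed(seed, 1L), {
            r1 <- addErrors(r1, config@baseErrorRate)
            r2 <- addErrors(r2, config@baseErrorRate)
        })
    f1 <- paste0(outPrefix, "_1.fastq")
    f2 <- paste0(outPrefix, "_2.fastq")
    writeFastq(ids, r1, f1, "/1")
    writeFastq(ids, r2, f2, "/2")
    out <- c(f1, f2)
    attr(out, "fragments") <- fragments
    invisible(out)
}

addErrors <- function(reads, rate) {
    nb <- sum(nchar(reads))
    nerr <- stats::rbinom(1L, nb, rate)
    if (nerr == 0L) return(reads)
    rl <- nchar(reads[1])
    pos <- sample.int(nb, nerr)
    ri <- (pos - 1L) %/% rl + 1L
    off <- (pos - 1L) %% rl + 1L
    for (k in seq_len(nerr)) {
        old <- substr(reads[ri[k]], off[k], off[k])
        subst <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
        substr(reads[ri[k]], off[k], off[k]) <- subst
    }
    reads
}

writeFastq <- function(ids, seqs, path, suffix) {
    qual <- strrep("I", nchar(seqs))
    out <- character(4L * length(ids))
    out[seq(1L, length(out), 4L)] <- paste0("@", ids, suffix)
    out[seq(2L, length(out), 4L)] <- seqs
    out[seq(3L, length(out), 4L)] <- "+"
    out[seq(4L, length(out), 4L)] <- qual
    writeLines(out, path)
}
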