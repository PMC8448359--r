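## SAM emission and ingest; truth-table TSV round trip.

cigarFor <- function(start, end, clipL, clipR, delPos, delLen) {
    mlen <- end - start
    mid <- ifelse(!is.na(delLen) & delLen > 0L,
                  paste0(delPos - start, "M", delLen, "D",
                         mlen - (delPos - start) - delLen, "M"),
                  paste0(mlen, "M"))
    paste0(ifelse(clipL > 0L, paste0(clipL, "S"), ""), mid,
           ifelse(clipR > 0L, paste0(clipR, "S"), ""))
}

samFlags <- function(p, mate) {
    other <- if (mate == 1L) 2L else 1L
    g <- function(f, m) p[[paste0(f, m)]]
    flag <- rep(1L, nrow(p))                      # paired
    flag <- flag + ifelse(p$proper, 2L, 0L)
    flag <- flag + ifelse(!g("mapped", mate), 4L, 0L)
    flag <- flag + ifelse(!g("mapped", other), 8L, 0L)
    flag <- flag + ifelse(g("mapped", mate) &
                              g("strand", mate) == "-", 16L, 0L)
    flag <- flag + ifelse(g("mapped", other) &
                              g("strand", other) == "-", 32L, 0L)
    flag + if (mate == 1L) 64L else 128L
}

#' Write a pair table as SAM
#'
#' Emits one coordinate-unsorted SAM record per mate with CIGAR built from
#' the clip/deletion structure; SEQ and QUAL are \code{*} (alignments are
#' emitted from truth, not from read sequences). The combined reference
#' header carries the chromosomes plus the plasmid contig.
#'
#' @param pairs Pair table from \code{\link{emitAlignments}}.
#' @param reference A \code{\link{ReferenceSet}}.
#' @param path Output SAM path.
#' @return Invisibly, \code{path}.
#' @export
writeSam <- function(pairs, reference, path) {
    sq <- c(Biostrings::width(reference@chromosomes),
            Biostrings::width(reference@plasmid))
    nm <- c(names(reference@chromosomes), reference@plasmidName)
    hdr <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:%s\tLN:%d", nm, sq))
    recs <- character(0)
    for (mate in 1:2) {
        g <- function(f) pairs[[paste0(f, mate)]]
        o <- function(f) pairs[[paste0(f, if (mate == 1L) 2L else 1L)]]
        flag <- samFlags(pairs, mate)
        mapped <- g("mapped")
        rname <- ifelse(mapped, g("contig"), "*")
        pos <- ifelse(mapped, g("start") + 1L, 0L)
        mapq <- ifelse(mapped, g("mapq"), 0L)
        cig <- ifelse(mapped,
                      cigarFor(g("start"), g("end"), g("clipL"),
                               g("clipR"), g("delPos"), g("delLen")),
                      "*")
        omapped <- o("mapped")
        rnext <- ifelse(omapped,
                        ifelse(o("contig") == rname, "=", o("contig")), "*")
        pnext <- ifelse(omapped, o("start") + 1L, 0L)
        tlen <- ifelse(mapped & omapped & o("contig") == g("contig"),
                       pmax(g("end"), o("end")) -
                           pmin(g("start"), o("start")), 0L)
        tlen <- ifelse(g("start") > o("start"), -tlen, tlen)
        recs <- c(recs, paste(pairs$read_id, flag, rname, pos, mapq, cig,
                              rnext, pnext, tlen, "*", "*", sep = "\t"))
    }
    writeLines(c(hdr, recs), path)
    invisible(path)
}

parseCigar <- function(cig) {
    ## returns clipL, clipR, refLen (M+D+N), largest D (pos offset, len)
    n <- length(cig)
    clipL <- clipR <- refLen <- integer(n)
    delOff <- delLen <- rep(NA_integer_, n)
    ops <- regmatches(cig, gregexpr("[0-9]+[MIDNSHP=X]", cig))
    for (k in seq_len(n)) {
        v <- ops[[k]]
        if (length(v) == 0L) next
        len <- as.integer(sub("[A-Z=]$", "", v))
        op <- sub("^[0-9]+", "", v)
        if (op[1] %in% c("S", "H")) clipL[k] <- len[1]
        last <- length(op)
        if (last > 1L && op[last] %in% c("S", "H")) clipR[k] <- len[last]
        refc <- op %in% c("M", "D", "N", "=", "X")
        refLen[k] <- sum(len[refc])
        dd <- which(op == "D")
        if (length(dd)) {
            dbest <- dd[which.max(len[dd])]
            before <- seq_len(dbest - 1L)
            delOff[k] <- sum(len[before][op[before] %in%
                                             c("M", "D", "N", "=", "X")])
            delLen[k] <- len[dbest]
        }
    }
    list(clipL = clipL, clipR = clipR, refLen = refLen,
         delOff = delOff, delLen = delLen)
}

#' Read alignments from SAM/BAM into a pair table
#'
#' Ingest adapter for externally produced alignments: accepts SAM (converted
#' via \code{Rsamtools::asBam}) or BAM, pairs primary records by read name
#' and returns the same pair-table layout that \code{\link{emitAlignments}}
#' produces, so all downstream calling behaves identically.
#'
#' @param path SAM or BAM file.
#' @param config A \code{\link{SimConfig}} supplying fragment statistics
#'   for the proper-pair recomputation.
#' @return Pair table (see \code{\link{emitAlignments}}).
#' @export
readAlignments <- function(path, config) {
    if (grepl("\\.sam$", path, ignore.case = TRUE)) {
        dest <- tempfile(fileext = "")
        path <- Rsamtools::asBam(path, destination = dest,
                                 overwrite = TRUE, indexDestination = FALSE)
    }
    par <- Rsamtools::ScanBamParam(
        what = c("qname", "flag", "rname", "pos", "mapq", "cigar"),
        flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                      isSupplementaryAlignment = FALSE))
    b <- Rsamtools::scanBam(path, param = par)[[1]]
    flag <- b$flag
    first <- bitwAnd(flag, 64L) > 0L
    unmapped <- bitwAnd(flag, 4L) > 0L
    rev <- bitwAnd(flag, 16L) > 0L
    cg <- parseCigar(ifelse(is.na(b$cigar), "", b$cigar))
    rec <- data.frame(
        read_id = b$qname,
        contig = as.character(b$rname),
        start = ifelse(unmapped, NA_integer_, b$pos - 1L),
        strand = ifelse(rev, "-", "+"),
        mapq = ifelse(unmapped, 0L, as.integer(b$mapq)),
        clipL = cg$clipL, clipR = cg$clipR,
        mapped = !unmapped, stringsAsFactors = FALSE)
    rec$end <- rec$start + cg$refLen
    rec$delPos <- ifelse(is.na(cg$delOff), NA_integer_,
                         rec$start + cg$delOff)
    rec$delLen <- cg$delLen
    m1 <- rec[first, , drop = FALSE]
    m2 <- rec[!first, , drop = FALSE]
    idx <- match(m1$read_id, m2$read_id)
    keep <- !is.na(idx)
    m1 <- m1[keep, , drop = FALSE]
    m2 <- m2[idx[keep], , drop = FALSE]
    out <- data.frame(
        read_id = m1$read_id,
        contig1 = m1$contig, start1 = m1$start, end1 = m1$end,
        strand1 = m1$strand, clipL1 = m1$clipL, clipR1 = m1$clipR,
        delPos1 = m1$delPos, delLen1 = m1$delLen, mapped1 = m1$mapped,
        contig2 = m2$contig, start2 = m2$start, end2 = m2$end,
        strand2 = m2$strand, clipL2 = m2$clipL, clipR2 = m2$clipR,
        delPos2 = m2$delPos, delLen2 = m2$delLen, mapped2 = m2$mapped,
        mapq1 = m1$mapq, mapq2 = m2$mapq,
        stringsAsFactors = FALSE)
    ## coordinates may be NA for unmapped mates; proper-pair recomputed
    out$start1[is.na(out$start1)] <- 0L; out$end1[is.na(out$end1)] <- 0L
    out$start2[is.na(out$start2)] <- 0L; out$end2[is.na(out$end2)] <- 0L
    out$proper <- properPair(out, config)
    hdr <- Rsamtools::scanBamHeader(path)[[1]]
    attr(out, "targets") <- names(hdr$targets)
    out
}

## ---------------------------------------------------------------------------
## truth tables
## ---------------------------------------------------------------------------

#' Write a truth-event table as TSV
#'
#' Coordinates are written 1-based inclusive (convention documented in the
#' file header): \code{left_bp} is the last chromosomal base before the
#' plasmid/deletion, \code{right_bp} the first base after it, so a deletion
#' of g bp spans [left_bp + 1, right_bp - 1]. \code{gap_size} is signed:
#' positive = deleted genome, negative = duplicated, 0 = perfect.
#'
#' @param truth Truth table from \code{\link{simulateMutant}} (internal
#'   0-based coordinates).
#' @param path Output TSV path.
#' @return Invisibly, \code{path}.
#' @export
writeTruth <- function(truth, path) {
    out <- truth
    out$left_bp <- out$left_bp          # 0-based junction == 1-based last base
    out$right_bp <- out$right_bp + 1L   # 1-based first base after
    out$partner_start <- out$partner_start + 1L
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("# truth events; coordinates 1-based inclusive",
                 "# left_bp = last base before event; right_bp = first base after",
                 "# gap_size: + deleted bp, - duplicated bp, 0 perfect"),
               con)
    utils::write.table(out, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a truth TSV back to internal coordinates
#' @param path TSV written by \code{\link{writeTruth}}.
#' @return Truth table in internal 0-based coordinates.
#' @export
readTruth <- function(path) {
    t <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
    t$right_bp <- t$right_bp - 1L
    t$partner_start <- t$partner_start - 1L
    t$partner_chrom <- as.character(t$partner_chrom)
    t
}
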