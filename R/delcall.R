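## Deletion calling unassociated with plasmid insertions: in-read gaps,
## spanning pairs with clip refinement, coverage drops.

emptyDeletions <- function() {
    data.frame(mutant_id = character(0), chrom = character(0),
               start = integer(0), end = integer(0), size = integer(0),
               evidence = character(0), n_support = integer(0),
               linked_to_insertion = logical(0), stringsAsFactors = FALSE)
}

#' Call deletions from in-read gap operations
#'
#' Per-read deletion gaps of at least \code{minSize} bp agreeing within
#' +/- 2 bp across at least \code{minSupport} reads are merged into one
#' call with the modal position and length (size-exact).
#'
#' @param gaps Gap table from \code{\link{gapTable}}.
#' @param minSize Minimum deletion size (bp).
#' @param minSupport Minimum supporting reads.
#' @return Deletion table (evidence \code{gapped_read}).
#' @export
callGapDeletions <- function(gaps, minSize = 20L, minSupport = 2L) {
    out <- emptyDeletions()
    if (is.null(gaps) || nrow(gaps) == 0L) return(out)
    g <- gaps[gaps$delLen >= minSize, , drop = FALSE]
    if (nrow(g) == 0L) return(out)
    for (ct in unique(g$contig)) {
        gc <- g[g$contig == ct, , drop = FALSE]
        cid <- chain1d(gc$delPos, 2L)
        for (cc in unique(cid)) {
            m <- gc[cid == cc, , drop = FALSE]
            if (nrow(m) < minSupport) next
            pos <- modalValue(m$delPos)
            len <- modalValue(m$delLen)
            out <- rbind(out, data.frame(
                mutant_id = NA_character_, chrom = ct, start = pos,
                end = pos + len, size = len, evidence = "gapped_read",
                n_support = nrow(m), linked_to_insertion = NA,
                stringsAsFactors = FALSE))
        }
    }
    out
}

modalValue <- function(x) {
    tab <- table(x)
    as.integer(names(tab)[which.max(tab)])
}

#' Call deletions from spanning pairs and paired soft-clips
#'
#' Two evidence routes for deletions too large for in-read gaps and too
#' small for robust coverage runs: (i) clusters of facing intrachromosomal
#' pairs with implied fragment length beyond fragmentMean + 3 fragmentSd,
#' whose innermost mate boundaries bracket the deletion, and (ii) a
#' right-clip cluster paired with a downstream left-clip cluster within
#' \code{maxClipPair} bp. Boundaries are refined to modal clip coordinates
#' when clips are present (size-exact in that case).
#'
#' @param aberrant Intrachromosomal-aberrant pair table from
#'   \code{\link{collectDiscordantPairs}}.
#' @param clips Clip table from \code{\link{clipTable}}.
#' @param params \code{\link{svParams}} list.
#' @param minSize Minimum reported size (bp).
#' @param maxClipPair Maximum span for clip-only pairing (bp).
#' @return Deletion table (evidence \code{spanning_pair}).
#' @export
callSpanningDeletions <- function(aberrant, clips, params, minSize = 100L,
                                  maxClipPair = 1000L) {
    out <- emptyDeletions()
    addCall <- function(ct, lo, hi, n) {
        if (hi - lo < minSize) return()
        out <<- rbind(out, data.frame(
            mutant_id = NA_character_, chrom = ct, start = lo, end = hi,
            size = hi - lo, evidence = "spanning_pair", n_support = n,
            linked_to_insertion = NA, stringsAsFactors = FALSE))
    }
    refine <- function(ct, coord, type) {
        cc <- clips$coord[clips$contig == ct & clips$type == type &
                              abs(clips$coord - coord) <= params$windowBp]
        if (length(cc) >= 1L && diff(range(cc)) <= 2L) modalValue(cc)
        else coord
    }
    ## (i) facing long-implied pairs
    if (!is.null(aberrant) && nrow(aberrant)) {
        a <- aberrant
        facing <- a$strand1 != a$strand2 &
            ifelse(a$strand1 == "+", a$start1 <= a$start2,
                   a$start2 <= a$start1)
        implied <- pmax(a$end1, a$end2) - pmin(a$start1, a$start2)
        ## 5 sd rather than the discordance definition's 3 sd: ordinary
        ## fragment-length outliers must not seed deletion candidates
        long <- facing &
            implied > params$fragmentMean + 5 * params$fragmentSd
        a <- a[long, , drop = FALSE]
        if (nrow(a)) {
            fwdEnd <- ifelse(a$strand1 == "+", a$end1, a$end2)
            revStart <- ifelse(a$strand1 == "+", a$start2, a$start1)
            for (ct in unique(a$contig1)) {
                sel <- a$contig1 == ct
                cid <- chain1d(fwdEnd[sel], params$windowBp)
                fe <- fwdEnd[sel]; rs <- revStart[sel]
                for (cc in unique(cid)) {
                    m <- cid == cc
                    if (sum(m) < params$minSupport) next
                    lo <- max(fe[m]); hi <- min(rs[m])
                    if (hi <= lo) next
                    addCall(ct, refine(ct, lo, "end"),
                            refine(ct, hi, "start"), sum(m))
                }
            }
        }
    }
    ## (ii) paired clip clusters (covers the band invisible to (i))
    if (!is.null(clips) && nrow(clips)) {
        for (ct in unique(clips$contig)) {
            ce <- sort(clips$coord[clips$contig == ct &
                                       clips$type == "end"])
            cs <- sort(clips$coord[clips$contig == ct &
                                       clips$type == "start"])
            if (!length(ce) || !length(cs)) next
            eid <- chain1d(ce, 2L); sid <- chain1d(cs, 2L)
            emod <- vapply(split(ce, eid), modalValue, integer(1))
            smod <- vapply(split(cs, sid), modalValue, integer(1))
            en <- vapply(split(ce, eid), length, integer(1))
            sn <- vapply(split(cs, sid), length, integer(1))
            for (i in seq_along(emod)) {
                d <- smod - emod[i]
                j <- which(d >= minSize & d <= maxClipPair)
                if (!length(j)) next
                j <- j[which.min(d[j])]
                if (en[i] + sn[j] < params$minSupport) next
                addCall(ct, emod[i], smod[j], en[i] + sn[j])
            }
        }
    }
    out
}

#' Call deletions from coverage drops
#'
#' Maximal runs of per-base depth at most \code{maxDepth} (default 1,
#' tolerating stray mismapped reads at low coverage) of length at least
#' \code{minSize}, rejected when the repeat mask covers half the run or
#' more (an unmappable region is indistinguishable from a deletion), with
#' boundaries refined by soft-clips when present.
#'
#' @param depth Depth list from \code{\link{computeDepth}}.
#' @param mask Repeat mask \code{GRanges} or NULL.
#' @param clips Clip table.
#' @param params \code{\link{svParams}} list.
#' @param minSize Minimum run length (bp).
#' @param maxDepth Maximum depth inside a deletion run.
#' @param plasmidContig Contig to skip (never call deletions on the
#'   plasmid).
#' @return Deletion table (evidence \code{coverage_drop}).
#' @export
callCoverageDeletions <- function(depth, mask, clips, params,
                                  minSize = 500L, maxDepth = 1L,
                                  plasmidContig = "plasmid") {
    out <- emptyDeletions()
    for (ct in names(depth)) {
        if (ct == plasmidContig) next
        r <- depth[[ct]] <= maxDepth
        rv <- S4Vectors::runValue(r)
        rl <- S4Vectors::runLength(r)
        ends <- cumsum(rl)
        starts <- ends - rl + 1L
        sel <- which(rv & rl >= minSize)
        n <- length(r)
        for (i in sel) {
            lo <- starts[i] - 1L; hi <- ends[i]   # 0-based half-open
            if (lo <= 0L || hi >= n) next  # chromosome-end artefacts
            if (!is.null(mask) && length(mask)) {
                sel2 <- as.character(GenomicRanges::seqnames(mask)) == ct
                ov <- sum(pmax(0L, pmin(GenomicRanges::end(mask)[sel2], hi) -
                                   pmax(GenomicRanges::start(mask)[sel2] - 1L,
                                        lo)))
                if (ov >= 0.5 * (hi - lo)) next
            }
            lo2 <- lo; hi2 <- hi
            cc <- clips$coord[clips$contig == ct & clips$type == "end" &
                                  abs(clips$coord - lo) <= params$windowBp]
            if (length(cc) && diff(range(cc)) <= 2L) lo2 <- modalValue(cc)
            cc <- clips$coord[clips$contig == ct & clips$type == "start" &
                                  abs(clips$coord - hi) <= params$windowBp]
            if (length(cc) && diff(range(cc)) <= 2L) hi2 <- modalValue(cc)
            if (hi2 <= lo2) { lo2 <- lo; hi2 <- hi }
            out <- rbind(out, data.frame(
                mutant_id = NA_character_, chrom = ct, start = lo2,
                end = hi2, size = hi2 - lo2, evidence = "coverage_drop",
                n_support = 0L, linked_to_insertion = NA,
                stringsAsFactors = FALSE))
        }
    }
    out
}

## merge overlapping calls from the three routes, preferring the most
## precise evidence; read + coverage agreement becomes "both"
mergeDeletionCalls <- function(calls) {
    if (nrow(calls) == 0L) return(calls)
    prio <- c(gapped_read = 1L, spanning_pair = 2L, coverage_drop = 3L)
    calls <- calls[order(calls$chrom, prio[calls$evidence],
                         calls$start), , drop = FALSE]
    keep <- rep(TRUE, nrow(calls))
    for (i in seq_len(nrow(calls))) {
        if (!keep[i]) next
        for (j in seq_len(nrow(calls))) {
            if (i == j || !keep[j]) next
            if (calls$chrom[i] != calls$chrom[j]) next
            if (calls$start[i] < calls$end[j] &&
                calls$start[j] < calls$end[i]) {
                ## overlapping: i has higher priority by sort order
                if (prio[calls$evidence[i]] <= prio[calls$evidence[j]]) {
                    if (calls$evidence[j] == "coverage_drop" &&
                        calls$evidence[i] != "coverage_drop")
                        calls$evidence[i] <- "both"
                    keep[j] <- FALSE
                }
            }
        }
    }
    out <- calls[keep, , drop = FALSE]
    out <- out[order(out$chrom, out$start), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Partition deletions by association with plasmid insertions
#'
#' A deletion within \code{slop} bp of any insertion junction, or
#' overlapping the deleted interval of a two-sided insertion, is
#' insertion-associated; all others are unassociated.
#'
#' @param deletions Deletion table.
#' @param events Insertion event table for the mutant.
#' @param slop Association distance (bp).
#' @return The deletion table with linked_to_insertion filled.
#' @export
partitionByInsertion <- function(deletions, events, slop = 1000L) {
    if (nrow(deletions) == 0L) return(deletions)
    iv <- insertionFootprintIntervals(events)
    linked <- rep(FALSE, nrow(deletions))
    if (!is.null(iv) && nrow(iv)) {
        for (k in seq_len(nrow(deletions))) {
            linked[k] <- any(iv$chrom == deletions$chrom[k] &
                                 iv$start - slop < deletions$end[k] &
                                 deletions$start[k] < iv$end + slop)
        }
    }
    deletions$linked_to_insertion <- linked
    deletions
}

## junction points and deleted intervals of all insertion events, 0-based
insertionFootprintIntervals <- function(events) {
    if (is.null(events) || nrow(events) == 0L) return(NULL)
    rows <- list()
    for (i in seq_len(nrow(events))) {
        e <- events[i, ]
        if (!is.na(e$left_jct))
            rows[[length(rows) + 1L]] <-
                data.frame(chrom = e$chrom, start = e$left_jct,
                           end = e$left_jct, stringsAsFactors = FALSE)
        if (!is.na(e$right_jct))
            rows[[length(rows) + 1L]] <-
                data.frame(chrom = e$chrom, start = e$right_jct,
                           end = e$right_jct, stringsAsFactors = FALSE)
        if (identical(e$gap_class, "deletion") && !is.na(e$left_jct) &&
            !is.na(e$right_jct))
            rows[[length(rows) + 1L]] <-
                data.frame(chrom = e$chrom, start = e$left_jct,
                           end = e$right_jct, stringsAsFactors = FALSE)
        if (!is.na(e$cof_chrom))
            rows[[length(rows) + 1L]] <-
                data.frame(chrom = e$cof_chrom, start = e$cof_start,
                           end = e$cof_end, stringsAsFactors = FALSE)
    }
    if (!length(rows)) return(NULL)
    do.call(rbind, rows)
}

#' Call secondary deletions for one mutant
#'
#' Runs the three deletion routes (in-read gaps, spanning pairs/clip
#' pairs, coverage drops), merges overlapping calls, and partitions them by
#' association with the mutant's insertion events. The emitted
#' "unassociated" set is \code{linked_to_insertion == FALSE}.
#'
#' @param pairs Pair table.
#' @param depth Depth list (computed from \code{pairs} if NULL).
#' @param mask Repeat mask \code{GRanges} or NULL.
#' @param events Insertion event table (may be empty).
#' @param params \code{\link{svParams}} list.
#' @param minGapSize,minCovSize,slop Tuning knobs (bp).
#' @param plasmidContig Plasmid contig name (excluded from coverage calls).
#' @return Deletion table with evidence and association flags.
#' @export
callSecondaryDeletions <- function(pairs, depth = NULL, mask = NULL,
                                   events = NULL, params,
                                   minGapSize = 20L, minCovSize = 500L,
                                   slop = 1000L, plasmidContig = "plasmid") {
    disc <- NULL
    clips <- clipTable(pairs, params)
    gaps <- gapTable(pairs, params)
    g1 <- callGapDeletions(gaps, minSize = minGapSize,
                           minSupport = params$minSupport)
    ## aberrant intrachromosomal pairs for the spanning route
    both <- pairs$mapped1 & pairs$mapped2
    p <- pairs[both & pairs$contig1 == pairs$contig2 &
                   pairs$mapq1 >= params$mapqMin &
                   pairs$mapq2 >= params$mapqMin, , drop = FALSE]
    g2 <- callSpanningDeletions(p, clips, params)
    g3 <- if (!is.null(depth))
        callCoverageDeletions(depth, mask, clips, params,
                              minSize = minCovSize,
                              plasmidContig = plasmidContig)
    else emptyDeletions()
    all <- mergeDeletionCalls(rbind(g1, g2, g3))
    partitionByInsertion(all, events, slop = slop)
}
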