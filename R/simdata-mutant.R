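## Event planning and application. A mutated chromosome is an ordered list
## of source segments (reference chromosome or plasmid, 0-based half-open,
## stranded); all downstream read placement flows from this segment map.

logUnifInt <- function(n, lo, hi) {
    as.integer(floor(exp(stats::runif(n, log(lo), log(hi + 1)))))
}

#' Draw insertion-event classes from a mixture
#'
#' @param mixture An \code{\link{EventMixture}}.
#' @param n Number of events to draw.
#' @return Character vector of event classes.
#' @export
drawEventClasses <- function(mixture, n) {
    p <- mixture@classProbs
    sample(names(p), size = n, replace = TRUE, prob = p)
}

## deletion size from the bimodal log-uniform mixture
drawDeletionSize <- function(mixture, n = 1L) {
    comp <- sample.int(nrow(mixture@deletionRanges), n, replace = TRUE,
                       prob = mixture@deletionWeights)
    r <- mixture@deletionRanges
    vapply(comp, function(k) logUnifInt(1L, r[k, 1], r[k, 2]), integer(1))
}

emptyTruth <- function() {
    data.frame(mutant_id = character(0), event_id = character(0),
               event_class = character(0), chrom = character(0),
               left_bp = integer(0), right_bp = integer(0),
               gap_size = integer(0), partner_chrom = character(0),
               partner_start = integer(0), partner_end = integer(0),
               stringsAsFactors = FALSE)
}

#' Simulate one mutant genome with its truth table
#'
#' Draws insertion events (and plasmid-unassociated deletions) from the
#' mixture, places them on the reference avoiding repeat blocks, chromosome
#' ends and each other, and applies them left-to-right to produce a segment
#' map per chromosome plus one truth row per event. A two-sided event with
#' gap g removes g bases (g > 0, junction deletion) or re-emits |g| bases on
#' both plasmid flanks (g < 0, target-site duplication). One-sided events
#' place a junction flush against a repeat block so one flank is
#' unmappable. Complex events create genome-genome junctions (an inversion
#' with the plasmid at one junction, or a reciprocal translocation with the
#' plasmid at one junction only). Cofragment events co-insert a short
#' (200-2000 bp) copy of a random fragment from another chromosome.
#'
#' @param reference A \code{\link{ReferenceSet}}.
#' @param mixture An \code{\link{EventMixture}}.
#' @param mutantId Mutant identifier.
#' @param seed Integer seed; identical inputs give identical output.
#' @param nInsertions Number of insertion events; default 1 +
#'   Poisson(\code{extraInsertionRate}).
#' @param classes Optional character vector forcing the event classes
#'   (may include \code{"unassociated_deletion"}).
#' @param gapSizes Optional numeric vector parallel to \code{classes}
#'   forcing junction gap sizes (positive deletion, negative duplication).
#' @param nUnassociated Number of unassociated deletions; default
#'   Poisson(\code{unassocDeletionRate}).
#' @param margin Exclusion margin around events and chromosome ends (bp).
#' @param intraSpanMin Minimum span of an intra-chromosomal complex
#'   rearrangement (bp); must exceed the caller's pairing distance so the
#'   two plasmid junctions are not greedily paired as one insertion.
#' @param maxRetries Placement retries per event before erroring.
#' @return A \code{\link{MutantGenome}}.
#' @examples
#' ref <- generateReference(SimConfig(seed = 1, chromosomeLength = 60000L,
#'                                    repeatFraction = 0))
#' mut <- simulateMutant(ref, mutantId = "M1", seed = 2,
#'                       classes = "two_sided_deletion", gapSizes = 100)
#' truthEvents(mut)
#' @export
simulateMutant <- function(reference, mixture = EventMixture(),
                           mutantId = "M1", seed = 1L, nInsertions = NULL,
                           classes = NULL, gapSizes = NULL,
                           nUnassociated = NULL, margin = 2000L,
                           intraSpanMin = 210000L, maxRetries = 100L) {
    validObject(mixture)
    withSeed(seed, {
        if (is.null(classes)) {
            if (is.null(nInsertions))
                nInsertions <- 1L + stats::rpois(1L, mixture@extraInsertionRate)
            classes <- drawEventClasses(mixture, nInsertions)
            if (is.null(nUnassociated))
                nUnassociated <- stats::rpois(1L, mixture@unassocDeletionRate)
            classes <- c(classes,
                         rep("unassociated_deletion", nUnassociated))
        }
        plan <- planEvents(reference, mixture, classes, gapSizes, margin,
                           intraSpanMin, maxRetries)
        buildMutant(reference, plan, mutantId, mixture@concatemerCopies)
    })
}

## ---------------------------------------------------------------------------
## event placement
## ---------------------------------------------------------------------------

## occ: per-chromosome matrix of reserved [start, end) intervals
occFree <- function(occ, chrom, s, e) {
    m <- occ[[chrom]]
    is.null(m) || !any(m[, 1] < e & s < m[, 2])
}
occAdd <- function(occ, chrom, s, e) {
    occ[[chrom]] <- rbind(occ[[chrom]], c(s, e))
    occ
}
maskFree <- function(reference, chrom, s, e) {
    m <- reference@repeatMask
    m <- m[as.character(GenomicRanges::seqnames(m)) == chrom]
    if (length(m) == 0L) return(TRUE)
    !any(GenomicRanges::start(m) - 1L < e & s < GenomicRanges::end(m))
}

planEvents <- function(reference, mixture, classes, gapSizes, margin,
                       intraSpanMin, maxRetries) {
    chrNames <- names(reference@chromosomes)
    L <- Biostrings::width(reference@chromosomes)
    names(L) <- chrNames
    occ <- stats::setNames(vector("list", length(chrNames)), chrNames)
    events <- list()
    for (k in seq_along(classes)) {
        cls <- classes[k]
        forcedGap <- if (!is.null(gapSizes) && k <= length(gapSizes))
            gapSizes[k] else NA_real_
        ev <- NULL
        for (try in seq_len(maxRetries)) {
            cand <- drawEvent(cls, reference, mixture, chrNames, L, margin,
                              intraSpanMin, forcedGap)
            if (is.null(cand)) next
            if (eventFits(cand, occ, reference, margin)) { ev <- cand; break }
        }
        if (is.null(ev))
            stop("could not place event of class '", cls, "' after ",
                 maxRetries, " retries (events drawn to overlap)")
        for (r in seq_len(nrow(ev$reserve)))
            occ <- occAdd(occ, ev$reserve[r, "chrom"],
                          as.numeric(ev$reserve[r, "start"]),
                          as.numeric(ev$reserve[r, "end"]))
        events[[length(events) + 1L]] <- ev
    }
    events
}

reserveRow <- function(chrom, s, e) {
    data.frame(chrom = chrom, start = s, end = e, stringsAsFactors = FALSE)
}

eventFits <- function(ev, occ, reference, margin) {
    for (r in seq_len(nrow(ev$reserve))) {
        ch <- ev$reserve[r, "chrom"]
        s <- as.numeric(ev$reserve[r, "start"])
        e <- as.numeric(ev$reserve[r, "end"])
        if (!occFree(occ, ch, s, e)) return(FALSE)
    }
    ## breakpoint flanks must be mappable unless the event demands a repeat
    for (r in seq_len(nrow(ev$clearMask))) {
        ch <- ev$clearMask[r, "chrom"]
        s <- as.numeric(ev$clearMask[r, "start"])
        e <- as.numeric(ev$clearMask[r, "end"])
        if (!maskFree(reference, ch, s, e)) return(FALSE)
    }
    TRUE
}

drawEvent <- function(cls, reference, mixture, chrNames, L, margin,
                      intraSpanMin, forcedGap) {
    win <- 1000  # flank that must stay mappable around a junction
    pick <- function() sample(chrNames, 1L)
    if (cls %in% c("two_sided_deletion", "two_sided_duplication",
                   "two_sided_perfect", "cofragment_insertion")) {
        gap <- if (!is.na(forcedGap)) as.integer(forcedGap)
        else switch(cls,
                    two_sided_deletion = drawDeletionSize(mixture),
                    two_sided_duplication =
                        -logUnifInt(1L, mixture@duplicationRange[1],
                                    mixture@duplicationRange[2]),
                    0L)
        ch <- pick()
        room <- L[ch] - 2L * margin - max(gap, 0L)
        if (room <= 1L) return(NULL)
        p <- margin + sample.int(room, 1L)
        ev <- list(class = cls, chrom = ch, p = p, gap = gap,
                   reserve = reserveRow(ch, p - margin,
                                        p + max(gap, 0L) + margin),
                   clearMask = rbind(
                       reserveRow(ch, p - win, p + win),
                       reserveRow(ch, p + gap - win, p + gap + win)))
        if (cls == "cofragment_insertion") {
            flen <- logUnifInt(1L, 200L, 2000L)
            pch <- pick()
            room2 <- L[pch] - 2L * margin - flen
            if (room2 <= 1L) return(NULL)
            q1 <- margin + sample.int(room2, 1L)
            ev$partner <- list(chrom = pch, q1 = q1, q2 = q1 + flen)
            ev$reserve <- rbind(ev$reserve,
                                reserveRow(pch, q1 - margin,
                                           q1 + flen + margin))
            ev$clearMask <- rbind(ev$clearMask,
                                  reserveRow(pch, q1 - win, q1 + flen + win))
        }
        return(ev)
    }
    if (cls == "one_sided_repeat") {
        m <- reference@repeatMask
        if (length(m) == 0L) return(NULL)
        i <- sample.int(length(m), 1L)
        ch <- as.character(GenomicRanges::seqnames(m))[i]
        p <- GenomicRanges::end(m)[i]      # 0-based junction at block end
        if (p < margin || p > L[ch] - margin) return(NULL)
        return(list(class = cls, chrom = ch, p = p, gap = 0L,
                    reserve = reserveRow(ch, p - margin, p + margin),
                    clearMask = reserveRow(ch, p, p + win)))
    }
    if (cls %in% c("complex_intra", "one_sided_complex")) {
        ch <- pick()
        spanMax <- L[ch] - 2L * margin - 1L
        if (spanMax <= intraSpanMin) return(NULL)
        span <- intraSpanMin +
            sample.int(max(spanMax - intraSpanMin, 1L), 1L)
        room <- L[ch] - 2L * margin - span
        if (room <= 1L) return(NULL)
        p <- margin + sample.int(room, 1L)
        q <- p + span
        return(list(class = cls, chrom = ch, p = p, q = q, gap = NA_integer_,
                    reserve = reserveRow(ch, p - margin, q + margin),
                    clearMask = rbind(reserveRow(ch, p - win, p + win),
                                      reserveRow(ch, q - win, q + win))))
    }
    if (cls %in% c("translocation", "complex_inter")) {
        if (length(chrNames) < 2L) return(NULL)
        chs <- sample(chrNames, 2L)
        del <- if (cls == "complex_inter") logUnifInt(1L, 11L, 100L) else 0L
        pA <- margin + sample.int(L[chs[1]] - 2L * margin - del, 1L)
        pB <- margin + sample.int(L[chs[2]] - 2L * margin, 1L)
        return(list(class = cls, chrom = chs[1], p = pA,
                    partnerChrom = chs[2], q = pB, gap = del,
                    reserve = rbind(reserveRow(chs[1], pA - margin,
                                               L[chs[1]]),
                                    reserveRow(chs[2], pB - margin,
                                               L[chs[2]])),
                    clearMask = rbind(
                        reserveRow(chs[1], pA - win, pA + del + win),
                        reserveRow(chs[2], pB - win, pB + win))))
    }
    if (cls == "unassociated_deletion") {
        sz <- if (!is.na(forcedGap)) as.integer(forcedGap)
        else logUnifInt(1L, mixture@unassocDeletionRange[1],
                        mixture@unassocDeletionRange[2])
        ch <- pick()
        room <- L[ch] - 2L * margin - sz
        if (room <= 1L) return(NULL)
        a <- margin + sample.int(room, 1L)
        return(list(class = cls, chrom = ch, p = a, gap = sz,
                    reserve = reserveRow(ch, a - margin, a + sz + margin),
                    clearMask = rbind(reserveRow(ch, a - win, a + win),
                                      reserveRow(ch, a + sz - win,
                                                 a + sz + win))))
    }
    stop("unknown event class: ", cls)
}

## ---------------------------------------------------------------------------
## segment-map assembly
## ---------------------------------------------------------------------------

segRow <- function(src, start, end, strand = "+") {
    data.frame(src = src, start = as.integer(start), end = as.integer(end),
               strand = strand, stringsAsFactors = FALSE)
}

buildMutant <- function(reference, events, mutantId, concatemerCopies) {
    chrNames <- names(reference@chromosomes)
    L <- Biostrings::width(reference@chromosomes)
    names(L) <- chrNames
    pn <- reference@plasmidName
    plen <- Biostrings::width(reference@plasmid)[1]
    plasSeg <- do.call(rbind, rep(list(segRow(pn, 0L, plen)),
                                  concatemerCopies))
    ops <- stats::setNames(rep(list(list()), length(chrNames)), chrNames)
    addOp <- function(ops, chrom, op) {
        ops[[chrom]] <- c(ops[[chrom]], list(op))
        ops
    }
    truth <- emptyTruth()
    addTruth <- function(truth, cls, chrom, left, right, gap,
                         pch = NA_character_, ps = NA_integer_,
                         pe = NA_integer_) {
        rbind(truth, data.frame(
            mutant_id = mutantId,
            event_id = sprintf("%s_e%02d", mutantId, nrow(truth) + 1L),
            event_class = cls, chrom = chrom,
            left_bp = as.integer(left), right_bp = as.integer(right),
            gap_size = as.integer(gap), partner_chrom = pch,
            partner_start = as.integer(ps), partner_end = as.integer(pe),
            stringsAsFactors = FALSE))
    }
    for (ev in events) {
        cls <- ev$class
        if (cls %in% c("two_sided_deletion", "two_sided_duplication",
                       "two_sided_perfect")) {
            ops <- addOp(ops, ev$chrom,
                         list(pos = ev$p, plasmid = TRUE, extra = NULL,
                              resume = ev$p + ev$gap, tail = NULL))
            truth <- addTruth(truth, cls, ev$chrom, ev$p, ev$p + ev$gap,
                              ev$gap)
        } else if (cls == "one_sided_repeat") {
            ops <- addOp(ops, ev$chrom,
                         list(pos = ev$p, plasmid = TRUE, extra = NULL,
                              resume = ev$p, tail = NULL))
            truth <- addTruth(truth, cls, ev$chrom, ev$p, ev$p, 0L)
        } else if (cls == "cofragment_insertion") {
            extra <- segRow(ev$partner$chrom, ev$partner$q1, ev$partner$q2)
            ops <- addOp(ops, ev$chrom,
                         list(pos = ev$p, plasmid = TRUE, extra = extra,
                              resume = ev$p + ev$gap, tail = NULL))
            truth <- addTruth(truth, cls, ev$chrom, ev$p, ev$p + ev$gap,
                              ev$gap, ev$partner$chrom, ev$partner$q1,
                              ev$partner$q2)
        } else if (cls %in% c("complex_intra", "one_sided_complex")) {
            extra <- segRow(ev$chrom, ev$p, ev$q, "-")
            ops <- addOp(ops, ev$chrom,
                         list(pos = ev$p, plasmid = TRUE, extra = extra,
                              resume = ev$q, tail = NULL))
            truth <- addTruth(truth, cls, ev$chrom, ev$p, ev$q,
                              NA_integer_, ev$chrom, ev$p, ev$q)
        } else if (cls %in% c("translocation", "complex_inter")) {
            A <- ev$chrom; B <- ev$partnerChrom
            ops <- addOp(ops, A,
                         list(pos = ev$p, plasmid = TRUE, extra = NULL,
                              resume = NA,
                              tail = segRow(B, ev$q, L[B])))
            ops <- addOp(ops, B,
                         list(pos = ev$q, plasmid = FALSE, extra = NULL,
                              resume = NA,
                              tail = segRow(A, ev$p + ev$gap, L[A])))
            truth <- addTruth(truth, cls, A, ev$p, ev$p + ev$gap, ev$gap,
                              B, ev$q, ev$q)
        } else if (cls == "unassociated_deletion") {
            ops <- addOp(ops, ev$chrom,
                         list(pos = ev$p, plasmid = FALSE, extra = NULL,
                              resume = ev$p + ev$gap, tail = NULL))
            truth <- addTruth(truth, cls, ev$chrom, ev$p, ev$p + ev$gap,
                              ev$gap)
        }
    }
    segments <- stats::setNames(vector("list", length(chrNames)), chrNames)
    for (ch in chrNames) {
        chOps <- ops[[ch]]
        if (length(chOps) > 1L)
            chOps <- chOps[order(vapply(chOps, `[[`, numeric(1), "pos"))]
        segs <- NULL
        cursor <- 0L
        ended <- FALSE
        for (op in chOps) {
            if (op$pos > cursor)
                segs <- rbind(segs, segRow(ch, cursor, op$pos))
            if (isTRUE(op$plasmid)) segs <- rbind(segs, plasSeg)
            if (!is.null(op$extra)) segs <- rbind(segs, op$extra)
            if (!is.null(op$tail)) {
                segs <- rbind(segs, op$tail)
                ended <- TRUE
                break
            }
            cursor <- as.integer(op$resume)
        }
        if (!ended)
            segs <- rbind(segs, segRow(ch, cursor, L[ch]))
        segs <- segs[segs$end > segs$start, , drop = FALSE]
        rownames(segs) <- NULL
        segments[[ch]] <- segs
    }
    new("MutantGenome", mutantId = mutantId, segments = segments,
        truth = truth)
}

#' Lengths of the mutated chromosomes
#' @param mutant A \code{\link{MutantGenome}}.
#' @return Named integer vector of mutated chromosome lengths (bp).
#' @export
mutatedLengths <- function(mutant) {
    vapply(mutant@segments,
           function(s) sum(as.numeric(s$end - s$start)), numeric(1))
}

#' Reconstruct the mutated chromosome sequences
#'
#' Concatenates the source intervals of each segment map (reverse
#' complementing minus-strand segments), yielding the full mutated genome.
#'
#' @param mutant A \code{\link{MutantGenome}}.
#' @param reference The \code{\link{ReferenceSet}} it was simulated from.
#' @return A \code{DNAStringSet} of mutated chromosomes.
#' @export
mutantSequences <- function(mutant, reference) {
    seqs <- c(reference@chromosomes, reference@plasmid)
    out <- lapply(mutant@segments, function(segs) {
        parts <- lapply(seq_len(nrow(segs)), function(i) {
            s <- subseq(seqs[[segs$src[i]]], segs$start[i] + 1L, segs$end[i])
            if (segs$strand[i] == "-") reverseComplement(s) else s
        })
        do.call(Biostrings::xscat, parts)
    })
    res <- DNAStringSet(out)
    names(res) <- names(mutant@segments)
    res
}
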