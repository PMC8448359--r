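## Insertion-event assembly: two-sided pairing, gap classification,
## cofragment detection, complex-lesion resolution, mutant classification.

emptyEvents <- function() {
    data.frame(event_id = character(0), mutant_id = character(0),
               classification = character(0), chrom = character(0),
               left_site = character(0), right_site = character(0),
               left_jct = integer(0), left_unc = integer(0),
               right_jct = integer(0), right_unc = integer(0),
               gap_class = character(0), gap_size = integer(0),
               one_sided_reason = character(0), lesion_id = character(0),
               ambiguous = logical(0), cof_chrom = character(0),
               cof_start = integer(0), cof_end = integer(0),
               stringsAsFactors = FALSE)
}

eventRow <- function(...) {
    tmpl <- emptyEvents()
    args <- list(...)
    row <- lapply(names(tmpl), function(nm) {
        if (!is.null(args[[nm]])) args[[nm]]
        else methods::as(NA, class(tmpl[[nm]]))
    })
    names(row) <- names(tmpl)
    do.call(data.frame, c(row, stringsAsFactors = FALSE))
}

#' Pair left and right plasmid sites into two-sided insertions
#'
#' Greedy nearest pairing: each left-side plasmid site is matched with the
#' nearest right-side plasmid site on the same chromosome whose junction
#' faces the same region, i.e. with signed distance d = right - left
#' satisfying -(duplicationCap + combined uncertainty) <= d <=
#' maxPairDistance. Each site is used at most once; candidate pairs are
#' consumed in order of increasing |d| with ties broken deterministically
#' by lower coordinate and flagged ambiguous.
#'
#' @param sites Plasmid site table with junctions estimated.
#' @param params \code{\link{svParams}} list.
#' @return List with \code{events} (two-sided insertion table, gap not yet
#'   classified) and \code{leftover} (unpaired site table).
#' @export
pairPlasmidSites <- function(sites, params) {
    L <- sites[sites$side == "left", , drop = FALSE]
    R <- sites[sites$side == "right", , drop = FALSE]
    cand <- NULL
    if (nrow(L) && nrow(R)) {
        for (i in seq_len(nrow(L))) for (j in seq_len(nrow(R))) {
            if (L$chrom[i] != R$chrom[j]) next
            d <- R$junction[j] - L$junction[i]
            loTol <- params$duplicationCap +
                L$junction_unc[i] + R$junction_unc[j]
            if (d < -loTol || d > params$maxPairDistance) next
            cand <- rbind(cand, data.frame(i = i, j = j, absd = abs(d),
                                           lj = L$junction[i],
                                           rj = R$junction[j]))
        }
    }
    events <- emptyEvents()
    usedL <- logical(nrow(L)); usedR <- logical(nrow(R))
    if (!is.null(cand)) {
        cand <- cand[order(cand$absd, cand$lj, cand$rj), , drop = FALSE]
        for (k in seq_len(nrow(cand))) {
            i <- cand$i[k]; j <- cand$j[k]
            if (usedL[i] || usedR[j]) next
            amb <- sum(cand$i == i & cand$absd == cand$absd[k] &
                           !usedR[cand$j]) > 1L
            usedL[i] <- TRUE; usedR[j] <- TRUE
            events <- rbind(events, eventRow(
                classification = "two_sided", chrom = L$chrom[i],
                left_site = L$site_id[i], right_site = R$site_id[j],
                left_jct = L$junction[i], left_unc = L$junction_unc[i],
                right_jct = R$junction[j], right_unc = R$junction_unc[j],
                ambiguous = amb))
        }
    }
    leftover <- rbind(L[!usedL, , drop = FALSE], R[!usedR, , drop = FALSE])
    list(events = events, leftover = leftover)
}

#' Classify the junction gap of two-sided insertions
#'
#' g = right junction - left junction: g > 0 is a junction deletion of g
#' bp, g < 0 a target-site duplication of -g bp, g = 0 a perfect
#' insertion. With discordant-only evidence on either side and |g| within
#' the combined uncertainty the gap class is unknown; duplications at or
#' beyond \code{duplicationCap} are likewise flagged unknown for review.
#'
#' @param events Two-sided event table from \code{\link{pairPlasmidSites}}.
#' @param params \code{\link{svParams}} list.
#' @return The event table with gap_class and gap_size filled.
#' @export
classifyGap <- function(events, params) {
    if (nrow(events) == 0L) return(events)
    g <- events$right_jct - events$left_jct
    unc <- events$left_unc + events$right_unc
    cls <- ifelse(g > 0L, "deletion", ifelse(g < 0L, "duplication",
                                             "perfect"))
    cls[unc > 0L & abs(g) <= unc] <- "unknown"
    cls[g < 0L & -g >= params$duplicationCap] <- "unknown"
    events$gap_class <- cls
    events$gap_size <- ifelse(cls == "deletion", g,
                              ifelse(cls == "duplication", -g, 0L))
    events$gap_size[cls == "unknown"] <- NA_integer_
    events
}

#' Detect co-inserted genome fragments
#'
#' A short random fragment of another locus co-inserted with the plasmid
#' leaves three signatures: discordant links from the insertion junction to
#' the source interval, roughly doubled read depth over that interval
#' (the source still exists, so the copy's reads pile onto it), and a
#' source interval shorter than 10 kb. All three are required.
#'
#' @param plasmidSites Plasmid site table.
#' @param ggSites Genome-partner site table.
#' @param events Two-sided event table.
#' @param depth Depth list from \code{\link{computeDepth}}.
#' @param params \code{\link{svParams}} list.
#' @param depthRatioMin Minimum source-to-baseline depth ratio (default
#'   1.6).
#' @param maxFragment Maximum co-fragment length (default 10 kb).
#' @return List with \code{events} (cofragment interval attached to the
#'   owning event when one exists), \code{cofragments} (call table),
#'   \code{absorbedSites}, \code{absorbedGG} (site ids explained by the
#'   cofragment, to drop before complex resolution).
#' @export
detectCofragment <- function(plasmidSites, ggSites, events, depth, params,
                             depthRatioMin = 1.6, maxFragment = 10000L) {
    cof <- NULL
    absorbedSites <- character(0); absorbedGG <- character(0)
    if (nrow(plasmidSites) == 0L || nrow(ggSites) == 0L)
        return(list(events = events, cofragments = cof,
                    absorbedSites = absorbedSites, absorbedGG = absorbedGG))
    for (i in seq_len(nrow(plasmidSites))) {
        ps <- plasmidSites[i, ]
        near <- ggSites$chrom == ps$chrom &
            abs(ggSites$junction - ps$junction) <= params$windowBp
        for (j in which(near)) {
            gs <- ggSites[j, ]
            ## distal partner interval
            if (gs$partner_chrom == ps$chrom &&
                abs((gs$partner_start + gs$partner_end) / 2 -
                        ps$junction) < 2L * params$windowBp) next
            i0 <- c(gs$partner_start, gs$partner_end)
            ## extend by plasmid sites anchored inside/near the source
            ext <- plasmidSites$chrom == gs$partner_chrom &
                plasmidSites$junction >= i0[1] - maxFragment &
                plasmidSites$junction <= i0[2] + maxFragment &
                plasmidSites$site_id != ps$site_id
            if (any(ext))
                i0 <- range(c(i0, plasmidSites$junction[ext]))
            if (diff(i0) >= maxFragment) next
            base <- mean(c(
                depthMean(depth, gs$partner_chrom,
                          i0[1] - 5000L, i0[1]),
                depthMean(depth, gs$partner_chrom,
                          i0[2], i0[2] + 5000L)), na.rm = TRUE)
            inside <- depthMean(depth, gs$partner_chrom, i0[1], i0[2])
            if (!is.finite(base) || base <= 0 || !is.finite(inside)) next
            if (inside / base < depthRatioMin) next
            cof <- rbind(cof, data.frame(
                site_id = ps$site_id, chrom = gs$partner_chrom,
                start = i0[1], end = i0[2],
                depth_ratio = inside / base, stringsAsFactors = FALSE))
            absorbedGG <- c(absorbedGG, gs$site_id)
            ## the mirrored cluster anchored at the source pointing back
            mirror <- ggSites$chrom == gs$partner_chrom &
                ggSites$partner_chrom == ps$chrom &
                abs(ggSites$partner_start - ps$junction) <=
                    2L * params$windowBp
            absorbedGG <- c(absorbedGG, ggSites$site_id[mirror])
            absorbedSites <- c(absorbedSites,
                               plasmidSites$site_id[ext])
            ## attach to the owning two-sided event if there is one
            own <- which(events$left_site == ps$site_id |
                             events$right_site == ps$site_id)
            if (length(own)) {
                events$cof_chrom[own[1]] <- gs$partner_chrom
                events$cof_start[own[1]] <- i0[1]
                events$cof_end[own[1]] <- i0[2]
            }
            break
        }
    }
    list(events = events, cofragments = cof,
         absorbedSites = unique(absorbedSites),
         absorbedGG = unique(absorbedGG))
}

#' Resolve leftover plasmid sites into complex lesions or one-sided calls
#'
#' A leftover plasmid site whose locus also anchors a genome-genome
#' discordant cluster is linked into a complex lesion with its partner
#' locus; link chains are followed transitively so multi-chromosome lesions
#' close (cycles are closed, not errors). Remaining leftover sites are
#' one-sided: if the opposite flank carries sub-mapping-quality
#' plasmid-paired anchors or repeat mask, the reason is repeat_flank,
#' otherwise no_discordant_reads. A lesion whose plasmid sites span two or
#' more chromosomes is classified translocation (plasmid present at one
#' junction of a chimeric chromosome pair); other genome-genome lesions are
#' complex.
#'
#' @param leftover Leftover plasmid site table.
#' @param ggSites Genome-partner site table (post cofragment absorption).
#' @param lowmapq Side channel from \code{\link{collectDiscordantPairs}}.
#' @param mask Repeat mask \code{GRanges} or NULL.
#' @param params \code{\link{svParams}} list.
#' @return List with \code{events} (complex and one-sided insertion rows)
#'   and \code{lesions} (lesion table for the complex components).
#' @export
resolveComplex <- function(leftover, ggSites, lowmapq, mask, params) {
    nP <- nrow(leftover); nG <- nrow(ggSites)
    parent <- seq_len(nP + nG)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    union2 <- function(a, b) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[rb] <<- ra
    }
    nearLocus <- function(chromA, posA, chromB, lo, hi)
        chromA == chromB & posA >= lo - params$windowBp &
        posA <= hi + params$windowBp
    if (nP && nG) {
        for (i in seq_len(nP)) for (j in seq_len(nG)) {
            if (nearLocus(leftover$chrom[i], leftover$junction[i],
                          ggSites$chrom[j], ggSites$wstart[j],
                          ggSites$wend[j]))
                union2(i, nP + j)
        }
    }
    if (nG > 1L) {
        for (j in seq_len(nG - 1L)) for (k in (j + 1L):nG) {
            ## mirrored ends of the same junction, or chained junctions
            mir <- ggSites$chrom[j] == ggSites$partner_chrom[k] &&
                ggSites$wstart[j] <= ggSites$partner_end[k] +
                    params$windowBp &&
                ggSites$wend[j] >= ggSites$partner_start[k] -
                    params$windowBp
            sameLocus <- ggSites$chrom[j] == ggSites$chrom[k] &&
                ggSites$wstart[j] <= ggSites$wend[k] + params$windowBp &&
                ggSites$wend[j] >= ggSites$wstart[k] - params$windowBp
            if (mir || sameLocus) union2(nP + j, nP + k)
        }
    }
    comp <- vapply(seq_len(nP + nG), find, integer(1))
    events <- emptyEvents()
    lesionRows <- NULL
    lesionN <- 0L
    for (cc in unique(comp)) {
        pIdx <- which(comp[seq_len(nP)] == cc)
        gIdx <- which(comp[nP + seq_len(nG)] == cc)
        if (length(pIdx) == 0L) next        # pure genome-genome: delcall's
        if (length(gIdx) == 0L) {
            ## isolated one-sided site(s)
            for (i in pIdx) {
                st <- leftover[i, ]
                reason <- oneSidedReason(st, lowmapq, mask, params)
                events <- rbind(events, eventRow(
                    classification = "one_sided", chrom = st$chrom,
                    left_site = if (st$side == "left") st$site_id
                                else NA_character_,
                    right_site = if (st$side == "right") st$site_id
                                 else NA_character_,
                    left_jct = if (st$side == "left") st$junction
                               else NA_integer_,
                    left_unc = if (st$side == "left") st$junction_unc
                               else NA_integer_,
                    right_jct = if (st$side == "right") st$junction
                                else NA_integer_,
                    right_unc = if (st$side == "right") st$junction_unc
                                else NA_integer_,
                    gap_class = "unknown", one_sided_reason = reason))
            }
            next
        }
        lesionN <- lesionN + 1L
        lid <- sprintf("L%03d", lesionN)
        chroms <- unique(c(leftover$chrom[pIdx], ggSites$chrom[gIdx],
                           ggSites$partner_chrom[gIdx]))
        lclass <- if (length(unique(leftover$chrom[pIdx])) >= 2L)
            "translocation" else "complex"
        lesionRows <- rbind(lesionRows, data.frame(
            lesion_id = lid, lesion_class = lclass,
            n_sites = length(pIdx) + length(gIdx),
            n_plasmid_sites = length(pIdx),
            chroms = paste(sort(chroms), collapse = ","),
            stringsAsFactors = FALSE))
        for (i in pIdx) {
            st <- leftover[i, ]
            events <- rbind(events, eventRow(
                classification = "complex", chrom = st$chrom,
                left_site = if (st$side == "left") st$site_id
                            else NA_character_,
                right_site = if (st$side == "right") st$site_id
                             else NA_character_,
                left_jct = if (st$side == "left") st$junction
                           else NA_integer_,
                right_jct = if (st$side == "right") st$junction
                            else NA_integer_,
                gap_class = "unknown",
                one_sided_reason = "paired_elsewhere", lesion_id = lid))
        }
    }
    list(events = events, lesions = lesionRows)
}

oneSidedReason <- function(site, lowmapq, mask, params) {
    w <- params$windowBp
    if (site$side == "left") { lo <- site$junction; hi <- site$junction + w }
    else { lo <- site$junction - w; hi <- site$junction }
    ## sub-mapq plasmid-paired anchors on the missing flank
    if (!is.null(lowmapq) && nrow(lowmapq)) {
        hit <- lowmapq$chrom == site$chrom & lowmapq$astart < hi &
            lowmapq$aend > lo & lowmapq$side != site$side
        if (any(hit)) return("repeat_flank")
    }
    if (!is.null(mask) && length(mask)) {
        sel <- as.character(GenomicRanges::seqnames(mask)) == site$chrom &
            GenomicRanges::start(mask) - 1L < hi &
            GenomicRanges::end(mask) > lo
        if (any(sel)) return("repeat_flank")
    }
    "no_discordant_reads"
}

#' Classify a mutant from its resolved events
#'
#' simple_only iff every insertion is two-sided or one-sided with an
#' unmappable flank (no complex lesion); complex_containing if any complex
#' lesion exists; no_insertion_found with no events at all.
#'
#' @param events Event table.
#' @param lesions Lesion table (may be NULL).
#' @param nSites Number of plasmid-paired discordant sites detected.
#' @return List with mutantClass and counts (sites, insertions, lesions).
#' @export
classifyMutant <- function(events, lesions, nSites) {
    nIns <- nrow(events)
    nComplexLesions <- if (is.null(lesions)) 0L else nrow(lesions)
    nSimpleLesions <- sum(events$classification %in%
                              c("two_sided", "one_sided"))
    cls <- if (nIns == 0L) "no_insertion_found"
    else if (nComplexLesions > 0L) "complex_containing"
    else "simple_only"
    list(mutantClass = cls,
         counts = c(sites = as.integer(nSites),
                    insertions = as.integer(nIns),
                    lesions = as.integer(nSimpleLesions + nComplexLesions)))
}

#' Call all structural variants for one mutant
#'
#' End-to-end per-mutant caller: discordant-pair collection, site
#' clustering, junction estimation, two-sided pairing and gap
#' classification, cofragment detection, complex-lesion resolution,
#' secondary-deletion calling and mutant classification.
#'
#' @param pairs Pair table for one mutant.
#' @param reference A \code{\link{ReferenceSet}} (contig names, repeat
#'   mask); the mask is advisory and may be empty for ingested data.
#' @param config A \code{\link{SimConfig}}.
#' @param params Optional \code{\link{svParams}} list.
#' @param mutantId Mutant identifier.
#' @param callDeletions Also run the secondary-deletion caller.
#' @return A \code{\link{MutantCallSet}}.
#' @examples
#' ref <- generateReference(SimConfig(seed = 5, chromosomeLength = 100000L,
#'                                    repeatFraction = 0))
#' mut <- simulateMutant(ref, mutantId = "M1", seed = 6,
#'                       classes = "two_sided_deletion", gapSizes = 25)
#' prs <- emitAlignments(mut, ref, SimConfig(seed = 5), seed = 7)
#' cs <- callMutant(prs, ref, SimConfig(seed = 5), mutantId = "M1")
#' insertionEvents(cs)
#' @export
callMutant <- function(pairs, reference, config, params = NULL,
                       mutantId = "mutant", callDeletions = TRUE) {
    if (is.null(params)) params <- svParams(config)
    disc <- collectDiscordantPairs(pairs, reference@plasmidName, params)
    clu <- clusterDiscordant(disc, params)
    clips <- clipTable(pairs, params)
    psites <- estimateJunction(clu$plasmid_sites, clips, params)
    gsites <- estimateJunction(clu$gg_sites, clips, params)
    pr <- pairPlasmidSites(psites, params)
    events <- classifyGap(pr$events, params)
    lens <- c(stats::setNames(Biostrings::width(reference@chromosomes),
                              names(reference@chromosomes)),
              stats::setNames(Biostrings::width(reference@plasmid),
                              reference@plasmidName))
    depth <- computeDepth(pairs, lens)
    cf <- detectCofragment(psites, gsites, events, depth, params)
    events <- cf$events
    leftover <- pr$leftover[!(pr$leftover$site_id %in% cf$absorbedSites), ,
                            drop = FALSE]
    gKeep <- gsites[!(gsites$site_id %in% cf$absorbedGG), , drop = FALSE]
    rc <- resolveComplex(leftover, gKeep, disc$lowmapq,
                         reference@repeatMask, params)
    events <- rbind(events, rc$events)
    ## surface cofragment calls on whichever event owns the anchoring site
    if (!is.null(cf$cofragments) && nrow(cf$cofragments) && nrow(events)) {
        for (k in seq_len(nrow(cf$cofragments))) {
            co <- cf$cofragments[k, ]
            own <- which((!is.na(events$left_site) &
                              events$left_site == co$site_id) |
                             (!is.na(events$right_site) &
                                  events$right_site == co$site_id))
            if (length(own)) {
                events$cof_chrom[own[1]] <- co$chrom
                events$cof_start[own[1]] <- co$start
                events$cof_end[own[1]] <- co$end
            }
        }
    }
    if (nrow(events)) {
        events$event_id <- sprintf("%s_v%02d", mutantId,
                                   seq_len(nrow(events)))
        events$mutant_id <- mutantId
        simple <- which(events$classification %in%
                            c("two_sided", "one_sided"))
        events$lesion_id[simple] <- sprintf("%s_S%02d", mutantId,
                                            seq_along(simple))
    }
    cm <- classifyMutant(events, rc$lesions, nrow(psites))
    lesions <- rc$lesions
    if (is.null(lesions))
        lesions <- data.frame(lesion_id = character(0),
                              lesion_class = character(0),
                              n_sites = integer(0),
                              n_plasmid_sites = integer(0),
                              chroms = character(0),
                              stringsAsFactors = FALSE)
    secondary <- if (callDeletions)
        callSecondaryDeletions(pairs, depth, reference@repeatMask, events,
                               params,
                               plasmidContig = reference@plasmidName)
    else emptyDeletions()
    if (nrow(secondary)) secondary$mutant_id <- mutantId
    new("MutantCallSet", mutantId = mutantId, sites = psites,
        events = events, lesions = lesions,
        secondaryDeletions = secondary, mutantClass = cm$mutantClass,
        counts = cm$counts)
}
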