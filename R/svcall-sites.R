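## Discordant-site clustering and junction estimation.

emptySites <- function() {
    data.frame(site_id = character(0), chrom = character(0),
               wstart = integer(0), wend = integer(0), side = character(0),
               partner = character(0), partner_chrom = character(0),
               partner_start = integer(0), partner_end = integer(0),
               n_support = integer(0), inner = integer(0),
               junction = integer(0), junction_unc = integer(0),
               junction_evidence = character(0), stringsAsFactors = FALSE)
}

#' Cluster discordant pairs into discordant sites
#'
#' Single-linkage clustering of chromosomal anchor intervals within
#' \code{windowBp}, split by chromosome, side (left = forward-strand
#' anchors pointing toward higher coordinates, right = reverse-strand
#' anchors pointing lower) and partner class. Plasmid-paired anchors
#' cluster into plasmid sites; genome-genome pairs contribute an anchor at
#' each end (partnered with the opposite end) and cluster into
#' genome-partner sites, additionally split when partner loci disagree by
#' more than \code{windowBp}. Clusters below \code{minSupport} are
#' discarded and counted.
#'
#' @param disc Output of \code{\link{collectDiscordantPairs}}.
#' @param params \code{\link{svParams}} list.
#' @return List with \code{plasmid_sites}, \code{gg_sites} (site tables)
#'   and \code{n_filtered} (clusters dropped for low support).
#' @export
clusterDiscordant <- function(disc, params) {
    filtered <- 0L

    clusterAnchors <- function(a, partnerLab) {
        if (nrow(a) == 0L) return(emptySites())
        key <- paste(a$chrom, a$side, a$partner_chrom, sep = "\r")
        out <- list()
        for (k in unique(key)) {
            g <- a[key == k, , drop = FALSE]
            mid <- (g$astart + g$aend) / 2
            cid <- chain1d(mid, params$windowBp)
            if (!is.na(g$partner_start[1])) {
                ## split clusters whose partner loci disagree
                pmid <- (g$partner_start + g$partner_end) / 2
                sub <- integer(length(pmid))
                for (u in unique(cid)) {
                    idx <- which(cid == u)
                    sub[idx] <- chain1d(pmid[idx], params$windowBp)
                }
                cid <- paste0(cid, "_", sub)
            }
            for (cc in unique(cid)) {
                m <- g[cid == cc, , drop = FALSE]
                if (nrow(m) < params$minSupport) {
                    filtered <<- filtered + 1L
                    next
                }
                out[[length(out) + 1L]] <- data.frame(
                    site_id = NA_character_, chrom = m$chrom[1],
                    wstart = min(m$astart), wend = max(m$aend),
                    side = m$side[1], partner = partnerLab,
                    partner_chrom = m$partner_chrom[1],
                    partner_start = if (is.na(m$partner_start[1]))
                        NA_integer_ else min(m$partner_start),
                    partner_end = if (is.na(m$partner_end[1]))
                        NA_integer_ else max(m$partner_end),
                    n_support = nrow(m),
                    inner = if (m$side[1] == "left") max(m$aend)
                            else min(m$astart),
                    junction = NA_integer_, junction_unc = NA_integer_,
                    junction_evidence = NA_character_,
                    stringsAsFactors = FALSE)
            }
        }
        if (length(out) == 0L) return(emptySites())
        do.call(rbind, out)
    }

    pp <- disc$plasmid_paired
    ppAnchors <- data.frame(chrom = pp$chrom, astart = pp$astart,
                            aend = pp$aend, side = pp$side,
                            partner_chrom = rep(NA_character_, nrow(pp)),
                            partner_start = rep(NA_integer_, nrow(pp)),
                            partner_end = rep(NA_integer_, nrow(pp)),
                            stringsAsFactors = FALSE)
    plasmidSites <- clusterAnchors(ppAnchors, "plasmid")

    ## same-contig facing pairs with merely long implied fragments are
    ## deletion evidence, not rearrangement evidence; keep them out of the
    ## genome-genome clustering (the deletion caller consumes them).
    intra <- disc$intrachromosomal_aberrant
    if (nrow(intra)) {
        facing <- intra$strand1 != intra$strand2 &
            ifelse(intra$strand1 == "+", intra$start1 <= intra$start2,
                   intra$start2 <= intra$start1)
        intra <- intra[!facing, , drop = FALSE]
    }
    gg <- rbind(disc$interchromosomal, intra)
    ggAnchors <- if (nrow(gg) > 0L) {
        a1 <- data.frame(chrom = gg$contig1, astart = gg$start1,
                         aend = gg$end1,
                         side = ifelse(gg$strand1 == "+", "left", "right"),
                         partner_chrom = gg$contig2,
                         partner_start = gg$start2, partner_end = gg$end2,
                         stringsAsFactors = FALSE)
        a2 <- data.frame(chrom = gg$contig2, astart = gg$start2,
                         aend = gg$end2,
                         side = ifelse(gg$strand2 == "+", "left", "right"),
                         partner_chrom = gg$contig1,
                         partner_start = gg$start1, partner_end = gg$end1,
                         stringsAsFactors = FALSE)
        rbind(a1, a2)
    } else ppAnchors[0, , drop = FALSE]
    ggSites <- clusterAnchors(ggAnchors, "chromosome")

    if (nrow(plasmidSites))
        plasmidSites$site_id <- sprintf("P%03d", seq_len(nrow(plasmidSites)))
    if (nrow(ggSites))
        ggSites$site_id <- sprintf("G%03d", seq_len(nrow(ggSites)))
    list(plasmid_sites = plasmidSites, gg_sites = ggSites,
         n_filtered = filtered)
}

#' Estimate junction coordinates for discordant sites
#'
#' Soft-clip evidence takes precedence: if at least one read is clipped at
#' a consistent coordinate (spread <= 2 bp) on the site's junction side,
#' the junction is the modal clip coordinate with uncertainty 0. With
#' conflicting clips (> 2 bp spread) or none, the innermost anchor boundary
#' is used with uncertainty fragmentMean - 2 * readLength
#' (discordant-only evidence).
#'
#' @param sites Site table from \code{\link{clusterDiscordant}}.
#' @param clips Clip table from \code{\link{clipTable}}.
#' @param params \code{\link{svParams}} list.
#' @return The site table with junction, junction_unc and
#'   junction_evidence filled.
#' @export
estimateJunction <- function(sites, clips, params) {
    if (nrow(sites) == 0L) return(sites)
    unc <- as.integer(params$fragmentMean - 2 * params$readLength)
    for (i in seq_len(nrow(sites))) {
        side <- sites$side[i]
        type <- if (side == "left") "end" else "start"
        lo <- if (side == "left") sites$wstart[i]
              else sites$wstart[i] - params$windowBp
        hi <- if (side == "left") sites$wend[i] + params$windowBp
              else sites$wend[i]
        cc <- clips$coord[clips$contig == sites$chrom[i] &
                              clips$type == type &
                              clips$coord >= lo & clips$coord <= hi]
        if (length(cc) >= 1L && diff(range(cc)) <= 2L) {
            tab <- table(cc)
            sites$junction[i] <-
                as.integer(names(tab)[which.max(tab)])
            sites$junction_unc[i] <- 0L
            sites$junction_evidence[i] <- "softclip"
        } else {
            if (length(cc) > 1L)
                warning("conflicting clip coordinates at ",
                        sites$chrom[i], ":", sites$inner[i],
                        "; falling back to discordant-only evidence")
            sites$junction[i] <- sites$inner[i]
            sites$junction_unc[i] <- unc
            sites$junction_evidence[i] <- "discordant_only"
        }
    }
    sites
}
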