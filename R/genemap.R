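## Gene-model IO, lesion footprints, gene disruption records,
## allele tables and disruption frequencies.

#' Generate synthetic gene models for a reference
#'
#' Tiles each chromosome with genes of realistic structure: a 5'-UTR exon,
#' several CDS exons separated by introns, and a 3'-UTR exon, on random
#' strands with intergenic gaps. Used to exercise annotation end-to-end
#' without external data.
#'
#' @param reference A \code{\link{ReferenceSet}}.
#' @param seed Integer seed.
#' @param meanIntergenic Mean intergenic gap (bp).
#' @param path Optional GFF3 output path; when given the models are
#'   written (1-based inclusive coordinates, as GFF3 requires).
#' @return A gene-model set (see \code{\link{loadGeneModels}}); written to
#'   \code{path} when requested.
#' @export
generateGeneModels <- function(reference, seed = 1L,
                               meanIntergenic = 2000L, path = NULL) {
    withSeed(seed, {
        rows <- list()
        gi <- 0L
        for (ch in names(reference@chromosomes)) {
            L <- Biostrings::width(reference@chromosomes[ch])
            pos <- 1L + stats::rpois(1L, meanIntergenic)
            while (TRUE) {
                nCds <- sample(2:5, 1L)
                cdsLen <- sample(150:400, nCds, replace = TRUE)
                intLen <- sample(100:300, nCds + 1L, replace = TRUE)
                utr5 <- 200L; utr3 <- 300L
                glen <- utr5 + utr3 + sum(cdsLen) + sum(intLen)
                if (pos + glen > L - 1000L) break
                gi <- gi + 1L
                gid <- sprintf("g%s.%04d", sub("chr", "", ch), gi)
                strand <- sample(c("+", "-"), 1L)
                ## exon layout, 1-based inclusive: UTR5 exon, CDS exons,
                ## UTR3 exon, introns between
                exons <- list(c(pos, pos + utr5 - 1L))
                cur <- pos + utr5 + intLen[1]
                for (k in seq_len(nCds)) {
                    exons[[length(exons) + 1L]] <-
                        c(cur, cur + cdsLen[k] - 1L)
                    cur <- cur + cdsLen[k] + intLen[k + 1L]
                }
                exons[[length(exons) + 1L]] <- c(cur, cur + utr3 - 1L)
                gend <- cur + utr3 - 1L
                u5 <- exons[[1]]; u3 <- exons[[length(exons)]]
                if (strand == "-") { tmp <- u5; u5 <- u3; u3 <- tmp }
                rows[[length(rows) + 1L]] <- data.frame(
                    gene_id = gid, chrom = ch, strand = strand,
                    gstart = pos, gend = gend,
                    feats = I(list(list(
                        exons = exons[-c(1L, length(exons))],
                        utr5 = list(u5), utr3 = list(u3),
                        allexons = exons))),
                    stringsAsFactors = FALSE)
                pos <- gend + 1L + stats::rpois(1L, meanIntergenic)
            }
        }
        models <- buildModels(do.call(rbind, rows))
        if (!is.null(path)) writeGff3(models, path)
        models
    })
}

buildModels <- function(tab) {
    genes <- GenomicRanges::GRanges(
        tab$chrom,
        IRanges::IRanges(tab$gstart, tab$gend),
        strand = tab$strand)
    S4Vectors::mcols(genes)$gene_id <- tab$gene_id
    asGRL <- function(field) {
        lst <- lapply(seq_len(nrow(tab)), function(i) {
            iv <- tab$feats[[i]][[field]]
            if (length(iv) == 0L)
                return(GenomicRanges::GRanges())
            m <- do.call(rbind, iv)
            GenomicRanges::GRanges(tab$chrom[i],
                                   IRanges::IRanges(m[, 1], m[, 2]))
        })
        names(lst) <- tab$gene_id
        lst
    }
    structure(list(genes = genes, cds = asGRL("exons"),
                   utr5 = asGRL("utr5"), utr3 = asGRL("utr3"),
                   exons = asGRL("allexons")),
              class = "GeneModels")
}

#' @export
print.GeneModels <- function(x, ...) {
    cat("GeneModels:", length(x$genes), "genes on",
        length(unique(as.character(GenomicRanges::seqnames(x$genes)))),
        "chromosomes\n")
    invisible(x)
}

#' Write gene models as GFF3
#' @param models A GeneModels set.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeGff3 <- function(models, path) {
    g <- models$genes
    out <- c("##gff-version 3")
    for (i in seq_along(g)) {
        gid <- S4Vectors::mcols(g)$gene_id[i]
        ch <- as.character(GenomicRanges::seqnames(g))[i]
        st <- as.character(GenomicRanges::strand(g))[i]
        line <- function(type, s, e, id, parent = NULL) {
            attr <- if (is.null(parent)) paste0("ID=", id)
            else paste0("ID=", id, ";Parent=", parent)
            paste(ch, "plasmidSV", type, s, e, ".", st, ".", attr,
                  sep = "\t")
        }
        mid <- paste0(gid, ".t1")
        out <- c(out, line("gene", GenomicRanges::start(g)[i],
                           GenomicRanges::end(g)[i], gid),
                 line("mRNA", GenomicRanges::start(g)[i],
                      GenomicRanges::end(g)[i], mid, gid))
        feats <- list(exon = models$exons[[gid]], CDS = models$cds[[gid]],
                      five_prime_UTR = models$utr5[[gid]],
                      three_prime_UTR = models$utr3[[gid]])
        for (type in names(feats)) {
            fr <- feats[[type]]
            for (k in seq_along(fr))
                out <- c(out, line(type, GenomicRanges::start(fr)[k],
                                   GenomicRanges::end(fr)[k],
                                   paste0(mid, ".", type, k), mid))
        }
    }
    writeLines(out, path)
    invisible(path)
}

#' Load gene models from GFF3
#'
#' Resolves the gene/mRNA/exon/CDS/UTR hierarchy; orphan features (whose
#' Parent cannot be resolved) are skipped with a message listing their
#' IDs. GFF3 1-based inclusive coordinates are kept in the native GRanges
#' representation; the package's 0-based half-open footprints are
#' converted at the overlap boundary.
#'
#' @param path GFF3 file.
#' @return A GeneModels set: list with \code{genes} (GRanges with
#'   gene_id), and per-gene \code{cds}, \code{utr5}, \code{utr3},
#'   \code{exons} interval lists.
#' @export
loadGeneModels <- function(path) {
    gr <- rtracklayer::import(path, format = "gff3")
    type <- as.character(gr$type)
    genes <- gr[type == "gene"]
    mrna <- gr[type == "mRNA"]
    m2g <- stats::setNames(as.character(unlist(mrna$Parent)),
                           as.character(mrna$ID))
    pick <- function(t) {
        f <- gr[type == t]
        if (length(f) == 0L) return(list(f = f, gene = character(0)))
        par <- S4Vectors::unstrsplit(f$Parent, ",")
        par[par == ""] <- NA_character_
        gene <- m2g[par]
        orphan <- is.na(gene)
        if (any(orphan))
            message("skipping ", sum(orphan), " orphan ", t,
                    " feature(s): ",
                    paste(utils::head(as.character(f$ID)[orphan], 5L),
                          collapse = ", "))
        list(f = f[!orphan], gene = gene[!orphan])
    }
    gids <- as.character(genes$ID)
    grl <- function(t) {
        p <- pick(t)
        f0 <- GenomicRanges::granges(p$f)
        sp <- S4Vectors::split(f0, factor(p$gene, levels = gids))
        stats::setNames(as.list(sp), gids)
    }
    g <- GenomicRanges::granges(genes)
    S4Vectors::mcols(g)$gene_id <- gids
    structure(list(genes = g, cds = grl("CDS"), utr5 = grl("five_prime_UTR"),
                   utr3 = grl("three_prime_UTR"), exons = grl("exon")),
              class = "GeneModels")
}

#' Genomic footprint of insertion events and deletions
#'
#' Maps each event to the intervals it can disrupt: a two-sided insertion
#' with a junction deletion contributes the deleted interval; perfect and
#' duplication insertions contribute their junction point(s) only (a
#' tandem micro-duplication deletes nothing); one-sided and complex
#' insertions contribute each mapped junction point; secondary deletions
#' contribute their interval. Coordinates are 0-based half-open; a
#' zero-length junction point at p intersects [a, b) iff a <= p < b.
#'
#' @param events Insertion event table (may be NULL).
#' @param deletions Secondary deletion table restricted to the rows to
#'   annotate (may be NULL).
#' @return data.frame with chrom, start, end, kind ("point" or
#'   "interval"), source_id, mutant_id.
#' @export
lesionFootprint <- function(events = NULL, deletions = NULL) {
    rows <- list()
    add <- function(chrom, s, e, kind, id, mut) {
        rows[[length(rows) + 1L]] <<- data.frame(
            chrom = chrom, start = as.integer(s), end = as.integer(e),
            kind = kind, source_id = id, mutant_id = mut,
            stringsAsFactors = FALSE)
    }
    if (!is.null(events) && nrow(events)) {
        for (i in seq_len(nrow(events))) {
            e <- events[i, ]
            mid <- if (is.na(e$mutant_id)) "" else e$mutant_id
            if (identical(e$gap_class, "deletion")) {
                add(e$chrom, e$left_jct, e$right_jct, "interval",
                    e$event_id, mid)
            } else {
                if (!is.na(e$left_jct))
                    add(e$chrom, e$left_jct, e$left_jct, "point",
                        e$event_id, mid)
                if (!is.na(e$right_jct) &&
                    !identical(e$right_jct, e$left_jct))
                    add(e$chrom, e$right_jct, e$right_jct, "point",
                        e$event_id, mid)
            }
        }
    }
    if (!is.null(deletions) && nrow(deletions)) {
        for (i in seq_len(nrow(deletions))) {
            d <- deletions[i, ]
            add(d$chrom, d$start, d$end, "interval",
                paste0("del_", i), d$mutant_id)
        }
    }
    if (!length(rows))
        return(data.frame(chrom = character(0), start = integer(0),
                          end = integer(0), kind = character(0),
                          source_id = character(0),
                          mutant_id = character(0),
                          stringsAsFactors = FALSE))
    do.call(rbind, rows)
}

.contextRank <- c(upstream_only = 0L, intron = 1L, three_prime_utr = 2L,
                  five_prime_utr = 3L, exon = 4L, whole_gene_deleted = 5L)

#' Intersect footprints with gene models
#'
#' A gene is affected iff any footprint interval intersects its gene body
#' (UTRs included). Context is the most severe overlapped feature:
#' whole_gene_deleted (a deletion interval covers the whole gene) > exon
#' (CDS) > five_prime_utr > three_prime_utr > intron. Point insertions
#' strictly upstream of a gene do not affect it unless a promoter window
#' is enabled (\code{promoterWindow} > 0, default off), in which case they
#' get context upstream_only.
#'
#' @param footprints Footprint table from \code{\link{lesionFootprint}}.
#' @param models GeneModels set.
#' @param promoterWindow Upstream window (bp) treated as regulatory.
#' @return Disruption-record data.frame: mutant_id, gene_id, source_id,
#'   context, severity.
#' @export
affectedGenes <- function(footprints, models, promoterWindow = 0L) {
    empty <- data.frame(mutant_id = character(0), gene_id = character(0),
                        source_id = character(0), context = character(0),
                        severity = integer(0), stringsAsFactors = FALSE)
    if (nrow(footprints) == 0L) return(empty)
    q <- GenomicRanges::GRanges(footprints$chrom,
                                asIRanges0(footprints$start,
                                           footprints$end))
    genes <- models$genes
    target <- genes
    if (promoterWindow > 0L)
        target <- GenomicRanges::resize(
            genes, GenomicRanges::width(genes) + promoterWindow,
            fix = "end")
    hits <- GenomicRanges::findOverlaps(q, target, ignore.strand = TRUE)
    if (length(hits) == 0L) return(empty)
    rows <- list()
    for (h in seq_along(hits)) {
        fi <- S4Vectors::queryHits(hits)[h]
        gi <- S4Vectors::subjectHits(hits)[h]
        gid <- S4Vectors::mcols(genes)$gene_id[gi]
        fp <- q[fi]
        gene <- genes[gi]
        inBody <- IRanges::overlapsAny(fp, gene, ignore.strand = TRUE)
        ctx <- if (!inBody) {
            "upstream_only"
        } else if (footprints$kind[fi] == "interval" &&
                   GenomicRanges::start(fp) <= GenomicRanges::start(gene) &&
                   GenomicRanges::end(fp) >= GenomicRanges::end(gene)) {
            "whole_gene_deleted"
        } else if (IRanges::overlapsAny(fp, models$cds[[gid]],
                                        ignore.strand = TRUE)) {
            "exon"
        } else if (IRanges::overlapsAny(fp, models$utr5[[gid]],
                                        ignore.strand = TRUE)) {
            "five_prime_utr"
        } else if (IRanges::overlapsAny(fp, models$utr3[[gid]],
                                        ignore.strand = TRUE)) {
            "three_prime_utr"
        } else "intron"
        rows[[length(rows) + 1L]] <- data.frame(
            mutant_id = footprints$mutant_id[fi], gene_id = gid,
            source_id = footprints$source_id[fi], context = ctx,
            severity = .contextRank[[ctx]], stringsAsFactors = FALSE)
    }
    rec <- do.call(rbind, rows)
    ## one record per (mutant, gene, source): keep the most severe
    rec <- rec[order(rec$mutant_id, rec$gene_id, -rec$severity), ,
               drop = FALSE]
    key <- paste(rec$mutant_id, rec$gene_id, rec$source_id)
    rec <- rec[!duplicated(key), , drop = FALSE]
    rownames(rec) <- NULL
    rec
}

#' Build the population allele table
#'
#' Maps each gene to the distinct mutants disrupting it (set-union over
#' insertion- and deletion-derived records) and bins genes by allele
#' count: 1, 2, 3, >= 4.
#'
#' @param records Disruption records from \code{\link{affectedGenes}}.
#' @return List with \code{table} (data.frame gene_id, n_alleles,
#'   mutants) and \code{histogram} (named counts for 1, 2, 3, ">=4").
#' @export
buildAlleleTable <- function(records) {
    if (nrow(records) == 0L)
        return(list(table = data.frame(gene_id = character(0),
                                       n_alleles = integer(0),
                                       mutants = character(0),
                                       stringsAsFactors = FALSE),
                    histogram = c(`1` = 0L, `2` = 0L, `3` = 0L,
                                  `>=4` = 0L)))
    sp <- split(records$mutant_id, records$gene_id)
    tab <- data.frame(
        gene_id = names(sp),
        n_alleles = vapply(sp, function(x) length(unique(x)), integer(1)),
        mutants = vapply(sp, function(x)
            paste(sort(unique(x)), collapse = ","), character(1)),
        stringsAsFactors = FALSE)
    rownames(tab) <- NULL
    h <- c(`1` = sum(tab$n_alleles == 1L),
           `2` = sum(tab$n_alleles == 2L),
           `3` = sum(tab$n_alleles == 3L),
           `>=4` = sum(tab$n_alleles >= 4L))
    list(table = tab[order(-tab$n_alleles, tab$gene_id), ], histogram = h)
}

#' Rank genes by disruption frequency within a mutant group
#'
#' For a group of mutants with overlapping lesions, each gene touched by
#' any member is scored by the fraction of group members affecting it;
#' genes are ranked by descending frequency, ties broken by maximum
#' severity then gene_id. The causative gene of a shared phenotype is
#' expected at frequency 1 (affected in all members).
#'
#' @param records Disruption records.
#' @param groupMutants Character vector of mutant ids forming the group.
#' @return data.frame gene_id, frequency, severity, rank, co_maximal.
#' @export
disruptionFrequency <- function(records, groupMutants) {
    r <- records[records$mutant_id %in% groupMutants, , drop = FALSE]
    stopIfNot0(length(unique(groupMutants)) >= 2L,
               "a frequency group needs >= 2 mutants")
    if (nrow(r) == 0L)
        return(data.frame(gene_id = character(0), frequency = numeric(0),
                          severity = integer(0), rank = integer(0),
                          co_maximal = logical(0), stringsAsFactors = FALSE))
    sp <- split(r, r$gene_id)
    out <- data.frame(
        gene_id = names(sp),
        frequency = vapply(sp, function(x)
            length(unique(x$mutant_id)), integer(1)) /
            length(unique(groupMutants)),
        severity = vapply(sp, function(x)
            max(x$severity), numeric(1)),
        stringsAsFactors = FALSE)
    out <- out[order(-out$frequency, -out$severity, out$gene_id), ,
               drop = FALSE]
    out$rank <- seq_len(nrow(out))
    out$co_maximal <- out$frequency == max(out$frequency)
    rownames(out) <- NULL
    out
}
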