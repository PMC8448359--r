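## Deterministic, auditable curation of higher-confidence candidate genes.

#' Flag genes with curation evidence
#'
#' Marks each gene with membership in a conserved-green-lineage set
#' (GreenCut2-style), photosynthesis co-expression, annotation-keyword
#' hits (case-insensitive fixed-string match against the description,
#' e.g. "redox", "chlorophyll a/b-binding", "Fe-S"), and hits in
#' cross-library candidate lists (Cr/Zm/At style). Gene ids present in a
#' list but absent from \code{geneIds} are logged, not fatal.
#'
#' @param geneIds Character vector: the gene universe to flag.
#' @param annotation data.frame with columns gene_id, description (or a
#'   TSV path). Missing genes get empty descriptions.
#' @param greencut,coexpression Character vectors of member gene ids (or
#'   TSV paths with a gene_id column).
#' @param crosslib Named list of character vectors (e.g. list(Cr=, Zm=,
#'   At=)), each a member list.
#' @param keywords Character vector of annotation keywords.
#' @return data.frame: gene_id, greencut2, coexpression_hit, keyword_hit,
#'   crosslib (comma-joined letters), flag columns are logical.
#' @export
flagGenes <- function(geneIds, annotation = NULL, greencut = character(0),
                      coexpression = character(0), crosslib = list(),
                      keywords = c("redox", "chlorophyll a/b-binding",
                                   "Fe-S")) {
    readList <- function(x) {
        if (is.character(x) && length(x) == 1L && file.exists(x))
            x <- utils::read.delim(x, stringsAsFactors = FALSE)
        if (is.data.frame(x)) {
            if (!"gene_id" %in% names(x))
                stop("membership list lacks a gene_id column")
            x <- x$gene_id
        }
        as.character(x)
    }
    if (is.character(annotation) && length(annotation) == 1L &&
        file.exists(annotation))
        annotation <- utils::read.delim(annotation,
                                        stringsAsFactors = FALSE)
    if (!is.null(annotation) && !"gene_id" %in% names(annotation))
        stop("annotation table lacks a gene_id column")
    desc <- rep("", length(geneIds))
    if (!is.null(annotation)) {
        m <- match(geneIds, annotation$gene_id)
        desc[!is.na(m)] <- annotation$description[m[!is.na(m)]]
    }
    greencut <- readList(greencut)
    coexpression <- readList(coexpression)
    crosslib <- lapply(crosslib, readList)
    for (nm in names(crosslib)) {
        unknown <- setdiff(crosslib[[nm]], geneIds)
        if (length(unknown))
            message("crosslib ", nm, ": ", length(unknown),
                    " unknown gene id(s) ignored")
    }
    unknown <- setdiff(c(greencut, coexpression), geneIds)
    if (length(unknown))
        message(length(unknown), " unknown gene id(s) in membership lists")
    kw <- rep(FALSE, length(geneIds))
    for (k in keywords)
        kw <- kw | grepl(k, desc, fixed = TRUE, ignore.case = FALSE) |
            grepl(tolower(k), tolower(desc), fixed = TRUE)
    cl <- vapply(geneIds, function(g)
        paste(names(crosslib)[vapply(crosslib, function(v) g %in% v,
                                     logical(1))], collapse = ","),
        character(1))
    data.frame(gene_id = geneIds, description = desc,
               greencut2 = geneIds %in% greencut,
               coexpression_hit = geneIds %in% coexpression,
               keyword_hit = kw, crosslib = unname(cl),
               stringsAsFactors = FALSE)
}

flagScore <- function(flags, weights) {
    ncl <- ifelse(flags$crosslib == "", 0L,
                  vapply(strsplit(flags$crosslib, ","), length, integer(1)))
    weights[["greencut2"]] * flags$greencut2 +
        weights[["keyword"]] * flags$keyword_hit +
        weights[["coexpression"]] * flags$coexpression_hit +
        weights[["crosslib"]] * ncl
}

#' Select higher-confidence candidate genes
#'
#' Deterministic re-implementation of a manual curation sweep, with a full
#' audit trail. Rules fire in fixed order per mutant:
#' \enumerate{
#'   \item a simple-only mutant with exactly one affected gene makes that
#'     gene a candidate (single_gene_simple);
#'   \item mutants sharing affected genes form a frequency group; a unique
#'     maximal gene by disruption frequency wins for every group member —
#'     complex mutants may join such groups;
#'   \item among multiple affected genes, flag scores (default greencut2
#'     2, keyword 1, coexpression 1, each cross-library hit 1) pick a
#'     unique maximum (flag_winner);
#'   \item a tie at a positive maximum reports all tied genes
#'     (multiple_candidates);
#'   \item otherwise none.
#' }
#' After the first pass, genes co-disrupted alongside any rule-1/rule-2
#' winner are demoted population-wide and all decisions are re-evaluated
#' once (a single sweep, guaranteeing termination); demoted genes never
#' appear as candidates.
#'
#' @param mutants data.frame with mutant_id and mutant_class.
#' @param records Disruption records (\code{\link{affectedGenes}}).
#' @param flags Gene flags (\code{\link{flagGenes}}).
#' @param weights Named numeric flag weights.
#' @return data.frame of decisions: mutant_id, basis, candidates
#'   (comma-joined), demoted (comma-joined); the audit trail is attached
#'   as attribute \code{"audit"} (character vector, one line per rule
#'   firing).
#' @export
selectCandidates <- function(mutants, records, flags,
                             weights = c(greencut2 = 2, keyword = 1,
                                         coexpression = 1, crosslib = 1)) {
    ## deterministic regardless of input order
    mutants <- mutants[order(mutants$mutant_id), , drop = FALSE]
    records <- records[order(records$mutant_id, records$gene_id), ,
                       drop = FALSE]
    audit <- character(0)
    log1 <- function(...) audit <<- c(audit, paste0(...))
    scores <- stats::setNames(flagScore(flags, weights), flags$gene_id)
    geneScore <- function(g) {
        s <- scores[g]
        s[is.na(s)] <- 0
        s
    }
    ## frequency groups: connected components over shared affected genes
    grp <- mutantGroups(records)

    decideOne <- function(mid, demoted) {
        mcls <- mutants$mutant_class[mutants$mutant_id == mid]
        genes <- sort(unique(records$gene_id[records$mutant_id == mid]))
        eligible <- setdiff(genes, demoted)
        simple <- identical(mcls, "simple_only")
        if (simple && length(genes) == 1L && length(eligible) == 1L) {
            log1(mid, ": R1 single simple insertion, single gene -> ",
                 genes)
            return(list(basis = "single_gene_simple", cand = genes))
        }
        gidx <- grp$membership[mid]
        gmates <- if (!is.na(gidx)) grp$groups[[gidx]] else NULL
        if (!is.null(gmates) && length(gmates) >= 2L) {
            fr <- disruptionFrequency(records, gmates)
            fr <- fr[!(fr$gene_id %in% demoted), , drop = FALSE]
            if (nrow(fr) && sum(fr$frequency == max(fr$frequency)) == 1L &&
                fr$gene_id[1] %in% genes) {
                log1(mid, ": R2 frequency winner in group of ",
                     length(gmates), " -> ", fr$gene_id[1])
                return(list(basis = "frequency_winner",
                            cand = fr$gene_id[1]))
            }
        }
        if (!simple) {
            log1(mid, ": complex mutant outside frequency group -> none")
            return(list(basis = "none", cand = character(0)))
        }
        if (length(eligible) == 0L) {
            log1(mid, ": no eligible genes -> none")
            return(list(basis = "none", cand = character(0)))
        }
        sc <- geneScore(eligible)
        mx <- max(sc)
        if (mx > 0 && sum(sc == mx) == 1L) {
            log1(mid, ": R3 flag winner (score ", mx, ") -> ",
                 eligible[sc == mx])
            return(list(basis = "flag_winner",
                        cand = eligible[which.max(sc)]))
        }
        if (mx > 0) {
            tied <- eligible[sc == mx]
            log1(mid, ": R4 flag tie -> ", paste(tied, collapse = ","))
            return(list(basis = "multiple_candidates", cand = tied))
        }
        log1(mid, ": R5 no evidence -> none")
        return(list(basis = "none", cand = character(0)))
    }

    runPass <- function(demoted) {
        out <- list()
        for (mid in mutants$mutant_id)
            out[[mid]] <- decideOne(mid, demoted)
        out
    }
    pass1 <- runPass(character(0))
    ## demote neighbours of R1/R2 winners, population-wide
    demoted <- character(0)
    for (mid in names(pass1)) {
        d <- pass1[[mid]]
        if (d$basis %in% c("single_gene_simple", "frequency_winner")) {
            neigh <- setdiff(
                unique(records$gene_id[records$mutant_id == mid]), d$cand)
            if (length(neigh)) {
                log1(mid, ": demoting co-disrupted neighbours ",
                     paste(neigh, collapse = ","))
                demoted <- union(demoted, neigh)
            }
        }
    }
    final <- if (length(demoted)) runPass(demoted) else pass1
    res <- data.frame(
        mutant_id = names(final),
        basis = vapply(final, `[[`, character(1), "basis"),
        candidates = vapply(final, function(d)
            paste(d$cand, collapse = ","), character(1)),
        demoted = paste(sort(demoted), collapse = ","),
        stringsAsFactors = FALSE)
    rownames(res) <- NULL
    attr(res, "audit") <- audit
    res
}

## connected components of mutants sharing >= 1 affected gene
mutantGroups <- function(records) {
    mids <- sort(unique(records$mutant_id))
    n <- length(mids)
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (g in unique(records$gene_id)) {
        mem <- match(unique(records$mutant_id[records$gene_id == g]), mids)
        if (length(mem) > 1L)
            for (k in 2:length(mem)) {
                ra <- find(mem[1]); rb <- find(mem[k])
                if (ra != rb) parent[rb] <- ra
            }
    }
    comp <- vapply(seq_len(n), find, integer(1))
    groups <- unname(split(mids, comp))
    membership <- stats::setNames(
        vapply(mids, function(m)
            which(vapply(groups, function(g) m %in% g, logical(1))),
            integer(1)), mids)
    list(groups = groups, membership = membership)
}

#' Build the candidate-gene report table
#'
#' One row per candidate gene: description, a "G" mark for
#' GreenCut2-style membership, keyword/co-expression marks, cross-library
#' letters, an "M" marker when the gene arose from a multiple-candidate
#' tie, and the supporting mutants.
#'
#' @param decisions Decisions from \code{\link{selectCandidates}}.
#' @param flags Gene flags.
#' @return data.frame (empty with header when there are no decisions).
#' @export
candidateReport <- function(decisions, flags) {
    empty <- data.frame(gene_id = character(0), description = character(0),
                        greencut2 = character(0), keyword = character(0),
                        coexpression = character(0),
                        crosslib = character(0), marker = character(0),
                        mutants = character(0), stringsAsFactors = FALSE)
    if (nrow(decisions) == 0L) return(empty)
    rows <- list()
    for (i in seq_len(nrow(decisions))) {
        if (decisions$candidates[i] == "") next
        for (g in strsplit(decisions$candidates[i], ",")[[1]])
            rows[[length(rows) + 1L]] <-
                data.frame(gene_id = g,
                           mutant_id = decisions$mutant_id[i],
                           multi = decisions$basis[i] ==
                               "multiple_candidates",
                           stringsAsFactors = FALSE)
    }
    if (!length(rows)) return(empty)
    long <- do.call(rbind, rows)
    sp <- split(long, long$gene_id)
    out <- do.call(rbind, lapply(sp, function(x) {
        f <- flags[match(x$gene_id[1], flags$gene_id), ]
        data.frame(
            gene_id = x$gene_id[1],
            description = if (nrow(f) && !is.na(f$description))
                f$description else "",
            greencut2 = if (nrow(f) && isTRUE(f$greencut2)) "G" else "",
            keyword = if (nrow(f) && isTRUE(f$keyword_hit)) "K" else "",
            coexpression = if (nrow(f) && isTRUE(f$coexpression_hit))
                "C" else "",
            crosslib = if (nrow(f) && !is.na(f$crosslib)) f$crosslib
                       else "",
            marker = if (any(x$multi)) "M" else "",
            mutants = paste(sort(unique(x$mutant_id)), collapse = ","),
            stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out[order(out$gene_id), , drop = FALSE]
}
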