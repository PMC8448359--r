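## End-to-end orchestration: simulate -> call -> annotate -> curate ->
## report, with deterministic seeding and TSV outputs.

#' Simulate a mutant population
#'
#' Generates a reference from the configuration and simulates
#' \code{nMutants} mutants from the mixture, with per-mutant seeds derived
#' deterministically from the base seed.
#'
#' @param config A \code{\link{SimConfig}}.
#' @param mixture An \code{\link{EventMixture}}.
#' @param nMutants Number of mutants.
#' @param seed Base seed (defaults to \code{config@seed}).
#' @param ... Passed to \code{\link{simulateMutant}}.
#' @return List with \code{reference} and \code{mutants} (list of
#'   \code{\link{MutantGenome}}).
#' @export
simulatePopulation <- function(config, mixture = EventMixture(),
                               nMutants = 10L, seed = NULL, ...) {
    if (is.null(seed)) seed <- config@seed
    reference <- generateReference(config)
    mutants <- lapply(seq_len(nMutants), function(i)
        simulateMutant(reference, mixture,
                       mutantId = sprintf("SIM%04d", i),
                       seed = subSeed(seed, i), ...))
    names(mutants) <- vapply(mutants, mutantId, character(1))
    list(reference = reference, mutants = mutants)
}

#' Run the full calling pipeline for one mutant
#'
#' Accepts either a pair table or a SAM/BAM path; verifies the plasmid
#' contig is present in the alignment header (configuration error naming
#' the contig otherwise); calls insertions and secondary deletions; and
#' optionally writes the per-mutant event and deletion TSVs.
#'
#' @param alignments Pair table or SAM/BAM path.
#' @param reference A \code{\link{ReferenceSet}}.
#' @param config A \code{\link{SimConfig}}.
#' @param mutantId Mutant identifier.
#' @param params Optional \code{\link{svParams}}.
#' @param outDir Optional output directory for TSVs.
#' @return A \code{\link{MutantCallSet}}.
#' @export
runMutant <- function(alignments, reference, config, mutantId,
                      params = NULL, outDir = NULL) {
    if (is.character(alignments)) {
        pairs <- readAlignments(alignments, config)
        targets <- attr(pairs, "targets")
        if (!is.null(targets) &&
            !(reference@plasmidName %in% targets))
            stop("configuration error: plasmid contig '",
                 reference@plasmidName,
                 "' is not a reference sequence of ", alignments)
    } else pairs <- alignments
    cs <- callMutant(pairs, reference, config, params = params,
                     mutantId = mutantId)
    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        writeTsv(insertionEvents(cs),
                 file.path(outDir, paste0(mutantId, "_events.tsv")))
        writeTsv(secondaryDeletions(cs),
                 file.path(outDir, paste0(mutantId, "_deletions.tsv")))
    }
    cs
}

writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Run the pipeline over a mutant population
#'
#' Calls every mutant, removes redundant mutants (entire groups), builds
#' gene disruption records and the allele table, curates candidates, and
#' writes the population tables: discordant sites (with the per-site
#' pairing columns), secondary deletions, affected genes, candidates, a
#' summary, the redundancy removal list, and a manifest of parameters.
#' Partial per-mutant failures are collected; the run fails only when
#' more than \code{maxFailFraction} of mutants error.
#'
#' @param alignmentsList Named list of pair tables (or SAM/BAM paths), one
#'   per mutant.
#' @param reference A \code{\link{ReferenceSet}}.
#' @param config A \code{\link{SimConfig}}.
#' @param geneModels GeneModels set (\code{\link{loadGeneModels}}).
#' @param outDir Output directory; created if needed.
#' @param params Optional \code{\link{svParams}}.
#' @param flags Optional gene flags (\code{\link{flagGenes}}); computed
#'   with empty evidence lists when NULL.
#' @param toleranceBp Redundancy coordinate tolerance.
#' @param maxFailFraction Tolerated fraction of failing mutants.
#' @return List: callSets, removal, records, alleles, decisions,
#'   candidates, summary, failures (named character of error messages).
#' @export
runPopulation <- function(alignmentsList, reference, config, geneModels,
                          outDir = NULL, params = NULL, flags = NULL,
                          toleranceBp = 10L, maxFailFraction = 0.2) {
    stopIfNot0(length(alignmentsList) >= 1L, "need >= 1 mutant")
    if (is.null(params)) params <- svParams(config)
    ids <- names(alignmentsList)
    if (is.null(ids))
        ids <- sprintf("MUT%04d", seq_along(alignmentsList))
    callSets <- list(); failures <- character(0)
    for (k in seq_along(alignmentsList)) {
        res <- tryCatch(
            runMutant(alignmentsList[[k]], reference, config, ids[k],
                      params = params),
            error = function(e) e)
        if (inherits(res, "error"))
            failures[ids[k]] <- conditionMessage(res)
        else callSets[[ids[k]]] <- res
    }
    if (length(failures) > maxFailFraction * length(alignmentsList))
        stop("pipeline failed for ", length(failures), " of ",
             length(alignmentsList), " mutants; first error: ",
             failures[1])
    red <- if (length(callSets) >= 2L)
        findRedundantMutants(callSets, toleranceBp = toleranceBp)
    else list(groups = list(), removal = character(0))
    kept <- callSets[setdiff(names(callSets), red$removal)]
    ## disruption records over insertion events + unassociated deletions
    records <- do.call(rbind, c(list(
        affectedGenes(lesionFootprint(NULL, NULL), geneModels)),
        lapply(kept, function(cs) {
            dels <- secondaryDeletions(cs)
            dels <- dels[!dels$linked_to_insertion, , drop = FALSE]
            affectedGenes(lesionFootprint(insertionEvents(cs), dels),
                          geneModels)
        })))
    alleles <- buildAlleleTable(records)
    if (is.null(flags))
        flags <- flagGenes(S4Vectors::mcols(geneModels$genes)$gene_id)
    mutTab <- data.frame(
        mutant_id = names(kept),
        mutant_class = vapply(kept, mutantClass, character(1)),
        stringsAsFactors = FALSE)
    decisions <- selectCandidates(mutTab, records, flags)
    candidates <- candidateReport(decisions, flags)
    summary <- summarizePopulation(kept,
                                   nRedundantRemoved = length(red$removal))
    out <- list(callSets = callSets, removal = red, records = records,
                alleles = alleles, decisions = decisions,
                candidates = candidates, summary = summary,
                failures = failures)
    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        writeTsv(siteTable(kept), file.path(outDir,
                                            "discordant_sites.tsv"))
        dels <- do.call(rbind, lapply(kept, secondaryDeletions))
        writeTsv(dels[!dels$linked_to_insertion, , drop = FALSE],
                 file.path(outDir, "unassociated_deletions.tsv"))
        writeTsv(records, file.path(outDir, "affected_genes.tsv"))
        writeTsv(alleles$table, file.path(outDir, "allele_table.tsv"))
        writeTsv(candidates, file.path(outDir, "candidates.tsv"))
        writeTsv(data.frame(key = names(unlist(summary)),
                            value = unlist(summary)),
                 file.path(outDir, "summary.tsv"))
        writeTsv(data.frame(mutant_id = red$removal),
                 file.path(outDir, "redundant_removed.tsv"))
        manifest <- c(sprintf("seed=%d", config@seed),
                      sprintf("coverage=%g", config@coverage),
                      sprintf("fragmentMean=%g", config@fragmentMean),
                      sprintf("fragmentSd=%g", config@fragmentSd),
                      sprintf("readLength=%d", config@readLength),
                      sprintf("mapqMin=%d", params$mapqMin),
                      sprintf("minSupport=%d", params$minSupport),
                      sprintf("windowBp=%d", params$windowBp),
                      sprintf("maxPairDistance=%d",
                              params$maxPairDistance),
                      sprintf("duplicationCap=%d", params$duplicationCap),
                      sprintf("toleranceBp=%d", as.integer(toleranceBp)))
        writeLines(manifest, file.path(outDir, "manifest.txt"))
    }
    out
}

## per-site summary table with pairing and per-mutant count columns
siteTable <- function(callSets) {
    rows <- list()
    for (cs in callSets) {
        s <- discordantSites(cs)
        ev <- insertionEvents(cs)
        nSites <- nrow(s)
        nLes <- unname(cs@counts[["lesions"]])
        for (i in seq_len(nrow(s))) {
            sid <- s$site_id[i]
            own <- ev[!is.na(ev$left_site) & ev$left_site == sid |
                          !is.na(ev$right_site) & ev$right_site == sid, ,
                      drop = FALSE]
            sides <- if (nrow(own) && own$classification[1] ==
                         "two_sided") 2L else 1L
            pairing <- "-"
            if (nrow(own)) {
                mate <- setdiff(c(own$left_site[1], own$right_site[1]),
                                c(sid, NA))
                if (length(mate)) pairing <- paste(mate, collapse = ",")
                else if (!is.na(own$lesion_id[1]))
                    pairing <- own$lesion_id[1]
            }
            rows[[length(rows) + 1L]] <- data.frame(
                `Mutant` = mutantId(cs),
                `Discordant site` = sprintf("%s:%d-%d", s$chrom[i],
                                            s$wstart[i] + 1L, s$wend[i]),
                `Number of sides paired with plasmid at site` = sides,
                `Pairing with other discordant site(s) in the same mutant` =
                    pairing,
                `Number of discordant sites for the mutant` = nSites,
                `Number of lesions for the mutant` = nLes,
                check.names = FALSE, stringsAsFactors = FALSE)
        }
    }
    if (!length(rows))
        return(data.frame(Mutant = character(0), check.names = FALSE))
    do.call(rbind, rows)
}
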