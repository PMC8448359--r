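## Shared fixtures, built once per test run and cached in-process.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, make) {
    if (!exists(name, envir = .fixtures, inherits = FALSE))
        assign(name, make(), envir = .fixtures)
    get(name, envir = .fixtures, inherits = FALSE)
}

## screen-scale config: 3 x 500 kb + 5 kb plasmid at 7.44x, 600 +/- 60 bp
## fragments, 2 x 150 bp reads
sharedCfg <- function(...) SimConfig(seed = 1, ...)

sharedRef <- function()
    fixture("sharedRef", function() generateReference(sharedCfg()))

## tiny single-chromosome reference for fast unit tests
tinyCfg <- function(...)
    SimConfig(seed = 2, nChromosomes = 1L, chromosomeLength = 80000L,
              repeatFraction = 0, ...)

tinyRef <- function()
    fixture("tinyRef", function() generateReference(tinyCfg()))

tinyModels <- function()
    fixture("tinyModels", function()
        generateGeneModels(tinyRef(), seed = 3))

## hand-built pair-table row; defaults describe a concordant pair
pairRow <- function(read_id = "r1",
                    contig1 = "chr1", start1 = 1000L, end1 = 1150L,
                    strand1 = "+", clipL1 = 0L, clipR1 = 0L,
                    delPos1 = NA_integer_, delLen1 = NA_integer_,
                    mapped1 = TRUE,
                    contig2 = "chr1", start2 = 1450L, end2 = 1600L,
                    strand2 = "-", clipL2 = 0L, clipR2 = 0L,
                    delPos2 = NA_integer_, delLen2 = NA_integer_,
                    mapped2 = TRUE, mapq1 = 60L, mapq2 = 60L,
                    proper = NA) {
    data.frame(read_id = read_id, contig1 = contig1, start1 = start1,
               end1 = end1, strand1 = strand1, clipL1 = clipL1,
               clipR1 = clipR1, delPos1 = delPos1, delLen1 = delLen1,
               mapped1 = mapped1, contig2 = contig2, start2 = start2,
               end2 = end2, strand2 = strand2, clipL2 = clipL2,
               clipR2 = clipR2, delPos2 = delPos2, delLen2 = delLen2,
               mapped2 = mapped2, mapq1 = mapq1, mapq2 = mapq2,
               proper = proper, stringsAsFactors = FALSE)
}

## minimal call set for population bookkeeping tests
fakeCallSet <- function(mutantId, classes) {
    ev <- plasmidSV:::emptyEvents()
    for (cl in classes)
        ev <- rbind(ev, plasmidSV:::eventRow(classification = cl,
                                             chrom = "chr1"))
    if (nrow(ev)) {
        ev$event_id <- sprintf("%s_v%02d", mutantId, seq_len(nrow(ev)))
        ev$mutant_id <- mutantId
    }
    nCpx <- sum(classes == "complex")
    lesions <- if (nCpx)
        data.frame(lesion_id = sprintf("L%02d", seq_len(nCpx)),
                   lesion_class = "complex", n_sites = 2L,
                   n_plasmid_sites = 1L, chroms = "chr1",
                   stringsAsFactors = FALSE)
    else data.frame(lesion_id = character(0),
                    lesion_class = character(0), n_sites = integer(0),
                    n_plasmid_sites = integer(0), chroms = character(0),
                    stringsAsFactors = FALSE)
    cls <- if (length(classes) == 0L) "no_insertion_found"
    else if (nCpx > 0L) "complex_containing" else "simple_only"
    new("MutantCallSet", mutantId = mutantId,
        sites = plasmidSV:::emptySites(), events = ev, lesions = lesions,
        secondaryDeletions = plasmidSV:::emptyDeletions(),
        mutantClass = cls,
        counts = c(sites = nrow(ev), insertions = nrow(ev),
                   lesions = nrow(ev)))
}

## single-site coordinate signature for redundancy tests
siteSig <- function(mutantId, chrom, coords) {
    df <- data.frame(chrom = chrom, junction = as.integer(coords),
                     stringsAsFactors = FALSE)
    attr(df, "mutant_id") <- mutantId
    df
}

## simulation-recovery trial shared by the property and acceptance tests:
## simulate nMutants from the default mixture at the given coverage, call
## them, and score two-sided insertion recovery against truth
recoveryTrial <- function(coverage, nMutants, seedBase) {
    ref <- sharedRef()
    cfg <- SimConfig(seed = 1, coverage = coverage)
    mix <- EventMixture()
    nTruth <- 0L; nFound <- 0L; nCalls <- 0L; nMatchedCalls <- 0L
    nClipBoth <- 0L; nExactGap <- 0L; delSizes <- integer(0)
    for (i in seq_len(nMutants)) {
        mid <- sprintf("RT%04d", i)
        mut <- simulateMutant(ref, mix, mutantId = mid,
                              seed = seedBase + i)
        prs <- emitAlignments(mut, ref, cfg, seed = seedBase + 5000L + i)
        cs <- callMutant(prs, ref, cfg, mutantId = mid,
                         callDeletions = FALSE)
        tr <- truthEvents(mut)
        tw <- tr[grepl("^two_sided", tr$event_class), , drop = FALSE]
        tc <- tr[tr$event_class == "cofragment_insertion", , drop = FALSE]
        ev <- insertionEvents(cs)
        te <- ev[ev$classification == "two_sided", , drop = FALSE]
        nTruth <- nTruth + nrow(tw)
        nCalls <- nCalls + nrow(te)
        matchedCall <- rep(FALSE, nrow(te))
        for (k in seq_len(nrow(tw))) {
            hit <- which(te$chrom == tw$chrom[k] &
                abs(te$left_jct - tw$left_bp[k]) <=
                    pmax(te$left_unc, 10L) &
                abs(te$right_jct - tw$right_bp[k]) <=
                    pmax(te$right_unc, 10L))
            if (length(hit)) {
                nFound <- nFound + 1L
                matchedCall[hit[1]] <- TRUE
                h <- hit[1]
                if (te$left_unc[h] == 0L && te$right_unc[h] == 0L) {
                    nClipBoth <- nClipBoth + 1L
                    exact <- switch(
                        tw$event_class[k],
                        two_sided_deletion =
                            te$gap_class[h] == "deletion" &&
                            te$gap_size[h] == tw$gap_size[k],
                        two_sided_duplication =
                            te$gap_class[h] == "duplication" &&
                            te$gap_size[h] == -tw$gap_size[k],
                        two_sided_perfect =
                            te$gap_class[h] == "perfect")
                    if (isTRUE(exact)) nExactGap <- nExactGap + 1L
                    if (te$gap_class[h] == "deletion")
                        delSizes <- c(delSizes, te$gap_size[h])
                }
            }
        }
        ## two-sided calls explained by a cofragment insertion (a
        ## two-sided event in its own right) are not false positives
        for (k in seq_len(nrow(tc))) {
            hit <- which(!matchedCall & te$chrom == tc$chrom[k] &
                abs(te$left_jct - tc$left_bp[k]) <=
                    pmax(te$left_unc, 10L))
            if (length(hit)) matchedCall[hit[1]] <- TRUE
        }
        nMatchedCalls <- nMatchedCalls + sum(matchedCall)
    }
    list(nTruth = nTruth, nFound = nFound, nCalls = nCalls,
         nMatchedCalls = nMatchedCalls, nClipBoth = nClipBoth,
         nExactGap = nExactGap, delSizes = delSizes)
}

## fixture population mirroring the narrative structures: one single-gene
## simple mutant; a five-mutant frequency group with one gene at 1.0; a
## 7 + 1 group (seven overlapping deletions of 33 genes + one complex
## mutant sharing only the common gene)
curationFixture <- function() {
    regionA <- sprintf("la%02d", 1:6)     # 5-mutant group, winner la03
    regionB <- sprintf("cb%02d", 1:33)    # 7+1 group, winner cb17
    rec <- rbind(
        recRow("solo1", "gSolo"),
        do.call(rbind, lapply(1:5, function(m) {
            ## overlapping deletions: every member hits la03; the flanking
            ## genes rotate so no neighbour reaches frequency 1
            genes <- unique(c(regionA[3], regionA[m],
                              regionA[(m %% 6) + 1L]))
            do.call(rbind, lapply(genes, function(g)
                recRow(paste0("grpA", m), g, context = "whole_gene_deleted",
                       severity = 5L)))
        })),
        do.call(rbind, lapply(1:7, function(m) do.call(rbind, lapply(
            regionB, function(g) recRow(paste0("grpB", m), g,
                                        context = "whole_gene_deleted",
                                        severity = 5L))))),
        recRow("grpB8", regionB[17]))
    mutants <- data.frame(
        mutant_id = c("solo1", paste0("grpA", 1:5), paste0("grpB", 1:7),
                      "grpB8"),
        mutant_class = c(rep("simple_only", 13), "complex_containing"),
        stringsAsFactors = FALSE)
    flags <- flagGenes(unique(rec$gene_id))
    list(records = rec, mutants = mutants, flags = flags,
         planted = c("gSolo", "la03", "cb17"))
}

## disruption-record row for genemap/curate fixtures
recRow <- function(mutant, gene, severity = 4L, context = "exon",
                   source = paste0(mutant, "_v01")) {
    data.frame(mutant_id = mutant, gene_id = gene, source_id = source,
               context = context, severity = severity,
               stringsAsFactors = FALSE)
}
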