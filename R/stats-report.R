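## Closed-form population statistics and summary tables.

#' Poisson gene-hit probability for an insertional library
#'
#' Probability that a library of n random insertions hits a given gene at
#' least once, under a Poisson model with per-insertion hit rate L / G
#' (average exon length per gene over genome size): 1 - exp(-n L / G).
#' Strictly increasing in n and L, decreasing in G; equals 1 - 1/e at
#' n L / G = 1.
#'
#' @param nInsertions Library size (insertions).
#' @param exonLenPerGene Average exon length per gene (bp).
#' @param genomeSize Genome size (bp).
#' @return Hit probability in [0, 1).
#' @examples
#' poissonHitProbability(60000, 1583, 111e6)  # ~0.575, i.e. 58%
#' @export
poissonHitProbability <- function(nInsertions, exonLenPerGene,
                                  genomeSize) {
    stopIfNot0(genomeSize > 0 && exonLenPerGene > 0 && nInsertions >= 0,
               "parameters must be positive (nInsertions >= 0)")
    1 - exp(-nInsertions * exonLenPerGene / genomeSize)
}

#' Linkage resolution from tetrad-selection counts
#'
#' For a backcross in which ~n zygospores are collected and
#' \code{resistantPerZygospore} antibiotic-resistant progeny per zygospore
#' are tested on selective medium, zero recombinants bound the
#' recombination frequency below 1 / (resistant progeny total), i.e. the
#' genetic distance below 100 / (r n) cM; with observed recombinants the
#' point estimate is 100 k / (r n) cM. The physical distance uses a
#' genome-average kb-per-cM conversion.
#'
#' @param nZygospores Zygospores tested per cross.
#' @param resistantPerZygospore Resistant progeny per zygospore (default
#'   2: half of each tetrad carries the marker).
#' @param nRecombinants Recombinant progeny observed (0 gives the
#'   detection bound).
#' @param kbPerCM Conversion factor (default 100 kb/cM).
#' @return List with \code{cM} (bound or estimate) and \code{kb}.
#' @examples
#' linkageResolution(100)  # < 0.5 cM, ~50 kb
#' @export
linkageResolution <- function(nZygospores, resistantPerZygospore = 2L,
                              nRecombinants = 0L, kbPerCM = 100) {
    total <- resistantPerZygospore * nZygospores
    stopIfNot0(total > 0, "zero progeny tested")
    stopIfNot0(nRecombinants <= total,
               "more recombinants than progeny tested")
    cM <- if (nRecombinants == 0L) 100 / total
          else 100 * nRecombinants / total
    list(cM = cM, kb = cM * kbPerCM,
         mode = if (nRecombinants == 0L) "bound" else "estimate")
}

#' Hypergeometric significance of a gene-set overlap
#'
#' One-sided upper-tail probability P(X >= overlap) with X ~
#' Hypergeometric(universe, nA, nB): the chance of observing at least the
#' given overlap between two gene sets drawn from a common universe
#' (equivalent to a one-sided Fisher's exact test). The universe size is a
#' required explicit argument.
#'
#' @param nA,nB Sizes of the two sets.
#' @param overlap Observed overlap.
#' @param universe Size of the gene universe.
#' @return One-sided p-value.
#' @export
overlapSignificance <- function(nA, nB, overlap, universe) {
    stopIfNot0(overlap <= min(nA, nB) && max(nA, nB) <= universe &&
                   overlap >= 0,
               "inconsistent counts: need overlap <= min(nA, nB) <= universe")
    stats::phyper(overlap - 1, nA, universe - nA, nB, lower.tail = FALSE)
}

#' Rounded percentage
#'
#' 100 * numerator / denominator rounded half-to-even at the requested
#' number of digits (the IEC 60559 behaviour of \code{round}).
#'
#' @param numerator,denominator Counts.
#' @param digits Decimal digits (default 0).
#' @return Rounded percentage.
#' @examples
#' percentage(374, 425)  # 88
#' @export
percentage <- function(numerator, denominator, digits = 0L) {
    stopIfNot0(denominator > 0, "denominator must be > 0")
    round(100 * numerator / denominator, digits)
}

#' Population summary counts
#'
#' Aggregates a set of per-mutant call sets: insertion totals by
#' classification, the simple-insertion total (two-sided plus one-sided
#' with an unmappable or evidence-free flank), mutants by class, mutants
#' with multiple insertions, mean insertions per mutant (1 decimal) and
#' the redundancy removal count.
#'
#' @param callSets List of \code{\link{MutantCallSet}} objects (possibly
#'   empty).
#' @param nRedundantRemoved Count of mutants removed as redundant.
#' @return Named list of summary values.
#' @export
summarizePopulation <- function(callSets, nRedundantRemoved = 0L) {
    if (length(callSets) == 0L)
        return(list(n_mutants = 0L, n_insertions = 0L, two_sided = 0L,
                    one_sided = 0L, complex = 0L, simple_insertions = 0L,
                    mutants_simple_only = 0L,
                    mutants_complex_containing = 0L,
                    mutants_no_insertion = 0L,
                    mutants_multi_insertion = 0L,
                    mean_insertions_per_mutant = 0,
                    redundant_removed = as.integer(nRedundantRemoved)))
    ev <- do.call(rbind, lapply(callSets, insertionEvents))
    cls <- vapply(callSets, mutantClass, character(1))
    nIns <- vapply(callSets, function(cs)
        nrow(insertionEvents(cs)), integer(1))
    twoS <- sum(ev$classification == "two_sided")
    oneS <- sum(ev$classification == "one_sided")
    cplx <- sum(ev$classification == "complex")
    list(n_mutants = length(callSets),
         n_insertions = nrow(ev),
         two_sided = twoS, one_sided = oneS, complex = cplx,
         simple_insertions = twoS + oneS,
         mutants_simple_only = sum(cls == "simple_only"),
         mutants_complex_containing = sum(cls == "complex_containing"),
         mutants_no_insertion = sum(cls == "no_insertion_found"),
         mutants_multi_insertion = sum(nIns > 1L),
         mean_insertions_per_mutant =
             round(nrow(ev) / length(callSets), 1L),
         redundant_removed = as.integer(nRedundantRemoved))
}

.sizeBins <- c(0, 10, 100, 1000, 10000, 100000, Inf)
.sizeBinLabels <- c("1-10", "11-100", "101-1000", "1001-10000",
                    "10001-100000", ">100000")

#' Histogram of junction deletion and duplication sizes
#'
#' Log10-scale bins (1-10, 11-100, 101-1000, 1001-10000, 10001-100000,
#' >100000 bp), one series per gap class.
#'
#' @param events Event table with gap_class and gap_size.
#' @return Matrix: rows deletion/duplication, columns size bins.
#' @export
sizeHistogram <- function(events) {
    out <- matrix(0L, nrow = 2, ncol = length(.sizeBinLabels),
                  dimnames = list(c("deletion", "duplication"),
                                  .sizeBinLabels))
    for (cl in rownames(out)) {
        sz <- events$gap_size[events$gap_class == cl &
                                  !is.na(events$gap_size)]
        if (length(sz))
            out[cl, ] <- as.integer(table(cut(sz, .sizeBins,
                                              labels = .sizeBinLabels)))
    }
    out
}

#' Histogram of genes affected per two-sided insertion
#'
#' Counts two-sided insertions by the number of genes their footprint
#' disrupts; insertions in intergenic territory (0 genes) are reported
#' separately in bin "0".
#'
#' @param events Event table (two-sided rows are used).
#' @param records Disruption records with source_id referencing event ids.
#' @return Named integer vector: bins "0", "1", "2", ... up to the
#'   observed maximum.
#' @export
genesPerInsertionHistogram <- function(events, records) {
    ts <- events[events$classification == "two_sided", , drop = FALSE]
    if (nrow(ts) == 0L) return(stats::setNames(integer(0), character(0)))
    cnt <- vapply(ts$event_id, function(eid)
        length(unique(records$gene_id[records$source_id == eid])),
        integer(1))
    mx <- max(cnt)
    h <- vapply(0:mx, function(k) sum(cnt == k), integer(1))
    stats::setNames(h, as.character(0:mx))
}
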