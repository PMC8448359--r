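#' @import methods
#' @importFrom S4Vectors isSingleNumber
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom GenomicRanges GRanges
NULL

## ---------------------------------------------------------------------------
## SimConfig
## ---------------------------------------------------------------------------

#' Simulation and calling configuration
#'
#' Holds the sequencing-experiment parameters shared by the simulator and the
#' structural-variant caller: a haploid nuclear genome of
#' \code{nChromosomes} chromosomes of \code{chromosomeLength} bp each, a
#' mutagenesis plasmid carried as an extra contig, mean sequence depth
#' \code{coverage} (default 7.44, the screen-scale average for low-coverage
#' whole-genome sequencing), \code{fragmentMean}/\code{fragmentSd} for the
#' sheared-fragment length distribution (default 600 +/- 60 bp) and 2 x
#' \code{readLength} paired-end reads (default 150 bp).
#'
#' @slot seed integer, base RNG seed.
#' @slot nChromosomes integer, number of nuclear chromosomes.
#' @slot chromosomeLength integer, length of each chromosome in bp.
#' @slot repeatFraction numeric in [0, 0.5), fraction of each chromosome
#'   covered by exact-duplication repeat blocks (unmappable; mapping
#'   quality 0 in emitted alignments).
#' @slot plasmidLength integer, plasmid length in bp.
#' @slot coverage numeric, mean sequence depth.
#' @slot fragmentMean,fragmentSd numeric, fragment length distribution (bp).
#' @slot readLength integer, read length in bp.
#' @slot baseErrorRate numeric, per-base substitution probability.
#'
#' @examples
#' cfg <- SimConfig(seed = 1)
#' cfg
#' @export
setClass("SimConfig", representation(
    seed = "integer",
    nChromosomes = "integer",
    chromosomeLength = "integer",
    repeatFraction = "numeric",
    plasmidLength = "integer",
    coverage = "numeric",
    fragmentMean = "numeric",
    fragmentSd = "numeric",
    readLength = "integer",
    baseErrorRate = "numeric"
))

setValidity("SimConfig", function(object) {
    msg <- character(0)
    if (object@coverage <= 0) msg <- c(msg, "coverage must be > 0")
    if (object@fragmentMean < 2 * object@readLength)
        msg <- c(msg, "fragmentMean must be >= 2 * readLength")
    if (object@repeatFraction < 0 || object@repeatFraction >= 0.5)
        msg <- c(msg, "repeatFraction must be in [0, 0.5)")
    if (object@nChromosomes < 1L) msg <- c(msg, "need >= 1 chromosome")
    if (object@chromosomeLength < 1000L)
        msg <- c(msg, "chromosomeLength must be >= 1000 bp")
    if (object@plasmidLength < 100L)
        msg <- c(msg, "plasmidLength must be >= 100 bp")
    if (object@baseErrorRate < 0 || object@baseErrorRate >= 1)
        msg <- c(msg, "baseErrorRate must be in [0, 1)")
    if (length(msg)) msg else TRUE
})

#' @rdname SimConfig-class
#' @param seed,nChromosomes,chromosomeLength,repeatFraction,plasmidLength
#'   See slot documentation.
#' @param coverage,fragmentMean,fragmentSd,readLength,baseErrorRate
#'   See slot documentation.
#' @return A \code{SimConfig} object.
#' @export
SimConfig <- function(seed = 1L, nChromosomes = 3L,
                      chromosomeLength = 500000L, repeatFraction = 0.05,
                      plasmidLength = 5000L, coverage = 7.44,
                      fragmentMean = 600, fragmentSd = 60,
                      readLength = 150L, baseErrorRate = 0) {
    new("SimConfig",
        seed = as.integer(seed),
        nChromosomes = as.integer(nChromosomes),
        chromosomeLength = as.integer(chromosomeLength),
        repeatFraction = as.numeric(repeatFraction),
        plasmidLength = as.integer(plasmidLength),
        coverage = as.numeric(coverage),
        fragmentMean = as.numeric(fragmentMean),
        fragmentSd = as.numeric(fragmentSd),
        readLength = as.integer(readLength),
        baseErrorRate = as.numeric(baseErrorRate))
}

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@nChromosomes, "chromosomes x",
        object@chromosomeLength, "bp + plasmid", object@plasmidLength,
        "bp\n  coverage", object@coverage, "| fragments",
        object@fragmentMean, "+/-", object@fragmentSd, "bp | 2 x",
        object@readLength, "bp reads | repeatFraction",
        object@repeatFraction, "\n")
})

## ---------------------------------------------------------------------------
## EventMixture
## ---------------------------------------------------------------------------

.eventClasses <- c("two_sided_deletion", "two_sided_duplication",
                   "two_sided_perfect", "one_sided_repeat",
                   "one_sided_complex", "complex_intra", "complex_inter",
                   "translocation", "cofragment_insertion")

#' Per-mutant structural-event mixture
#'
#' Probabilities over insertion-event classes, the junction-deletion size
#' model (a two-component log-uniform mixture reproducing the bimodal size
#' spectrum peaking at 11-100 bp and 10-100 kb), the duplication size range
#' (all < 1000 bp), the rate of additional insertions beyond the first, and
#' the per-mutant rate of deletions unassociated with any plasmid insertion
#' (sizes 20 bp - 36 kb).
#'
#' Defaults reflect the event frequencies observed in a screen-scale
#' insertional-mutagenesis library: ~77\% of insertions two-sided (of which
#' 88\% carry a deletion, 7\% a duplication, 5\% perfect), a few percent
#' one-sided at repetitive flanks, ~2\% with a co-inserted random genome
#' fragment, and ~19\% complex rearrangements including translocations.
#'
#' @slot classProbs named numeric, probabilities over event classes
#'   (must sum to 1).
#' @slot deletionRanges 2x2 numeric matrix, per-component [min, max] bp of
#'   the log-uniform deletion size mixture.
#' @slot deletionWeights numeric length-2, component weights (sum to 1).
#' @slot duplicationRange numeric length-2, [min, max) bp, max <= 1000.
#' @slot extraInsertionRate numeric, Poisson mean of additional insertions
#'   per mutant beyond the first.
#' @slot unassocDeletionRate numeric, Poisson mean of plasmid-unassociated
#'   deletions per mutant.
#' @slot unassocDeletionRange numeric length-2, [min, max] bp.
#' @slot concatemerCopies integer, plasmid copies inserted per event.
#' @export
setClass("EventMixture", representation(
    classProbs = "numeric",
    deletionRanges = "matrix",
    deletionWeights = "numeric",
    duplicationRange = "numeric",
    extraInsertionRate = "numeric",
    unassocDeletionRate = "numeric",
    unassocDeletionRange = "numeric",
    concatemerCopies = "integer"
))

setValidity("EventMixture", function(object) {
    msg <- character(0)
    p <- object@classProbs
    if (!all(names(p) %in% .eventClasses) || is.null(names(p)))
        msg <- c(msg, "classProbs must be named by known event classes")
    if (abs(sum(p) - 1) > 1e-8) msg <- c(msg, "classProbs must sum to 1")
    if (any(p < 0)) msg <- c(msg, "classProbs must be non-negative")
    dr <- object@deletionRanges
    if (!is.matrix(dr) || ncol(dr) != 2L)
        msg <- c(msg, "deletionRanges must be an n x 2 matrix")
    else if (any(dr <= 0) || any(dr[, 1] > dr[, 2]))
        msg <- c(msg, "deletionRanges components must be positive, ordered")
    if (abs(sum(object@deletionWeights) - 1) > 1e-8)
        msg <- c(msg, "deletionWeights must sum to 1")
    if (object@duplicationRange[2] > 1000)
        msg <- c(msg, "duplications must be < 1000 bp")
    if (object@unassocDeletionRange[1] < 20 ||
        object@unassocDeletionRange[2] > 36000)
        msg <- c(msg, "unassociated deletion sizes must lie in [20, 36000]")
    if (object@concatemerCopies < 1L)
        msg <- c(msg, "concatemerCopies must be >= 1")
    if (length(msg)) msg else TRUE
})

#' @rdname EventMixture-class
#' @param classProbs,deletionRanges,deletionWeights,duplicationRange
#'   See slot documentation.
#' @param extraInsertionRate,unassocDeletionRate,unassocDeletionRange
#'   See slot documentation.
#' @param concatemerCopies See slot documentation.
#' @return An \code{EventMixture} object.
#' @export
EventMixture <- function(classProbs = c(two_sided_deletion = 0.675,
                                        two_sided_duplication = 0.052,
                                        two_sided_perfect = 0.040,
                                        one_sided_repeat = 0.025,
                                        cofragment_insertion = 0.018,
                                        complex_intra = 0.080,
                                        complex_inter = 0.080,
                                        translocation = 0.030),
                         deletionRanges = rbind(c(11, 100), c(10000, 100000)),
                         deletionWeights = c(0.5, 0.5),
                         duplicationRange = c(1, 999),
                         extraInsertionRate = 0.09,
                         unassocDeletionRate = 0.13,
                         unassocDeletionRange = c(20, 36000),
                         concatemerCopies = 1L) {
    classProbs <- classProbs / sum(classProbs)
    new("EventMixture", classProbs = classProbs,
        deletionRanges = deletionRanges,
        deletionWeights = deletionWeights,
        duplicationRange = as.numeric(duplicationRange),
        extraInsertionRate = as.numeric(extraInsertionRate),
        unassocDeletionRate = as.numeric(unassocDeletionRate),
        unassocDeletionRange = as.numeric(unassocDeletionRange),
        concatemerCopies = as.integer(concatemerCopies))
}

setMethod("show", "EventMixture", function(object) {
    cat("EventMixture over", length(object@classProbs), "event classes\n")
    print(round(object@classProbs, 3))
    cat("deletion size mixture (bp):\n")
    print(object@deletionRanges)
})

## ---------------------------------------------------------------------------
## ReferenceSet
## ---------------------------------------------------------------------------

#' Combined simulation reference: chromosomes, repeat mask, plasmid
#'
#' @slot chromosomes \code{DNAStringSet} of nuclear chromosomes.
#' @slot plasmid \code{DNAStringSet} of length 1, the mutagenesis plasmid.
#' @slot repeatMask \code{GRanges} of exact-duplication repeat blocks
#'   (1-based closed, as GRanges conventions require).
#' @slot plasmidName character, the plasmid contig name.
#' @export
setClass("ReferenceSet", representation(
    chromosomes = "DNAStringSet",
    plasmid = "DNAStringSet",
    repeatMask = "GRanges",
    plasmidName = "character"
))

setValidity("ReferenceSet", function(object) {
    if (length(object@plasmid) != 1L)
        return("plasmid must contain exactly one sequence")
    TRUE
})

setMethod("show", "ReferenceSet", function(object) {
    cat("ReferenceSet:", length(object@chromosomes), "chromosomes (",
        sum(Biostrings::width(object@chromosomes)), "bp ), plasmid '",
        object@plasmidName, "' (", Biostrings::width(object@plasmid),
        "bp ),", length(object@repeatMask), "repeat blocks\n")
})

#' @describeIn ReferenceSet-class chromosome sequences
#' @param x A \code{ReferenceSet}.
#' @export
setGeneric("chromosomes", function(x) standardGeneric("chromosomes"))
#' @rdname ReferenceSet-class
#' @export
setMethod("chromosomes", "ReferenceSet", function(x) x@chromosomes)

#' @describeIn ReferenceSet-class plasmid sequence
#' @export
setGeneric("plasmidSeq", function(x) standardGeneric("plasmidSeq"))
#' @rdname ReferenceSet-class
#' @export
setMethod("plasmidSeq", "ReferenceSet", function(x) x@plasmid)

#' @describeIn ReferenceSet-class repeat mask as GRanges
#' @export
setGeneric("repeatMask", function(x) standardGeneric("repeatMask"))
#' @rdname ReferenceSet-class
#' @export
setMethod("repeatMask", "ReferenceSet", function(x) x@repeatMask)

## ---------------------------------------------------------------------------
## MutantGenome
## ---------------------------------------------------------------------------

#' A simulated mutant genome with its truth table
#'
#' The mutated genome is represented as one segment map per chromosome: an
#' ordered table of source intervals (reference chromosome or plasmid,
#' 0-based half-open, with strand) whose concatenation is the mutated
#' chromosome. Every read simulated from the mutant can therefore be mapped
#' back to its true reference origin, which is how truth-based alignments
#' are emitted without re-implementing an aligner.
#'
#' @slot mutantId character.
#' @slot segments list of data.frames (one per mutated chromosome) with
#'   columns src, start, end, strand.
#' @slot truth data.frame of truth events (see \code{\link{simulateMutant}}).
#' @export
setClass("MutantGenome", representation(
    mutantId = "character",
    segments = "list",
    truth = "data.frame"
))

setMethod("show", "MutantGenome", function(object) {
    cat("MutantGenome", object@mutantId, ":", length(object@segments),
        "chromosomes,", nrow(object@truth), "truth events\n")
})

#' @describeIn MutantGenome-class mutant identifier
#' @param x object.
#' @export
setGeneric("mutantId", function(x) standardGeneric("mutantId"))
#' @rdname MutantGenome-class
#' @export
setMethod("mutantId", "MutantGenome", function(x) x@mutantId)

#' @describeIn MutantGenome-class truth event table
#' @export
setGeneric("truthEvents", function(x) standardGeneric("truthEvents"))
#' @rdname MutantGenome-class
#' @export
setMethod("truthEvents", "MutantGenome", function(x) x@truth)

#' @describeIn MutantGenome-class segment maps of the mutated chromosomes
#' @export
setGeneric("segmentMaps", function(x) standardGeneric("segmentMaps"))
#' @rdname MutantGenome-class
#' @export
setMethod("segmentMaps", "MutantGenome", function(x) x@segments)

## ---------------------------------------------------------------------------
## MutantCallSet
## ---------------------------------------------------------------------------

#' All structural-variant calls for one mutant
#'
#' @slot mutantId character.
#' @slot sites data.frame of discordant sites.
#' @slot events data.frame of classified insertion events.
#' @slot lesions data.frame of lesions (paired discordant-site groups).
#' @slot secondaryDeletions data.frame of deletions (gapped-read,
#'   spanning-pair or coverage evidence), with the unassociated flag.
#' @slot mutantClass one of simple_only, complex_containing,
#'   no_insertion_found.
#' @slot counts named integer vector: discordant sites, insertions, lesions.
#' @export
setClass("MutantCallSet", representation(
    mutantId = "character",
    sites = "data.frame",
    events = "data.frame",
    lesions = "data.frame",
    secondaryDeletions = "data.frame",
    mutantClass = "character",
    counts = "integer"
))

setValidity("MutantCallSet", function(object) {
    ok <- object@mutantClass %in%
        c("simple_only", "complex_containing", "no_insertion_found")
    if (!ok) return("invalid mutantClass")
    TRUE
})

setMethod("show", "MutantCallSet", function(object) {
    cat("MutantCallSet", object@mutantId, "(", object@mutantClass, "):",
        object@counts[["sites"]], "discordant sites,",
        object@counts[["insertions"]], "insertions,",
        object@counts[["lesions"]], "lesions,",
        nrow(object@secondaryDeletions), "secondary deletions\n")
})

#' @rdname MutantCallSet-class
#' @export
setMethod("mutantId", "MutantCallSet", function(x) x@mutantId)

#' @describeIn MutantCallSet-class discordant-site table
#' @param x object.
#' @export
setGeneric("discordantSites", function(x) standardGeneric("discordantSites"))
#' @rdname MutantCallSet-class
#' @export
setMethod("discordantSites", "MutantCallSet", function(x) x@sites)

#' @describeIn MutantCallSet-class classified insertion events
#' @export
setGeneric("insertionEvents", function(x) standardGeneric("insertionEvents"))
#' @rdname MutantCallSet-class
#' @export
setMethod("insertionEvents", "MutantCallSet", function(x) x@events)

#' @describeIn MutantCallSet-class lesion table
#' @export
setGeneric("lesions", function(x) standardGeneric("lesions"))
#' @rdname MutantCallSet-class
#' @export
setMethod("lesions", "MutantCallSet", function(x) x@lesions)

#' @describeIn MutantCallSet-class secondary-deletion table
#' @export
setGeneric("secondaryDeletions",
           function(x) standardGeneric("secondaryDeletions"))
#' @rdname MutantCallSet-class
#' @export
setMethod("secondaryDeletions", "MutantCallSet",
          function(x) x@secondaryDeletions)

#' @describeIn MutantCallSet-class mutant classification
#' @export
setGeneric("mutantClass", function(x) standardGeneric("mutantClass"))
#' @rdname MutantCallSet-class
#' @export
setMethod("mutantClass", "MutantCallSet", function(x) x@mutantClass)
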