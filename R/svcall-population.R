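## Population-level redundancy detection.

#' Find redundant (duplicated) mutants in a population
#'
#' Mutants whose full insertion-site coordinate sets match within
#' \code{toleranceBp} are grouped; because clones cannot be told apart,
#' every member of each group is listed for removal (the removal count is
#' the sum of the group sizes). Two mutants match only if they carry the
#' same number of insertion junctions, on the same chromosomes, each
#' within tolerance — sharing a subset of sites is not enough.
#'
#' @param callSets List of \code{\link{MutantCallSet}} objects, or a list
#'   of per-mutant data.frames with columns chrom and junction.
#' @param toleranceBp Coordinate tolerance (bp, default 10).
#' @return List with \code{groups} (list of mutant-id vectors, size >= 2)
#'   and \code{removal} (character vector of all mutants to remove).
#' @export
findRedundantMutants <- function(callSets, toleranceBp = 10L) {
    sigs <- lapply(callSets, function(cs) {
        df <- if (methods::is(cs, "MutantCallSet")) {
            ev <- insertionEvents(cs)
            jl <- data.frame(chrom = ev$chrom, coord = ev$left_jct)
            jr <- data.frame(chrom = ev$chrom, coord = ev$right_jct)
            rbind(jl, jr)
        } else data.frame(chrom = cs$chrom, coord = cs$junction)
        df <- df[!is.na(df$coord), , drop = FALSE]
        df[order(df$chrom, df$coord), , drop = FALSE]
    })
    ids <- vapply(callSets, function(cs)
        if (methods::is(cs, "MutantCallSet")) mutantId(cs)
        else attr(cs, "mutant_id"), character(1))
    n <- length(sigs)
    stopIfNot0(n >= 2L, "need at least two mutants")
    sameSig <- function(a, b) {
        if (nrow(a) != nrow(b) || nrow(a) == 0L) return(FALSE)
        all(a$chrom == b$chrom) &&
            all(abs(a$coord - b$coord) <= toleranceBp)
    }
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
        if (sameSig(sigs[[i]], sigs[[j]])) {
            ri <- find(i); rj <- find(j)
            if (ri != rj) parent[rj] <- ri
        }
    comp <- vapply(seq_len(n), find, integer(1))
    groups <- split(ids, comp)
    groups <- unname(groups[vapply(groups, length, integer(1)) >= 2L])
    list(groups = groups, removal = unlist(groups, use.names = FALSE))
}
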