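test_that("SimConfig and EventMixture enforce their invariants", {
    expect_error(SimConfig(coverage = 0), "coverage")
    expect_error(SimConfig(fragmentMean = 250, readLength = 150),
                 "fragmentMean")
    expect_error(SimConfig(repeatFraction = 0.6), "repeatFraction")
    expect_error(EventMixture(duplicationRange = c(1, 1500)), "1000")
    expect_error(EventMixture(unassocDeletionRange = c(10, 36000)),
                 "20")
    mx <- EventMixture()
    expect_equal(sum(mx@classProbs), 1)
})

test_that("reference generation is deterministic with exact sizes and mask", {
    cfg <- sharedCfg()
    ref <- sharedRef()
    expect_equal(unname(Biostrings::width(chromosomes(ref))),
                 rep(500000L, 3))
    ## masked fraction ~ repeatFraction
    frac <- sum(IRanges::width(GenomicRanges::ranges(repeatMask(ref)))) /
        sum(Biostrings::width(chromosomes(ref)))
    expect_lt(abs(frac - 0.05), 0.01)
    ## byte-identical FASTA for the same seed
    d1 <- tempfile(); d2 <- tempfile()
    writeReference(ref, d1)
    writeReference(generateReference(cfg), d2)
    expect_identical(readLines(file.path(d1, "reference.fasta")),
                     readLines(file.path(d2, "reference.fasta")))
})

test_that("plasmid shares no 31-mer with the chromosomes (exhaustive oracle)", {
    cfg <- SimConfig(seed = 7, nChromosomes = 1L,
                     chromosomeLength = 30000L, repeatFraction = 0,
                     plasmidLength = 2000L)
    ref <- generateReference(cfg)
    k <- 31L
    kmers <- function(s) {
        n <- nchar(s)
        unique(substring(s, 1:(n - k + 1L), k:n))
    }
    chr <- as.character(chromosomes(ref)[[1]])
    pl <- as.character(plasmidSeq(ref)[[1]])
    plrc <- as.character(
        Biostrings::reverseComplement(plasmidSeq(ref)[[1]]))
    expect_length(intersect(kmers(pl), kmers(chr)), 0)
    expect_length(intersect(kmers(plrc), kmers(chr)), 0)
})

test_that("undersized chromosomes cannot host the requested repeats", {
    expect_error(
        generateReference(SimConfig(seed = 1, chromosomeLength = 2000L,
                                    repeatFraction = 0.45),
                          repeatUnitLength = 1000L),
        "too small")
})

test_that("mutant genomes conserve sequence per event type", {
    ref <- tinyRef()
    base <- 80000L + 5000L
    mut <- simulateMutant(ref, mutantId = "p", seed = 1,
                          classes = "two_sided_perfect")
    expect_equal(unname(mutatedLengths(mut)), base)
    mut <- simulateMutant(ref, mutantId = "d", seed = 1,
                          classes = "two_sided_deletion", gapSizes = 10)
    expect_equal(unname(mutatedLengths(mut)), base - 10L)
    mut <- simulateMutant(ref, mutantId = "u", seed = 1,
                          classes = "two_sided_duplication",
                          gapSizes = -7)
    expect_equal(unname(mutatedLengths(mut)), base + 7L)
    ## general conservation over a mixed draw
    mut <- simulateMutant(sharedRef(), EventMixture(), mutantId = "m",
                          seed = 42)
    tr <- truthEvents(mut)
    plas <- sum(tr$event_class != "unassociated_deletion") * 5000L
    gain <- sum(ifelse(tr$event_class == "cofragment_insertion",
                       tr$partner_end - tr$partner_start, 0L))
    net <- sum(ifelse(grepl("two_sided|unassociated|complex_inter",
                            tr$event_class) & !is.na(tr$gap_size),
                      tr$gap_size, 0L))
    expect_equal(sum(mutatedLengths(mut)),
                 1500000L + plas + gain - net)
})

test_that("event class frequencies recover the mixture (binomial error)", {
    mx <- EventMixture()
    n <- 3000L
    cls <- withr::with_seed(11, drawEventClasses(mx, n))
    p <- mx@classProbs
    for (k in names(p)) {
        if (p[[k]] == 0) next
        se <- sqrt(p[[k]] * (1 - p[[k]]) / n)
        expect_lt(abs(mean(cls == k) - p[[k]]), 3.2 * se + 1e-9,
                  label = paste("class", k))
    }
})

test_that("overlapping event draws error out after bounded retries", {
    ref <- tinyRef()
    ## an 80 kb chromosome cannot host four 60 kb deletions
    expect_error(
        simulateMutant(ref, mutantId = "x", seed = 1,
                       classes = rep("two_sided_deletion", 4),
                       gapSizes = rep(60000, 4), maxRetries = 5L),
        "overlap")
})

test_that("fragment counts and lengths follow the configuration", {
    ref <- tinyRef()
    cfg <- tinyCfg()
    mut <- simulateMutant(ref, mutantId = "f", seed = 1,
                          classes = character(0))
    fr <- simulateFragments(mut, cfg, seed = 5)
    expect_equal(nrow(fr), round(7.44 * 80000 / 300))
    ## 1 Mb mutated genome at 7.44x, 2 x 150 -> 24,800 pairs
    cfg1 <- SimConfig(seed = 3, nChromosomes = 2L,
                      chromosomeLength = 497500L, repeatFraction = 0)
    ref1 <- generateReference(cfg1)
    mut1 <- simulateMutant(ref1, mutantId = "g", seed = 1,
                           classes = "two_sided_perfect")
    expect_equal(sum(mutatedLengths(mut1)), 1000000L)  # 995 kb + plasmid
    fr1 <- simulateFragments(mut1, cfg1, seed = 6)
    expect_equal(nrow(fr1), 24800L)
    ## mean fragment length within 1% of 600 over 10^4 pairs
    expect_lt(abs(mean(fr1$len) - 600) / 600, 0.01)
    expect_true(all(fr1$len >= 300))
})

test_that("zero-error reads are exact substrings of the mutated genome", {
    ref <- tinyRef()
    cfg <- tinyCfg()
    mut <- simulateMutant(ref, mutantId = "r", seed = 2,
                          classes = "two_sided_deletion", gapSizes = 500)
    fq <- simulateReads(mut, ref, cfg, seed = 9, outPrefix = tempfile())
    l1 <- readLines(fq[1]); l2 <- readLines(fq[2])
    s1 <- l1[seq(2, length(l1), 4)]
    s2 <- l2[seq(2, length(l2), 4)]
    gen <- as.character(mutantSequences(mut, ref)[[1]])
    rc <- function(x) as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(x)))
    idx <- seq(1, length(s1), length.out = 40)
    expect_true(all(vapply(s1[idx], grepl, logical(1), x = gen,
                           fixed = TRUE)))
    expect_true(all(vapply(s2[idx], function(s)
        grepl(rc(s), gen, fixed = TRUE), logical(1))))
    ## determinism: same seed, same bytes
    fqb <- simulateReads(mut, ref, cfg, seed = 9,
                         outPrefix = tempfile())
    expect_identical(readLines(fq[1]), readLines(fqb[1]))
})

test_that("truth tables round-trip losslessly with signed gaps", {
    ref <- sharedRef()   # large enough for every event class
    muts <- lapply(1:20, function(i)
        simulateMutant(ref, EventMixture(), mutantId = paste0("T", i),
                       seed = 100 + i))
    truth <- do.call(rbind, lapply(muts, truthEvents))
    path <- tempfile(fileext = ".tsv")
    writeTruth(truth, path)
    back <- readTruth(path)
    rownames(truth) <- rownames(back) <- NULL
    expect_equal(back, truth)
    ## sign convention in the file: deletion 50 -> +50; duplication 7 -> -7
    t2 <- truthEvents(simulateMutant(ref, mutantId = "s", seed = 1,
                                     classes = c("two_sided_deletion",
                                                 "two_sided_duplication"),
                                     gapSizes = c(50, -7)))
    p2 <- tempfile(); writeTruth(t2, p2)
    f <- utils::read.delim(p2, comment.char = "#")
    expect_equal(sort(f$gap_size), c(-7L, 50L))
    ## empty event list -> header-only table
    p3 <- tempfile()
    writeTruth(plasmidSV:::emptyTruth(), p3)
    expect_equal(nrow(readTruth(p3)), 0L)
})
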