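test_that("Poisson gene-hit probability matches its closed form", {
    p <- poissonHitProbability(60000, 1583, 111e6)
    expect_equal(p, 1 - exp(-60000 * 1583 / 111e6))
    expect_equal(round(100 * p), 58)
    expect_equal(poissonHitProbability(0, 1583, 111e6), 0)
    ## n L / G = ln 2 -> exactly one half
    expect_equal(poissonHitProbability(log(2) * 1e6, 1, 1e6), 0.5)
    ## 1 - 1/e at unit intensity; monotonicity in each argument
    expect_equal(poissonHitProbability(1e6, 1, 1e6), 1 - exp(-1))
    expect_gt(poissonHitProbability(70000, 1583, 111e6), p)
    expect_gt(poissonHitProbability(60000, 1800, 111e6), p)
    expect_lt(poissonHitProbability(60000, 1583, 120e6), p)
})

test_that("linkage resolution reproduces the tetrad arithmetic", {
    lr <- linkageResolution(100)
    expect_equal(lr$cM, 0.5)
    expect_equal(lr$kb, 50)
    expect_equal(lr$mode, "bound")
    expect_equal(linkageResolution(50)$cM, 1.0)
    ## the bound halves when the zygospore count doubles
    expect_equal(linkageResolution(200)$cM,
                 linkageResolution(100)$cM / 2)
    ## point-estimate mode with observed recombinants
    lr2 <- linkageResolution(100, nRecombinants = 4L)
    expect_equal(lr2$cM, 100 * 4 / 200)
    expect_equal(lr2$mode, "estimate")
    expect_error(linkageResolution(0), "zero progeny")
    expect_error(linkageResolution(10, nRecombinants = 50L), "more")
})

test_that("hypergeometric overlap matches exhaustive enumeration", {
    N <- 20L; nA <- 5L; nB <- 5L
    A <- seq_len(nA)
    draws <- utils::combn(N, nB)
    ov <- apply(draws, 2, function(d) sum(d %in% A))
    for (k in 0:5) {
        expect_lt(abs(overlapSignificance(nA, nB, k, N) -
                          mean(ov >= k)), 1e-12)
    }
    expect_equal(overlapSignificance(nA, nB, 5L, N),
                 1 / choose(20, 5), tolerance = 1e-12)
    expect_equal(overlapSignificance(3L, 4L, 0L, 30L), 1)
    ## at the floored expectation the upper tail is at least one half
    expE <- floor(nA * nB / N)
    expect_gte(overlapSignificance(nA, nB, expE, N), 0.5)
    expect_error(overlapSignificance(5, 5, 6, 20), "inconsistent")
})

test_that("percentages round half-to-even and match printed values", {
    expect_equal(percentage(374, 425), 88)
    expect_equal(percentage(22, 425), 5)
    expect_equal(percentage(29, 425), 7)
    expect_equal(percentage(25, 1000), 2)    # 2.5 -> even
    expect_equal(percentage(35, 1000), 4)    # 3.5 -> even
    expect_equal(percentage(554, 509, 1), 108.8)
    expect_error(percentage(1, 0), "denominator")
})

test_that("population summaries reproduce the bookkeeping identities", {
    ## 509 analyzed mutants carrying 425 two-sided, 21 one-sided and 108
    ## complex insertions (554 total)
    pool <- c(rep("two_sided", 425), rep("one_sided", 21),
              rep("complex", 108))               # 554 insertions
    ## 45 mutants carry two insertions, the rest one: 509 mutants total
    classes <- c(lapply(seq(1, 89, 2), function(i) pool[c(i, i + 1)]),
                 as.list(pool[91:554]))
    expect_length(classes, 509L)
    cs <- lapply(seq_along(classes), function(i)
        fakeCallSet(sprintf("mm%03d", i), classes[[i]]))
    s <- summarizePopulation(cs, nRedundantRemoved = 79L)
    expect_equal(s$n_mutants, 509L)
    expect_equal(s$n_insertions, 554L)
    expect_equal(s$two_sided, 425L)
    expect_equal(s$one_sided, 21L)
    expect_equal(s$simple_insertions, 446L)       # 425 + 21
    expect_equal(s$mean_insertions_per_mutant, 1.1)  # 554 / 509
    expect_equal(s$redundant_removed, 79L)
    ## mutants analyzed: 660 sequenced - 72 without sites - 79 redundant
    expect_equal(660L - 72L - s$redundant_removed, s$n_mutants)
    ## empty population -> zeros
    s0 <- summarizePopulation(list())
    expect_equal(s0$n_insertions, 0L)
    expect_equal(s0$n_mutants, 0L)
})

test_that("size histograms bin on the log10 scale and conserve counts", {
    ev <- rbind(
        plasmidSV:::eventRow(classification = "two_sided",
                             gap_class = "deletion", gap_size = 50L),
        plasmidSV:::eventRow(classification = "two_sided",
                             gap_class = "deletion", gap_size = 133000L),
        plasmidSV:::eventRow(classification = "two_sided",
                             gap_class = "deletion", gap_size = 25000L),
        plasmidSV:::eventRow(classification = "two_sided",
                             gap_class = "duplication", gap_size = 7L),
        plasmidSV:::eventRow(classification = "two_sided",
                             gap_class = "perfect", gap_size = 0L))
    h <- sizeHistogram(ev)
    expect_equal(h["deletion", "11-100"], 1L)
    expect_equal(h["deletion", ">100000"], 1L)
    expect_equal(h["deletion", "10001-100000"], 1L)
    expect_equal(h["duplication", "1-10"], 1L)
    expect_equal(sum(h), 4L)  # all sized events, perfect excluded
})

test_that("genes-per-insertion histogram separates intergenic events", {
    ev <- rbind(
        plasmidSV:::eventRow(event_id = "e1",
                             classification = "two_sided"),
        plasmidSV:::eventRow(event_id = "e2",
                             classification = "two_sided"),
        plasmidSV:::eventRow(event_id = "e3",
                             classification = "two_sided"),
        plasmidSV:::eventRow(event_id = "e4",
                             classification = "one_sided"))
    rec <- rbind(recRow("m", "g1", source = "e1"),
                 recRow("m", "g1", source = "e2"),
                 recRow("m", "g2", source = "e2"),
                 recRow("m", "g3", source = "e2"))
    h <- genesPerInsertionHistogram(ev, rec)
    expect_equal(unname(h[c("0", "1", "3")]), c(1L, 1L, 1L))
    expect_equal(sum(h), 3L)   # one-sided events are not counted
})
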