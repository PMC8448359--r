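params0 <- svParams(SimConfig(seed = 1))

test_that("pair partition follows the discordance definition", {
    pairs <- rbind(
        pairRow("conc", start1 = 1000L, end1 = 1150L, start2 = 1400L,
                end2 = 1550L),          # mates 400 bp apart, facing
        pairRow("plas", contig2 = "plasmid", start2 = 100L, end2 = 250L),
        pairRow("far", start2 = 51000L, end2 = 51150L), # 50 kb apart
        pairRow("inter", contig2 = "chr2"),
        pairRow("lowq", contig2 = "plasmid", mapq1 = 5L),
        pairRow("orient", strand2 = "+"))               # non-facing
    disc <- collectDiscordantPairs(pairs, "plasmid", params0)
    expect_equal(disc$plasmid_paired$read_id, "plas")
    expect_equal(disc$plasmid_paired$side, "left")
    expect_equal(disc$interchromosomal$read_id, "inter")
    expect_setequal(disc$intrachromosomal_aberrant$read_id,
                    c("far", "orient"))
    expect_equal(disc$lowmapq$read_id, "lowq")
    ## unmapped mate -> skipped with a count
    pairs$mapped2[1] <- FALSE
    disc2 <- collectDiscordantPairs(pairs, "plasmid", params0)
    expect_equal(disc2$skipped, 1L)
})

test_that("clustering respects side, support threshold and noise", {
    mk <- function(id, s) pairRow(id, start1 = s, end1 = s + 150L,
                                  contig2 = "plasmid", start2 = 10L,
                                  end2 = 160L)
    ## 5 forward anchors ending within 300 bp -> one left site, support 5
    pairs <- do.call(rbind, lapply(1:5, function(i)
        mk(paste0("r", i), 10000L + 60L * i)))
    disc <- collectDiscordantPairs(pairs, "plasmid", params0)
    clu <- clusterDiscordant(disc, params0)
    expect_equal(nrow(clu$plasmid_sites), 1L)
    expect_equal(clu$plasmid_sites$n_support, 5L)
    expect_equal(clu$plasmid_sites$side, "left")
    expect_equal(clu$n_filtered, 0L)
    ## a singleton below minSupport is dropped and counted
    disc1 <- collectDiscordantPairs(mk("solo", 40000L), "plasmid",
                                    params0)
    clu1 <- clusterDiscordant(disc1, params0)
    expect_equal(nrow(clu1$plasmid_sites), 0L)
    expect_equal(clu1$n_filtered, 1L)
    ## scattered singleton noise never forms sites
    noise <- do.call(rbind, lapply(1:8, function(i)
        mk(paste0("n", i), i * 9000L)))
    cluN <- clusterDiscordant(
        collectDiscordantPairs(noise, "plasmid", params0), params0)
    expect_equal(nrow(cluN$plasmid_sites), 0L)
})

test_that("junction estimation prefers consistent soft-clips", {
    site <- plasmidSV:::emptySites()[0, ]
    site[1, ] <- list("P001", "chr1", 9500L, 10020L, "left", "plasmid",
                      NA, NA, NA, 3L, 10020L, NA, NA, NA)
    clips3 <- data.frame(contig = "chr1", coord = rep(10050L, 3),
                         type = "end", stringsAsFactors = FALSE)
    est <- estimateJunction(site, clips3, params0)
    expect_equal(est$junction, 10050L)
    expect_equal(est$junction_unc, 0L)
    expect_equal(est$junction_evidence, "softclip")
    ## no clips: innermost boundary, uncertainty fragmentMean - 2*readLength
    est2 <- estimateJunction(site, clips3[0, ], params0)
    expect_equal(est2$junction, 10020L)
    expect_equal(est2$junction_unc, 300L)
    expect_equal(est2$junction_evidence, "discordant_only")
    ## conflicting clips (> 2 bp spread) fall back with a warning
    clipsX <- data.frame(contig = "chr1",
                         coord = c(10050L, 10060L, 10070L),
                         type = "end", stringsAsFactors = FALSE)
    expect_warning(est3 <- estimateJunction(site, clipsX, params0),
                   "conflicting")
    expect_equal(est3$junction_evidence, "discordant_only")
})

test_that("site pairing and gap classification follow the sign rules", {
    mkSite <- function(id, side, jct, unc = 0L) {
        s <- plasmidSV:::emptySites()[0, ]
        s[1, ] <- list(id, "chr1", jct - 300L, jct + 300L, side,
                       "plasmid", NA, NA, NA, 5L, jct, jct, unc,
                       if (unc == 0L) "softclip" else "discordant_only")
        s
    }
    sites <- rbind(mkSite("L1", "left", 10000L),
                   mkSite("R1", "right", 35000L))
    pr <- pairPlasmidSites(sites, params0)
    expect_equal(nrow(pr$events), 1L)
    ev <- classifyGap(pr$events, params0)
    expect_equal(ev$gap_class, "deletion")
    expect_equal(ev$gap_size, 25000L)
    ## a lone left site stays leftover
    pr1 <- pairPlasmidSites(mkSite("L9", "left", 5000L), params0)
    expect_equal(nrow(pr1$events), 0L)
    expect_equal(pr1$leftover$site_id, "L9")
    ## perfect / small deletion / duplication sign conventions
    g <- function(l, r) classifyGap(pairPlasmidSites(
        rbind(mkSite("L", "left", l), mkSite("R", "right", r)),
        params0)$events, params0)
    expect_equal(g(10000L, 10000L)$gap_class, "perfect")
    expect_equal(g(10000L, 10000L)$gap_size, 0L)
    expect_equal(g(10000L, 10010L)$gap_class, "deletion")
    expect_equal(g(10000L, 10010L)$gap_size, 10L)
    expect_equal(g(10000L, 9993L)$gap_class, "duplication")
    expect_equal(g(10000L, 9993L)$gap_size, 7L)
    ## beyond maxPairDistance no pairing happens
    far <- rbind(mkSite("L2", "left", 10000L),
                 mkSite("R2", "right", 260000L))
    expect_equal(nrow(pairPlasmidSites(far, params0)$events), 0L)
    ## uncertain junctions with |g| inside the envelope are unknown
    unc <- rbind(mkSite("L3", "left", 10000L, unc = 300L),
                 mkSite("R3", "right", 10100L))
    evu <- classifyGap(pairPlasmidSites(unc, params0)$events, params0)
    expect_equal(evu$gap_class, "unknown")
})

test_that("tandem insertions pair without crossing", {
    ref <- sharedRef()
    cfg <- sharedCfg()
    mut <- simulateMutant(ref, mutantId = "t", seed = 21,
                          classes = c("two_sided_deletion",
                                      "two_sided_deletion"),
                          gapSizes = c(40, 60))
    tr <- truthEvents(mut)
    prs <- emitAlignments(mut, ref, cfg, seed = 22)
    cs <- callMutant(prs, ref, cfg, mutantId = "t",
                     callDeletions = FALSE)
    ev <- insertionEvents(cs)
    expect_equal(nrow(ev), 2L)
    expect_true(all(ev$classification == "two_sided"))
    ev <- ev[order(ev$left_jct), ]
    tr <- tr[order(tr$left_bp), ]
    expect_equal(ev$left_jct, tr$left_bp)
    expect_equal(ev$right_jct, tr$right_bp)
    expect_equal(ev$gap_size, tr$gap_size)
    expect_equal(mutantClass(cs), "simple_only")
    expect_equal(unname(cs@counts["lesions"]), 2L)
})

test_that("repeat-flanked insertions are one-sided with the right reason", {
    ref <- sharedRef()
    cfg <- sharedCfg()
    mut <- simulateMutant(ref, mutantId = "o", seed = 23,
                          classes = "one_sided_repeat")
    prs <- emitAlignments(mut, ref, cfg, seed = 24)
    cs <- callMutant(prs, ref, cfg, mutantId = "o",
                     callDeletions = FALSE)
    ev <- insertionEvents(cs)
    expect_equal(nrow(ev), 1L)
    expect_equal(ev$classification, "one_sided")
    expect_equal(ev$one_sided_reason, "repeat_flank")
    expect_equal(mutantClass(cs), "simple_only")
})

test_that("rearrangements resolve into complex lesions and translocations", {
    ref <- sharedRef()
    cfg <- sharedCfg()
    run1 <- function(cls, seed) {
        mut <- simulateMutant(ref, mutantId = cls, seed = seed,
                              classes = cls)
        prs <- emitAlignments(mut, ref, cfg, seed = seed + 1L)
        callMutant(prs, ref, cfg, mutantId = cls, callDeletions = FALSE)
    }
    csI <- run1("complex_intra", 31)
    expect_equal(mutantClass(csI), "complex_containing")
    expect_equal(lesions(csI)$lesion_class, "complex")
    expect_true(all(insertionEvents(csI)$one_sided_reason ==
                        "paired_elsewhere"))
    csT <- run1("translocation", 33)
    expect_equal(mutantClass(csT), "complex_containing")
    expect_equal(lesions(csT)$lesion_class, "translocation")
    expect_equal(sum(insertionEvents(csT)$classification == "complex"),
                 2L)
    expect_equal(length(unique(insertionEvents(csT)$chrom)), 2L)
    ## classification closure
    ev <- insertionEvents(csT)
    expect_equal(sum(ev$classification %in%
                         c("two_sided", "one_sided", "complex")),
                 nrow(ev))
})

test_that("cofragment detection needs links, depth and a short interval", {
    ref <- sharedRef()
    cfg <- sharedCfg()
    mut <- simulateMutant(ref, mutantId = "cf", seed = 41,
                          classes = "cofragment_insertion")
    tr <- truthEvents(mut)
    prs <- emitAlignments(mut, ref, cfg, seed = 42)
    cs <- callMutant(prs, ref, cfg, mutantId = "cf",
                     callDeletions = FALSE)
    ev <- insertionEvents(cs)
    hit <- ev[!is.na(ev$cof_chrom), , drop = FALSE]
    expect_equal(nrow(hit), 1L)
    expect_equal(hit$cof_chrom, tr$partner_chrom)
    ## recovered interval overlaps the truth source interval
    expect_lt(max(hit$cof_start, tr$partner_start),
              min(hit$cof_end, tr$partner_end))
    ## depth ratio below threshold -> no call (direct threshold check)
    psites <- discordantSites(cs)
    flat <- list(chr2 = S4Vectors::Rle(7L, 500000L),
                 chr1 = S4Vectors::Rle(7L, 500000L),
                 chr3 = S4Vectors::Rle(7L, 500000L))
    disc <- collectDiscordantPairs(prs, "plasmid", params0)
    clu <- clusterDiscordant(disc, params0)
    cf2 <- detectCofragment(estimateJunction(clu$plasmid_sites,
                                             clipTable(prs, params0),
                                             params0),
                            estimateJunction(clu$gg_sites,
                                             clipTable(prs, params0),
                                             params0),
                            plasmidSV:::emptyEvents(), flat, params0)
    expect_null(cf2$cofragments)
    ## no links, uniform depth -> none
    cf3 <- detectCofragment(clu$plasmid_sites, clu$gg_sites[0, ],
                            plasmidSV:::emptyEvents(), flat, params0)
    expect_null(cf3$cofragments)
})

test_that("mutant classification covers the three outcomes", {
    ref <- tinyRef()
    cfg <- tinyCfg()
    mut <- simulateMutant(ref, mutantId = "z", seed = 51,
                          classes = character(0))
    prs <- emitAlignments(mut, ref, cfg, seed = 52)
    cs <- callMutant(prs, ref, cfg, mutantId = "z",
                     callDeletions = FALSE)
    expect_equal(mutantClass(cs), "no_insertion_found")
    expect_equal(nrow(insertionEvents(cs)), 0L)
    ## one two-sided event: 2 sites, 1 insertion, 1 lesion, simple_only
    mut1 <- simulateMutant(ref, mutantId = "z1", seed = 53,
                           classes = "two_sided_deletion",
                           gapSizes = 1000)
    cs1 <- callMutant(emitAlignments(mut1, ref, cfg, seed = 54), ref,
                      cfg, mutantId = "z1", callDeletions = FALSE)
    expect_equal(mutantClass(cs1), "simple_only")
    expect_equal(unname(cs1@counts),
                 c(2L, 1L, 1L))
})

test_that("two-sided recall is non-decreasing in sequencing coverage", {
    covs <- c(3, 7.44, 15)
    rec <- vapply(covs, function(cv) {
        rt <- recoveryTrial(cv, 45L, 30000L)
        rt$nFound / rt$nTruth
    }, numeric(1))
    expect_true(all(diff(rec) >= 0),
                info = paste("recall:", paste(round(rec, 3),
                                              collapse = " ")))
    expect_gte(rec[2], 0.9)
})

test_that("redundant mutants are grouped and fully removed", {
    ## printed-count fixture: 33 duplicated, 3 triplicated, 1 quadruplicated
    sigs <- list()
    mk <- function(id, coord) siteSig(id, "chr1", coord)
    n <- 0L
    for (g in 1:33) for (m in 1:2) {
        n <- n + 1L
        sigs[[n]] <- mk(sprintf("dup%02d_%d", g, m),
                        g * 10000L + (m - 1L))   # within tolerance 10
    }
    for (g in 1:3) for (m in 1:3) {
        n <- n + 1L
        sigs[[n]] <- mk(sprintf("tri%d_%d", g, m), 400000L + g * 5000L)
    }
    for (m in 1:4) {
        n <- n + 1L
        sigs[[n]] <- mk(paste0("quad_", m), 450000L)
    }
    for (u in 1:20) {
        n <- n + 1L
        sigs[[n]] <- mk(paste0("uniq", u), 460000L + u * 3000L)
    }
    red <- findRedundantMutants(sigs, toleranceBp = 10L)
    expect_equal(length(red$removal), 33L * 2L + 3L * 3L + 1L * 4L)  # 79
    sz <- vapply(red$groups, length, integer(1))
    expect_equal(as.integer(table(sz)[c("2", "3", "4")]),
                 c(33L, 3L, 1L))
    ## all unique -> nothing removed
    redU <- findRedundantMutants(sigs[80:99], toleranceBp = 10L)
    expect_length(redU$removal, 0L)
    ## sharing one site of two is not enough (full-set match required)
    a <- siteSig("a", c("chr1", "chr1"), c(1000L, 50000L))
    b <- siteSig("b", c("chr1", "chr1"), c(1000L, 90000L))
    expect_length(findRedundantMutants(list(a, b))$removal, 0L)
})
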