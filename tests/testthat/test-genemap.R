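test_that("GFF3 gene models round-trip through write and load", {
    gm <- tinyModels()
    expect_gt(length(gm$genes), 3L)
    path <- tempfile(fileext = ".gff3")
    writeGff3(gm, path)
    gm2 <- loadGeneModels(path)
    expect_identical(S4Vectors::mcols(gm$genes)$gene_id,
                     S4Vectors::mcols(gm2$genes)$gene_id)
    expect_identical(GenomicRanges::start(gm$genes),
                     GenomicRanges::start(gm2$genes))
    gid <- S4Vectors::mcols(gm$genes)$gene_id[2]
    expect_identical(GenomicRanges::start(gm$cds[[gid]]),
                     GenomicRanges::start(gm2$cds[[gid]]))
    expect_identical(GenomicRanges::start(gm$utr5[[gid]]),
                     GenomicRanges::start(gm2$utr5[[gid]]))
})

test_that("orphan features are skipped, not fatal", {
    gm <- tinyModels()
    path <- tempfile(fileext = ".gff3")
    writeGff3(gm, path)
    lines <- readLines(path)
    lines <- c(lines,
               "chr1\tx\texon\t10\t50\t.\t+\t.\tID=orphan1;Parent=ghost.t1")
    path2 <- tempfile(fileext = ".gff3")
    writeLines(lines, path2)
    expect_message(gm2 <- loadGeneModels(path2), "orphan")
    expect_identical(S4Vectors::mcols(gm2$genes)$gene_id,
                     S4Vectors::mcols(gm$genes)$gene_id)
})

test_that("lesion footprints follow the event taxonomy", {
    evs <- rbind(
        plasmidSV:::eventRow(event_id = "e1", mutant_id = "m1",
                             classification = "two_sided", chrom = "chr1",
                             left_jct = 10000L, right_jct = 35000L,
                             gap_class = "deletion", gap_size = 25000L),
        plasmidSV:::eventRow(event_id = "e2", mutant_id = "m1",
                             classification = "two_sided", chrom = "chr1",
                             left_jct = 70000L, right_jct = 70000L,
                             gap_class = "perfect", gap_size = 0L))
    fp <- lesionFootprint(evs)
    d <- fp[fp$source_id == "e1", ]
    expect_equal(nrow(d), 1L)
    expect_equal(c(d$start, d$end), c(10000L, 35000L))
    expect_equal(d$kind, "interval")
    p <- fp[fp$source_id == "e2", ]
    expect_equal(nrow(p), 1L)
    expect_equal(c(p$start, p$end), c(70000L, 70000L))
    expect_equal(p$kind, "point")
    ## a complex lesion with 4 junctions on 4 chromosomes -> 4 points
    cpx <- do.call(rbind, lapply(1:4, function(k)
        plasmidSV:::eventRow(event_id = paste0("c", k), mutant_id = "m2",
                             classification = "complex",
                             chrom = paste0("chr", k),
                             left_jct = 1000L * k,
                             gap_class = "unknown")))
    fpc <- lesionFootprint(cpx)
    expect_equal(nrow(fpc), 4L)
    expect_true(all(fpc$kind == "point"))
    expect_equal(length(unique(fpc$chrom)), 4L)
})

test_that("context assignment picks the most severe overlapped feature", {
    gm <- tinyModels()
    g <- gm$genes[3]
    gid <- S4Vectors::mcols(g)$gene_id
    gs <- GenomicRanges::start(g); ge <- GenomicRanges::end(g)
    cds1 <- gm$cds[[gid]][1]
    u5 <- gm$utr5[[gid]][1]
    u3 <- gm$utr3[[gid]][1]
    mkfp <- function(s, e, kind)
        data.frame(chrom = "chr1", start = s, end = e, kind = kind,
                   source_id = "x", mutant_id = "m",
                   stringsAsFactors = FALSE)
    ctx <- function(fp) affectedGenes(fp, gm)$context[
        affectedGenes(fp, gm)$gene_id == gid]
    ## whole-gene deletion
    expect_equal(ctx(mkfp(gs - 100L, ge + 100L, "interval")),
                 "whole_gene_deleted")
    ## point inside a CDS exon (0-based point = 1-based start - 1)
    expect_equal(ctx(mkfp(GenomicRanges::start(cds1),
                          GenomicRanges::start(cds1), "point")), "exon")
    ## UTR points
    expect_equal(ctx(mkfp(GenomicRanges::start(u5),
                          GenomicRanges::start(u5), "point")),
                 "five_prime_utr")
    expect_equal(ctx(mkfp(GenomicRanges::start(u3),
                          GenomicRanges::start(u3), "point")),
                 "three_prime_utr")
    ## intron: first base after the 5'-most exon (plus strand layout)
    ex <- sort(gm$exons[[gid]])
    intronPos <- GenomicRanges::end(ex)[1] + 10L
    expect_equal(ctx(mkfp(intronPos, intronPos, "point")), "intron")
    ## an interval straddling intron and CDS ranks as exon
    expect_equal(ctx(mkfp(intronPos - 1L,
                          GenomicRanges::start(cds1) + 5L, "interval")),
                 "exon")
    ## strictly intergenic point affects nothing with the window off
    mid <- ge + 50L
    expect_equal(nrow(affectedGenes(mkfp(mid, mid, "point"), gm)), 0L)
})

test_that("interval engine matches a per-base brute-force oracle", {
    gm <- tinyModels()
    genes <- gm$genes
    set.seed(17)
    for (rep in 1:30) {
        s <- sample.int(78000L, 1L)
        e <- s + sample.int(3000L, 1L)
        kind <- sample(c("point", "interval"), 1L)
        if (kind == "point") e <- s
        fp <- data.frame(chrom = "chr1", start = s, end = e, kind = kind,
                         source_id = "x", mutant_id = "m",
                         stringsAsFactors = FALSE)
        got <- sort(affectedGenes(fp, gm)$gene_id)
        ## oracle: 0-based half-open footprint vs 1-based gene [a, b]:
        ## point p hits iff a <= p + 1 <= b; interval hits iff it
        ## contains any base of the gene
        a <- GenomicRanges::start(genes); b <- GenomicRanges::end(genes)
        hit <- if (kind == "point") a <= s + 1L & s + 1L <= b
               else (s + 1L) <= b & e >= a
        want <- sort(S4Vectors::mcols(genes)$gene_id[hit])
        expect_identical(got, want, label = paste("replicate", rep))
    }
})

test_that("allele tables count distinct mutants and bin correctly", {
    rec <- rbind(recRow("m1", "gA"), recRow("m2", "gA"),
                 recRow("m3", "gA"), recRow("m3", "gA"),  # same mutant twice
                 recRow("m1", "gB"), recRow("m4", "gC"))
    at <- buildAlleleTable(rec)
    expect_equal(at$table$n_alleles[at$table$gene_id == "gA"], 3L)
    expect_equal(unname(at$histogram),
                 c(2L, 0L, 1L, 0L))
    ## set-union arithmetic: |A| = 1404, |B| = 77, |A intersect B| = 11
    insGenes <- sprintf("ins%04d", 1:1404)
    delGenes <- c(insGenes[1:11], sprintf("del%03d", 1:66))
    rec2 <- rbind(
        do.call(rbind, lapply(insGenes, function(g)
            recRow("mi", g, source = "ins"))),
        do.call(rbind, lapply(delGenes, function(g)
            recRow("md", g, source = "del"))))
    at2 <- buildAlleleTable(rec2)
    expect_equal(nrow(at2$table), 1404L + 77L - 11L)  # 1470
})

test_that("a gene shared by a deletion cluster plus one extra mutant tops \
the allele counts", {
    ## seven mutants share an overlapping deletion region of 33 genes;
    ## an eighth hits only the common gene
    region <- sprintf("rg%02d", 1:33)
    common <- "rg17"
    rec <- do.call(rbind, c(
        lapply(1:7, function(m) do.call(rbind, lapply(
            region, function(g) recRow(paste0("mm", m), g,
                                       context = "whole_gene_deleted",
                                       severity = 5L)))),
        list(recRow("mm8", common))))
    at <- buildAlleleTable(rec)
    expect_equal(at$table$n_alleles[at$table$gene_id == common], 8L)
    others <- at$table$n_alleles[at$table$gene_id != common]
    expect_true(all(others < 8L))
    ## and it wins the disruption-frequency ranking
    fr <- disruptionFrequency(rec, paste0("mm", 1:8))
    expect_equal(fr$gene_id[1], common)
    expect_equal(fr$frequency[1], 1)
    expect_false(any(fr$co_maximal[-1]))
})

test_that("disruption frequencies rank with deterministic tie handling", {
    rec <- rbind(
        do.call(rbind, lapply(1:5, function(m) recRow(paste0("m", m),
                                                      "gAll"))),
        do.call(rbind, lapply(1:3, function(m) recRow(paste0("m", m),
                                                      "gSome"))))
    fr <- disruptionFrequency(rec, paste0("m", 1:5))
    expect_equal(fr$frequency[fr$gene_id == "gAll"], 1)
    expect_equal(fr$rank[fr$gene_id == "gAll"], 1L)
    expect_equal(fr$frequency[fr$gene_id == "gSome"], 0.6)
    ## two genes at 1.0: both flagged co-maximal, order by gene_id
    rec2 <- rbind(
        do.call(rbind, lapply(1:2, function(m) recRow(paste0("m", m),
                                                      "gB"))),
        do.call(rbind, lapply(1:2, function(m) recRow(paste0("m", m),
                                                      "gA"))))
    fr2 <- disruptionFrequency(rec2, c("m1", "m2"))
    expect_equal(sum(fr2$co_maximal), 2L)
    expect_equal(fr2$gene_id, c("gA", "gB"))
})
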