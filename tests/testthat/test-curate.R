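test_that("gene flags derive from lists and keyword matches", {
    ann <- data.frame(gene_id = c("g1", "g2", "g3"),
                      description = c("Rieske Fe-S cluster subunit",
                                      "unknown protein",
                                      "chlorophyll a/b-binding protein"),
                      stringsAsFactors = FALSE)
    fl <- flagGenes(c("g1", "g2", "g3", "g4"), annotation = ann,
                    greencut = "g2",
                    crosslib = list(Cr = "g1", Zm = c("g1", "g3")))
    expect_true(fl$keyword_hit[fl$gene_id == "g1"])   # "Fe-S"
    expect_true(fl$keyword_hit[fl$gene_id == "g3"])
    expect_false(fl$keyword_hit[fl$gene_id == "g2"])
    expect_true(fl$greencut2[fl$gene_id == "g2"])
    expect_equal(fl$crosslib[fl$gene_id == "g1"], "Cr,Zm")
    ## empty lists -> all flags false
    fl0 <- flagGenes(c("a", "b"))
    expect_false(any(fl0$greencut2 | fl0$keyword_hit |
                         fl0$coexpression_hit))
    expect_error(flagGenes("a", greencut = data.frame(x = 1)), "gene_id")
})

test_that("curation rules recover the planted causative genes exactly", {
    fx <- curationFixture()
    dec <- selectCandidates(fx$mutants, fx$records, fx$flags)
    ## R1: the single-gene simple mutant
    expect_equal(dec$basis[dec$mutant_id == "solo1"],
                 "single_gene_simple")
    expect_equal(dec$candidates[dec$mutant_id == "solo1"], "gSolo")
    ## R2: frequency winner for every member of the 5-mutant group
    for (m in paste0("grpA", 1:5)) {
        expect_equal(dec$basis[dec$mutant_id == m], "frequency_winner")
        expect_equal(dec$candidates[dec$mutant_id == m], "la03")
    }
    ## the complex mutant joins the 7+1 group and wins via frequency
    for (m in c(paste0("grpB", 1:7), "grpB8")) {
        expect_equal(dec$basis[dec$mutant_id == m], "frequency_winner")
        expect_equal(dec$candidates[dec$mutant_id == m], "cb17")
    }
    ## planted set recovered exactly, nothing else
    expect_setequal(
        unique(unlist(strsplit(dec$candidates[dec$candidates != ""],
                               ","))),
        c("gSolo", "la03", "cb17"))
    ## demotion soundness: demoted genes never appear as candidates
    demoted <- unlist(strsplit(dec$demoted[1], ","))
    expect_length(intersect(
        demoted,
        unlist(strsplit(dec$candidates[dec$candidates != ""], ","))), 0L)
    expect_true(all(c("la01", "cb01") %in% demoted))
    ## audit trail records every decision
    expect_gte(length(attr(dec, "audit")), nrow(dec))
})

test_that("decisions are invariant to input row order", {
    fx <- curationFixture()
    dec1 <- selectCandidates(fx$mutants, fx$records, fx$flags)
    perm <- withr::with_seed(5, sample(nrow(fx$records)))
    dec2 <- selectCandidates(fx$mutants[rev(seq_len(nrow(fx$mutants))), ],
                             fx$records[perm, ], fx$flags)
    expect_equal(dec1, dec2, ignore_attr = TRUE)
})

test_that("flag scoring picks a unique winner or reports ties", {
    rec <- do.call(rbind, lapply(sprintf("fg%d", 1:5), function(g)
        recRow("fm1", g)))
    mut <- data.frame(mutant_id = "fm1", mutant_class = "simple_only",
                      stringsAsFactors = FALSE)
    flags <- flagGenes(sprintf("fg%d", 1:5), greencut = "fg3")
    dec <- selectCandidates(mut, rec, flags)
    expect_equal(dec$basis, "flag_winner")
    expect_equal(dec$candidates, "fg3")
    ## tie at the maximum -> multiple candidates, both reported
    flags2 <- flagGenes(sprintf("fg%d", 1:5),
                        greencut = c("fg2", "fg4"))
    dec2 <- selectCandidates(mut, rec, flags2)
    expect_equal(dec2$basis, "multiple_candidates")
    expect_equal(dec2$candidates, "fg2,fg4")
    ## no evidence at all -> none
    dec3 <- selectCandidates(mut, rec, flagGenes(sprintf("fg%d", 1:5)))
    expect_equal(dec3$basis, "none")
    ## a complex mutant outside any group yields none
    mutC <- data.frame(mutant_id = "fm1",
                       mutant_class = "complex_containing",
                       stringsAsFactors = FALSE)
    decC <- selectCandidates(mutC, rec, flags)
    expect_equal(decC$basis, "none")
})

test_that("candidate report carries flag letters and tie markers", {
    rec <- rbind(recRow("cm1", "cg1"),
                 do.call(rbind, lapply(c("cg2", "cg3"), function(g)
                     recRow("cm2", g))))
    mut <- data.frame(mutant_id = c("cm1", "cm2"),
                      mutant_class = "simple_only",
                      stringsAsFactors = FALSE)
    flags <- flagGenes(c("cg1", "cg2", "cg3"),
                       annotation = data.frame(
                           gene_id = "cg1",
                           description = "redox enzyme",
                           stringsAsFactors = FALSE),
                       greencut = c("cg1", "cg2", "cg3"))
    dec <- selectCandidates(mut, rec, flags)
    rep <- candidateReport(dec, flags)
    expect_equal(rep$greencut2[rep$gene_id == "cg1"], "G")
    expect_equal(rep$keyword[rep$gene_id == "cg1"], "K")
    ## cm2 ties cg2/cg3 at the max -> both flagged "M"
    expect_equal(rep$marker[rep$gene_id == "cg2"], "M")
    expect_equal(rep$marker[rep$gene_id == "cg3"], "M")
    ## no decisions -> header-only table
    expect_equal(nrow(candidateReport(dec[0, ], flags)), 0L)
})
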