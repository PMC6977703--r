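test_that("expression generator plants exact shapes at zero noise and is deterministic", {
    d <- syntheticDesign(replicates = 2, nBackground = 0,
                         planted = list(list(shape = c(0, -1, -1, -2),
                                             nGenes = 1, base = 10,
                                             noiseSd = 0)),
                         seed = 1)
    e <- syntheticExpression(d)
    expect_equal(unname(conditionMeans(e$expression)[1, ]),
                 c(10, 5, 5, 2.5))

    d2 <- syntheticDesign(replicates = 3, nBackground = 30,
                          planted = list(list(shape = c(0, 1, 1, 0),
                                              nGenes = 5, base = 4,
                                              noiseSd = 0.3)),
                          seed = 7)
    e1 <- syntheticExpression(d2)
    e2 <- syntheticExpression(d2)
    expect_identical(exprValues(e1$expression), exprValues(e2$expression))

    expect_error(
        syntheticDesign(planted = list(list(shape = c(0, -1), nGenes = 1,
                                            base = 1, noiseSd = 0))),
        "incompatible")
})

test_that("noisy planted genes are recovered by profile assignment", {
    d <- syntheticDesign(replicates = 3, nBackground = 1000,
                         planted = list(list(shape = c(0, -1, -1, -2),
                                             nGenes = 50, base = 10,
                                             noiseSd = 0.2)),
                         seed = 1)
    e <- syntheticExpression(d)
    ps <- enumerateProfiles(4, 1, TRUE)
    a <- assignProfiles(toLog2Series(e$expression), ps)
    target <- matchProfile(ps, c(0, -1, -1, -2))
    hit <- a$profile_id[a$gene_id %in% e$truth$gene_id] == target
    expect_gte(sum(hit, na.rm = TRUE), 45)
})

test_that("sequence generator plants clean sites and clean negatives", {
    sq <- syntheticSequences(6, 6, 4, plantedTriplets = 3, seqLength = 150,
                             seed = 2)
    # planted members carry at least one site of their shared miRNA
    for (i in 1:3) {
        tr <- sq$truth[i, ]
        mir <- as.character(sq$mirnas[[tr$mirna_id]])
        expect_gte(length(seedMatch(mir, sq$lncrnas[[tr$lncrna_id]])), 1)
        expect_gte(length(seedMatch(mir, sq$mrnas[[tr$mrna_id]])), 1)
    }
    # background sequences carry no site of any miRNA
    for (mid in names(sq$mirnas)) {
        mir <- as.character(sq$mirnas[[mid]])
        for (bg in names(sq$lncrnas)[4:6])
            expect_length(seedMatch(mir, sq$lncrnas[[bg]]), 0)
        for (bg in names(sq$mrnas)[4:6])
            expect_length(seedMatch(mir, sq$mrnas[[bg]]), 0)
    }
    # planted members carry no site of the other miRNAs
    for (i in 1:3) {
        tr <- sq$truth[i, ]
        for (mid in setdiff(names(sq$mirnas), tr$mirna_id))
            expect_length(seedMatch(as.character(sq$mirnas[[mid]]),
                                    sq$lncrnas[[tr$lncrna_id]]), 0)
    }

    # byte determinism through FASTA
    f1 <- tempfile(); f2 <- tempfile()
    Biostrings::writeXStringSet(sq$lncrnas, f1)
    sq2 <- syntheticSequences(6, 6, 4, plantedTriplets = 3,
                              seqLength = 150, seed = 2)
    Biostrings::writeXStringSet(sq2$lncrnas, f2)
    expect_identical(readLines(f1), readLines(f2))

    expect_error(syntheticSequences(2, 2, 2, 1, seqLength = 20), ">= 30")
    expect_error(syntheticSequences(2, 2, 3, plantedTriplets = 3),
                 "smallest set size")
})

test_that("annotation generator places pairs exactly at the labeled distances", {
    an <- syntheticAnnotation(4, 3, seed = 5)
    expect_true(all(an$truth$distance_bp[an$truth$cis] <= 10000))
    expect_true(all(an$truth$distance_bp[!an$truth$cis] > 10000))

    # cis target prediction on the emitted annotation recovers exactly the
    # planted cis set, with the recorded distances
    hits <- cisTargets(an$lncrnas, an$genes)
    truthCis <- an$truth[an$truth$cis, ]
    expect_setequal(paste(hits$lncrna_id, hits$gene_id),
                    paste(truthCis$lncrna_id, truthCis$gene_id))
    m <- merge(hits, truthCis, by = c("lncrna_id", "gene_id"))
    expect_equal(m$distance_bp.x, m$distance_bp.y)

    # GTF round trip preserves the geometry
    gtf <- tempfile(fileext = ".gtf")
    writeGtf(an$lncrnas, gtf)
    back <- readTranscripts(gtf)
    expect_setequal(transcriptIds(back), transcriptIds(an$lncrnas))
    hits2 <- cisTargets(back, an$genes)
    expect_setequal(paste(hits2$lncrna_id, hits2$gene_id),
                    paste(truthCis$lncrna_id, truthCis$gene_id))

    expect_error(syntheticAnnotation(5, 5, chromLength = 1000, seed = 1),
                 "placement failure")
})

test_that("transcript generator's candidacy labels agree with the filter chain", {
    syn <- syntheticTranscripts(4, 12, seed = 11)
    v <- classifyLncrna(syn$transcripts, syn$evidence)
    expect_identical(v$is_candidate, syn$truth$is_candidate)
    # each reject violates exactly the labeled rule
    ruleCol <- c(length = "rule_length", exons = "rule_exons",
                 orf = "rule_orf", cpc = "rule_cpc", cnci = "rule_cnci",
                 pfam = "rule_pfam")
    for (i in which(!syn$truth$is_candidate)) {
        col <- ruleCol[[syn$truth$violated_rule[i]]]
        expect_false(v[[col]][i])
        others <- setdiff(unname(ruleCol), col)
        expect_true(all(vapply(others, function(cn) v[[cn]][i],
                               logical(1))))
    }
})
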