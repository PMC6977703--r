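test_that("co-expression edges match brute-force all-pairs computation", {
    conds <- c("Sham", "PD", "NLID", "LID")
    m <- rbind(a = 1:8, b = (1:8) * 2 + 5, c = rev(1:8), d = rep(3, 8))
    m <- m + 0  # doubles
    colnames(m) <- paste0(rep(conds, each = 2), "_", 1:2)
    ce <- ConditionExperiment(m, rep(conds, each = 2), conds)

    expect_warning(net <- coexpressionNetwork(ce, rThreshold = 0.99),
                   "zero-variance")
    # identical shape -> r = 1 edge; anti-correlated pair is not an edge
    expect_true(any(net$gene_a == "a" & net$gene_b == "b"))
    expect_false(any((net$gene_a == "a" & net$gene_b == "c") |
                     (net$gene_a == "c" & net$gene_b == "a")))

    for (seed in 1:5) {
        ce2 <- randomCE(20, seed = seed * 100)
        got <- coexpressionNetwork(ce2, rThreshold = 0.3)
        want <- bruteEdges(exprValues(ce2), 0.3)
        expect_equal(got, want, tolerance = 1e-12)
    }

    tiny <- ConditionExperiment(
        matrix(1:4, 2, 2, dimnames = list(c("x", "y"), c("s1", "s2"))),
        c("A", "B"), c("A", "B"))
    expect_error(coexpressionNetwork(tiny), "at least 3 samples")
    expect_error(coexpressionNetwork(randomCE(5, 1), geneSubset = "nope"),
                 "not in the matrix")
})

test_that("nearest-rank percentile threshold retains the right tail", {
    set.seed(1)
    x <- sample(seq(0.01, 1, by = 0.01))  # 100 distinct values
    thr <- percentilePairThreshold(x, 99)
    expect_equal(thr, sort(x)[99])
    expect_equal(sum(x >= thr), 2)

    expect_equal(percentilePairThreshold(rep(0.5, 10)), 0.5)
    expect_equal(percentilePairThreshold(0.7), 0.7)
    expect_error(percentilePairThreshold(x, 0), "\\(0, 100\\]")
    expect_error(percentilePairThreshold(numeric(0)), "empty")

    # brute nearest-rank on random pools
    for (seed in 1:10) {
        set.seed(seed)
        pool <- rnorm(sample(5:200, 1))
        p <- sample(c(50, 90, 95, 99, 100), 1)
        expect_equal(percentilePairThreshold(pool, p),
                     sort(pool)[ceiling(p / 100 * length(pool))])
    }
})

test_that("seed matching finds exact reverse-complement 6mer sites", {
    # seed of UAGCUUAU... is AGCUUA; its reverse complement is TAAGCT
    expect_equal(seedMatch("UAGCUUAUCAGACUGAUGUUGA", "GGGTAAGCTGGG"), 3L)
    expect_identical(seedMatch("UAGCUUAUCAGACUGAUGUUGA", "GGGGG"),
                     integer(0))
    expect_identical(seedMatch("UAGCUUAUCAGACUGAUGUUGA", ""), integer(0))
    expect_error(seedMatch("UANCUUAUCAG", "ACGT"), "ambiguous")
    expect_error(seedMatch("UAGCU", "ACGT"), "shorter than the seed")

    # multiple sites, sorted offsets, against the character-level oracle
    for (seed in 1:10) {
        set.seed(seed)
        mir <- chartr("T", "U", randSeqChar(22))
        target <- randSeqChar(300)
        expect_identical(seedMatch(mir, target),
                         as.integer(bruteSeedSites(mir, target)))
    }

    # planted sites from the generator are found at the recorded offsets
    sq <- syntheticSequences(4, 4, 3, plantedTriplets = 2, seqLength = 120,
                             seed = 6)
    for (i in seq_len(nrow(sq$truth))) {
        tr <- sq$truth[i, ]
        mir <- as.character(sq$mirnas[[tr$mirna_id]])
        expect_true(tr$lncrna_offset %in%
                    seedMatch(mir, sq$lncrnas[[tr$lncrna_id]]))
        expect_true(tr$mrna_offset %in%
                    seedMatch(mir, sq$mrnas[[tr$mrna_id]]))
    }
})

test_that("ceRNA triplet inference matches a brute-force three-loop scan", {
    for (seed in 1:5) {
        set.seed(seed)
        nl <- 6; nm <- 6
        conds <- c("Sham", "PD", "NLID", "LID")
        v <- matrix(2^runif((nl + nm) * 8, 0, 6), nl + nm, 8)
        ids <- c(sprintf("L%02d", 1:nl), sprintf("M%02d", 1:nm))
        rownames(v) <- ids
        colnames(v) <- paste0(rep(conds, each = 2), "_", 1:2)
        ce <- ConditionExperiment(v, rep(conds, each = 2), conds)
        mirs <- setNames(vapply(1:3, function(i)
            chartr("T", "U", randSeqChar(22)), character(1)),
            c("mirA", "mirB", "mirC"))
        seqs <- setNames(vapply(seq_along(ids), function(i)
            randSeqChar(150), character(1)), ids)
        got <- buildCernaNetwork(ce, ids[1:nl], ids[nl + 1:nm],
                                 mirs, seqs, percentile = 80)
        want <- bruteTriplets(v, ids[1:nl], ids[nl + 1:nm], as.list(mirs),
                              as.list(seqs), percentile = 80)
        expect_equal(got[c("lncrna_id", "mirna_id", "mrna_id")],
                     want[c("lncrna_id", "mirna_id", "mrna_id")])
        # every emitted triplet satisfies both defining predicates
        if (nrow(got)) {
            thr <- percentilePairThreshold(
                as.vector(cor(t(v[ids[1:nl], ]), t(v[ids[nl + 1:nm], ]))),
                80)
            expect_true(all(got$r >= thr))
            expect_true(all(got$n_sites_lncrna >= 1 &
                            got$n_sites_mrna >= 1))
        }
    }
})

test_that("planted ceRNA instances are recovered exactly, and the filter is monotone", {
    sq <- syntheticSequences(8, 8, 4, plantedTriplets = 3, seqLength = 200,
                             seed = 9)
    # expression: planted pairs exactly proportional, everything else noise
    set.seed(10)
    conds <- c("Sham", "PD", "NLID", "LID")
    ids <- c(names(sq$lncrnas), names(sq$mrnas))
    v <- matrix(2^runif(16 * 8, 0, 6), 16, 8,
                dimnames = list(ids, paste0(rep(conds, each = 2), "_", 1:2)))
    for (i in 1:3) v[8 + i, ] <- 0.5 * v[i, ]
    ce <- ConditionExperiment(v, rep(conds, each = 2), conds)
    seqs <- c(sq$lncrnas, sq$mrnas)

    got <- buildCernaNetwork(ce, names(sq$lncrnas), names(sq$mrnas),
                             sq$mirnas, seqs, percentile = 95)
    key <- function(d) paste(d$lncrna_id, d$mirna_id, d$mrna_id)
    expect_setequal(key(got), key(sq$truth))

    # input-order invariance
    got2 <- buildCernaNetwork(ce, rev(names(sq$lncrnas)),
                              rev(names(sq$mrnas)),
                              rev(sq$mirnas), rev(seqs), percentile = 95)
    expect_identical(got, got2)

    # raising the percentile never adds triplets
    lo <- buildCernaNetwork(ce, names(sq$lncrnas), names(sq$mrnas),
                            sq$mirnas, seqs, percentile = 80)
    expect_true(all(key(got) %in% key(lo)))

    expect_error(buildCernaNetwork(ce, names(sq$lncrnas), names(sq$mrnas),
                                   sq$mirnas, seqs[-1], percentile = 95),
                 "missing sequence")
    expect_error(buildCernaNetwork(ce, "nope", names(sq$mrnas),
                                   sq$mirnas, seqs),
                 "not in the expression matrix")
})
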