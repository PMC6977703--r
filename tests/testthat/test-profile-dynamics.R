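test_that("profile enumeration matches the closed form and brute force", {
    expect_equal(nProfiles(enumerateProfiles(4, 1, TRUE)), 26)

    p2 <- enumerateProfiles(2, 1, TRUE)
    expect_equal(nProfiles(p2), 2)
    expect_setequal(apply(profileMatrix(p2), 1, paste, collapse = ","),
                    c("0,-1", "0,1"))

    expect_equal(nProfiles(enumerateProfiles(3, 2, TRUE)), 24)
    expect_error(enumerateProfiles(1, 1), ">= 2")

    # brute force: enumerate all step sequences directly and count
    for (T in 2:5) for (c in 1:2) for (ef in c(TRUE, FALSE)) {
        grid <- do.call(expand.grid, rep(list(-c:c), T - 1))
        vecs <- unique(apply(grid, 1, function(d)
            paste(cumsum(c(0, d)), collapse = ",")))
        if (ef) vecs <- setdiff(vecs, paste(rep(0, T), collapse = ","))
        ps <- enumerateProfiles(T, c, ef)
        expect_equal(nProfiles(ps), length(vecs))
        expect_equal(nProfiles(ps), (2 * c + 1)^(T - 1) - as.integer(ef))
        expect_setequal(apply(profileMatrix(ps), 1, paste, collapse = ","),
                        vecs)
    }

    # ids are stable: rows already in lexicographic order
    pm <- profileMatrix(enumerateProfiles(4, 1, TRUE))
    ord <- do.call(order, as.data.frame(pm))
    expect_identical(ord, seq_len(nrow(pm)))
})

test_that("log2-ratio series transform is exact", {
    m <- matrix(rep(c(10, 5, 5, 2.5), each = 2), nrow = 1, byrow = FALSE)
    m <- rbind(`g1` = rep(c(10, 5, 5, 2.5), each = 2))
    colnames(m) <- paste0(rep(c("Sham", "PD", "NLID", "LID"), each = 2),
                          "_", 1:2)
    ce <- ConditionExperiment(m, rep(c("Sham", "PD", "NLID", "LID"),
                                     each = 2),
                              c("Sham", "PD", "NLID", "LID"))
    s <- toLog2Series(ce, pseudocount = 1e-12)
    expect_equal(unname(s[1, ]), c(0, -1, -1, -2), tolerance = 1e-9)

    # all conditions equal -> all-zero series
    m2 <- rbind(g1 = rep(7, 8)); colnames(m2) <- colnames(m)
    ce2 <- ConditionExperiment(m2, sampleConditions(ce), conditionOrder(ce))
    expect_equal(unname(toLog2Series(ce2)[1, ]), rep(0, 4))

    # reference mean 0 with pseudocount 1
    m3 <- rbind(g1 = rep(c(0, 1, 3, 7), each = 2)); colnames(m3) <- colnames(m)
    ce3 <- ConditionExperiment(m3, sampleConditions(ce), conditionOrder(ce))
    expect_equal(unname(toLog2Series(ce3, 1)[1, ]), c(0, 1, 2, 3))

    expect_error(toLog2Series(ce, 0), "> 0")
})

test_that("profile assignment matches a brute-force argmax scan", {
    ps <- enumerateProfiles(4, 1, TRUE)
    pm <- profileMatrix(ps)

    # a profile's own vector self-matches with similarity 1
    s <- rbind(g = c(0, -1, -1, -2))
    a <- assignProfiles(s, ps)
    expect_equal(a$similarity, 1)
    expect_identical(a$profile_id, matchProfile(ps, c(0, -1, -1, -2)))

    # flat series is unassigned with a reason
    a0 <- assignProfiles(rbind(g = c(0, 0, 0, 0)), ps)
    expect_true(is.na(a0$profile_id))
    expect_identical(a0$reason, "zero_variance")

    for (seed in 1:5) {
        set.seed(seed)
        series <- matrix(rnorm(200 * 4), 200, 4)
        series[, 1] <- 0
        rownames(series) <- sprintf("g%03d", 1:200)
        got <- assignProfiles(series, ps)
        want <- bruteAssign(series, pm)
        expect_identical(got$profile_id, want$profile_id)
        expect_equal(got$similarity, want$similarity, tolerance = 1e-12)
    }

    expect_error(assignProfiles(matrix(0, 2, 3), ps), "does not match")
})

test_that("assignment is invariant to positive affine scaling", {
    ps <- enumerateProfiles(4, 1, TRUE)
    set.seed(42)
    series <- matrix(rnorm(50 * 4), 50, 4)
    rownames(series) <- sprintf("g%02d", 1:50)
    a1 <- assignProfiles(series, ps)
    a2 <- assignProfiles(series * 3.7 + 0.9, ps)
    expect_identical(a1$profile_id, a2$profile_id)
})

test_that("permutation null expected counts equal a brute-force average", {
    ps <- enumerateProfiles(4, 1, TRUE)
    set.seed(99)
    series <- matrix(rnorm(20 * 4, sd = 0.5), 20, 4)
    series[, 1] <- 0
    rownames(series) <- sprintf("g%02d", 1:20)
    a <- assignProfiles(series, ps)
    sig <- profileSignificance(a, series, ps, permutations = "exhaustive")

    # brute force: every one of the 4! = 24 permutations, re-referenced,
    # re-assigned with the independent scanner
    perms <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
    perms <- perms[apply(perms, 1, function(x) length(unique(x)) == 4), ]
    counts <- matrix(0, nrow(perms), nProfiles(ps),
                     dimnames = list(NULL, profileIds(ps)))
    for (i in seq_len(nrow(perms))) {
        p <- perms[i, ]
        sp <- series[, p] - series[, p[1]]
        asg <- bruteAssign(sp, profileMatrix(ps))$profile_id
        tab <- table(factor(asg, levels = profileIds(ps)))
        counts[i, ] <- as.numeric(tab)
    }
    expect_equal(nrow(perms), 24)
    expect_equal(sig$expected, unname(colMeans(counts)), tolerance = 1e-12)
    expect_true(all(sig$p_value >= 0 & sig$p_value <= 1))

    expect_error(profileSignificance(a, series, ps, permutations = 5),
                 "at least 10")
})

test_that("permutation p-values are calibrated on flat-noise data", {
    ps <- enumerateProfiles(4, 1, TRUE)
    frac <- vapply(1:20, function(seed) {
        d <- syntheticDesign(replicates = 3, nBackground = 120,
                             planted = list(), seed = seed)
        e <- syntheticExpression(d)
        s <- toLog2Series(e$expression)
        a <- assignProfiles(s, ps)
        sig <- profileSignificance(a, s, ps)
        mean(sig$p_value < 0.05)
    }, numeric(1))
    expect_lte(mean(frac), 0.1)
})

test_that("pattern-gene selection returns exactly the planted set at zero noise", {
    ps <- enumerateProfiles(4, 1, TRUE)
    d <- syntheticDesign(replicates = 2, nBackground = 50,
                         planted = list(list(shape = c(0, -1, -1, -2),
                                             nGenes = 8, base = 10,
                                             noiseSd = 0)),
                         seed = 3)
    e <- syntheticExpression(d)
    s <- toLog2Series(e$expression, pseudocount = 1e-9)
    a <- assignProfiles(s, ps)
    sig <- profileSignificance(a, s, ps)
    sel <- selectPatternGenes(a, sig, ps, c(0, -1, -1, -2))
    expect_setequal(sel$genes, e$truth$gene_id)
    expect_error(selectPatternGenes(a, sig, ps, c(0, 5, 5, 5)),
                 "not in the profile set")

    empty <- a[0, ]
    selE <- selectPatternGenes(empty, sig[0, ], ps, c(0, -1, -1, -2))
    expect_length(selE$genes, 0)
})
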