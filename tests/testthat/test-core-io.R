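test_that("expression TSV round trip is bit-exact and validation catches bad input", {
    ce <- randomCE(5, seed = 11)
    f <- tempfile(fileext = ".tsv")
    writeExpressionMatrix(ce, f)
    back <- readExpressionMatrix(f, sampleConditions(ce), conditionOrder(ce))
    expect_identical(exprValues(back), exprValues(ce))
    expect_identical(conditionOrder(back), conditionOrder(ce))

    # negative value rejected, naming the cell
    df <- read.delim(f, check.names = FALSE)
    df[2, 3] <- -1
    write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    expect_error(
        readExpressionMatrix(f, sampleConditions(ce), conditionOrder(ce)),
        "negative value at gene 'g002'")

    # duplicate gene id rejected
    df <- read.delim(f, check.names = FALSE)
    df[2, 3] <- 1
    df$gene_id[2] <- df$gene_id[1]
    write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    expect_error(
        readExpressionMatrix(f, sampleConditions(ce), conditionOrder(ce)),
        "duplicate gene ids")

    # sample absent from the condition map
    writeExpressionMatrix(ce, f)
    cm <- sampleConditions(ce)[-1]
    expect_error(readExpressionMatrix(f, cm, conditionOrder(ce)),
                 "missing from the condition map")
})

test_that("ConditionExperiment enforces its invariants", {
    m <- matrix(1:8, 2, 4,
                dimnames = list(c("a", "b"), paste0("s", 1:4)))
    expect_error(ConditionExperiment(m, rep("Sham", 4), "Sham"),
                 "at least 2")
    expect_error(ConditionExperiment(m, rep(c("Sham", "X"), 2),
                                     c("Sham", "LID")),
                 "unknown condition")
    m2 <- m; m2[1, 2] <- -3
    expect_error(ConditionExperiment(m2, rep(c("Sham", "LID"), each = 2),
                                     c("Sham", "LID")),
                 "negative")
    ce <- ConditionExperiment(m, rep(c("Sham", "LID"), each = 2),
                              c("Sham", "LID"))
    expect_equal(unname(conditionMeans(ce)[, "Sham"]), c(2, 3))
})

test_that("GTF round trip assembles exons, spans and sequences correctly", {
    gtf <- tempfile(fileext = ".gtf")
    fa <- tempfile(fileext = ".fa")
    set.seed(5)
    ts <- makeTx(c("tx1", "tx2"), "chr1",
                 list(c(101, 301), 500), list(c(200, 400), 650),
                 seqs = c(randSeqChar(200), randSeqChar(151)))
    writeGtf(ts, gtf)
    Biostrings::writeXStringSet(transcriptSequences(ts), fa)
    back <- readTranscripts(gtf, fa)
    expect_setequal(transcriptIds(back), c("tx1", "tx2"))
    expect_equal(unname(splicedLength(back)["tx1"]), 200)
    expect_equal(unname(exonCount(back)["tx2"]), 1)
    expect_equal(as.character(transcriptSequences(back)[["tx1"]]),
                 as.character(transcriptSequences(ts)[["tx1"]]))

    # wrong-length FASTA entry is a validity error
    bad <- Biostrings::DNAStringSet(setNames(c("ACGT"), "tx1"))
    Biostrings::writeXStringSet(bad, fa)
    expect_error(readTranscripts(gtf, fa), "spliced length")

    # exon outside a declared transcript span
    writeLines(c(
        "chr1\tx\ttranscript\t100\t150\t.\t+\t.\tgene_id \"g\"; transcript_id \"t\";",
        "chr1\tx\texon\t100\t200\t.\t+\t.\tgene_id \"g\"; transcript_id \"t\";"),
        gtf)
    expect_error(readTranscripts(gtf), "outside transcript span")
})

test_that("network writers are deterministic and round trip", {
    f <- tempfile()
    e1 <- data.frame(node_a = "A", node_b = "B", r = 1.0)
    writeNetwork(e1, f, "sif")
    expect_identical(readLines(f), "A\tcoexp\tB")

    writeNetwork(e1[0, ], f, "sif")
    expect_identical(readLines(f), character(0))

    set.seed(7)
    ee <- data.frame(node_a = sample(LETTERS, 10),
                     node_b = sample(letters, 10),
                     r = round(runif(10), 3))
    writeNetwork(ee, f, "tsv")
    back <- readNetwork(f, "tsv")
    key <- function(d) sort(paste(d$node_a, d$node_b, d$r))
    expect_identical(key(back), key(ee))

    expect_error(writeNetwork(ee, f, "xml"), "should be one of")
    expect_error(writeNetwork(data.frame(node_a = "", node_b = "B"), f,
                              "sif"),
                 "non-empty")
})

test_that("packaged profile-3 fixtures keep entries verbatim", {
    fx <- loadProfile3()
    expect_length(fx$mrnas, 135)
    expect_length(fx$lncrnas, 79)
    # one mRNA identifier is duplicated in the source table
    expect_equal(length(unique(fx$mrnas)), 134)
    expect_equal(sum(fx$mrnas == "Hist1h2ac"), 2)
    expect_true(all(nzchar(fx$mrnas)) && all(nzchar(fx$lncrnas)))
})

test_that("Ct and evidence table readers validate their columns", {
    f <- tempfile()
    write.table(data.frame(sample_id = "s1", condition = "Sham",
                           gene = "Gsto2", ct = 25),
                f, sep = "\t", quote = FALSE, row.names = FALSE)
    expect_equal(nrow(readCtTable(f)), 1)
    write.table(data.frame(sample_id = "s1", condition = "Sham",
                           gene = "Gsto2", ct = 55),
                f, sep = "\t", quote = FALSE, row.names = FALSE)
    expect_error(readCtTable(f), "\\(0, 50\\)")

    write.table(data.frame(transcript_id = "t", cpc_score = -1,
                           cnci_score = 0.2, pfam_significant = FALSE),
                f, sep = "\t", quote = FALSE, row.names = FALSE)
    ev <- readCodingEvidence(f)
    expect_identical(ev$pfam_significant, FALSE)
    write.table(data.frame(transcript_id = "t", cpc_score = -1),
                f, sep = "\t", quote = FALSE, row.names = FALSE)
    expect_error(readCodingEvidence(f), "columns")
})
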