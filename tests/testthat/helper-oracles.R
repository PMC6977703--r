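# Independent brute-force oracles. These deliberately share no code with the
# package implementations: plain loops, explicit formulas, base arithmetic.

# argmax-correlation profile assignment by exhaustive scan
bruteAssign <- function(series, pm) {
    res <- character(nrow(series))
    sim <- numeric(nrow(series))
    for (g in seq_len(nrow(series))) {
        s <- series[g, ]
        if (stats::sd(s) == 0) { res[g] <- NA; sim[g] <- NA; next }
        best <- -Inf; bestId <- NA
        for (p in seq_len(nrow(pm))) {
            r <- suppressWarnings(stats::cor(s, pm[p, ]))
            if (is.na(r)) next
            if (r > best) { best <- r; bestId <- rownames(pm)[p] }
        }
        res[g] <- bestId; sim[g] <- best
    }
    list(profile_id = res, similarity = sim)
}

# BH step-up from the definition: q_i = min_{j >= rank(i)} m * p_(j) / j
bruteBH <- function(p) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    q <- numeric(m)
    for (i in seq_len(m)) q[i] <- min(m * ps[i:m] / (i:m), 1)
    out <- numeric(m)
    out[o] <- q
    out
}

# all-pairs co-expression edges by double loop
bruteEdges <- function(v, thr) {
    ids <- rownames(v)
    out <- NULL
    for (i in seq_len(nrow(v) - 1)) for (j in (i + 1):nrow(v)) {
        if (stats::sd(v[i, ]) == 0 || stats::sd(v[j, ]) == 0) next
        r <- stats::cor(v[i, ], v[j, ])
        if (r >= thr) {
            a <- min(ids[i], ids[j]); b <- max(ids[i], ids[j])
            out <- rbind(out, data.frame(gene_a = a, gene_b = b, r = r,
                                         stringsAsFactors = FALSE))
        }
    }
    if (is.null(out)) return(data.frame(gene_a = character(0),
                                        gene_b = character(0),
                                        r = numeric(0)))
    out <- out[order(out$gene_a, out$gene_b), ]
    rownames(out) <- NULL
    out
}

# manual reverse complement (DNA, character level)
bruteRevComp <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# all 0-based offsets of the reverse complement of miRNA positions 2-7
bruteSeedSites <- function(mirna, target) {
    m <- chartr("U", "T", toupper(mirna))
    t <- chartr("U", "T", toupper(target))
    site <- bruteRevComp(substr(m, 2, 7))
    hits <- integer(0)
    if (nchar(t) >= 6)
        for (o in 0:(nchar(t) - 6))
            if (substr(t, o + 1, o + 6) == site) hits <- c(hits, o)
    hits
}

# ceRNA triplets by three explicit loops
bruteTriplets <- function(v, lncIds, mrnaIds, mirs, seqs, percentile = 99) {
    pool <- numeric(0)
    for (l in lncIds) for (g in mrnaIds)
        pool <- c(pool, stats::cor(v[l, ], v[g, ]))
    n <- length(pool)
    thr <- sort(pool)[ceiling(percentile / 100 * n)]
    out <- NULL
    for (l in lncIds) for (g in mrnaIds) {
        r <- stats::cor(v[l, ], v[g, ])
        if (r < thr) next
        for (mi in names(mirs)) {
            sl <- length(bruteSeedSites(mirs[[mi]], seqs[[l]]))
            sg <- length(bruteSeedSites(mirs[[mi]], seqs[[g]]))
            if (sl >= 1 && sg >= 1)
                out <- rbind(out, data.frame(
                    lncrna_id = l, mirna_id = mi, mrna_id = g, r = r,
                    stringsAsFactors = FALSE))
        }
    }
    if (is.null(out)) return(data.frame(lncrna_id = character(0),
                                        mirna_id = character(0),
                                        mrna_id = character(0)))
    out <- out[order(out$lncrna_id, out$mirna_id, out$mrna_id), ]
    rownames(out) <- NULL
    out
}

# interval gap on 1-based inclusive spans: 0 on overlap, else
# later.start - earlier.end - 1
bruteGap <- function(s1, e1, s2, e2) {
    if (s1 <= e2 && s2 <= e1) return(0L)
    if (s1 > e2) s1 - e2 - 1L else s2 - e1 - 1L
}

# all-pairs cis hits from plain span tables
bruteCis <- function(lncDf, geneDf, window) {
    out <- NULL
    for (i in seq_len(nrow(lncDf))) for (j in seq_len(nrow(geneDf))) {
        if (lncDf$chrom[i] != geneDf$chrom[j]) next
        g <- bruteGap(lncDf$start[i], lncDf$end[i],
                      geneDf$start[j], geneDf$end[j])
        if (g <= window)
            out <- rbind(out, data.frame(lncrna_id = lncDf$id[i],
                                         gene_id = geneDf$id[j],
                                         distance_bp = g,
                                         stringsAsFactors = FALSE))
    }
    if (is.null(out)) return(data.frame(lncrna_id = character(0),
                                        gene_id = character(0),
                                        distance_bp = integer(0)))
    out <- out[order(out$lncrna_id, out$gene_id), ]
    rownames(out) <- NULL
    out
}

# best ungapped antisense alignment score by trying every offset and
# counting Watson-Crick pairs directly on the original orientations
bruteDuplex <- function(a, b) {
    wc <- c(A = "T", C = "G", G = "C", T = "A")
    av <- strsplit(toupper(a), "")[[1]]
    bv <- rev(strsplit(toupper(b), "")[[1]])  # read b 3'->5'
    na <- length(av); nb <- length(bv)
    best <- 0
    for (s in (-(nb - 1)):(na - 1)) {
        sc <- 0
        for (k in 1:nb) {
            i <- s + k
            if (i >= 1 && i <= na && wc[[av[i]]] == bv[k]) sc <- sc + 1
        }
        best <- max(best, sc)
    }
    best
}

# hypergeometric upper tail by explicit summation over choose()
bruteHyperTail <- function(k, K, N, n) {
    tot <- 0
    for (x in k:min(n, K))
        tot <- tot + choose(K, x) * choose(N - K, n - x) / choose(N, n)
    tot
}

# longest ORF by scanning all (start, stop) codon pairs in all 3 frames,
# requiring no internal stop
bruteOrf <- function(s) {
    s <- chartr("U", "T", toupper(s))
    n <- nchar(s)
    stops <- c("TAA", "TAG", "TGA")
    best <- 0
    for (f in 0:2) {
        L <- (n - f) %/% 3
        if (L < 2) next
        codons <- vapply(seq_len(L), function(i)
            substr(s, f + 3 * i - 2, f + 3 * i), character(1))
        for (i in seq_len(L - 1)) {
            if (codons[i] != "ATG") next
            for (j in (i + 1):L) {
                if (codons[j] %in% stops) {
                    best <- max(best, 3 * (j - i + 1))
                    break
                }
            }
        }
    }
    best
}

# random small expression instance
randomCE <- function(nGenes, seed, conds = c("Sham", "PD", "NLID", "LID"),
                     reps = 3) {
    set.seed(seed)
    m <- matrix(2^runif(nGenes * length(conds) * reps, 0, 8), nrow = nGenes)
    rownames(m) <- sprintf("g%03d", seq_len(nGenes))
    colnames(m) <- paste0(rep(conds, each = reps), "_", seq_len(reps))
    ConditionExperiment(m, rep(conds, each = reps), conds)
}

randSeqChar <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                        replace = TRUE), collapse = "")

# small TranscriptSet builder for tests
makeTx <- function(ids, chrom, exonStarts, exonEnds, strand = "+",
                   seqs = NULL, biotype = "novel", geneIds = NULL) {
    if (is.null(geneIds)) geneIds <- paste0(ids, "_g")
    exl <- GenomicRanges::GRangesList(lapply(seq_along(ids), function(i)
        GenomicRanges::GRanges(chrom,
            IRanges::IRanges(exonStarts[[i]], exonEnds[[i]]),
            strand = strand)))
    names(exl) <- ids
    anchors <- BiocGenerics::unlist(base::range(exl))
    S4Vectors::mcols(anchors)$gene_id <- geneIds
    S4Vectors::mcols(anchors)$biotype <- biotype
    sq <- if (is.null(seqs)) Biostrings::DNAStringSet() else
        Biostrings::DNAStringSet(setNames(seqs, ids))
    TranscriptSet(anchors, exl, sq)
}
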