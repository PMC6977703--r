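# Co-expression network and ceRNA (lncRNA-miRNA-mRNA) triplet inference:
# percentile-thresholded Pearson correlation between expression series plus
# perfect 6mer seed matches with a shared miRNA.

#' Pearson co-expression network
#'
#' Computes all unordered gene pairs whose Pearson correlation across
#' samples meets the threshold (signed r, as printed: anti-correlated pairs
#' are not edges). Zero-variance genes are skipped with a warning. Edges are
#' returned in canonical (lexicographic) order so output is deterministic.
#'
#' @param x a [ConditionExperiment-class] with >= 3 samples.
#' @param geneSubset optional character vector restricting the genes.
#' @param rThreshold minimum signed correlation (default 0.99).
#' @return data.frame with columns `gene_a`, `gene_b`, `r`
#'   (`gene_a < gene_b` lexicographically).
#' @export
coexpressionNetwork <- function(x, geneSubset = NULL, rThreshold = 0.99) {
    if (ncol(x) < 3) stop("need at least 3 samples")
    v <- exprValues(x)
    if (!is.null(geneSubset)) {
        missing <- setdiff(geneSubset, rownames(v))
        if (length(missing))
            stop("gene(s) not in the matrix: ",
                 paste(utils::head(missing, 5), collapse = ", "))
        v <- v[geneSubset, , drop = FALSE]
    }
    sds <- apply(v, 1, stats::sd)
    if (any(sds == 0)) {
        warning("skipping zero-variance gene(s): ",
                paste(utils::head(rownames(v)[sds == 0], 5), collapse = ", "))
        v <- v[sds > 0, , drop = FALSE]
    }
    if (nrow(v) < 2)
        return(data.frame(gene_a = character(0), gene_b = character(0),
                          r = numeric(0)))
    C <- cor(t(v))
    idx <- which(upper.tri(C) & C >= rThreshold, arr.ind = TRUE)
    a <- rownames(C)[idx[, 1]]
    b <- rownames(C)[idx[, 2]]
    swap <- a > b
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    out <- data.frame(gene_a = a, gene_b = b, r = C[idx],
                      stringsAsFactors = FALSE)
    out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Nearest-rank percentile threshold for a correlation pool
#'
#' Returns the `ceiling(p/100 * n)`-th order statistic of the pool
#' (nearest-rank percentile, deterministic and interpolation-free). Pairs
#' with `r >=` the returned value form the retained set.
#'
#' @param correlations non-empty numeric vector.
#' @param percentile percentile in (0, 100\] (default 99).
#' @return the threshold value.
#' @export
percentilePairThreshold <- function(correlations, percentile = 99) {
    n <- length(correlations)
    if (n == 0) stop("empty correlation pool")
    if (any(!is.finite(correlations)))
        stop("correlation pool must be finite")
    if (percentile <= 0 || percentile > 100)
        stop("percentile must lie in (0, 100]")
    sort(correlations)[ceiling(percentile / 100 * n)]
}

#' Perfect 6mer seed sites of a miRNA in a target sequence
#'
#' The seed is miRNA positions `seedStart` to `seedStart + seedLength - 1`
#' (default 2-7, the TargetScan 6mer convention); a site is an exact match
#' of its reverse complement in the target. G:U wobble is not counted (the
#' match is perfect Watson-Crick). All 0-based site offsets are returned,
#' sorted.
#'
#' @param mirnaSeq miRNA sequence, 5'->3', RNA or DNA alphabet,
#'   length >= `seedStart + seedLength - 1`.
#' @param targetSeq target nucleotide sequence (DNA or RNA; normalized
#'   internally).
#' @param seedStart 1-based start of the seed in the miRNA (default 2).
#' @param seedLength seed length (default 6).
#' @return sorted integer vector of 0-based offsets (empty when no site or
#'   the target is shorter than the seed).
#' @examples
#' seedMatch("UAGCUUAUCAGACUGAUGUUGA", "GGGTAAGCTGGG")  # offset 3
#' @export
seedMatch <- function(mirnaSeq, targetSeq, seedStart = 2, seedLength = 6) {
    m <- chartr("U", "T", toupper(as.character(mirnaSeq)))
    if (nchar(m) < seedStart + seedLength - 1)
        stop("miRNA shorter than the seed region")
    seed <- substr(m, seedStart, seedStart + seedLength - 1)
    if (grepl("[^ACGT]", seed))
        stop("ambiguous base in the seed region: ", seed)
    t <- chartr("U", "T", toupper(as.character(targetSeq)))
    if (nchar(t) < seedLength) return(integer(0))
    site <- reverseComplement(DNAString(seed))
    hits <- matchPattern(site, DNAString(t))
    sort(BiocGenerics::start(hits) - 1L)
}

#' Infer the lncRNA-miRNA-mRNA ceRNA network
#'
#' Three steps, mirroring the statistical-plus-seed-match construction:
#' (1) compute the Pearson correlation of every lncRNA x mRNA expression
#' pair across all samples; (2) keep pairs at or above the nearest-rank
#' percentile threshold of that overall correlation pool (signed r);
#' (3) expand kept pairs over the supplied miRNAs and retain triplets in
#' which both the lncRNA and the mRNA carry at least one perfect 6mer seed
#' match with the shared miRNA. Output order is deterministic and invariant
#' to the input ordering of genes and miRNAs.
#'
#' @param x a [ConditionExperiment-class] holding all lncRNA and mRNA rows.
#' @param lncrnaIds,mrnaIds character vectors of row ids in `x`.
#' @param mirnas named [Biostrings::RNAStringSet] (or named character) of
#'   mature miRNA sequences.
#' @param sequences named [Biostrings::DNAStringSet] (or named character)
#'   with the transcript sequence of every retained lncRNA and mRNA.
#' @param percentile correlation-pool percentile (default 99).
#' @param seedStart,seedLength seed-match convention (defaults 2 and 6).
#' @return data.frame with columns `lncrna_id`, `mirna_id`, `mrna_id`,
#'   `r`, `n_sites_lncrna`, `n_sites_mrna`, sorted by the three ids.
#' @export
buildCernaNetwork <- function(x, lncrnaIds, mrnaIds, mirnas, sequences,
                              percentile = 99, seedStart = 2,
                              seedLength = 6) {
    v <- exprValues(x)
    missing <- setdiff(c(lncrnaIds, mrnaIds), rownames(v))
    if (length(missing))
        stop("id(s) not in the expression matrix: ",
             paste(utils::head(missing, 5), collapse = ", "))
    lncrnaIds <- sort(unique(lncrnaIds))
    mrnaIds <- sort(unique(mrnaIds))
    C <- suppressWarnings(
        cor(t(v[lncrnaIds, , drop = FALSE]), t(v[mrnaIds, , drop = FALSE])))
    if (anyNA(C)) {
        warning("dropping pair(s) with zero-variance expression")
    }
    pool <- C[is.finite(C)]
    thr <- percentilePairThreshold(pool, percentile)
    keep <- which(is.finite(C) & C >= thr, arr.ind = TRUE)
    if (nrow(keep) == 0)
        return(.emptyTriplets())
    pairLnc <- lncrnaIds[keep[, 1]]
    pairMrna <- mrnaIds[keep[, 2]]
    seqNames <- names(sequences)
    noSeq <- setdiff(unique(c(pairLnc, pairMrna)), seqNames)
    if (length(noSeq))
        stop("missing sequence for retained gene(s): ",
             paste(utils::head(noSeq, 5), collapse = ", "))
    mirIds <- sort(names(mirnas))
    seqChar <- setNames(as.character(sequences), seqNames)
    mirChar <- setNames(as.character(mirnas), names(mirnas))
    involved <- unique(c(pairLnc, pairMrna))
    nSites <- matrix(0L, length(involved), length(mirIds),
                     dimnames = list(involved, mirIds))
    for (mid in mirIds)
        for (sid in involved)
            nSites[sid, mid] <- length(seedMatch(
                mirChar[[mid]], seqChar[[sid]], seedStart, seedLength))
    out <- do.call(rbind, lapply(seq_len(nrow(keep)), function(i) {
        sl <- nSites[pairLnc[i], ]
        sm <- nSites[pairMrna[i], ]
        hit <- sl >= 1 & sm >= 1
        if (!any(hit)) return(NULL)
        data.frame(lncrna_id = pairLnc[i], mirna_id = mirIds[hit],
                   mrna_id = pairMrna[i], r = C[keep[i, 1], keep[i, 2]],
                   n_sites_lncrna = unname(sl[hit]),
                   n_sites_mrna = unname(sm[hit]),
                   stringsAsFactors = FALSE)
    }))
    if (is.null(out)) return(.emptyTriplets())
    out <- out[order(out$lncrna_id, out$mirna_id, out$mrna_id), ,
               drop = FALSE]
    rownames(out) <- NULL
    out
}

.emptyTriplets <- function()
    data.frame(lncrna_id = character(0), mirna_id = character(0),
               mrna_id = character(0), r = numeric(0),
               n_sites_lncrna = integer(0), n_sites_mrna = integer(0))

#' Export a ceRNA network as typed SIF
#'
#' Writes lncRNA-miRNA and miRNA-mRNA edges with typed interactions so the
#' three node classes render distinctly in Cytoscape.
#'
#' @param triplets output of [buildCernaNetwork()].
#' @param path output SIF path.
#' @return `path`, invisibly.
#' @export
writeCernaSif <- function(triplets, path) {
    edges <- unique(rbind(
        data.frame(node_a = triplets$lncrna_id, interaction = "lncRNA-miRNA",
                   node_b = triplets$mirna_id, stringsAsFactors = FALSE),
        data.frame(node_a = triplets$mirna_id, interaction = "miRNA-mRNA",
                   node_b = triplets$mrna_id, stringsAsFactors = FALSE)))
    writeNetwork(edges, path, format = "sif")
}
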