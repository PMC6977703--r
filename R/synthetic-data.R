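# Synthetic-data generators with planted, recorded ground truth. Every
# generator is a pure function of its arguments including the seed, so the
# same call is bit-reproducible; truth records make downstream recovery
# checkable without any external data.

#' Describe a synthetic expression design
#'
#' Captures the study geometry the expression generator emulates: an
#' ordered condition axis (default the four-group Sham -> PD -> NLID -> LID
#' progression), a replicate count per condition, flat background genes, and
#' blocks of genes planted on specific integer profile shapes with lognormal
#' noise (normal on the log2 scale, so planted shapes stay unbiased after
#' the log2-ratio transform).
#'
#' @param conditionOrder ordered condition labels (default
#'   `c("Sham", "PD", "NLID", "LID")`).
#' @param replicates replicates per condition (default 3).
#' @param nBackground number of flat background genes.
#' @param planted list of planted blocks, each a list with elements `shape`
#'   (integer vector over the conditions, starting at 0), `nGenes`,
#'   `base` (FPKM at the reference condition) and `noiseSd` (sd of the
#'   normal noise on the log2 scale).
#' @param seed integer RNG seed.
#' @return validated design list (class `synthetic_design`).
#' @export
syntheticDesign <- function(conditionOrder = c("Sham", "PD", "NLID", "LID"),
                            replicates = 3, nBackground = 1000,
                            planted = list(), seed = 1) {
    if (length(conditionOrder) < 2) stop("need at least 2 conditions")
    if (replicates < 1 || nBackground < 0) stop("counts must be >= 0")
    for (b in planted) {
        stopifnot(all(c("shape", "nGenes", "base", "noiseSd") %in% names(b)))
        if (length(b$shape) != length(conditionOrder))
            stop("planted shape incompatible with the condition count")
        if (b$shape[1] != 0) stop("planted shapes must start at 0")
        if (b$nGenes < 0 || b$base <= 0 || b$noiseSd < 0)
            stop("invalid planted block")
    }
    structure(list(conditionOrder = conditionOrder, replicates = replicates,
                   nBackground = nBackground, planted = planted,
                   seed = as.integer(seed)),
              class = "synthetic_design")
}

#' Generate a synthetic expression matrix with planted profile structure
#'
#' Planted genes take replicate values `base * 2^(shape[t] + e)` with
#' `e ~ N(0, noiseSd)` drawn i.i.d. per replicate; with zero noise the
#' condition means are exactly `base * 2^shape`. Background genes are flat
#' with the same form of noise and lognormally spread base levels.
#' Deterministic under the design seed.
#'
#' @param design a [syntheticDesign()] object.
#' @return list with `expression` (a [ConditionExperiment-class]) and
#'   `truth` (data.frame `gene_id`, `shape` as comma-joined integers, one
#'   row per planted gene).
#' @export
syntheticExpression <- function(design) {
    stopifnot(inherits(design, "synthetic_design"))
    set.seed(design$seed)
    ord <- design$conditionOrder
    T <- length(ord)
    R <- design$replicates
    samples <- paste0(rep(ord, each = R), "_", rep(seq_len(R), times = T))
    cond <- rep(ord, each = R)
    rows <- list()
    truth <- list()
    bi <- 0
    for (b in design$planted) {
        bi <- bi + 1
        if (b$nGenes == 0) next
        ids <- sprintf("PG%d_%04d", bi, seq_len(b$nGenes))
        shapeRep <- rep(b$shape, each = R)
        block <- t(vapply(seq_len(b$nGenes), function(g)
            b$base * 2^(shapeRep + rnorm(T * R, 0, b$noiseSd)),
            numeric(T * R)))
        rownames(block) <- ids
        rows[[length(rows) + 1]] <- block
        truth[[length(truth) + 1]] <- data.frame(
            gene_id = ids, shape = paste(b$shape, collapse = ","),
            stringsAsFactors = FALSE)
    }
    if (design$nBackground > 0) {
        ids <- sprintf("BG%04d", seq_len(design$nBackground))
        noise <- if (length(design$planted))
            design$planted[[1]]$noiseSd else 0.2
        base <- 2^runif(design$nBackground, 1, 8)
        block <- t(vapply(seq_len(design$nBackground), function(g)
            base[g] * 2^rnorm(T * R, 0, noise), numeric(T * R)))
        rownames(block) <- ids
        rows[[length(rows) + 1]] <- block
    }
    m <- do.call(rbind, rows)
    colnames(m) <- samples
    list(expression = ConditionExperiment(m, cond, ord),
         truth = if (length(truth)) do.call(rbind, truth) else
             data.frame(gene_id = character(0), shape = character(0)))
}

.randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

.hasAnySite <- function(s, sites)
    any(vapply(sites, function(x) grepl(x, s, fixed = TRUE), logical(1)))

#' Generate lncRNA/mRNA/miRNA sequences with planted ceRNA seed sites
#'
#' For each of the first `plantedTriplets` index-matched
#' (lncRNA, miRNA, mRNA) triples, the exact reverse complement of the
#' miRNA's 6mer seed (positions 2-7) is inserted at a recorded offset in
#' both the lncRNA and the mRNA. Every sequence is screened by rejection
#' sampling (bounded retries) to be free of seed sites of all *other*
#' miRNAs, and background sequences are free of all seed sites, so planted
#' negatives are guaranteed clean.
#'
#' @param nLncrnas,nMrnas,nMirnas set sizes.
#' @param plantedTriplets number of planted triplets, at most
#'   `min(nLncrnas, nMrnas, nMirnas)`.
#' @param seqLength transcript sequence length, >= 30 (default 500).
#' @param seed integer RNG seed.
#' @param mirnaLength mature miRNA length (default 22).
#' @param maxRetries rejection-sampling cap per sequence (default 1000).
#' @return list with `lncrnas` and `mrnas` (named
#'   [Biostrings::DNAStringSet]), `mirnas` (named
#'   [Biostrings::RNAStringSet]), and `truth` (data.frame `lncrna_id`,
#'   `mirna_id`, `mrna_id`, `lncrna_offset`, `mrna_offset`; offsets are
#'   0-based).
#' @export
syntheticSequences <- function(nLncrnas, nMrnas, nMirnas, plantedTriplets,
                               seqLength = 500, seed = 1, mirnaLength = 22,
                               maxRetries = 1000) {
    if (seqLength < 30) stop("seqLength must be >= 30")
    if (plantedTriplets > min(nLncrnas, nMrnas, nMirnas))
        stop("plantedTriplets exceeds the smallest set size")
    set.seed(as.integer(seed))
    # distinct seeds so planted sites are unambiguous
    for (try in seq_len(maxRetries)) {
        mir <- vapply(seq_len(nMirnas), function(i)
            chartr("T", "U", .randSeq(mirnaLength)), character(1))
        seeds <- substr(chartr("U", "T", mir), 2, 7)
        if (!anyDuplicated(seeds)) break
        if (try == maxRetries) stop("could not draw distinct miRNA seeds")
    }
    sites <- vapply(seeds, function(s)
        as.character(reverseComplement(DNAString(s))), character(1))
    names(mir) <- sprintf("MIR%03d", seq_len(nMirnas))
    drawClean <- function(exclude) {
        for (try in seq_len(maxRetries)) {
            s <- .randSeq(seqLength)
            if (!.hasAnySite(s, sites[exclude])) return(s)
        }
        stop("screening failed after ", maxRetries,
             " retries (sequence too short or too many sites to avoid)")
    }
    plantSite <- function(mirIdx) {
        for (try in seq_len(maxRetries)) {
            s <- drawClean(seq_along(sites))
            off <- sample.int(seqLength - 6L + 1L, 1L) - 1L
            substr(s, off + 1L, off + 6L) <- sites[mirIdx]
            # insertion may create a site of another miRNA across the joint
            if (!.hasAnySite(s, sites[-mirIdx]))
                return(list(seq = s, offset = off))
        }
        stop("screening failed after ", maxRetries, " retries")
    }
    lnc <- character(nLncrnas); lncOff <- rep(NA_integer_, nLncrnas)
    mrna <- character(nMrnas); mrnaOff <- rep(NA_integer_, nMrnas)
    for (i in seq_len(nLncrnas)) {
        if (i <= plantedTriplets) {
            p <- plantSite(i); lnc[i] <- p$seq; lncOff[i] <- p$offset
        } else lnc[i] <- drawClean(seq_along(sites))
    }
    for (i in seq_len(nMrnas)) {
        if (i <= plantedTriplets) {
            p <- plantSite(i); mrna[i] <- p$seq; mrnaOff[i] <- p$offset
        } else mrna[i] <- drawClean(seq_along(sites))
    }
    lncIds <- sprintf("LNC%03d", seq_len(nLncrnas))
    mrnaIds <- sprintf("MRNA%03d", seq_len(nMrnas))
    truth <- data.frame(
        lncrna_id = lncIds[seq_len(plantedTriplets)],
        mirna_id = names(mir)[seq_len(plantedTriplets)],
        mrna_id = mrnaIds[seq_len(plantedTriplets)],
        lncrna_offset = lncOff[seq_len(plantedTriplets)],
        mrna_offset = mrnaOff[seq_len(plantedTriplets)],
        stringsAsFactors = FALSE)
    list(lncrnas = setNames(DNAStringSet(lnc), lncIds),
         mrnas = setNames(DNAStringSet(mrna), mrnaIds),
         mirnas = setNames(RNAStringSet(mir), names(mir)),
         truth = truth)
}

#' Generate a genomic annotation with planted cis pairs
#'
#' Lays out (lncRNA, gene) transcript pairs along one chromosome: the first
#' `nPairsWithin` pairs have an inter-span gap of at most `window` bp
#' (labeled cis in the truth), the next `nPairsBeyond` have a gap beyond
#' the window. Pair blocks are separated by much more than the window so no
#' cross-pair hit exists; [cisTargets()] on the emitted annotation recovers
#' exactly the planted cis set.
#'
#' @param nPairsWithin,nPairsBeyond pair counts.
#' @param chromLength chromosome length; an error is raised when the layout
#'   does not fit.
#' @param seed integer RNG seed.
#' @param window cis window in bp (default 10000).
#' @return list with `lncrnas` and `genes` ([TranscriptSet-class]) and
#'   `truth` (data.frame `lncrna_id`, `gene_id`, `distance_bp`, `cis`).
#' @export
syntheticAnnotation <- function(nPairsWithin, nPairsBeyond,
                                chromLength = 10e6, seed = 1,
                                window = 10000) {
    set.seed(as.integer(seed))
    window <- as.integer(window)
    nPairs <- nPairsWithin + nPairsBeyond
    txLen <- 1000L
    spacer <- 5L * window
    cur <- 1L
    lncList <- list(); geneList <- list(); truth <- list()
    for (k in seq_len(nPairs)) {
        cis <- k <= nPairsWithin
        gap <- if (cis) sample.int(window + 1L, 1L) - 1L
               else window + sample.int(window, 1L)
        lncStart <- cur
        lncEnd <- lncStart + txLen - 1L
        geneStart <- lncEnd + gap + 1L
        geneEnd <- geneStart + txLen - 1L
        if (geneEnd > chromLength)
            stop("placement failure: chromLength too small for the layout")
        lncList[[k]] <- c(lncStart, lncEnd)
        geneList[[k]] <- c(geneStart, geneEnd)
        truth[[k]] <- data.frame(
            lncrna_id = sprintf("ALNC%03d", k),
            gene_id = sprintf("GENE%03d", k),
            distance_bp = gap, cis = cis, stringsAsFactors = FALSE)
        cur <- geneEnd + spacer
    }
    mkSet <- function(coords, ids, geneIds, biotype) {
        st <- vapply(coords, `[`, integer(1), 1)
        en <- vapply(coords, `[`, integer(1), 2)
        anchors <- GRanges("chrS", IRanges(st, en), strand = "+")
        names(anchors) <- ids
        mcols(anchors)$gene_id <- geneIds
        mcols(anchors)$biotype <- biotype
        # two exons per transcript with a fixed internal intron
        mid <- st + 399L
        exons <- GRangesList(lapply(seq_along(st), function(i)
            GRanges("chrS", IRanges(c(st[i], mid[i] + 201L),
                                    c(mid[i], en[i])), strand = "+")))
        names(exons) <- ids
        TranscriptSet(anchors, exons)
    }
    tdf <- do.call(rbind, truth)
    list(lncrnas = mkSet(lncList, tdf$lncrna_id,
                         paste0(tdf$lncrna_id, "_g"), "known_lncRNA"),
         genes = mkSet(geneList, tdf$gene_id,
                       paste0(tdf$gene_id, "_g"), "known_coding"),
         truth = tdf)
}

#' Generate novel transcripts with planted lncRNA candidacy labels
#'
#' Emits a [TranscriptSet-class] with sequences plus a coding-evidence
#' table in which the first `nCandidates` transcripts pass every lncRNA
#' filter rule and the remaining `nRejects` each violate exactly one rule
#' (cycling through short length, single exon, long ORF, CPC >= 0,
#' CNCI >= 0, Pfam hit), so the filter chain's behaviour is fully
#' determined by construction.
#'
#' @param nCandidates,nRejects transcript counts.
#' @param seed integer RNG seed.
#' @return list with `transcripts` ([TranscriptSet-class]), `evidence`
#'   (data.frame for [classifyLncrna()]) and `truth` (data.frame
#'   `transcript_id`, `is_candidate`, `violated_rule`).
#' @export
syntheticTranscripts <- function(nCandidates, nRejects, seed = 1) {
    set.seed(as.integer(seed))
    rules <- c("length", "exons", "orf", "cpc", "cnci", "pfam")
    n <- nCandidates + nRejects
    ids <- sprintf("NOVEL%03d", seq_len(n))
    seqs <- character(n)
    nEx <- integer(n)
    ev <- data.frame(transcript_id = ids, cpc_score = -1, cnci_score = -0.5,
                     pfam_significant = FALSE, stringsAsFactors = FALSE)
    truth <- data.frame(transcript_id = ids,
                        is_candidate = seq_len(n) <= nCandidates,
                        violated_rule = NA_character_,
                        stringsAsFactors = FALSE)
    drawShortOrf <- function(len, cap = 300) {
        for (try in 1:1000) {
            s <- .randSeq(len)
            if (longestOrf(s) <= cap) return(s)
        }
        stop("could not draw a sequence with ORF <= ", cap)
    }
    for (i in seq_len(n)) {
        nEx[i] <- 2L
        seqs[i] <- drawShortOrf(400L)
        if (i > nCandidates) {
            rule <- rules[((i - nCandidates - 1) %% length(rules)) + 1]
            truth$violated_rule[i] <- rule
            switch(rule,
                length = { seqs[i] <- drawShortOrf(150L) },
                exons = { nEx[i] <- 1L },
                orf = {
                    # ATG + 120 non-stop codons + TAA = 366 nt ORF
                    body <- paste0("ATG", strrep("GCT", 120), "TAA")
                    seqs[i] <- paste0(substr(seqs[i], 1, 17), body,
                                      substr(seqs[i], 18, 400 - 366 + 17))
                },
                cpc = { ev$cpc_score[i] <- 1 },
                cnci = { ev$cnci_score[i] <- 0.5 },
                pfam = { ev$pfam_significant[i] <- TRUE })
        }
    }
    st <- 1L + (seq_len(n) - 1L) * 100000L
    lens <- nchar(seqs)
    exonList <- vector("list", n)
    for (i in seq_len(n)) {
        if (nEx[i] == 1L) {
            exonList[[i]] <- GRanges("chrN",
                IRanges(st[i], width = lens[i]), strand = "+")
        } else {
            w1 <- lens[i] %/% 2L
            exonList[[i]] <- GRanges("chrN",
                IRanges(c(st[i], st[i] + w1 + 500L),
                        width = c(w1, lens[i] - w1)), strand = "+")
        }
    }
    exons <- GRangesList(exonList)
    names(exons) <- ids
    anchors <- unlist(range(exons))
    mcols(anchors)$gene_id <- paste0(ids, "_g")
    mcols(anchors)$biotype <- "novel"
    ts <- TranscriptSet(anchors, exons, setNames(DNAStringSet(seqs), ids))
    list(transcripts = ts, evidence = ev, truth = truth)
}
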