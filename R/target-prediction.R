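# lncRNA target prediction: cis by genomic proximity (10-kb window up- or
# downstream, strand-agnostic) and trans by a two-stage sequence-
# complementarity screen (exact reverse-complement k-mer filter, then best
# ungapped antisense match count).

#' Cis targets of lncRNAs within a genomic window
#'
#' A gene is a cis target of a lncRNA when both lie on the same chromosome
#' and the gap between their transcript spans is at most `windowBp`
#' (symmetric up/downstream, strand ignored). The gap convention is
#' `later.start - earlier.end - 1` on 1-based inclusive spans; overlapping
#' spans have distance 0.
#'
#' @param lncrnas,genes [TranscriptSet-class] objects.
#' @param windowBp window size in bp (default 10000).
#' @return data.frame with columns `lncrna_id`, `gene_id`, `distance_bp`,
#'   sorted by the id pair. Identical ids are never paired with themselves.
#' @export
cisTargets <- function(lncrnas, genes, windowBp = 10000) {
    la <- transcriptAnchors(lncrnas)
    ga <- transcriptAnchors(genes)
    if (length(la) == 0 || length(ga) == 0)
        return(data.frame(lncrna_id = character(0), gene_id = character(0),
                          distance_bp = integer(0)))
    i <- rep(seq_along(la), each = length(ga))
    j <- rep(seq_along(ga), times = length(la))
    d <- suppressWarnings(
        GenomicRanges::distance(la[i], ga[j], ignore.strand = TRUE))
    hit <- !is.na(d) & d <= windowBp & names(la)[i] != names(ga)[j]
    out <- data.frame(lncrna_id = names(la)[i][hit],
                      gene_id = names(ga)[j][hit],
                      distance_bp = as.integer(d[hit]),
                      stringsAsFactors = FALSE)
    out <- out[order(out$lncrna_id, out$gene_id), , drop = FALSE]
    rownames(out) <- NULL
    out
}

.revcompChar <- function(s)
    as.character(reverseComplement(DNAString(s)))

.kmerSet <- function(s, k) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
}

# Best ungapped antisense alignment between a and b: a is slid along
# revcomp(b) and matching positions are counted (a match in this frame is a
# Watson-Crick pair in the duplex). With wobble, G:U pairs also score:
# a = G over rc = A (original U/T), or a = T over rc = C (original G).
.duplexScore <- function(a, b, wobble = FALSE) {
    rb <- .revcompChar(b)
    av <- strsplit(a, "")[[1]]
    bv <- strsplit(rb, "")[[1]]
    na <- length(av); nb <- length(bv)
    best <- 0L; bestA <- 0L; bestB <- 0L
    for (s in seq.int(-(nb - 1L), na - 1L)) {
        ia <- max(1L, s + 1L):min(na, s + nb)
        ib <- ia - s
        m <- av[ia] == bv[ib]
        if (wobble)
            m <- m | (av[ia] == "G" & bv[ib] == "A") |
                     (av[ia] == "T" & bv[ib] == "C")
        sc <- sum(m)
        if (sc > best) {
            best <- as.integer(sc)
            bestA <- ia[1] - 1L
            # offset in the original b (0-based): rc index ib maps to
            # nb - ib position
            bestB <- nb - ib[length(ib)]
        }
    }
    list(score = best, offset_a = bestA, offset_b = bestB)
}

#' Trans targets of a lncRNA by sequence complementarity
#'
#' Two-stage screen-then-score architecture: stage 1 keeps candidates that
#' share at least one exact reverse-complement k-mer with the lncRNA
#' (`screenKmer`); stage 2 computes, for each survivor, the best ungapped
#' antisense alignment score over all offsets (Watson-Crick pairs score 1,
#' G:U scores 1 only when `wobble = TRUE`). Candidates with best score >=
#' `minScore` are reported. The match-count duplex score is a deliberately
#' simplified stand-in for thermodynamic duplex prediction that preserves
#' the screen-then-score design.
#'
#' @param lncrnaSeq lncRNA sequence (character or `DNAString`).
#' @param candidateSeqs named character vector or `DNAStringSet` of
#'   candidate target sequences.
#' @param minScore minimum paired-position count to report a hit.
#' @param screenKmer stage-1 k-mer length, >= 6 (default 12).
#' @param wobble count G:U pairs in stage 2 (default `FALSE`).
#' @param lncrnaId id used in the output (default `"lncRNA"`).
#' @return data.frame with columns `lncrna_id`, `target_id`, `best_score`,
#'   `lncrna_offset`, `target_offset` (0-based offsets of the best duplex),
#'   sorted by target id.
#' @export
transTargets <- function(lncrnaSeq, candidateSeqs, minScore,
                         screenKmer = 12, wobble = FALSE,
                         lncrnaId = "lncRNA") {
    if (screenKmer < 6) stop("screenKmer must be >= 6")
    a <- chartr("U", "T", toupper(as.character(lncrnaSeq)))
    if (!nchar(a)) stop("empty lncRNA sequence")
    cand <- setNames(chartr("U", "T", toupper(as.character(candidateSeqs))),
                     names(candidateSeqs))
    if (any(!nzchar(cand))) stop("empty candidate sequence")
    aKmers <- .kmerSet(a, screenKmer)
    rows <- lapply(names(cand), function(id) {
        rcKmers <- .kmerSet(.revcompChar(cand[[id]]), screenKmer)
        if (!length(intersect(aKmers, rcKmers))) return(NULL)  # stage 1
        ds <- .duplexScore(a, cand[[id]], wobble)              # stage 2
        if (ds$score < minScore) return(NULL)
        data.frame(lncrna_id = lncrnaId, target_id = id,
                   best_score = ds$score, lncrna_offset = ds$offset_a,
                   target_offset = ds$offset_b, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        return(data.frame(lncrna_id = character(0), target_id = character(0),
                          best_score = integer(0), lncrna_offset = integer(0),
                          target_offset = integer(0)))
    out <- out[order(out$target_id), , drop = FALSE]
    rownames(out) <- NULL
    out
}
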