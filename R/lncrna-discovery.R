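# Rule-based lncRNA candidate classification for novel transcripts:
# length >= 200 nt, >= 2 exons, longest ORF <= 300 nt, CPC < 0, CNCI < 0,
# no significant Pfam hit. All thresholds inclusive as printed.

#' Longest open reading frame of a transcript sequence
#'
#' Scans the three sense-strand frames for ATG...stop (TAA/TAG/TGA) open
#' reading frames and returns the length in nucleotides of the longest one,
#' stop codon included; 0 when no ORF exists. U is treated as T and N never
#' matches a codon. An optional six-frame mode also scans the reverse
#' complement (off by default: transcripts are stranded, spliced sequences,
#' so antisense ORFs belong to a different transcript).
#'
#' @param sequence nucleotide string (or `DNAString`) over A/C/G/T/U/N.
#' @param sixFrame also scan the reverse complement (default `FALSE`).
#' @return integer ORF length in nt (a multiple of 3), 0 if none.
#' @examples
#' longestOrf("ATGAAATAA")  # 9
#' @export
longestOrf <- function(sequence, sixFrame = FALSE) {
    s <- chartr("U", "T", toupper(as.character(sequence)))
    best <- .orfScan3(s)
    if (sixFrame) {
        rc <- as.character(reverseComplement(DNAString(s)))
        best <- max(best, .orfScan3(rc))
    }
    best
}

.STOPS <- c("TAA", "TAG", "TGA")

.orfScan3 <- function(s) {
    n <- nchar(s)
    if (n < 6) return(0L)
    best <- 0L
    for (f in 0:2) {
        L <- (n - f) %/% 3L
        if (L < 2) next
        pos <- f + 1L + 3L * (seq_len(L) - 1L)
        codons <- substring(s, pos, pos + 2L)
        starts <- which(codons == "ATG")
        stops <- which(codons %in% .STOPS)
        if (!length(starts) || !length(stops)) next
        # first in-frame stop strictly downstream of each start
        nxt <- findInterval(starts, stops) + 1L
        ok <- nxt <= length(stops)
        if (!any(ok)) next
        lens <- (stops[nxt[ok]] - starts[ok] + 1L) * 3L
        best <- max(best, lens)
    }
    best
}

#' Apply the lncRNA candidate filter chain
#'
#' Evaluates every rule independently for each transcript and reports the
#' per-rule outcome plus the conjunction: spliced length >= `minLen`, exon
#' count >= `minExons`, longest ORF <= `maxOrf` (computed from the attached
#' sequence, or taken from an `orf_nt` evidence column when no sequence is
#' present), CPC score < 0, CNCI score < 0, and no significant Pfam
#' similarity. Thresholds are inclusive.
#'
#' @param transcripts a [TranscriptSet-class]; the ORF rule needs either an
#'   attached sequence or an `orf_nt` column in `evidence`.
#' @param evidence data.frame with columns `transcript_id`, `cpc_score`,
#'   `cnci_score`, `pfam_significant` (and optionally `orf_nt`); see
#'   [readCodingEvidence()]. Must cover every transcript.
#' @param minLen minimum spliced length, nt (default 200).
#' @param minExons minimum exon count (default 2).
#' @param maxOrf maximum longest-ORF length, nt (default 300).
#' @return data.frame with one row per transcript: `transcript_id`,
#'   `longest_orf_nt`, the six rule columns (`rule_length`, `rule_exons`,
#'   `rule_orf`, `rule_cpc`, `rule_cnci`, `rule_pfam`), and `is_candidate`
#'   (the conjunction).
#' @export
classifyLncrna <- function(transcripts, evidence, minLen = 200,
                           minExons = 2, maxOrf = 300) {
    ids <- transcriptIds(transcripts)
    missing <- setdiff(ids, evidence$transcript_id)
    if (length(missing))
        stop("no coding evidence for transcript(s): ",
             paste(utils::head(missing, 5), collapse = ", "))
    ev <- evidence[match(ids, evidence$transcript_id), , drop = FALSE]
    seqs <- transcriptSequences(transcripts)
    orf <- vapply(ids, function(id) {
        if (id %in% names(seqs))
            longestOrf(seqs[[id]])
        else if ("orf_nt" %in% colnames(ev) &&
                 is.finite(ev$orf_nt[match(id, ids)]))
            as.integer(ev$orf_nt[match(id, ids)])
        else
            stop("transcript '", id,
                 "' has neither a sequence nor a precomputed ORF length")
    }, integer(1))
    res <- data.frame(
        transcript_id = ids,
        longest_orf_nt = unname(orf),
        rule_length = unname(splicedLength(transcripts) >= minLen),
        rule_exons = unname(exonCount(transcripts) >= minExons),
        rule_orf = unname(orf <= maxOrf),
        rule_cpc = ev$cpc_score < 0,
        rule_cnci = ev$cnci_score < 0,
        rule_pfam = !ev$pfam_significant,
        stringsAsFactors = FALSE)
    res$is_candidate <- res$rule_length & res$rule_exons & res$rule_orf &
        res$rule_cpc & res$rule_cnci & res$rule_pfam
    res
}

#' Merge novel lncRNA candidates with a known lncRNA catalogue
#'
#' Takes the union of passing novel candidates and known lncRNA ids,
#' de-duplicated by id with a provenance tag. On an id collision the known
#' annotation wins, with a warning.
#'
#' @param verdicts output of [classifyLncrna()].
#' @param knownIds character vector of known lncRNA ids.
#' @return data.frame with columns `id`, `provenance` (`known` or `novel`),
#'   ordered by id.
#' @export
mergeWithKnown <- function(verdicts, knownIds) {
    novel <- verdicts$transcript_id[verdicts$is_candidate]
    knownIds <- unique(knownIds)
    clash <- intersect(novel, knownIds)
    if (length(clash))
        warning("candidate id(s) already known, keeping known annotation: ",
                paste(clash, collapse = ", "))
    newNovel <- setdiff(novel, knownIds)
    out <- data.frame(
        id = c(knownIds, newNovel),
        provenance = rep(c("known", "novel"),
                         c(length(knownIds), length(newNovel))),
        stringsAsFactors = FALSE)
    out <- out[order(out$id), , drop = FALSE]
    rownames(out) <- NULL
    out
}
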