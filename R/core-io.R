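# Readers and writers for the plain-text formats the pipeline touches.
# TSV dialect: tab-separated, '.' decimal, no quoting, mandatory header.

#' Read an expression matrix from TSV
#'
#' The file must have a header row of sample ids and one row per gene, the
#' first column holding gene ids. Values must be non-negative; duplicate gene
#' ids and samples absent from the condition map are rejected.
#'
#' @param path TSV file path.
#' @param conditionMap named character vector mapping sample id -> condition.
#' @param conditionOrder ordered vector of condition labels.
#' @param units expression unit, `"FPKM"` (default) or `"counts"`.
#' @return A [ConditionExperiment-class].
#' @export
readExpressionMatrix <- function(path, conditionMap, conditionOrder,
                                 units = "FPKM") {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(df[[1]])
    if (anyDuplicated(ids))
        stop("duplicate gene ids in ", path, ": ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    bad <- which(m < 0, arr.ind = TRUE)
    if (nrow(bad) > 0)
        stop(sprintf("negative value at gene '%s', sample '%s'",
                     rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
    missing <- setdiff(colnames(m), names(conditionMap))
    if (length(missing))
        stop("sample(s) missing from the condition map: ",
             paste(missing, collapse = ", "))
    ConditionExperiment(m, conditionMap[colnames(m)], conditionOrder, units)
}

#' Write an expression matrix as TSV
#'
#' Values are written with 17 significant digits so a write/read round trip
#' reproduces doubles bit-exactly.
#'
#' @param x a [ConditionExperiment-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(x, path) {
    v <- exprValues(x)
    fmt <- matrix(sprintf("%.17g", v), nrow = nrow(v),
                  dimnames = dimnames(v))
    df <- data.frame(gene_id = rownames(v), fmt, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read transcript models from a GTF file, optionally with spliced sequences
#'
#' Exon features are grouped by `transcript_id` and sorted; the transcript
#' span is taken from a `transcript` feature when present, else from the exon
#' range. Sequences from `fastaPath` (FASTA keyed by transcript id) are
#' attached where present; a sequence whose length differs from the spliced
#' exon length is an error, as is an exon outside a declared transcript span.
#'
#' @param gtfPath GTF file with `exon` (and optionally `transcript`)
#'   features carrying `transcript_id` and `gene_id` attributes.
#' @param fastaPath optional FASTA of spliced sense-strand sequences.
#' @param biotype default biotype for transcripts lacking a `biotype`
#'   attribute; one of `known_coding`, `known_lncRNA`, `novel`.
#' @return A [TranscriptSet-class].
#' @export
readTranscripts <- function(gtfPath, fastaPath = NULL, biotype = "novel") {
    gr <- rtracklayer::import(gtfPath)
    ex <- gr[gr$type == "exon"]
    if (length(ex) == 0) stop("no exon features in ", gtfPath)
    exl <- S4Vectors::split(granges(ex), ex$transcript_id)
    exl <- sort(exl)
    meta <- unique(data.frame(
        transcript_id = ex$transcript_id,
        gene_id = ex$gene_id,
        biotype = if ("biotype" %in% colnames(mcols(ex)))
            ex$biotype else biotype,
        stringsAsFactors = FALSE))
    rownames(meta) <- meta$transcript_id
    meta <- meta[names(exl), ]
    anchors <- unlist(range(exl))
    tx <- gr[gr$type == "transcript"]
    if (length(tx)) {
        names(tx) <- tx$transcript_id
        common <- intersect(names(tx), names(anchors))
        for (id in common) {
            if (GenomicRanges::start(anchors[id]) <
                    GenomicRanges::start(tx[id]) ||
                GenomicRanges::end(anchors[id]) > GenomicRanges::end(tx[id]))
                stop("exon outside transcript span for '", id, "'")
        }
        anchors[common] <- granges(tx[common])
    }
    mcols(anchors)$gene_id <- meta$gene_id
    mcols(anchors)$biotype <- meta$biotype
    seqs <- Biostrings::DNAStringSet()
    if (!is.null(fastaPath)) {
        seqs <- readDNAStringSet(fastaPath)
        names(seqs) <- sub("\\s.*$", "", names(seqs))
        seqs <- seqs[intersect(names(seqs), names(anchors))]
    }
    TranscriptSet(anchors, exl, seqs)
}

#' Write a TranscriptSet as GTF
#'
#' Emits one `transcript` line and one `exon` line per exon, with
#' `gene_id`/`transcript_id`/`biotype` attributes, in the same dialect
#' [readTranscripts()] consumes. 1-based inclusive coordinates.
#'
#' @param transcripts a [TranscriptSet-class].
#' @param path output GTF path.
#' @return `path`, invisibly.
#' @export
writeGtf <- function(transcripts, path) {
    a <- transcriptAnchors(transcripts)
    e <- transcriptExons(transcripts)
    gi <- geneIds(transcripts)
    bt <- mcols(a)$biotype
    lines <- character(0)
    for (i in seq_along(a)) {
        id <- names(a)[i]
        attr <- sprintf(
            'gene_id "%s"; transcript_id "%s"; biotype "%s";',
            gi[[id]], id, bt[i])
        chr <- as.character(seqnames(a)[i])
        str <- as.character(BiocGenerics::strand(a)[i])
        if (str == "*") str <- "+"
        lines <- c(lines, paste(chr, "ceRNAprofiler", "transcript",
            BiocGenerics::start(a)[i], BiocGenerics::end(a)[i],
            ".", str, ".", attr, sep = "\t"))
        ex <- e[[id]]
        lines <- c(lines, paste(chr, "ceRNAprofiler", "exon",
            BiocGenerics::start(ex), BiocGenerics::end(ex),
            ".", str, ".", attr, sep = "\t"))
    }
    writeLines(lines, path)
    invisible(path)
}

#' Read mature miRNA sequences from FASTA
#'
#' Sequences are coerced to the RNA alphabet; each must be at least 7 nt and
#' contain only A, C, G, U.
#'
#' @param path FASTA file of mature miRNA sequences (5'->3').
#' @return A named [Biostrings::RNAStringSet].
#' @export
readMiRNA <- function(path) {
    s <- readRNAStringSet(path)
    names(s) <- sub("\\s.*$", "", names(s))
    if (any(Biostrings::width(s) < 7))
        stop("miRNA sequences must be at least 7 nt: ",
             paste(names(s)[Biostrings::width(s) < 7], collapse = ", "))
    freq <- Biostrings::alphabetFrequency(s)
    extra <- rowSums(freq) - rowSums(freq[, c("A", "C", "G", "U"),
                                         drop = FALSE])
    if (any(extra > 0))
        stop("miRNA sequences must use only A/C/G/U: ",
             paste(names(s)[extra > 0], collapse = ", "))
    s
}

#' Packaged Profile-3 gene lists
#'
#' Returns the two fixture lists shipped with the package: the mRNAs and
#' lncRNAs of the monotone-decreasing profile (Sham > PD ~ NLID > LID) from
#' the rat PD/LID striatum study the pipeline re-implements. Entries are
#' preserved verbatim (one mRNA identifier is duplicated in the source
#' table), so entry counts, not unique counts, are the contract: 135 mRNAs
#' and 79 lncRNAs.
#'
#' @return A list with character vectors `mrnas` (135 entries) and
#'   `lncrnas` (79 entries).
#' @examples
#' str(loadProfile3())
#' @export
loadProfile3 <- function() {
    rd <- function(f) readLines(system.file("extdata", f,
                                            package = "ceRNAprofiler"))
    list(mrnas = rd("profile3_mrnas.txt"),
         lncrnas = rd("profile3_lncrnas.txt"))
}

#' Write a network as edge-list TSV or SIF
#'
#' Edges are written in lexicographic order of (node_a, node_b) so the output
#' is byte-reproducible. The SIF dialect is `node_a <tab> interaction <tab>
#' node_b` with no header (Cytoscape interchange); the TSV dialect keeps all
#' attribute columns under a header.
#'
#' @param edges data.frame with character columns `node_a`, `node_b` and any
#'   attribute columns (an `interaction` column types the SIF edge; default
#'   type is `"coexp"`).
#' @param path output path.
#' @param format `"tsv"` or `"sif"`.
#' @return `path`, invisibly.
#' @export
writeNetwork <- function(edges, path, format = c("tsv", "sif")) {
    format <- match.arg(format)
    stopifnot(all(c("node_a", "node_b") %in% colnames(edges)))
    if (nrow(edges) > 0 &&
        (any(!nzchar(edges$node_a)) || any(!nzchar(edges$node_b))))
        stop("node names must be non-empty")
    edges <- edges[order(edges$node_a, edges$node_b), , drop = FALSE]
    if (format == "sif") {
        if (nrow(edges) == 0) {
            writeLines(character(0), path)
            return(invisible(path))
        }
        inter <- if ("interaction" %in% colnames(edges))
            edges$interaction else rep("coexp", nrow(edges))
        writeLines(paste(edges$node_a, inter, edges$node_b, sep = "\t"), path)
    } else {
        num <- vapply(edges, is.numeric, logical(1))
        edges[num] <- lapply(edges[num], function(z) sprintf("%.17g", z))
        write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    invisible(path)
}

#' Read a network written by [writeNetwork()]
#'
#' @param path file path.
#' @param format `"tsv"` or `"sif"`.
#' @return data.frame of edges (`node_a`, `node_b`, attributes).
#' @export
readNetwork <- function(path, format = c("tsv", "sif")) {
    format <- match.arg(format)
    if (format == "sif") {
        ln <- readLines(path)
        if (length(ln) == 0)
            return(data.frame(node_a = character(0),
                              interaction = character(0),
                              node_b = character(0)))
        parts <- do.call(rbind, strsplit(ln, "\t", fixed = TRUE))
        data.frame(node_a = parts[, 1], interaction = parts[, 2],
                   node_b = parts[, 3], stringsAsFactors = FALSE)
    } else {
        read.delim(path, stringsAsFactors = FALSE)
    }
}

#' Read a coding-evidence table
#'
#' Expected columns: `transcript_id`, `cpc_score`, `cnci_score`,
#' `pfam_significant` (logical or 0/1). The scores are externally computed
#' coding-potential scores consumed as-is by [classifyLncrna()].
#'
#' @param path TSV path.
#' @return data.frame keyed by `transcript_id`.
#' @export
readCodingEvidence <- function(path) {
    ev <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("transcript_id", "cpc_score", "cnci_score", "pfam_significant")
    if (!all(need %in% colnames(ev)))
        stop("evidence table must have columns: ",
             paste(need, collapse = ", "))
    ev$pfam_significant <- as.logical(ev$pfam_significant)
    if (any(!is.finite(ev$cpc_score)) || any(!is.finite(ev$cnci_score)))
        stop("coding-potential scores must be finite")
    ev
}

#' Read a qPCR cycle-threshold table
#'
#' Long format, one row per technical replicate: columns `sample_id`,
#' `condition`, `gene`, `ct`. Ct values must lie in (0, 50).
#'
#' @param path TSV path.
#' @return data.frame of Ct measurements.
#' @export
readCtTable <- function(path) {
    ct <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("sample_id", "condition", "gene", "ct")
    if (!all(need %in% colnames(ct)))
        stop("Ct table must have columns: ", paste(need, collapse = ", "))
    if (any(!is.finite(ct$ct)) || any(ct$ct <= 0) || any(ct$ct >= 50))
        stop("Ct values must lie in (0, 50)")
    ct
}
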