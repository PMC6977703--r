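#' @import methods
#' @importFrom BiocGenerics start end width strand sort unlist
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges GRangesList granges
#' @importFrom GenomeInfoDb seqnames
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom Biostrings DNAString DNAStringSet RNAString RNAStringSet
#'   reverseComplement matchPattern readDNAStringSet readRNAStringSet
#'   writeXStringSet
#' @importFrom limma lmFit eBayes
#' @importFrom stats cor cor.test p.adjust pbinom phyper rnorm runif t.test
#'   setNames
#' @importFrom utils read.delim write.table packageVersion
NULL

# ---------------------------------------------------------------------------
# ConditionExperiment
# ---------------------------------------------------------------------------

#' Expression matrix over an ordered condition series
#'
#' `ConditionExperiment` extends
#' [SummarizedExperiment::SummarizedExperiment-class] with an ordered
#' condition axis: every sample (column) belongs to one condition, and the
#' conditions themselves are ordered (for example Sham, PD, NLID, LID along a
#' disease progression). The single assay holds non-negative expression
#' values, FPKM by default; the unit is recorded in `metadata(x)$units`.
#'
#' Validity requires non-negative finite values, unique non-empty gene ids,
#' a `condition` column in `colData` whose labels all appear in the ordered
#' condition vector stored in `metadata(x)$conditionOrder`, and at least two
#' conditions in that order.
#'
#' @slot .. inherits all slots from `SummarizedExperiment`.
#' @seealso [conditionOrder()], [sampleConditions()], [conditionMeans()],
#'   [readExpressionMatrix()]
#' @export
setClass("ConditionExperiment", contains = "SummarizedExperiment")

setValidity("ConditionExperiment", function(object) {
    msg <- character()
    v <- assay(object)
    if (is.null(rownames(object)) || anyNA(rownames(object)) ||
        any(rownames(object) == ""))
        msg <- c(msg, "gene ids must be non-empty")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, sprintf("duplicate gene ids: %s",
                 paste(unique(rownames(object)[duplicated(rownames(object))]),
                       collapse = ", ")))
    if (any(!is.finite(v)))
        msg <- c(msg, "expression values must be finite")
    bad <- which(v < 0, arr.ind = TRUE)
    if (nrow(bad) > 0)
        msg <- c(msg, sprintf(
            "negative expression value at gene '%s', sample '%s'",
            rownames(v)[bad[1, 1]], colnames(v)[bad[1, 2]]))
    ord <- metadata(object)$conditionOrder
    if (is.null(ord) || length(ord) < 2)
        msg <- c(msg, "conditionOrder must list at least 2 conditions")
    if (!"condition" %in% colnames(colData(object))) {
        msg <- c(msg, "colData must contain a 'condition' column")
    } else {
        cond <- as.character(colData(object)$condition)
        if (!all(cond %in% ord))
            msg <- c(msg, sprintf("samples mapped to unknown condition(s): %s",
                     paste(setdiff(cond, ord), collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
})

#' Construct a ConditionExperiment
#'
#' @param values numeric matrix, genes x samples, with gene ids as rownames
#'   and sample ids as colnames. All values must be non-negative.
#' @param conditions character vector (or named map sample -> condition)
#'   giving each sample's condition label.
#' @param conditionOrder character vector of condition labels in their
#'   biological order (first entry is the reference condition).
#' @param units expression unit label, `"FPKM"` by default; use `"counts"`
#'   for raw counts.
#' @return A [ConditionExperiment-class] object.
#' @examples
#' m <- matrix(1:8, nrow = 2, dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
#' ce <- ConditionExperiment(m, rep(c("Sham", "LID"), each = 2),
#'                           c("Sham", "LID"))
#' conditionOrder(ce)
#' @export
ConditionExperiment <- function(values, conditions, conditionOrder,
                                units = "FPKM") {
    values <- as.matrix(values)
    if (!is.null(names(conditions)))
        conditions <- conditions[colnames(values)]
    if (length(conditions) != ncol(values))
        stop("need one condition per sample")
    if (anyNA(conditions))
        stop("sample(s) missing from the condition map: ",
             paste(colnames(values)[is.na(conditions)], collapse = ", "))
    se <- SummarizedExperiment(
        assays = list(expr = values),
        colData = DataFrame(condition = as.character(conditions),
                            row.names = colnames(values)))
    metadata(se)$conditionOrder <- as.character(conditionOrder)
    metadata(se)$units <- units
    new("ConditionExperiment", se)
}

#' @describeIn ConditionExperiment ordered condition labels
#' @param x a `ConditionExperiment`
#' @export
conditionOrder <- function(x) metadata(x)$conditionOrder

#' @describeIn ConditionExperiment named sample -> condition map
#' @export
sampleConditions <- function(x)
    setNames(as.character(colData(x)$condition), colnames(x))

#' @describeIn ConditionExperiment the expression matrix (genes x samples)
#' @export
exprValues <- function(x) assay(x, "expr")

#' @describeIn ConditionExperiment genes x conditions matrix of replicate
#'   means, columns in condition order
#' @export
conditionMeans <- function(x) {
    ord <- conditionOrder(x)
    cond <- sampleConditions(x)
    v <- exprValues(x)
    m <- vapply(ord, function(g) rowMeans(v[, cond == g, drop = FALSE]),
                numeric(nrow(v)))
    if (nrow(v) == 1L) m <- matrix(m, nrow = 1,
                                   dimnames = list(rownames(v), ord))
    m
}

setMethod("show", "ConditionExperiment", function(object) {
    cat("ConditionExperiment:", nrow(object), "genes x", ncol(object),
        "samples (", metadata(object)$units, ")\n")
    cat("condition order:", paste(conditionOrder(object), collapse = " -> "),
        "\n")
    print(table(factor(sampleConditions(object),
                       levels = conditionOrder(object))))
})

# ---------------------------------------------------------------------------
# TranscriptSet
# ---------------------------------------------------------------------------

#' Transcript models with exon structure and optional spliced sequence
#'
#' A `TranscriptSet` holds, for each transcript: its genomic span as a
#' [GenomicRanges::GRanges] anchor (with `gene_id` and `biotype` metadata
#' columns), its exons as a named [GenomicRanges::GRangesList] parallel to the
#' anchors, and optionally its spliced sense-strand sequence as a named
#' [Biostrings::DNAStringSet]. Coordinates are 1-based inclusive throughout
#' (GTF convention).
#'
#' Validity: exon lists are sorted, pairwise non-overlapping and contained in
#' the transcript span; any attached sequence has width equal to the spliced
#' (summed exon) length; biotype is one of `known_coding`, `known_lncRNA`,
#' `novel`.
#'
#' @slot anchors `GRanges` of transcript spans, named by transcript id.
#' @slot exons `GRangesList` of exons, parallel to `anchors`.
#' @slot sequences `DNAStringSet` of spliced sequences for a subset of
#'   transcripts (possibly empty).
#' @seealso [readTranscripts()], [splicedLength()], [cisTargets()]
#' @export
setClass("TranscriptSet",
    representation(anchors = "GRanges", exons = "GRangesList",
                   sequences = "DNAStringSet"))

.BIOTYPES <- c("known_coding", "known_lncRNA", "novel")

setValidity("TranscriptSet", function(object) {
    a <- object@anchors
    e <- object@exons
    s <- object@sequences
    msg <- character()
    if (is.null(names(a)) || anyDuplicated(names(a)))
        msg <- c(msg, "transcript ids must be unique and non-NULL")
    if (length(e) != length(a) || !identical(names(e), names(a)))
        msg <- c(msg, "exons must be parallel to anchors (same names)")
    if (!all(c("gene_id", "biotype") %in% colnames(mcols(a))))
        msg <- c(msg, "anchors need gene_id and biotype metadata columns")
    else if (!all(mcols(a)$biotype %in% .BIOTYPES))
        msg <- c(msg, sprintf("biotype must be one of %s",
                              paste(.BIOTYPES, collapse = ", ")))
    if (length(msg)) return(msg)
    for (i in seq_along(a)) {
        ex <- e[[i]]
        id <- names(a)[i]
        if (length(ex) == 0) {
            msg <- c(msg, sprintf("transcript '%s' has no exons", id))
            next
        }
        st <- GenomicRanges::start(ex); en <- GenomicRanges::end(ex)
        if (is.unsorted(st) || (length(ex) > 1 &&
            any(st[-1] <= en[-length(ex)])))
            msg <- c(msg, sprintf(
                "exons of '%s' must be sorted and non-overlapping", id))
        if (min(st) < GenomicRanges::start(a)[i] ||
            max(en) > GenomicRanges::end(a)[i])
            msg <- c(msg, sprintf("exon outside transcript span for '%s'", id))
    }
    if (length(s)) {
        if (is.null(names(s)) || !all(names(s) %in% names(a)))
            msg <- c(msg, "sequence names must be transcript ids")
        else {
            sl <- splicedLengthFrom(e)[names(s)]
            badlen <- Biostrings::width(s) != sl
            if (any(badlen))
                msg <- c(msg, sprintf(
                    "sequence length != spliced length for '%s'",
                    names(s)[which(badlen)[1]]))
        }
    }
    if (length(msg)) msg else TRUE
})

splicedLengthFrom <- function(exons)
    setNames(vapply(exons, function(e) sum(GenomicRanges::width(e)),
                    integer(1)), names(exons))

#' Construct a TranscriptSet
#'
#' @param anchors named `GRanges` of transcript spans with `gene_id` and
#'   `biotype` metadata columns.
#' @param exons named `GRangesList` of exons, parallel to `anchors`.
#' @param sequences optional named `DNAStringSet` of spliced sequences.
#' @return A [TranscriptSet-class].
#' @export
TranscriptSet <- function(anchors, exons,
                          sequences = Biostrings::DNAStringSet()) {
    new("TranscriptSet", anchors = anchors, exons = exons,
        sequences = sequences)
}

#' @describeIn TranscriptSet transcript identifiers
#' @param x a `TranscriptSet`
#' @export
transcriptIds <- function(x) names(x@anchors)

#' @describeIn TranscriptSet named vector of gene ids
#' @export
geneIds <- function(x) setNames(mcols(x@anchors)$gene_id, names(x@anchors))

#' @describeIn TranscriptSet spliced (summed exon) length per transcript, nt
#' @export
splicedLength <- function(x) splicedLengthFrom(x@exons)

#' @describeIn TranscriptSet number of exons per transcript
#' @export
exonCount <- function(x)
    setNames(lengths(x@exons), names(x@anchors))

#' @describeIn TranscriptSet transcript span `GRanges`
#' @export
transcriptAnchors <- function(x) x@anchors

#' @describeIn TranscriptSet exon `GRangesList`
#' @export
transcriptExons <- function(x) x@exons

#' @describeIn TranscriptSet spliced sequences (`DNAStringSet`, may be empty)
#' @export
transcriptSequences <- function(x) x@sequences

setMethod("show", "TranscriptSet", function(object) {
    cat("TranscriptSet:", length(object@anchors), "transcripts,",
        length(object@sequences), "with sequence\n")
    print(table(mcols(object@anchors)$biotype))
})

setMethod("length", "TranscriptSet", function(x) length(x@anchors))

#' Subset a TranscriptSet by transcript id or index
#' @param x a `TranscriptSet`
#' @param i character ids or indices
#' @param j,...,drop ignored
#' @export
setMethod("[", "TranscriptSet", function(x, i, j, ..., drop = FALSE) {
    ids <- if (is.character(i)) i else names(x@anchors)[i]
    TranscriptSet(x@anchors[ids], x@exons[ids],
                  x@sequences[intersect(names(x@sequences), ids)])
})

# ---------------------------------------------------------------------------
# ModelProfileSet
# ---------------------------------------------------------------------------

#' Candidate model expression profiles over an ordered condition series
#'
#' A `ModelProfileSet` enumerates the integer-valued candidate expression
#' shapes over `T` ordered conditions used by short-series profile
#' clustering: every profile starts at 0 and moves by at most `maxStep`
#' units between successive conditions. With the flat (all-zero) profile
#' excluded the set has `(2*maxStep + 1)^(T - 1) - 1` members; for four
#' conditions and unit steps that is the classical 26-profile set.
#'
#' Profile ids are stable: profiles are stored in lexicographic order of
#' their vectors and identified as `P01`, `P02`, ...
#'
#' @slot profiles integer matrix, profiles x conditions.
#' @slot nConditions number of ordered conditions `T`.
#' @slot maxStep maximum unit change between successive conditions.
#' @slot excludeFlat whether the all-zero profile was excluded.
#' @seealso [enumerateProfiles()], [assignProfiles()]
#' @export
setClass("ModelProfileSet",
    representation(profiles = "matrix", nConditions = "integer",
                   maxStep = "integer", excludeFlat = "logical"))

setValidity("ModelProfileSet", function(object) {
    p <- object@profiles
    msg <- character()
    if (ncol(p) != object@nConditions)
        msg <- c(msg, "profile length must equal nConditions")
    if (any(p[, 1] != 0))
        msg <- c(msg, "profiles must start at 0")
    if (ncol(p) > 1) {
        d <- p[, -1, drop = FALSE] - p[, -ncol(p), drop = FALSE]
        if (any(abs(d) > object@maxStep))
            msg <- c(msg, "successive changes must be within maxStep")
    }
    if (anyDuplicated(p))
        msg <- c(msg, "profiles must be distinct")
    if (object@excludeFlat && any(rowSums(p != 0) == 0))
        msg <- c(msg, "flat profile present despite excludeFlat")
    expected <- (2L * object@maxStep + 1L)^(object@nConditions - 1L) -
        as.integer(object@excludeFlat)
    if (nrow(p) != expected)
        msg <- c(msg, sprintf("expected %d profiles, found %d",
                              expected, nrow(p)))
    if (length(msg)) msg else TRUE
})

#' @describeIn ModelProfileSet profiles x conditions integer matrix, rownames
#'   are the stable profile ids
#' @param x a `ModelProfileSet`
#' @export
profileMatrix <- function(x) x@profiles

#' @describeIn ModelProfileSet number of profiles
#' @export
nProfiles <- function(x) nrow(x@profiles)

#' @describeIn ModelProfileSet stable profile ids
#' @export
profileIds <- function(x) rownames(x@profiles)

#' @describeIn ModelProfileSet id of the profile equal to `shape`, or an
#'   error when `shape` is not in the set
#' @param shape integer vector of length `T` starting at 0
#' @export
matchProfile <- function(x, shape) {
    shape <- as.integer(shape)
    if (length(shape) != x@nConditions)
        stop("shape length must equal the number of conditions")
    hit <- which(apply(x@profiles, 1, identical, shape))
    if (length(hit) == 0)
        stop("shape [", paste(shape, collapse = ","),
             "] is not in the profile set")
    rownames(x@profiles)[hit]
}

setMethod("show", "ModelProfileSet", function(object) {
    cat("ModelProfileSet:", nrow(object@profiles), "profiles over",
        object@nConditions, "ordered conditions (maxStep =", object@maxStep,
        if (object@excludeFlat) ", flat excluded" else "", ")\n")
})
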