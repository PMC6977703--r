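# Differential-expression thresholding (fold change + FDR) and Fisher-exact
# term enrichment over a supplied annotation table.

#' Benjamini-Hochberg FDR adjustment
#'
#' Thin validated wrapper over `stats::p.adjust(method = "BH")`: input order
#' is preserved and q-values follow the step-up definition
#' `q_i = min_{j >= rank(i)} m * p_(j) / j`.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values, same length and order as `p`.
#' @export
bhAdjust <- function(p) {
    if (length(p) == 0) stop("empty p-value vector")
    if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
        stop("p-values must lie in [0, 1]")
    p.adjust(p, method = "BH")
}

# Welch t on log2(value + 1); degenerate (constant) groups fall back to
# p = 1 for equal means, p = 0 for perfectly separated means.
.welchP <- function(a, b) {
    la <- log2(a + 1); lb <- log2(b + 1)
    if (stats::var(la) < .Machine$double.eps &&
        stats::var(lb) < .Machine$double.eps) {
        return(if (isTRUE(all.equal(mean(la), mean(lb)))) 1 else 0)
    }
    t.test(la, lb)$p.value
}

# limma moderated t on log2(value + 1); non-finite p (all-constant input)
# falls back to 1
.moderatedP <- function(va, vb) {
    m <- log2(cbind(va, vb) + 1)
    grp <- factor(rep(c("A", "B"), c(ncol(va), ncol(vb))))
    design <- stats::model.matrix(~grp)
    fit <- limma::eBayes(limma::lmFit(m, design))
    p <- fit$p.value[, 2]
    p[!is.finite(p)] <- 1
    unname(p)
}

#' Differential-expression screen between two conditions
#'
#' Computes a per-gene log2 fold change from condition means with a
#' pseudocount, obtains a p-value, adjusts with Benjamini-Hochberg, and
#' flags genes passing both the fold-change and the FDR threshold. The
#' default p-value source is limma's moderated t on log2(value + 1) —
#' the standard choice at small replicate counts, where per-gene variance
#' estimates are unstable; a plain Welch t is available, as is a
#' user-supplied table of externally computed p-values (for example from a
#' negative-binomial count model). The thresholding logic is the screen
#' proper and is identical across p-value sources.
#'
#' @param x a [ConditionExperiment-class].
#' @param groupA,groupB condition labels; fold change is B relative to A.
#' @param fcThreshold fold-change threshold on the linear scale, >= 1
#'   (default 2, i.e. |log2FC| >= 1).
#' @param fdrThreshold BH q-value threshold (default 0.05).
#' @param pValues optional named numeric vector of per-gene p-values; must
#'   cover every gene in `x` and overrides `pSource`.
#' @param pSource built-in p-value source: `"moderated"` (limma, default)
#'   or `"welch_t"`; both require >= 2 replicates per group.
#' @param pseudocount added to condition means before the ratio (default 1).
#' @param direction `"both"` (|log2FC|), `"up"` or `"down"` for one-sided
#'   fold-change screening.
#' @return data.frame with columns `gene_id`, `log2_fold_change`, `p_value`,
#'   `q_value`, `passes`.
#' @export
deScreen <- function(x, groupA, groupB, fcThreshold = 2,
                     fdrThreshold = 0.05, pValues = NULL,
                     pSource = c("moderated", "welch_t"), pseudocount = 1,
                     direction = c("both", "up", "down")) {
    direction <- match.arg(direction)
    pSource <- match.arg(pSource)
    if (fcThreshold < 1) stop("fcThreshold must be >= 1")
    ord <- conditionOrder(x)
    if (!all(c(groupA, groupB) %in% ord))
        stop("unknown condition: ",
             paste(setdiff(c(groupA, groupB), ord), collapse = ", "))
    cond <- sampleConditions(x)
    v <- exprValues(x)
    va <- v[, cond == groupA, drop = FALSE]
    vb <- v[, cond == groupB, drop = FALSE]
    lfc <- log2((rowMeans(vb) + pseudocount) / (rowMeans(va) + pseudocount))
    if (is.null(pValues)) {
        if (ncol(va) < 2 || ncol(vb) < 2)
            stop("built-in tests need >= 2 replicates per group")
        p <- if (pSource == "moderated") .moderatedP(va, vb)
        else vapply(seq_len(nrow(v)),
                    function(i) .welchP(va[i, ], vb[i, ]), numeric(1))
    } else {
        missing <- setdiff(rownames(v), names(pValues))
        if (length(missing))
            stop("supplied p-value table missing gene(s): ",
                 paste(utils::head(missing, 5), collapse = ", "))
        p <- unname(pValues[rownames(v)])
    }
    q <- bhAdjust(p)
    fcPass <- switch(direction,
        both = abs(lfc) >= log2(fcThreshold),
        up   = lfc >= log2(fcThreshold),
        down = lfc <= -log2(fcThreshold))
    data.frame(gene_id = rownames(v), log2_fold_change = unname(lfc),
               p_value = p, q_value = q,
               passes = fcPass & q <= fdrThreshold,
               stringsAsFactors = FALSE)
}

#' Fisher-exact (hypergeometric) term enrichment
#'
#' One-sided over-representation test per term: with `N` background genes of
#' which `K` carry the term, and `n` study genes of which `k` carry it, the
#' p-value is the upper hypergeometric tail `P(X >= k)`. Annotation genes
#' outside the background are ignored; the study set must be a subset of the
#' background.
#'
#' @param studyGenes character vector of study gene ids.
#' @param backgroundGenes character vector of background gene ids.
#' @param annotation data.frame with columns `term_id`, `gene_id`.
#' @param alpha significance level used for the `significant` flag
#'   (default 0.05; raw p-values, no cross-term correction).
#' @return data.frame with columns `term_id`, `k`, `n`, `K`, `N`,
#'   `p_value`, `significant`, ordered by p-value.
#' @export
enrichTerms <- function(studyGenes, backgroundGenes, annotation,
                        alpha = 0.05) {
    backgroundGenes <- unique(backgroundGenes)
    studyGenes <- unique(studyGenes)
    if (length(backgroundGenes) == 0) stop("empty background gene set")
    if (!all(studyGenes %in% backgroundGenes))
        stop("study genes must be a subset of the background")
    if (!all(c("term_id", "gene_id") %in% colnames(annotation)))
        stop("annotation must have columns term_id, gene_id")
    ann <- annotation[annotation$gene_id %in% backgroundGenes, , drop = FALSE]
    N <- length(backgroundGenes)
    n <- length(studyGenes)
    bySet <- split(unique(ann)[["gene_id"]], unique(ann)[["term_id"]])
    res <- lapply(names(bySet), function(term) {
        g <- bySet[[term]]
        K <- length(g)
        k <- sum(g %in% studyGenes)
        data.frame(term_id = term, k = k, n = n, K = K, N = N,
                   p_value = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    out <- out[order(out$p_value, out$term_id), , drop = FALSE]
    out$significant <- out$p_value < alpha
    rownames(out) <- NULL
    out
}
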