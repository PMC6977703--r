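# qRT-PCR relative quantification (2^-ddCt) and Pearson correlation for
# validation against behavioral scores.

#' 2^-ddCt relative quantification
#'
#' Technical replicates are averaged on the Ct scale (arithmetic mean). Per
#' sample, `dCt = mean Ct(target) - mean Ct(reference)`; `ddCt = dCt - mean
#' dCt` of the calibrator condition; the relative quantity is `2^-ddCt`. By
#' construction the geometric mean of the calibrator condition's relative
#' quantities is 1, and the result is invariant to adding a constant to
#' every Ct of both genes.
#'
#' @param ct long-format Ct table: columns `sample_id`, `condition`,
#'   `gene`, `ct`, one row per technical replicate (see [readCtTable()]).
#' @param targetGene gene to quantify.
#' @param referenceGene normalization gene (e.g. `"GAPDH"`); every sample
#'   carrying the target must also carry the reference.
#' @param calibratorCondition condition whose mean dCt anchors ddCt
#'   (default `"Sham"`).
#' @return data.frame with columns `sample_id`, `condition`, `gene`,
#'   `delta_ct`, `delta_delta_ct`, `rq`.
#' @export
ddCt <- function(ct, targetGene, referenceGene,
                 calibratorCondition = "Sham") {
    tg <- ct[ct$gene == targetGene, , drop = FALSE]
    rf <- ct[ct$gene == referenceGene, , drop = FALSE]
    if (nrow(tg) == 0) stop("no Ct measurements for target '",
                            targetGene, "'")
    samples <- unique(tg$sample_id)
    noRef <- setdiff(samples, unique(rf$sample_id))
    if (length(noRef))
        stop("missing reference gene measurement for sample(s): ",
             paste(noRef, collapse = ", "))
    mt <- tapply(tg$ct, tg$sample_id, mean)
    mr <- tapply(rf$ct, rf$sample_id, mean)
    cond <- tapply(as.character(tg$condition), tg$sample_id,
                   function(z) z[1])
    dct <- mt[samples] - mr[samples]
    calib <- samples[cond[samples] == calibratorCondition]
    if (length(calib) == 0)
        stop("no sample in calibrator condition '", calibratorCondition, "'")
    ddct <- dct - mean(dct[calib])
    data.frame(sample_id = samples, condition = unname(cond[samples]),
               gene = targetGene, delta_ct = unname(dct),
               delta_delta_ct = unname(ddct), rq = unname(2^(-ddct)),
               stringsAsFactors = FALSE)
}

#' Pearson correlation between expression and a per-animal score
#'
#' Standard Pearson r with a two-sided t-distribution p-value, as used to
#' relate striatal expression levels to dyskinesia (AIM) scores.
#'
#' @param values numeric vector (e.g. relative expression per animal).
#' @param scores numeric vector of the same length (>= 3), e.g. AIM scores.
#' @return list with elements `r`, `p_value`, `n`.
#' @export
pearsonWithScore <- function(values, scores) {
    if (length(values) != length(scores)) stop("length mismatch")
    if (length(values) < 3) stop("need at least 3 paired observations")
    if (any(!is.finite(values)) || any(!is.finite(scores)))
        stop("values and scores must be finite")
    if (stats::var(values) == 0 || stats::var(scores) == 0)
        stop("zero variance in values or scores")
    ht <- cor.test(values, scores, method = "pearson")
    list(r = unname(ht$estimate), p_value = ht$p.value, n = length(values))
}
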