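# Short-series model-profile clustering over an ordered condition axis:
# enumerate candidate shapes, assign genes by Pearson similarity, score
# per-profile gene counts against a condition-permutation null.

#' Enumerate candidate model profiles
#'
#' Exhaustively enumerates all integer vectors of length `nConditions` that
#' start at 0 and change by at most `maxStep` units between successive
#' conditions; optionally drops the flat (all-zero) profile. The count obeys
#' the closed form `(2*maxStep + 1)^(nConditions - 1) - excludeFlat`; for
#' four conditions, unit steps and no flat profile this yields the classical
#' set of 26 model profiles. Ids are assigned in lexicographic order of the
#' profile vectors and are stable across calls.
#'
#' @param nConditions number of ordered conditions, >= 2.
#' @param maxStep maximum unit change between successive conditions, >= 1.
#' @param excludeFlat drop the all-zero profile (default `TRUE`).
#' @return A [ModelProfileSet-class].
#' @examples
#' nProfiles(enumerateProfiles(4, 1, TRUE))  # 26
#' @export
enumerateProfiles <- function(nConditions, maxStep = 1, excludeFlat = TRUE) {
    if (nConditions < 2) stop("nConditions must be >= 2")
    if (maxStep < 1) stop("maxStep must be >= 1")
    nConditions <- as.integer(nConditions)
    maxStep <- as.integer(maxStep)
    steps <- seq.int(-maxStep, maxStep)
    diffs <- as.matrix(expand.grid(rep(list(steps), nConditions - 1L),
                                   KEEP.OUT.ATTRS = FALSE))
    prof <- cbind(0L, t(apply(diffs, 1, cumsum)))
    if (nConditions == 2L) prof <- cbind(0L, diffs[, 1])
    storage.mode(prof) <- "integer"
    if (excludeFlat)
        prof <- prof[rowSums(prof != 0) > 0, , drop = FALSE]
    prof <- prof[do.call(order, as.data.frame(prof)), , drop = FALSE]
    dimnames(prof) <- list(
        sprintf("P%0*d", nchar(nrow(prof)), seq_len(nrow(prof))),
        NULL)
    new("ModelProfileSet", profiles = prof, nConditions = nConditions,
        maxStep = maxStep, excludeFlat = excludeFlat)
}

#' Collapse an expression matrix to per-gene log2-ratio series
#'
#' Replicates are first collapsed to condition means, then each gene's
#' series is expressed as log2 ratios relative to the first (reference)
#' condition: `series[t] = log2((mean[t] + pseudocount) / (mean[1] +
#' pseudocount))`. The first element is exactly 0 by construction and the
#' pseudocount keeps the transform defined at zero expression.
#'
#' @param x a [ConditionExperiment-class].
#' @param pseudocount positive constant added before the ratio (default 1).
#' @return numeric matrix, genes x conditions, of log2 ratios; first column
#'   all zero.
#' @export
toLog2Series <- function(x, pseudocount = 1) {
    if (pseudocount <= 0) stop("pseudocount must be > 0")
    m <- conditionMeans(x) + pseudocount
    s <- log2(m / m[, 1])
    s[, 1] <- 0
    s
}

# Pearson correlation of every series row against every profile row.
# Rows with zero variance get NA.
.profileCor <- function(series, profiles) {
    T <- ncol(series)
    zrow <- function(m) {
        c <- m - rowMeans(m)
        sd <- sqrt(rowSums(c^2))
        sd[sd == 0] <- NA_real_
        c / sd
    }
    zs <- zrow(series)
    zp <- zrow(profiles)
    zs %*% t(zp)
}

#' Assign genes to their best-matching model profile
#'
#' Each gene's log2-ratio series is matched to the candidate profile with
#' the highest Pearson correlation; ties go to the smallest profile id.
#' Genes with a zero-variance (flat) series, or whose best similarity falls
#' below `minSimilarity`, are returned unassigned with a reason code.
#'
#' @param series genes x conditions log2-ratio matrix (see [toLog2Series()]).
#' @param profiles a [ModelProfileSet-class] with matching `nConditions`.
#' @param minSimilarity minimum Pearson similarity to accept an assignment
#'   (default 0; every non-degenerate gene is assigned).
#' @return data.frame with columns `gene_id`, `profile_id` (NA when
#'   unassigned), `similarity`, `reason` (`assigned`, `zero_variance`, or
#'   `below_threshold`).
#' @export
assignProfiles <- function(series, profiles, minSimilarity = 0) {
    pm <- profileMatrix(profiles)
    if (ncol(series) != ncol(pm))
        stop("series length (", ncol(series),
             ") does not match the profile set (", ncol(pm), " conditions)")
    cors <- .profileCor(series, pm)
    n <- nrow(series)
    out <- data.frame(gene_id = if (is.null(rownames(series)))
                          as.character(seq_len(n)) else rownames(series),
                      profile_id = rep(NA_character_, n),
                      similarity = rep(NA_real_, n),
                      reason = rep("zero_variance", n),
                      stringsAsFactors = FALSE)
    if (n == 0) return(out)
    ok <- !apply(is.na(cors), 1, all)
    if (any(ok)) {
        sub <- cors[ok, , drop = FALSE]
        sub[is.na(sub)] <- -Inf  # zero-variance profiles never win
        best <- apply(sub, 1, which.max)  # first max = smallest profile id
        sim <- sub[cbind(seq_len(nrow(sub)), best)]
        pass <- sim >= minSimilarity
        out$similarity[ok] <- sim
        out$profile_id[ok][pass] <- rownames(pm)[best][pass]
        out$reason[ok] <- ifelse(pass, "assigned", "below_threshold")
    }
    out
}

# all permutations of 1..n, one per row, in lexicographic order
.allPerms <- function(n) {
    if (n == 1L) return(matrix(1L, 1, 1))
    sub <- .allPerms(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(k) {
        rest <- seq_len(n)[-k]
        cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
    }))
}

#' Permutation significance of per-profile gene counts
#'
#' Builds a null for the number of genes assigned to each profile by
#' permuting the condition order of every gene's series, re-referencing so
#' the first element of the permuted series is 0, and re-running the
#' assignment. The expected count per profile is the mean assigned count
#' across permutations and the p-value is the upper-tail binomial
#' probability of at least the observed count in `n` genes with success
#' probability `expected / n`. For four conditions the exhaustive null has
#' 4! = 24 permutations; the identity permutation is included by default
#' (conservative).
#'
#' @param assignments output of [assignProfiles()] on the observed series.
#' @param series the genes x conditions log2-ratio matrix.
#' @param profiles the [ModelProfileSet-class] used for assignment.
#' @param permutations `"exhaustive"` (all `T!` permutations) or an integer
#'   number of sampled permutations (>= 10).
#' @param seed RNG seed for sampled permutations.
#' @param includeIdentity include the identity permutation in the null
#'   average (default `TRUE`).
#' @param minSimilarity passed through to the re-assignment.
#' @return data.frame with columns `profile_id`, `observed`, `expected`,
#'   `p_value`, ordered by profile id.
#' @export
profileSignificance <- function(assignments, series, profiles,
                                permutations = "exhaustive", seed = NULL,
                                includeIdentity = TRUE, minSimilarity = 0) {
    if (!any(!is.na(assignments$profile_id)))
        stop("no assigned genes")
    T <- ncol(series)
    n <- nrow(series)
    ids <- profileIds(profiles)
    if (identical(permutations, "exhaustive")) {
        perms <- .allPerms(T)
    } else {
        nd <- as.integer(permutations)
        if (is.na(nd) || nd < 10)
            stop("sampled mode needs at least 10 permutation draws")
        if (!is.null(seed)) set.seed(seed)
        perms <- t(vapply(seq_len(nd), function(i) sample.int(T),
                          integer(T)))
    }
    if (!includeIdentity) {
        keep <- rowSums(perms != matrix(seq_len(T), nrow(perms), T,
                                        byrow = TRUE)) > 0
        perms <- perms[keep, , drop = FALSE]
    }
    countOf <- function(a) {
        tab <- table(factor(a$profile_id, levels = ids))
        as.numeric(tab)
    }
    nullCounts <- vapply(seq_len(nrow(perms)), function(i) {
        p <- perms[i, ]
        sp <- series[, p, drop = FALSE] - series[, p[1]]
        countOf(assignProfiles(sp, profiles, minSimilarity))
    }, numeric(length(ids)))
    expected <- rowMeans(nullCounts)
    observed <- countOf(assignments)
    pval <- pbinom(observed - 1, size = n, prob = pmin(expected / n, 1),
                   lower.tail = FALSE)
    data.frame(profile_id = ids, observed = observed, expected = expected,
               p_value = pval, stringsAsFactors = FALSE)
}

#' Select the genes following a target expression shape
#'
#' Returns the genes assigned to the profile whose shape equals
#' `targetShape` (for example `c(0, -1, -1, -2)`, the monotone decrease
#' across Sham -> PD -> NLID -> LID), together with that profile's
#' permutation significance.
#'
#' @param assignments output of [assignProfiles()].
#' @param significance output of [profileSignificance()].
#' @param profiles the [ModelProfileSet-class].
#' @param targetShape integer vector present in the profile set.
#' @param alpha significance level (default 0.05).
#' @return list with `genes` (character vector), `profile_id`, `p_value`,
#'   and `significant` (logical, `p_value < alpha`).
#' @export
selectPatternGenes <- function(assignments, significance, profiles,
                               targetShape, alpha = 0.05) {
    pid <- matchProfile(profiles, targetShape)
    genes <- assignments$gene_id[!is.na(assignments$profile_id) &
                                 assignments$profile_id == pid]
    p <- significance$p_value[significance$profile_id == pid]
    list(genes = genes, profile_id = pid,
         p_value = if (length(p)) p else NA_real_,
         significant = length(p) > 0 && is.finite(p) && p < alpha)
}
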