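# End-to-end orchestration: screen -> profile dynamics -> lncRNA filter ->
# networks -> target prediction -> enrichment, on synthetic or user data,
# with every intermediate written as TSV and a JSON run manifest.

#' Build and validate a pipeline configuration
#'
#' All thresholds of the analysis chain in one validated object. In
#' synthetic mode the generators supply every input; otherwise file paths
#' are read with the package readers and stages without inputs are skipped.
#'
#' @param outDir output directory (created if needed).
#' @param seed integer master seed; all stage seeds derive from it.
#' @param synthetic generate all inputs with the synthetic module.
#' @param conditionOrder ordered condition labels.
#' @param screenGroups length-2 character vector: the two conditions
#'   contrasted by the DE screen (default first and last of the order).
#' @param fcThreshold,fdrThreshold DE screen thresholds (defaults 2, 0.05).
#' @param maxStep,excludeFlat model-profile enumeration parameters
#'   (defaults 1, `TRUE`, giving 26 profiles for four conditions).
#' @param targetShape integer shape whose genes are selected (default
#'   `c(0, -1, -1, -2)`, the monotone decrease).
#' @param alpha profile/enrichment significance level (default 0.05).
#' @param profileOn `"screened"` (default) profiles only genes passing the
#'   DE screen; `"all"` profiles every gene.
#' @param rThreshold co-expression edge threshold (default 0.99).
#' @param percentile ceRNA correlation-pool percentile (default 99).
#' @param windowBp cis-target window (default 10000).
#' @param transMinScore,transScreenKmer trans-target thresholds
#'   (defaults 15, 12).
#' @param minLen,minExons,maxOrf lncRNA filter thresholds
#'   (defaults 200, 2, 300).
#' @param matrixPath,conditionMap,gtfPath,fastaPath,evidencePath,mirnaPath,
#'   annotationTermsPath input paths for non-synthetic runs (`conditionMap`
#'   is a named sample -> condition vector).
#' @param syntheticDemo parameters of the synthetic demo instance; see
#'   [demoConfig()].
#' @return validated config list (class `pipeline_config`).
#' @export
pipelineConfig <- function(outDir, seed = 1, synthetic = FALSE,
                           conditionOrder = c("Sham", "PD", "NLID", "LID"),
                           screenGroups = NULL, fcThreshold = 2,
                           fdrThreshold = 0.05, maxStep = 1,
                           excludeFlat = TRUE,
                           targetShape = c(0, -1, -1, -2), alpha = 0.05,
                           profileOn = c("screened", "all"),
                           rThreshold = 0.99, percentile = 99,
                           windowBp = 10000, transMinScore = 15,
                           transScreenKmer = 12, minLen = 200, minExons = 2,
                           maxOrf = 300, matrixPath = NULL,
                           conditionMap = NULL, gtfPath = NULL,
                           fastaPath = NULL, evidencePath = NULL,
                           mirnaPath = NULL, annotationTermsPath = NULL,
                           syntheticDemo = list()) {
    profileOn <- match.arg(profileOn)
    if (length(conditionOrder) < 2) stop("need at least 2 conditions")
    if (is.null(screenGroups))
        screenGroups <- c(conditionOrder[1],
                          conditionOrder[length(conditionOrder)])
    if (!all(screenGroups %in% conditionOrder))
        stop("screenGroups must be conditions of conditionOrder")
    if (percentile <= 0 || percentile > 100)
        stop("percentile must lie in (0, 100]")
    if (fcThreshold < 1) stop("fcThreshold must be >= 1")
    if (fdrThreshold <= 0 || fdrThreshold > 1)
        stop("fdrThreshold must lie in (0, 1]")
    if (rThreshold < -1 || rThreshold > 1)
        stop("rThreshold must lie in [-1, 1]")
    if (windowBp < 0) stop("windowBp must be >= 0")
    if (maxStep < 1) stop("maxStep must be >= 1")
    if (length(targetShape) != length(conditionOrder) || targetShape[1] != 0)
        stop("targetShape must start at 0 and span the condition order")
    if (!synthetic && is.null(matrixPath))
        stop("either synthetic mode or a matrixPath is required")
    cfg <- list(outDir = outDir, seed = as.integer(seed),
                synthetic = synthetic, conditionOrder = conditionOrder,
                screenGroups = screenGroups, fcThreshold = fcThreshold,
                fdrThreshold = fdrThreshold, maxStep = as.integer(maxStep),
                excludeFlat = excludeFlat,
                targetShape = as.integer(targetShape), alpha = alpha,
                profileOn = profileOn, rThreshold = rThreshold,
                percentile = percentile, windowBp = windowBp,
                transMinScore = transMinScore,
                transScreenKmer = transScreenKmer, minLen = minLen,
                minExons = minExons, maxOrf = maxOrf,
                matrixPath = matrixPath, conditionMap = conditionMap,
                gtfPath = gtfPath, fastaPath = fastaPath,
                evidencePath = evidencePath, mirnaPath = mirnaPath,
                annotationTermsPath = annotationTermsPath,
                syntheticDemo = syntheticDemo)
    structure(cfg, class = "pipeline_config")
}

#' Configuration of the synthetic demonstration run
#'
#' The demo instance plants known structure at a fixed, documented scale:
#' 50 genes on the monotone-decreasing shape (log2 noise sd 0.2, base
#' 10 FPKM) among 1000 flat background genes over 4 conditions x 3
#' replicates; 5 ceRNA triplets among 25 lncRNAs x 25 mRNAs (planted
#' expression pairs exactly proportional, so pair correlations are
#' noise-free); 5 cis pairs inside and 5 beyond the 10-kb window; and 4
#' candidate plus 6 rule-violating novel transcripts.
#'
#' @param seed master seed (default 1).
#' @param outDir output directory.
#' @return a [pipelineConfig()] object in synthetic mode.
#' @export
demoConfig <- function(seed = 1, outDir = tempfile("cerna_demo_")) {
    pipelineConfig(
        outDir = outDir, seed = seed, synthetic = TRUE,
        syntheticDemo = list(
            nPlanted = 50, plantedBase = 10, noiseSd = 0.2,
            nBackground = 1000, replicates = 3,
            nLncrnas = 25, nMrnas = 25, nMirnas = 8, plantedTriplets = 5,
            seqLength = 500, nCisWithin = 5, nCisBeyond = 5,
            nCandidates = 4, nRejects = 6))
}

.writeTsv <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}

#' Run the full analysis pipeline
#'
#' Executes, in order: differential-expression screen, model-profile
#' dynamics (on the screened set by default), lncRNA candidate filtering,
#' co-expression plus ceRNA network inference, cis/trans target prediction,
#' and term enrichment of the selected pattern genes. Every intermediate is
#' written as TSV under `config$outDir` and a JSON manifest records the
#' run. When profiling is restricted to the screened set and no gene passes
#' the screen, the profiling stage falls back to the full gene set. The
#' configuration hash, seed and per-stage status. Identical config and seed
#' give byte-identical output trees. A stage whose inputs are absent (only
#' possible outside synthetic mode) is recorded as skipped; any stage error
#' aborts the run naming the stage.
#'
#' @param config a [pipelineConfig()] object.
#' @return invisibly, a list with `manifest` (what was written) and
#'   `results` (the in-memory stage outputs).
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "pipeline_config"))
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    inDir <- file.path(config$outDir, "inputs")
    dir.create(inDir, showWarnings = FALSE)
    res <- list()
    stages <- list()
    note <- function(name, status, outputs = character(0))
        stages[[length(stages) + 1]] <<- list(name = name, status = status,
                                              outputs = as.list(outputs))
    withStage <- function(name, expr)
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE))

    # ---- inputs -----------------------------------------------------------
    if (config$synthetic) {
        d <- config$syntheticDemo
        des <- syntheticDesign(
            conditionOrder = config$conditionOrder,
            replicates = d$replicates, nBackground = d$nBackground,
            planted = list(list(shape = config$targetShape,
                                nGenes = d$nPlanted, base = d$plantedBase,
                                noiseSd = d$noiseSd)),
            seed = config$seed)
        ex <- syntheticExpression(des)
        sq <- syntheticSequences(d$nLncrnas, d$nMrnas, d$nMirnas,
                                 d$plantedTriplets, d$seqLength,
                                 seed = config$seed + 1L)
        an <- syntheticAnnotation(d$nCisWithin, d$nCisBeyond,
                                  seed = config$seed + 2L,
                                  window = config$windowBp)
        tr <- syntheticTranscripts(d$nCandidates, d$nRejects,
                                   seed = config$seed + 3L)
        # ceRNA expression block: planted pairs exactly proportional
        # (noise-free correlation), background genes independent noise
        set.seed(config$seed + 4L)
        ns <- ncol(ex$expression)
        cm <- matrix(0, d$nLncrnas + d$nMrnas, ns)
        shapePerSample <- rep(config$targetShape,
                              each = d$replicates)
        for (i in seq_len(d$nLncrnas))
            cm[i, ] <- d$plantedBase *
                2^(shapePerSample + rnorm(ns, 0, d$noiseSd))
        for (i in seq_len(d$nMrnas)) {
            cm[d$nLncrnas + i, ] <- if (i <= d$plantedTriplets)
                0.8 * cm[i, ] else 2^runif(1, 1, 6) * 2^rnorm(ns, 0, 0.3)
        }
        rownames(cm) <- c(names(sq$lncrnas), names(sq$mrnas))
        colnames(cm) <- colnames(ex$expression)
        allv <- rbind(exprValues(ex$expression), cm)
        mat <- ConditionExperiment(allv, sampleConditions(ex$expression),
                                   config$conditionOrder)
        lncIds <- names(sq$lncrnas)
        mrnaIds <- names(sq$mrnas)
        mirnas <- sq$mirnas
        sequences <- c(sq$lncrnas, sq$mrnas)
        cisLnc <- an$lncrnas
        cisGenes <- an$genes
        novel <- tr$transcripts
        evidence <- tr$evidence
        # term table: one term collecting the planted genes, plus
        # size-matched random terms over the background
        set.seed(config$seed + 5L)
        bg <- rownames(allv)
        terms <- rbind(
            data.frame(term_id = "TERM_PLANTED",
                       gene_id = ex$truth$gene_id,
                       stringsAsFactors = FALSE),
            do.call(rbind, lapply(1:5, function(k)
                data.frame(term_id = sprintf("TERM_RAND%d", k),
                           gene_id = sample(bg, 50),
                           stringsAsFactors = FALSE))))
        writeExpressionMatrix(mat, file.path(inDir, "expression.tsv"))
        writeXStringSet(sq$lncrnas, file.path(inDir, "lncrnas.fa"))
        writeXStringSet(sq$mrnas, file.path(inDir, "mrnas.fa"))
        writeXStringSet(sq$mirnas, file.path(inDir, "mirnas.fa"))
        writeGtf(cisLnc, file.path(inDir, "cis_lncrnas.gtf"))
        writeGtf(cisGenes, file.path(inDir, "cis_genes.gtf"))
        writeGtf(novel, file.path(inDir, "novel_transcripts.gtf"))
        .writeTsv(evidence, file.path(inDir, "coding_evidence.tsv"))
        .writeTsv(terms, file.path(inDir, "term_annotation.tsv"))
        truth <- list(profiles = ex$truth, triplets = sq$truth,
                      cis = an$truth, lncrna = tr$truth)
        .writeTsv(ex$truth, file.path(inDir, "truth_profiles.tsv"))
        .writeTsv(sq$truth, file.path(inDir, "truth_triplets.tsv"))
        .writeTsv(an$truth, file.path(inDir, "truth_cis.tsv"))
        .writeTsv(tr$truth, file.path(inDir, "truth_lncrna.tsv"))
        res$truth <- truth
    } else {
        mat <- readExpressionMatrix(config$matrixPath, config$conditionMap,
                                    config$conditionOrder)
        mirnas <- if (!is.null(config$mirnaPath))
            readMiRNA(config$mirnaPath) else NULL
        sequences <- if (!is.null(config$fastaPath)) {
            s <- readDNAStringSet(config$fastaPath)
            names(s) <- sub("\\s.*$", "", names(s))
            s
        } else NULL
        lncIds <- mrnaIds <- NULL
        cisLnc <- cisGenes <- novel <- evidence <- NULL
        if (!is.null(config$gtfPath)) {
            novel <- readTranscripts(config$gtfPath, config$fastaPath)
        }
        if (!is.null(config$evidencePath))
            evidence <- readCodingEvidence(config$evidencePath)
        terms <- if (!is.null(config$annotationTermsPath))
            read.delim(config$annotationTermsPath,
                       stringsAsFactors = FALSE) else NULL
    }
    res$expression <- mat

    # ---- stage 1: DE screen ----------------------------------------------
    de <- withStage("expression_screen",
        deScreen(mat, config$screenGroups[1], config$screenGroups[2],
                 fcThreshold = config$fcThreshold,
                 fdrThreshold = config$fdrThreshold))
    f <- .writeTsv(de, file.path(config$outDir, "de_screen.tsv"))
    note("expression_screen", "completed", f)
    res$de <- de

    # ---- stage 2: profile dynamics ---------------------------------------
    keep <- if (config$profileOn == "screened" && any(de$passes))
        de$gene_id[de$passes] else de$gene_id
    res$profiled_genes <- keep
    pd <- withStage("profile_dynamics", {
        profiles <- enumerateProfiles(length(config$conditionOrder),
                                      config$maxStep, config$excludeFlat)
        series <- toLog2Series(mat[keep, ])
        assign <- assignProfiles(series, profiles)
        signif <- profileSignificance(assign, series, profiles,
                                      permutations = "exhaustive")
        sel <- selectPatternGenes(assign, signif, profiles,
                                  config$targetShape, config$alpha)
        list(profiles = profiles, series = series, assignments = assign,
             significance = signif, selection = sel)
    })
    f <- c(.writeTsv(pd$assignments,
                     file.path(config$outDir, "profile_assignments.tsv")),
           .writeTsv(pd$significance,
                     file.path(config$outDir, "profile_significance.tsv")))
    writeLines(pd$selection$genes,
               file.path(config$outDir, "pattern_genes.txt"))
    f <- c(f, file.path(config$outDir, "pattern_genes.txt"))
    note("profile_dynamics", "completed", f)
    res$profile <- pd

    # ---- stage 3: lncRNA discovery ---------------------------------------
    if (!is.null(novel) && !is.null(evidence)) {
        verdicts <- withStage("lncrna_discovery",
            classifyLncrna(novel, evidence, config$minLen, config$minExons,
                           config$maxOrf))
        merged <- mergeWithKnown(verdicts, loadProfile3()$lncrnas)
        f <- c(.writeTsv(verdicts,
                         file.path(config$outDir, "lncrna_verdicts.tsv")),
               .writeTsv(merged,
                         file.path(config$outDir, "lncrna_catalogue.tsv")))
        note("lncrna_discovery", "completed", f)
        res$lncrna <- list(verdicts = verdicts, merged = merged)
    } else note("lncrna_discovery", "skipped")

    # ---- stage 4: networks -----------------------------------------------
    if (!is.null(mirnas) && !is.null(sequences)) {
        net <- withStage("network_inference", {
            if (is.null(lncIds)) {
                lncIds <- intersect(names(sequences), rownames(mat))
                mrnaIds <- character(0)
            }
            coexpGenes <- unique(c(pd$selection$genes, lncIds, mrnaIds))
            coexp <- coexpressionNetwork(mat, coexpGenes,
                                         config$rThreshold)
            triplets <- buildCernaNetwork(mat, lncIds, mrnaIds, mirnas,
                                          sequences, config$percentile)
            list(coexp = coexp, triplets = triplets)
        })
        coexpEdges <- data.frame(node_a = net$coexp$gene_a,
                                 node_b = net$coexp$gene_b,
                                 r = net$coexp$r)
        f <- c(.writeTsv(net$coexp,
                         file.path(config$outDir, "coexpression.tsv")),
               writeNetwork(coexpEdges,
                            file.path(config$outDir, "coexpression.sif"),
                            "sif"),
               .writeTsv(net$triplets,
                         file.path(config$outDir, "cerna_triplets.tsv")),
               writeCernaSif(net$triplets,
                             file.path(config$outDir, "cerna.sif")))
        note("network_inference", "completed", f)
        res$network <- net
    } else note("network_inference", "skipped")

    # ---- stage 5: target prediction --------------------------------------
    if (!is.null(cisLnc) || !is.null(sequences)) {
        tp <- withStage("target_prediction", {
            cis <- if (!is.null(cisLnc))
                cisTargets(cisLnc, cisGenes, config$windowBp)
            else data.frame()
            trans <- if (!is.null(sequences) && !is.null(lncIds) &&
                         length(lncIds) && length(mrnaIds))
                do.call(rbind, lapply(lncIds, function(id)
                    transTargets(sequences[[id]], sequences[mrnaIds],
                                 config$transMinScore,
                                 config$transScreenKmer, lncrnaId = id)))
            else data.frame()
            list(cis = cis, trans = trans)
        })
        f <- c(.writeTsv(tp$cis, file.path(config$outDir,
                                           "cis_targets.tsv")),
               .writeTsv(tp$trans, file.path(config$outDir,
                                             "trans_targets.tsv")))
        note("target_prediction", "completed", f)
        res$targets <- tp
    } else note("target_prediction", "skipped")

    # ---- stage 6: enrichment ---------------------------------------------
    if (!is.null(terms)) {
        enr <- withStage("enrichment",
            enrichTerms(pd$selection$genes, rownames(mat), terms,
                        config$alpha))
        f <- .writeTsv(enr, file.path(config$outDir, "enrichment.tsv"))
        note("enrichment", "completed", f)
        res$enrichment <- enr
    } else note("enrichment", "skipped")

    # ---- manifest ---------------------------------------------------------
    cfgPath <- file.path(config$outDir, "config.json")
    cfgOut <- unclass(config)
    cfgOut <- cfgOut[!vapply(cfgOut, is.null, logical(1))]
    jsonlite::write_json(cfgOut, cfgPath, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    manifest <- list(
        package = "ceRNAprofiler",
        version = as.character(packageVersion("ceRNAprofiler")),
        seed = config$seed,
        config_hash = unname(tools::md5sum(cfgPath)),
        stages = stages)
    jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(list(manifest = manifest, results = res))
}
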