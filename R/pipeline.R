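#' Validated pipeline configuration
#'
#' @param outDir output directory for all artifacts.
#' @param qCut DEG significance cut-off on the BH q value (default 0.01).
#' @param filterMean mean-normalized-count filter threshold (default 1).
#' @param gAlpha stopping alpha of the backward-elimination G-test.
#' @param fegAlpha alpha for the FE_g direction calls.
#' @param zMajor major-regulator |z| threshold (default 2).
#' @param logpCut -log10(p) pathway filter threshold (default 1.3).
#' @param topK top-regulator list size (default 10).
#' @param pcaVarianceTarget cumulative-variance retention target.
#' @param pcaSignificantOnly restrict the PCA to genes significant in at
#'   least one strain-comparison (default TRUE).
#' @param seed RNG seed for the simulation stage.
#' @param simParams a [simParams()] object for the simulation stage; its
#'   seed is overridden by \code{seed}.
#' @return a validated list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(outDir, qCut = 0.01, filterMean = 1,
                           gAlpha = 0.05, fegAlpha = 0.05, zMajor = 2,
                           logpCut = 1.3, topK = 10,
                           pcaVarianceTarget = 0.843,
                           pcaSignificantOnly = TRUE,
                           seed = 1L, simParams = NULL) {
    cfg <- list(outDir = outDir, qCut = qCut, filterMean = filterMean,
                gAlpha = gAlpha, fegAlpha = fegAlpha, zMajor = zMajor,
                logpCut = logpCut, topK = topK,
                pcaVarianceTarget = pcaVarianceTarget,
                pcaSignificantOnly = pcaSignificantOnly,
                seed = as.integer(seed), simParams = simParams)
    for (f in c("qCut", "gAlpha", "fegAlpha"))
        if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0 || cfg[[f]] > 1)
            stop(sprintf("config field '%s' must lie in (0, 1]", f))
    if (cfg$filterMean < 0) stop("config field 'filterMean' must be >= 0")
    if (cfg$zMajor < 0) stop("config field 'zMajor' must be >= 0")
    if (cfg$topK < 1) stop("config field 'topK' must be >= 1")
    stopIfNot01(cfg$pcaVarianceTarget, "pcaVarianceTarget")
    structure(cfg, class = "PipelineConfig")
}

writeTSV <- function(x, path)
    utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)

#' Run the full comparative-transcriptomics pipeline on simulated data
#'
#' Executes, in order: simulation, per-strain differential expression for
#' the three comparisons (HvC, LvC, HvL), cross-strain shared-gene
#' accounting, PCA, GO-slim backward-elimination G-tests, orthologue
#' consolidation with mismatch summaries, and the FE_g functional-effects
#' analysis. Every intermediate table is written as UTF-8 TSV under
#' \code{config$outDir}; nested summaries go to \code{report.json} together
#' with a manifest (stages run, seed, package version). The whole run is a
#' pure function of the configuration.
#'
#' @param config a [pipelineConfig()] object.
#' @return the report list, invisibly; artifacts on disk.
#' @export
runPipeline <- function(config) {
    if (!inherits(config, "PipelineConfig"))
        stop("config must be built with pipelineConfig()")
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    report <- list(stages = character(), seed = config$seed,
                   version = as.character(utils::packageVersion("ThermoTrout")))
    stage <- function(name, expr) {
        t0 <- proc.time()[["elapsed"]]
        out <- tryCatch(expr, error = function(e)
            stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                 call. = FALSE))
        message(sprintf("[%s] done in %.2fs", name,
                        proc.time()[["elapsed"]] - t0))
        report$stages <<- c(report$stages, name)
        out
    }

    sim <- stage("simulate", {
        sp <- config$simParams %||% simParams()
        sp$seed <- config$seed
        s <- simulateStudy(sp)
        writeSimulation(s, file.path(config$outDir, "sim"))
        s
    })
    te <- sim$experiment
    strains <- unique(colData(te)$strain)
    groups <- unique(colData(te)$group)       # C, L, H order from simParams
    cmps <- list(HvC = c(groups[1], groups[3]),
                 LvC = c(groups[1], groups[2]),
                 HvL = c(groups[2], groups[3]))

    degs <- stage("deg", {
        out <- list()
        for (cmp in names(cmps)) for (s in strains) {
            d <- testDE(te, cmps[[cmp]][1], cmps[[cmp]][2], strain = s,
                        filterThreshold = config$filterMean,
                        qCut = config$qCut, comparison = cmp)
            writeTSV(as.data.frame(d),
                     file.path(config$outDir,
                               sprintf("deg_%s_%s.tsv", s, cmp)))
            out[[cmp]][[s]] <- d
        }
        out
    })
    report$degCounts <- lapply(degs, function(x)
        lapply(x, function(d) sum(d$significant)))

    shared <- stage("shared", {
        out <- list()
        for (cmp in names(cmps)) {
            sh <- intersectShared(degs[[cmp]][[strains[1]]],
                                  degs[[cmp]][[strains[2]]],
                                  qCut = config$qCut)
            writeTSV(as.data.frame(sharedTable(sh)),
                     file.path(config$outDir, sprintf("shared_%s.tsv", cmp)))
            jsonlite::write_json(
                as.list(vennCounts(sh)),
                file.path(config$outDir, sprintf("venn_%s.json", cmp)),
                auto_unbox = TRUE, digits = NA)
            out[[cmp]] <- sh
        }
        out
    })
    report$venn <- lapply(shared, function(s) as.list(vennCounts(s)))
    report$sharedProportions <- lapply(shared, function(s)
        as.list(s@sharedProportion))
    report$upProportions <- lapply(shared, function(s)
        as.list(s@upProportion))

    pca <- stage("pca", {
        expr <- normalizeExpression(te, "TPM")
        if (config$pcaSignificantOnly) {
            sig <- unique(unlist(lapply(degs, function(x)
                lapply(x, function(d) d$gene[d$significant]))))
            if (length(sig) >= 2L) expr <- expr[rownames(expr) %in% sig, ,
                                                drop = FALSE]
        }
        p <- suppressWarnings(runPCA(expr, config$pcaVarianceTarget))
        writeTSV(data.frame(sample = rownames(p$scores), p$scores,
                            check.names = FALSE),
                 file.path(config$outDir, "pca_scores.tsv"))
        p
    })
    report$pca <- list(nRetained = pca$nRetained,
                       percentVariance = round(pca$percentVariance, 4))

    slim <- stage("goslim", {
        out <- list()
        for (cmp in names(cmps)) {
            sh <- sharedTable(shared[[cmp]])
            up <- sh$gene[sh$avgLog2FC > 0]
            dn <- sh$gene[sh$avgLog2FC < 0]
            if (!length(up) && !length(dn)) next
            labs <- c(cmps[[cmp]][2], cmps[[cmp]][1])
            tabs <- countSlim(up, dn, sim$annotations, groups = labs)
            for (ns in names(tabs)) {
                g <- backwardEliminate(tabs[[ns]], alpha = config$gAlpha,
                                       namespace = ns, groups = labs)
                writeTSV(as.data.frame(g@table),
                         file.path(config$outDir,
                                   sprintf("goslim_%s_%s.tsv", cmp, ns)))
                out[[cmp]][[ns]] <- g
            }
        }
        out
    })
    report$goslim <- lapply(slim, function(x) lapply(x, function(g) {
        rem <- removedTerms(g)
        list(removed = rem$term, enriched = rem$enrichedGroup)
    }))

    consolidated <- stage("consolidate", {
        out <- list()
        for (cmp in names(cmps)) {
            ct <- suppressMessages(
                consolidateOrthologs(shared[[cmp]], sim$orthologMap))
            writeTSV(as.data.frame(ct),
                     file.path(config$outDir,
                               sprintf("consolidated_%s.tsv", cmp)))
            out[[cmp]] <- ct
        }
        jsonlite::write_json(lapply(out, summarizeMismatches),
                             file.path(config$outDir, "mismatch_summary.json"),
                             auto_unbox = TRUE, digits = NA)
        out
    })
    report$mismatches <- lapply(consolidated, summarizeMismatches)

    feg <- stage("funcfx", {
        ## orthologue-level enhanced-group directions from the consolidated
        ## H-vs-L table: positive selected fold change in both strains -> H
        ct <- consolidated$HvL
        dir <- ifelse(ct$selLFC1 > 0 & ct$selLFC2 > 0, "H",
                      ifelse(ct$selLFC1 < 0 & ct$selLFC2 < 0, "L",
                             NA_character_))
        names(dir) <- ct$ortholog
        f <- suppressMessages(
            computeFEG(sim$associations, dir, alpha = config$fegAlpha))
        writeTSV(f, file.path(config$outDir, "feg_results.tsv"))
        f
    })
    report$feg <- list(nFunctions = nrow(feg),
                       nSignificant = sum(!is.na(feg$pvalue) &
                                          feg$pvalue <= config$fegAlpha))

    cfgForHash <- unclass(config)[setdiff(names(config), "outDir")]
    js <- jsonlite::toJSON(cfgForHash, auto_unbox = TRUE, digits = NA,
                           force = TRUE)
    v <- utf8ToInt(js)
    report$configHash <- sum(v * (seq_along(v) %% 97)) %% 1e9
    jsonlite::write_json(report, file.path(config$outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    invisible(report)
}
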