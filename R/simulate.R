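#' Simulation parameters for a synthetic thermal-tolerance study
#'
#' Builds and validates the parameter set for [simulateStudy()]. The defaults
#' emulate the design of a two-strain critical-thermal-maximum study: two
#' strains, three experimental groups (control C, low-tolerance L,
#' high-tolerance H), six biological replicates per strain-by-group cell, and
#' negative-binomial gene counts with planted differential expression.
#'
#' @param nGenes number of genes.
#' @param nRepsPerGroup replicates per strain-by-group cell (>= 2).
#' @param strains two strain labels.
#' @param groups three group labels; the first is the control/reference.
#' @param fracDE fraction of genes differentially expressed per comparison
#'   driver (H and L effects are planted independently).
#' @param sharedFraction fraction of DE genes whose effect is shared (same
#'   log2FC) across the two strains; the rest are strain-specific.
#' @param lfcMean,lfcSd mean and sd of planted absolute log2 fold changes
#'   (signs split 50/50 up/down; magnitudes floored at 0.25).
#' @param dispersion negative-binomial dispersion phi in Var = mu + phi*mu^2;
#'   0 gives the Poisson limit.
#' @param libSizeMean,libSizeCV expected library size and its coefficient of
#'   variation (log-normal model).
#' @param dupFraction fraction of orthologue IDs carrying 2-3 trout copies.
#' @param discordRate probability that a duplicated orthologue is planted
#'   strain-discordant: the maximum-|log2FC| copy differs in sign between
#'   strains after consolidation.
#' @param nTerms GO-slim terms per namespace (BP, CC, MF).
#' @param termsPerGeneMean expected annotations per gene per namespace; each
#'   gene-term pair is an independent Bernoulli draw with probability
#'   \code{termsPerGeneMean/nTerms}, multiplied for enriched terms.
#' @param enrichedTerms data.frame with columns \code{term}, \code{group},
#'   \code{multiplier}: planted annotation-probability multipliers for genes
#'   upregulated in \code{group}.
#' @param nFunctions,genesPerFunction function-association table size.
#' @param effectMixByGroup named list (one entry per non-control group) of
#'   length-3 probability vectors over \code{increases}, \code{decreases},
#'   \code{affects}; each must sum to 1.
#' @param seed master RNG seed; fixes every artifact bit-for-bit.
#' @return a validated list of class \code{"SimulationParams"}.
#' @examples
#' p <- simParams(nGenes = 200, seed = 7)
#' @export
simParams <- function(nGenes = 5000L,
                      nRepsPerGroup = 6L,
                      strains = c("Alma", "Lyndon"),
                      groups = c("C", "L", "H"),
                      fracDE = 0.1,
                      sharedFraction = 0.5,
                      lfcMean = 1.5,
                      lfcSd = 0.5,
                      dispersion = 0.1,
                      libSizeMean = 2e6,
                      libSizeCV = 0.2,
                      dupFraction = 0.3,
                      discordRate = 0.03,
                      nTerms = 15L,
                      termsPerGeneMean = 2,
                      enrichedTerms = NULL,
                      nFunctions = 20L,
                      genesPerFunction = 40L,
                      effectMixByGroup = list(
                          H = c(increases = 1/3, decreases = 1/3, affects = 1/3),
                          L = c(increases = 1/3, decreases = 1/3, affects = 1/3)),
                      seed = 1L) {
    p <- list(nGenes = as.integer(nGenes),
              nRepsPerGroup = as.integer(nRepsPerGroup),
              strains = as.character(strains), groups = as.character(groups),
              fracDE = fracDE, sharedFraction = sharedFraction,
              lfcMean = lfcMean, lfcSd = lfcSd, dispersion = dispersion,
              libSizeMean = libSizeMean, libSizeCV = libSizeCV,
              dupFraction = dupFraction, discordRate = discordRate,
              nTerms = as.integer(nTerms),
              termsPerGeneMean = termsPerGeneMean,
              enrichedTerms = enrichedTerms,
              nFunctions = as.integer(nFunctions),
              genesPerFunction = as.integer(genesPerFunction),
              effectMixByGroup = effectMixByGroup,
              seed = as.integer(seed))
    if (p$nGenes < 1L) stop("parameter 'nGenes' must be positive")
    if (p$nRepsPerGroup < 2L)
        stop("parameter 'nRepsPerGroup' must be at least 2")
    if (length(p$strains) != 2L) stop("parameter 'strains' needs 2 labels")
    if (length(p$groups) != 3L) stop("parameter 'groups' needs 3 labels")
    for (f in c("fracDE", "sharedFraction", "dupFraction", "discordRate"))
        stopIfNot01(p[[f]], f)
    if (p$dispersion < 0) stop("parameter 'dispersion' must be >= 0")
    if (p$libSizeMean <= 0) stop("parameter 'libSizeMean' must be positive")
    if (p$libSizeCV < 0) stop("parameter 'libSizeCV' must be >= 0")
    if (p$termsPerGeneMean < 0)
        stop("parameter 'termsPerGeneMean' must be >= 0")
    for (g in names(p$effectMixByGroup)) {
        mix <- p$effectMixByGroup[[g]]
        if (length(mix) != 3L || any(mix < 0) || abs(sum(mix) - 1) > 1e-8)
            stop(sprintf(
                "parameter 'effectMixByGroup[%s]' must be 3 proportions summing to 1", g))
    }
    if (!is.null(p$enrichedTerms)) {
        need <- setdiff(c("term", "group", "multiplier"),
                        colnames(p$enrichedTerms))
        if (length(need))
            stop("parameter 'enrichedTerms' missing columns: ",
                 paste(need, collapse = ", "))
    }
    structure(p, class = "SimulationParams")
}

## ---- effect planning ------------------------------------------------------

## Per-gene, per-strain log2 effects for the H and L groups relative to C.
## Shared DE genes carry identical effects in both strains; the rest are
## strain-specific. Effects are the single source of truth for all planted
## fold changes: HvC = betaH, LvC = betaL, HvL = betaH - betaL.
planEffects <- function(params) {
    n <- params$nGenes
    genes <- sprintf("g%05d", seq_len(n))
    lengths <- round(exp(runif(n, log(300), log(10000))))
    abundance <- rlnorm(n, meanlog = 0, sdlog = 1)
    abundance <- abundance / sum(abundance)
    betaH <- matrix(0, n, 2, dimnames = list(genes, params$strains))
    betaL <- matrix(0, n, 2, dimnames = list(genes, params$strains))
    drawLFC <- function(k) {
        if (k == 0L) return(numeric())
        mag <- pmax(abs(rnorm(k, params$lfcMean, params$lfcSd)), 0.25)
        mag * sample(c(-1, 1), k, replace = TRUE)
    }
    ## H- and L-driver DE pools are drawn disjointly so the H-vs-L effect of
    ## any gene has a single driver (and a single sign) in every strain
    avail <- genes
    for (driver in c("H", "L")) {
        beta <- if (driver == "H") betaH else betaL
        nDE <- round(params$fracDE * n)
        nShared <- round(params$sharedFraction * nDE)
        pool <- sample(avail, min(nDE, length(avail)))
        avail <- setdiff(avail, pool)
        shared <- pool[seq_len(nShared)]
        beta[shared, 1] <- beta[shared, 2] <- drawLFC(nShared)
        uniq <- pool[-seq_len(nShared)]
        if (length(uniq)) {
            half <- seq_len(length(uniq) %/% 2L)
            u1 <- uniq[half]; u2 <- setdiff(uniq, u1)
            beta[u1, 1] <- drawLFC(length(u1))
            beta[u2, 2] <- drawLFC(length(u2))
        }
        if (driver == "H") betaH <- beta else betaL <- beta
    }
    list(genes = genes, lengths = lengths, abundance = abundance,
         betaH = betaH, betaL = betaL)
}

## True log2FC for a comparison, per strain (focal vs reference group).
effectFor <- function(plan, comparison) {
    switch(comparison,
           HvC = plan$betaH,
           LvC = plan$betaL,
           HvL = plan$betaH - plan$betaL,
           stop("unknown comparison: ", comparison))
}

truthDEGenes <- function(plan) {
    out <- list()
    for (cmp in c("HvC", "LvC", "HvL")) {
        eff <- effectFor(plan, cmp)
        for (s in colnames(eff)) {
            keep <- eff[, s] != 0
            out[[cmp]][[s]] <- data.frame(gene = rownames(eff)[keep],
                                          log2FC = unname(eff[keep, s]))
        }
    }
    out
}

## Planted enhanced group per gene: H if the shared H-vs-L effect is positive
## in both strains, L if negative in both; NA otherwise.
enhancedGroups <- function(plan) {
    eff <- plan$betaH - plan$betaL
    grp <- rep(NA_character_, nrow(eff))
    up <- eff[, 1] > 0 & eff[, 2] > 0
    dn <- eff[, 1] < 0 & eff[, 2] < 0
    grp[up] <- "H"; grp[dn] <- "L"
    stats::setNames(grp, rownames(eff))
}

## ---- ortholog map ---------------------------------------------------------

#' Simulate a trout-gene to mammalian-orthologue map with planted duplicates
#'
#' Partitions the gene universe into orthologue groups: a \code{dupFraction}
#' of orthologue IDs receive 2-3 trout copies, the rest are singletons. A
#' \code{discordRate} fraction of duplicated orthologues is planted
#' strain-discordant by overriding the true effects of two copies so that the
#' maximum-|log2FC| copy is positive in one strain and negative in the other
#' (both copies significant in both strains, each copy direction-concordant
#' across strains). The returned truth records the planted discordant set.
#'
#' @param params a [simParams()] object.
#' @param truth the truth list from effect planning (internally, the plan);
#'   when called standalone use the \code{$truth} of a [simulateStudy()]
#'   result.
#' @return list with \code{map} (data.frame \code{gene}, \code{ortholog}) and
#'   the updated \code{truth}.
#' @export
simulateOrthologMap <- function(params, truth) {
    stopIfNot01(params$dupFraction, "dupFraction")
    stopIfNot01(params$discordRate, "discordRate")
    withSeed(subSeed(params$seed, 3L), {
        plan <- truth$plan
        genes <- sample(plan$genes)
        map <- data.frame(gene = character(), ortholog = character())
        orth <- list(); i <- 1L; oid <- 0L
        while (i <= length(genes)) {
            oid <- oid + 1L
            k <- if (runif(1) < params$dupFraction)
                sample(2:3, 1L) else 1L
            k <- min(k, length(genes) - i + 1L)
            orth[[oid]] <- genes[i:(i + k - 1L)]
            i <- i + k
        }
        ids <- sprintf("ORTH%05d", seq_along(orth))
        map <- data.frame(
            gene = unlist(orth),
            ortholog = rep(ids, lengths(orth)),
            stringsAsFactors = FALSE)
        dup <- ids[lengths(orth) >= 2L]
        discordant <- dup[runif(length(dup)) < params$discordRate]
        for (d in discordant) {
            copies <- orth[[match(d, ids)]]
            a <- copies[1L]; b <- copies[2L]
            ## strain 1 selects copy a (up); strain 2 selects copy b (down)
            plan$betaL[c(a, b), ] <- 0
            plan$betaH[a, ] <- c(2.5, 0.8)
            plan$betaH[b, ] <- c(-0.8, -2.5)
        }
        truth$plan <- plan
        truth$duplicatedIDs <- dup
        truth$discordantIDs <- discordant
        truth$orthologMap <- map
        list(map = map, truth = truth)
    })
}

## ---- counts ---------------------------------------------------------------

#' Simulate negative-binomial counts for the planted design
#'
#' Counts for gene g in sample s are drawn NB with mean
#' \code{libSize_s * abundance_g * 2^beta}, where beta is the planted effect
#' of the sample's (strain, group) cell, and variance \code{mu + phi*mu^2};
#' \code{dispersion = 0} degenerates to Poisson. Library sizes recorded in
#' the metadata are the realized column sums.
#'
#' @param params a [simParams()] object.
#' @param truth optional truth carrying an (ortholog-adjusted) effect plan;
#'   when missing, effects are planned fresh from \code{params}.
#' @return list with \code{experiment} (a [ThermalExperiment-class]) and
#'   \code{truth}.
#' @export
simulateCounts <- function(params, truth = NULL) {
    if (!inherits(params, "SimulationParams")) params <- do.call(simParams, params)
    if (is.null(truth))
        truth <- list(plan = withSeed(subSeed(params$seed, 1L),
                                      planEffects(params)))
    plan <- truth$plan
    withSeed(subSeed(params$seed, 2L), {
        nrep <- params$nRepsPerGroup
        cells <- expand.grid(rep = seq_len(nrep), group = params$groups,
                             strain = params$strains,
                             stringsAsFactors = FALSE)
        samples <- sprintf("%s_%s_%d", cells$strain, cells$group, cells$rep)
        sdlog <- sqrt(log(1 + params$libSizeCV^2))
        lib <- rlnorm(nrow(cells), log(params$libSizeMean) - sdlog^2 / 2, sdlog)
        n <- params$nGenes
        counts <- matrix(0L, n, nrow(cells),
                         dimnames = list(plan$genes, samples))
        for (j in seq_len(nrow(cells))) {
            st <- cells$strain[j]; gr <- cells$group[j]
            beta <- if (gr == params$groups[3]) plan$betaH[, st]
                    else if (gr == params$groups[2]) plan$betaL[, st]
                    else 0
            mu <- lib[j] * plan$abundance * 2^beta
            counts[, j] <- if (params$dispersion == 0) rpois(n, mu)
                           else rnbinom(n, mu = mu,
                                        size = 1 / params$dispersion)
        }
        te <- ThermalExperiment(counts, geneLength = plan$lengths,
                                strain = cells$strain, group = cells$group)
        truth$deGenes <- truthDEGenes(plan)
        truth$enhancedGroup <- enhancedGroups(plan)
        list(experiment = te, truth = truth)
    })
}

## ---- annotations ----------------------------------------------------------

#' Simulate gene to GO-slim annotations with planted enrichment
#'
#' Each (gene, namespace, term) triple is an independent Bernoulli draw with
#' base probability \code{termsPerGeneMean/nTerms}; for genes upregulated in
#' an enriched term's target group the probability is multiplied by the
#' planted multiplier (capped at 1).
#'
#' @param params a [simParams()] object.
#' @param truth a truth list with \code{enhancedGroup} (from
#'   [simulateCounts()]).
#' @return data.frame with columns \code{gene}, \code{namespace}, \code{term}.
#' @export
simulateAnnotations <- function(params, truth) {
    namespaces <- c("BP", "CC", "MF")
    terms <- lapply(namespaces, function(ns)
        sprintf("%s%02d", ns, seq_len(params$nTerms)))
    names(terms) <- namespaces
    enr <- params$enrichedTerms
    if (!is.null(enr)) {
        universe <- unlist(terms, use.names = FALSE)
        bad <- setdiff(enr$term, universe)
        if (length(bad))
            stop("enriched term(s) not in the term universe: ",
                 paste(bad, collapse = ", "))
    }
    if (params$termsPerGeneMean == 0)
        return(data.frame(gene = character(), namespace = character(),
                          term = character()))
    genes <- truth$plan$genes
    grp <- truth$enhancedGroup[genes]
    p0 <- min(1, params$termsPerGeneMean / params$nTerms)
    withSeed(subSeed(params$seed, 4L), {
        out <- vector("list", length(namespaces))
        for (ns in namespaces) {
            tm <- terms[[ns]]
            prob <- matrix(p0, length(genes), length(tm),
                           dimnames = list(genes, tm))
            if (!is.null(enr))
                for (k in seq_len(nrow(enr))) {
                    t <- enr$term[k]
                    if (!t %in% tm) next
                    hit <- !is.na(grp) & grp == enr$group[k]
                    prob[hit, t] <- min(1, p0 * enr$multiplier[k])
                }
            draw <- matrix(runif(length(prob)) < prob, nrow(prob))
            idx <- which(draw, arr.ind = TRUE)
            out[[ns]] <- data.frame(gene = genes[idx[, 1]], namespace = ns,
                                    term = tm[idx[, 2]])
        }
        res <- do.call(rbind, out)
        res[order(res$gene, res$namespace, res$term), , drop = FALSE]
    })
}

## ---- function associations -------------------------------------------------

#' Simulate gene-function effect associations with planted group mixes
#'
#' Links orthologue IDs to synthetic functions; each linked gene's effect
#' label (\code{increases}, \code{decreases}, \code{affects}) is drawn from
#' the planted mix of the gene's enhanced group.
#'
#' @param params a [simParams()] object.
#' @param truth truth list with \code{orthologMap} and \code{enhancedGroup}.
#' @return data.frame with columns \code{ortholog}, \code{functionID},
#'   \code{effect}; generating proportions are recorded in
#'   \code{attr(, "mix")}.
#' @export
simulateFunctionAssociations <- function(params, truth) {
    mix <- params$effectMixByGroup
    map <- truth$orthologMap
    grp <- truth$enhancedGroup
    ## orthologue-level enhanced group: first non-NA copy (copies of a
    ## planted-DE orthologue share direction by construction)
    og <- vapply(split(map$gene, map$ortholog), function(gs) {
        g <- grp[gs]; g <- g[!is.na(g)]
        if (length(g)) g[[1]] else NA_character_
    }, character(1))
    pool <- names(og)[!is.na(og)]
    withSeed(subSeed(params$seed, 5L), {
        out <- vector("list", params$nFunctions)
        for (f in seq_len(params$nFunctions)) {
            fid <- sprintf("F%03d", f)
            k <- min(params$genesPerFunction, length(pool))
            if (k == 0L) {
                out[[f]] <- data.frame(ortholog = character(),
                                       functionID = character(),
                                       effect = character())
                next
            }
            genes <- sample(pool, k)
            eff <- vapply(genes, function(o)
                sample(names(mix[[og[[o]]]]), 1L, prob = mix[[og[[o]]]]),
                character(1))
            out[[f]] <- data.frame(ortholog = genes, functionID = fid,
                                   effect = unname(eff))
        }
        res <- do.call(rbind, out)
        rownames(res) <- NULL
        attr(res, "mix") <- mix
        res
    })
}

## ---- orchestration ---------------------------------------------------------

#' Simulate a complete synthetic study with planted truth
#'
#' Runs the full generator: effect planning, orthologue map with planted
#' discordance (which shapes the true effects of discordant duplicate
#' copies), negative-binomial counts, GO-slim annotations and gene-function
#' associations. Identical parameters and seed reproduce every artifact
#' bit-for-bit.
#'
#' @param params a [simParams()] object (or a list of arguments for it).
#' @return list with \code{experiment}, \code{annotations},
#'   \code{orthologMap}, \code{associations} and \code{truth}.
#' @examples
#' sim <- simulateStudy(simParams(nGenes = 300, seed = 11))
#' sim$experiment
#' @export
simulateStudy <- function(params = simParams()) {
    if (!inherits(params, "SimulationParams")) params <- do.call(simParams, params)
    truth <- list(plan = withSeed(subSeed(params$seed, 1L),
                                  planEffects(params)))
    om <- simulateOrthologMap(params, truth)
    truth <- om$truth
    sc <- simulateCounts(params, truth)
    truth <- sc$truth
    annot <- simulateAnnotations(params, truth)
    assoc <- simulateFunctionAssociations(params, truth)
    truth$functionMix <- params$effectMixByGroup
    list(experiment = sc$experiment, annotations = annot,
         orthologMap = om$map, associations = assoc, truth = truth)
}

#' Write simulated artifacts as plain-text files
#'
#' Writes \code{counts.tsv}, \code{counts.mtx} (MatrixMarket, with
#' \code{counts.mtx.rownames}/\code{.colnames}), \code{meta.tsv},
#' \code{lengths.tsv}, \code{annot.tsv}, \code{orthomap.tsv},
#' \code{assoc.tsv} and \code{truth.json} into \code{dir}.
#'
#' @param sim a [simulateStudy()] result.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    te <- sim$experiment
    cts <- assay(te, "counts")
    utils::write.table(data.frame(gene = rownames(cts), cts,
                                  check.names = FALSE),
                       file.path(dir, "counts.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    Matrix::writeMM(Matrix::Matrix(cts, sparse = TRUE),
                    file.path(dir, "counts.mtx"))
    writeLines(rownames(cts), file.path(dir, "counts.mtx.rownames"))
    writeLines(colnames(cts), file.path(dir, "counts.mtx.colnames"))
    meta <- data.frame(sample = colnames(te),
                       strain = colData(te)$strain,
                       group = colData(te)$group,
                       lib_size = colData(te)$lib_size)
    utils::write.table(meta, file.path(dir, "meta.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(gene = rownames(te),
                                  length = geneLengths(te)),
                       file.path(dir, "lengths.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(sim$annotations, file.path(dir, "annot.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(sim$orthologMap, file.path(dir, "orthomap.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(sim$associations, file.path(dir, "assoc.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    truth <- sim$truth
    json <- list(deGenes = truth$deGenes,
                 duplicatedIDs = truth$duplicatedIDs,
                 discordantIDs = truth$discordantIDs,
                 enhancedGroup = as.list(truth$enhancedGroup[
                     !is.na(truth$enhancedGroup)]),
                 functionMix = truth$functionMix)
    jsonlite::write_json(json, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    invisible(dir)
}

#' Read a ThermalExperiment back from a simulation directory
#'
#' @param dir a directory written by [writeSimulation()] (or TSV files with
#'   the same layout).
#' @return a [ThermalExperiment-class].
#' @export
readThermalExperiment <- function(dir) {
    cts <- utils::read.delim(file.path(dir, "counts.tsv"),
                             check.names = FALSE)
    m <- as.matrix(cts[, -1, drop = FALSE])
    rownames(m) <- cts$gene
    meta <- utils::read.delim(file.path(dir, "meta.tsv"))
    len <- utils::read.delim(file.path(dir, "lengths.tsv"))
    m <- m[, meta$sample, drop = FALSE]
    ThermalExperiment(m, geneLength = len$length[match(rownames(m), len$gene)],
                      strain = meta$strain, group = meta$group)
}
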