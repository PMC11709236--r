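test_that("identical parameters and seed reproduce every artifact exactly", {
    p <- simParams(nGenes = 300, seed = 42)
    a <- simulateStudy(p)
    b <- simulateStudy(p)
    expect_identical(SummarizedExperiment::assay(a$experiment, "counts"),
                     SummarizedExperiment::assay(b$experiment, "counts"))
    expect_identical(a$annotations, b$annotations)
    expect_identical(a$orthologMap, b$orthologMap)
    expect_identical(a$associations, b$associations)
    expect_identical(a$truth$discordantIDs, b$truth$discordantIDs)
})

test_that("library sizes in the metadata are the realized column sums", {
    sim <- simulateStudy(simParams(nGenes = 250, seed = 42))
    te <- sim$experiment
    expect_equal(unname(librarySizes(te)),
                 unname(colSums(SummarizedExperiment::assay(te, "counts"))))
})

test_that("a null simulation plants no effects and balances group means", {
    sim <- simulateCounts(simParams(nGenes = 400, fracDE = 0,
                                    discordRate = 0, seed = 42))
    for (cmp in names(sim$truth$deGenes))
        for (s in names(sim$truth$deGenes[[cmp]]))
            expect_equal(nrow(sim$truth$deGenes[[cmp]][[s]]), 0L)
    te <- sim$experiment
    cd <- SummarizedExperiment::colData(te)
    cts <- SummarizedExperiment::assay(te, "counts")
    depth <- colSums(cts)
    sel <- cd$strain == "Alma"
    mH <- rowMeans(sweep(cts[, sel & cd$group == "H"], 2,
                         depth[sel & cd$group == "H"], "/"))
    mC <- rowMeans(sweep(cts[, sel & cd$group == "C"], 2,
                         depth[sel & cd$group == "C"], "/"))
    ## group means equal in expectation: median ratio near 1
    expect_lt(abs(log2(median(mH / mC))), 0.1)
})

test_that("zero dispersion reaches the Poisson limit (variance = mean)", {
    sim <- simulateCounts(simParams(nGenes = 5000, fracDE = 0,
                                    dispersion = 0, libSizeCV = 0,
                                    nRepsPerGroup = 6, seed = 42))
    te <- sim$experiment
    cd <- SummarizedExperiment::colData(te)
    cts <- SummarizedExperiment::assay(te, "counts")[,
        cd$strain == "Alma" & cd$group == "C"]
    m <- rowMeans(cts)
    v <- apply(cts, 1, var)
    keep <- m > 5
    ## mean variance-to-mean ratio over thousands of genes is 1 within
    ## sampling error (ratio variance ~ 2/(n-1) per gene)
    expect_gt(sum(keep), 3000)
    expect_lt(abs(mean(v[keep] / m[keep]) - 1), 0.05)
})

test_that("annotation density zero yields an empty table", {
    tr <- makeDirectedTruth(50)
    p <- simParams(nGenes = 100, termsPerGeneMean = 0, seed = 42)
    expect_equal(nrow(simulateAnnotations(p, tr)), 0L)
})

test_that("an enriched term outside the universe is rejected", {
    tr <- makeDirectedTruth(50)
    p <- simParams(nGenes = 100, seed = 42,
                   enrichedTerms = data.frame(term = "XX99", group = "H",
                                              multiplier = 3))
    expect_error(simulateAnnotations(p, tr), "term universe")
})

test_that("a 3x annotation multiplier shifts term frequency by about 3x", {
    tr <- makeDirectedTruth(500)
    p <- simParams(nGenes = 1000, nTerms = 15, termsPerGeneMean = 2,
                   seed = 42,
                   enrichedTerms = data.frame(term = "BP01", group = "H",
                                              multiplier = 3))
    ann <- simulateAnnotations(p, tr)
    hGenes <- names(tr$enhancedGroup)[tr$enhancedGroup == "H"]
    lGenes <- names(tr$enhancedGroup)[tr$enhancedGroup == "L"]
    hit <- ann$gene[ann$term == "BP01"]
    pH <- mean(hGenes %in% hit)
    pL <- mean(lGenes %in% hit)
    ## base rate 2/15, enriched 6/15; binomial sd ~ 0.02 at n = 500
    expect_gt(pH / pL, 2.2)
    expect_lt(pH / pL, 4.0)
})

test_that("dupFraction 0 gives a bijective orthologue map", {
    sim <- simulateStudy(simParams(nGenes = 300, dupFraction = 0, seed = 42))
    expect_equal(anyDuplicated(sim$orthologMap$ortholog), 0L)
    expect_equal(nrow(sim$orthologMap), 300L)
    expect_length(sim$truth$discordantIDs, 0L)
})

test_that("planted discordant orthologues are recovered exactly from truth", {
    for (seed in c(42, 43, 44)) {
        sim <- simulateStudy(simParams(nGenes = 1500, dupFraction = 0.5,
                                       discordRate = 0.1, seed = seed))
        eff <- sim$truth$plan$betaH - sim$truth$plan$betaL
        keep <- eff[, 1] != 0 & eff[, 2] != 0
        shared <- data.frame(gene = rownames(eff)[keep],
                             log2FC1 = eff[keep, 1], log2FC2 = eff[keep, 2])
        ct <- suppressMessages(
            consolidateOrthologs(shared, sim$orthologMap,
                                 comparison = "HvL"))
        flagged <- ct$ortholog[ct$mismatch & ct$isDuplicated]
        expect_setequal(flagged, sim$truth$discordantIDs)
        expect_equal(sum(ct$mismatch & !ct$isDuplicated), 0L)
    }
})

test_that("discordRate 0 yields a zero mismatch summary", {
    sim <- simulateStudy(simParams(nGenes = 800, dupFraction = 0.5,
                                   discordRate = 0, seed = 42))
    eff <- sim$truth$plan$betaH - sim$truth$plan$betaL
    keep <- eff[, 1] != 0 & eff[, 2] != 0
    shared <- data.frame(gene = rownames(eff)[keep],
                         log2FC1 = eff[keep, 1], log2FC2 = eff[keep, 2])
    ct <- suppressMessages(consolidateOrthologs(shared, sim$orthologMap))
    expect_equal(summarizeMismatches(ct)$nMismatches, 0L)
})

test_that("malformed effect mixes are rejected by name", {
    expect_error(simParams(effectMixByGroup = list(
        H = c(increases = 0.5, decreases = 0.5, affects = 0.5),
        L = c(increases = 1/3, decreases = 1/3, affects = 1/3))),
        "effectMixByGroup\\[H\\]")
    expect_error(simParams(fracDE = 1.2), "fracDE")
    expect_error(simParams(nRepsPerGroup = 1), "nRepsPerGroup")
    expect_error(simParams(dispersion = -0.1), "dispersion")
})

test_that("functions with no eligible genes are emitted empty and skipped", {
    tr <- makeDirectedTruth(5)
    tr$enhancedGroup[] <- NA_character_   # no gene has a direction
    p <- simParams(nGenes = 10, nFunctions = 3, genesPerFunction = 5,
                   seed = 42)
    assoc <- simulateFunctionAssociations(p, tr)
    expect_equal(nrow(assoc), 0L)
    res <- suppressMessages(
        computeFEG(data.frame(ortholog = character(),
                              functionID = character(),
                              effect = character()),
                   stats::setNames("H", "g1")))
    expect_equal(nrow(res), 0L)
})

test_that("written artifacts round-trip through the plain-text readers", {
    sim <- simulateStudy(simParams(nGenes = 120, seed = 42))
    dir <- withr::local_tempdir()
    writeSimulation(sim, dir)
    expect_true(all(file.exists(file.path(dir,
        c("counts.tsv", "counts.mtx", "meta.tsv", "lengths.tsv",
          "annot.tsv", "orthomap.tsv", "assoc.tsv", "truth.json")))))
    te2 <- readThermalExperiment(dir)
    expect_equal(SummarizedExperiment::assay(te2, "counts"),
                 SummarizedExperiment::assay(sim$experiment, "counts"))
    expect_equal(unname(geneLengths(te2)),
                 unname(geneLengths(sim$experiment)))
})
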