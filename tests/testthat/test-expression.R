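makeTE <- function(counts, len) {
    dimnames(counts) <- list(sprintf("g%d", seq_len(nrow(counts))),
                             sprintf("s%d", seq_len(ncol(counts))))
    ThermalExperiment(counts, geneLength = len,
                      strain = rep("A", ncol(counts)),
                      group = rep(c("C", "H"), each = ncol(counts) / 2))
}

test_that("TPM matches the closed form and sums to one million", {
    te <- makeTE(matrix(c(10, 90, 20, 180), 2, 2), len = c(1000, 1000))
    tpm <- normalizeExpression(te, "TPM")
    expect_equal(unname(tpm[, 1]), c(1e5, 9e5))
    expect_equal(unname(colSums(tpm)), rep(1e6, 2))
    one <- makeTE(matrix(c(5, 17), 1, 2), len = 700)
    expect_equal(unname(normalizeExpression(one, "TPM")[1, ]), c(1e6, 1e6))
})

test_that("RPKM follows 1e9 * c / (L * N)", {
    te <- makeTE(matrix(c(10, 90, 20, 180), 2, 2), len = c(500, 2000))
    rpkm <- normalizeExpression(te, "RPKM")
    N <- colSums(SummarizedExperiment::assay(te, "counts"))
    expect_equal(rpkm[1, 1], 1e9 * 10 / (500 * N[1]), ignore_attr = TRUE)
    expect_equal(rpkm[2, 2], 1e9 * 180 / (2000 * N[2]), ignore_attr = TRUE)
})

test_that("degenerate normalization inputs raise named errors", {
    te <- makeTE(matrix(c(0, 0, 5, 7), 2, 2), len = c(1000, 1000))
    expect_error(normalizeExpression(te, "TPM"), "zero library size")
    te2 <- makeTE(matrix(1:4, 2, 2), len = c(1000, NA))
    expect_error(normalizeExpression(te2, "TPM"), "missing gene length")
})

test_that("identical group count vectors give log2FC 0 and p = 1", {
    cts <- matrix(rep(c(30, 60, 90), 8), 3, 8,
                  dimnames = list(paste0("g", 1:3), paste0("s", 1:8)))
    te <- ThermalExperiment(cts, geneLength = rep(1000, 3),
                            strain = rep("A", 8),
                            group = rep(c("C", "H"), each = 4))
    d <- testDE(te, "C", "H")
    expect_equal(unname(d$log2FC), rep(0, 3))
    expect_equal(unname(d$pvalue), rep(1, 3))
})

test_that("all-zero genes are excluded by the filter with sentinel q", {
    set.seed(42)
    cts <- matrix(rpois(40, 50), 5, 8)
    cts[2, ] <- 0
    dimnames(cts) <- list(paste0("g", 1:5), paste0("s", 1:8))
    te <- ThermalExperiment(cts, geneLength = rep(1000, 5),
                            strain = rep("A", 8),
                            group = rep(c("C", "H"), each = 4))
    d <- testDE(te, "C", "H", filterThreshold = 1)
    expect_false(d["g2", "passedFilter"])
    expect_true(is.na(d["g2", "qvalue"]))
    expect_false(d["g2", "significant"])
})

test_that("design errors are caught before testing", {
    sim <- simulateCounts(simParams(nGenes = 50, seed = 42))
    expect_error(testDE(sim$experiment, "C", "X", strain = "Alma"),
                 "group absent")
    te <- sim$experiment[, 1:7]   # 6 C + 1 L within Alma
    expect_error(testDE(te, "C", "L", strain = "Alma"), "2 replicates")
})

test_that("q-values are BH-monotone and the filter leaves p untouched", {
    sim <- simulateCounts(simParams(nGenes = 800, seed = 42))
    d1 <- testDE(sim$experiment, "C", "H", strain = "Alma",
                 filterThreshold = 1)
    ok <- d1$passedFilter
    ord <- order(d1$pvalue[ok])
    expect_true(all(diff(d1$qvalue[ok][ord]) >= -1e-12))
    expect_true(all(d1$qvalue[ok] >= d1$pvalue[ok] - 1e-12))
    d0 <- testDE(sim$experiment, "C", "H", strain = "Alma",
                 filterThreshold = 0)
    ## filtering must not change p-values (hence not their rank order)
    expect_equal(d1$pvalue[ok], d0$pvalue[ok])
})

test_that("planted four-fold changes are recovered without gross bias", {
    med <- vapply(1:30, function(s) {
        p <- simParams(nGenes = 500, fracDE = 0.1, sharedFraction = 1,
                       lfcMean = 2, lfcSd = 0, dispersion = 0.1,
                       seed = 100 + s)
        sim <- simulateCounts(p)
        d <- testDE(sim$experiment, "C", "H", strain = "Alma")
        tr <- sim$truth$deGenes$HvC$Alma
        median(abs(d[tr$gene, "log2FC"]))
    }, numeric(1))
    expect_gt(median(med), 1.7)
    expect_lt(median(med), 2.3)
})

test_that("calls agree with edgeR as an independent reference", {
    skip_if_not_installed("edgeR")
    sim <- simulateCounts(simParams(nGenes = 400, seed = 42))
    te <- sim$experiment
    cd <- SummarizedExperiment::colData(te)
    sel <- cd$strain == "Alma" & cd$group %in% c("C", "H")
    cts <- SummarizedExperiment::assay(te, "counts")[, sel]
    grp <- factor(cd$group[sel], levels = c("C", "H"))
    y <- edgeR::DGEList(cts, group = grp)
    y <- edgeR::calcNormFactors(y)
    y <- edgeR::estimateDisp(y)
    et <- edgeR::exactTest(y)
    d <- testDE(te, "C", "H", strain = "Alma")
    ok <- d$passedFilter
    expect_gt(cor(d$log2FC[ok], et$table$logFC[ok]), 0.95)
    mineSig <- d$gene[d$significant]
    edgerSig <- rownames(et$table)[p.adjust(et$table$PValue, "BH") <= 0.01]
    ## strong overlap between the two callers on planted effects
    expect_gt(length(intersect(mineSig, edgerSig)) /
              max(1, length(union(mineSig, edgerSig))), 0.6)
})

test_that("shared-DEG intersection matches brute-force set arithmetic", {
    d1 <- makeDEG(c("g1", "g2", "g3"), c(2, -1, 4), c(0.001, 0.002, 0.003),
                  strain = "A")
    d2 <- makeDEG(c("g2", "g3", "g4"), c(-3, 2, 1), c(0.001, 0.004, 0.005),
                  strain = "B")
    sh <- intersectShared(d1, d2)
    tab <- sharedTable(sh)
    expect_equal(tab$gene, c("g3", "g2"))           # ranked by avg log2FC
    expect_equal(tab$avgLog2FC, c(3, -2))
    expect_equal(unname(vennCounts(sh)), c(1L, 1L, 2L))
    expect_false(any(tab$discordant))
    expect_equal(unname(sh@sharedProportion), c(2 / 3, 2 / 3))
})

test_that("disjoint and identical significant sets hit the extremes", {
    dA <- makeDEG(c("g1", "g2"), c(1, 2), c(0.001, 0.001), strain = "A")
    dB <- makeDEG(c("g3", "g4"), c(1, 2), c(0.001, 0.001), strain = "B")
    expect_equal(nrow(sharedTable(intersectShared(dA, dB))), 0L)
    expect_equal(unname(intersectShared(dA, dB)@sharedProportion), c(0, 0))
    dC <- makeDEG(c("g1", "g2"), c(1, 2), c(0.001, 0.001), strain = "B")
    expect_equal(unname(intersectShared(dA, dC)@sharedProportion), c(1, 1))
    dX <- makeDEG("g1", 1, 0.001, comparison = "LvC")
    expect_error(intersectShared(dA, dX), "comparison labels differ")
})

test_that("discordant shared genes are flagged but retained", {
    d1 <- makeDEG(c("g1", "g2"), c(2, 1), c(0.001, 0.001), strain = "A")
    d2 <- makeDEG(c("g1", "g2"), c(-2, 1), c(0.001, 0.001), strain = "B")
    tab <- sharedTable(intersectShared(d1, d2))
    expect_equal(nrow(tab), 2L)
    expect_true(tab$discordant[tab$gene == "g1"])
    expect_false(tab$discordant[tab$gene == "g2"])
})

test_that("PCA percent variance is normalized and degenerate cases behave", {
    set.seed(42)
    expr <- matrix(rnorm(200), 20, 10,
                   dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
    p <- runPCA(expr)
    expect_equal(sum(p$percentVariance), 100)
    expect_true(all(diff(p$eigenvalues) <= 1e-9))
    ## two perfectly correlated genes: PC1 carries everything
    base <- rnorm(10)
    expr2 <- rbind(g1 = base, g2 = 2 * base + 1)
    colnames(expr2) <- paste0("s", 1:10)
    p2 <- runPCA(expr2)
    expect_equal(p2$percentVariance[1], 100, tolerance = 1e-9)
    expr3 <- rbind(expr, gz = rep(1, 10))
    expect_warning(runPCA(expr3), "zero-variance")
    expect_error(suppressWarnings(runPCA(expr2[1, , drop = FALSE] * 0 + 1)),
                 "non-constant|2 samples|fewer")
})

test_that("planted group shifts separate on the leading components", {
    posSil <- vapply(1:20, function(s) {
        sim <- simulateCounts(simParams(nGenes = 200, fracDE = 0.2,
                                        sharedFraction = 1, seed = 200 + s))
        te <- sim$experiment
        cd <- SummarizedExperiment::colData(te)
        sel <- cd$strain == "Alma"
        tpm <- normalizeExpression(te[, sel], "TPM")
        p <- suppressWarnings(runPCA(tpm))
        sil <- cluster::silhouette(as.integer(factor(cd$group[sel])),
                                   dist(p$scores[, 1:2]))
        mean(sil[, 3]) > 0
    }, logical(1))
    expect_gte(mean(posSil), 0.9)
})

test_that("retained components are the smallest set reaching the target", {
    sim <- simulateCounts(simParams(nGenes = 300, seed = 42))
    tpm <- normalizeExpression(sim$experiment, "TPM")
    p <- runPCA(tpm, varianceTarget = 0.843)
    cum <- cumsum(p$percentVariance)
    expect_gte(cum[p$nRetained], 84.3)
    if (p$nRetained > 1) expect_lt(cum[p$nRetained - 1], 84.3)
})
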