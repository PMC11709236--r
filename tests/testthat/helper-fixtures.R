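## Shared fixture builders; everything is generated in code.

## A shared-DEG table + orthologue map with exact duplicate/mismatch counts:
## nSingle singleton orthologues, nDup2 with two copies, nDup3 with three,
## nMismatch of the duplicated ones planted strain-discordant.
makeConsolidationFixture <- function(nSingle, nDup2, nDup3, nMismatch) {
    stopifnot(nMismatch <= nDup2 + nDup3)
    genes <- character(); orth <- character()
    l1 <- numeric(); l2 <- numeric()
    addCopy <- function(o, g, a, b) {
        genes <<- c(genes, g); orth <<- c(orth, o)
        l1 <<- c(l1, a); l2 <<- c(l2, b)
    }
    oid <- 0
    nDup <- nDup2 + nDup3
    for (i in seq_len(nDup)) {
        oid <- oid + 1
        o <- sprintf("D%06d", oid)
        k <- if (i <= nDup2) 2L else 3L
        mism <- i <= nMismatch
        ## copy 1 dominates strain 1, copy 2 dominates strain 2
        if (mism) {
            addCopy(o, paste0(o, "_a"), 3.0, 0.5)
            addCopy(o, paste0(o, "_b"), -1.0, -2.5)
        } else {
            addCopy(o, paste0(o, "_a"), 2.0, 2.2)
            addCopy(o, paste0(o, "_b"), 1.0, 0.8)
        }
        if (k == 3L) addCopy(o, paste0(o, "_c"), 0.5, 0.4)
    }
    for (i in seq_len(nSingle)) {
        o <- sprintf("S%06d", i)
        addCopy(o, paste0(o, "_a"), 1.5, 1.2)
    }
    list(shared = data.frame(gene = genes, log2FC1 = l1, log2FC2 = l2),
         map = data.frame(gene = genes, ortholog = orth))
}

## Minimal DEGTable from gene/log2FC/q vectors (all passing the filter).
makeDEG <- function(genes, lfc, q, comparison = "HvC", strain = "s",
                    qCut = 0.01) {
    tab <- S4Vectors::DataFrame(
        gene = genes, log2FC = lfc, pvalue = pmin(q, 1) / 2, qvalue = q,
        passedFilter = rep(TRUE, length(genes)),
        significant = q <= qCut, row.names = genes)
    new("DEGTable", tab, strain = strain, comparison = comparison,
        qCut = qCut, filterThreshold = 0)
}

## Truth skeleton for annotation/association generators: genes with fixed
## enhanced groups, identity orthologue map.
makeDirectedTruth <- function(nPerGroup) {
    genes <- sprintf("g%04d", seq_len(2 * nPerGroup))
    grp <- rep(c("H", "L"), each = nPerGroup)
    list(plan = list(genes = genes),
         enhancedGroup = stats::setNames(grp, genes),
         orthologMap = data.frame(gene = genes, ortholog = genes))
}

## Random term-by-2 count table for G-test property checks.
randomCountTable <- function(nTerms = 8, N = 400) {
    prop <- as.vector(stats::rgamma(nTerms, 1.5)) + 0.05
    prop <- prop / sum(prop)
    cbind(stats::rmultinom(1, N, prop)[, 1],
          stats::rmultinom(1, N, prop)[, 1])
}
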