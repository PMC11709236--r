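#' Cross-strain shared differentially expressed genes
#'
#' Intersects the significant gene sets of two strains for the same
#' comparison, records per-strain directions and the average log2 fold
#' change (the cross-strain ranking statistic), and summarizes Venn counts
#' and per-strain proportions. Direction-discordant shared genes are flagged
#' (\code{discordant}) but retained.
#'
#' @param deg1,deg2 [DEGTable-class] results for the two strains, same
#'   comparison.
#' @param qCut significance cut-off applied to both tables (default 0.01).
#' @return a [SharedDEGSet-class]. The table is sorted by average log2FC,
#'   descending; ties break by gene ID.
#' @examples
#' sim <- simulateStudy(simParams(nGenes = 400, seed = 3))
#' d1 <- testDE(sim$experiment, "C", "H", strain = "Alma")
#' d2 <- testDE(sim$experiment, "C", "H", strain = "Lyndon")
#' intersectShared(d1, d2)
#' @export
intersectShared <- function(deg1, deg2, qCut = 0.01) {
    if (!identical(deg1@comparison, deg2@comparison))
        stop("comparison labels differ: ", deg1@comparison, " vs ",
             deg2@comparison)
    sig <- function(d) d$gene[d$significant & !is.na(d$qvalue) &
                              d$qvalue <= qCut]
    set1 <- sig(deg1); set2 <- sig(deg2)
    shared <- intersect(set1, set2)
    lfc1 <- stats::setNames(deg1$log2FC, deg1$gene)[shared]
    lfc2 <- stats::setNames(deg2$log2FC, deg2$gene)[shared]
    avg <- (lfc1 + lfc2) / 2
    ord <- order(-avg, shared)
    tab <- S4Vectors::DataFrame(
        gene = shared[ord],
        log2FC1 = unname(lfc1[ord]), log2FC2 = unname(lfc2[ord]),
        direction1 = ifelse(lfc1[ord] > 0, "up", "down"),
        direction2 = ifelse(lfc2[ord] > 0, "up", "down"),
        avgLog2FC = unname(avg[ord]),
        discordant = unname(sign(lfc1[ord]) != sign(lfc2[ord])))
    strains <- c(deg1@strain, deg2@strain)
    venn <- c(length(setdiff(set1, set2)), length(setdiff(set2, set1)),
              length(shared))
    names(venn) <- c(paste0("unique_", strains[1]),
                     paste0("unique_", strains[2]), "shared")
    prop <- c(if (length(set1)) length(shared) / length(set1) else 0,
              if (length(set2)) length(shared) / length(set2) else 0)
    upp <- c(if (length(set1))
                 mean(stats::setNames(deg1$log2FC, deg1$gene)[set1] > 0) else NA,
             if (length(set2))
                 mean(stats::setNames(deg2$log2FC, deg2$gene)[set2] > 0) else NA)
    new("SharedDEGSet", comparison = deg1@comparison, strains = strains,
        table = tab, vennCounts = as.integer(venn),
        sharedProportion = stats::setNames(prop, strains),
        upProportion = stats::setNames(upp, strains),
        strainSets = stats::setNames(list(set1, set2), strains))
}

#' Accessor: the shared-gene table of a SharedDEGSet
#' @param x a [SharedDEGSet-class]
#' @return a \code{DFrame} sorted by average log2FC, descending
#' @export
sharedTable <- function(x) x@table

#' Accessor: Venn counts of a SharedDEGSet
#' @param x a [SharedDEGSet-class]
#' @return integer vector (unique to strain 1, unique to strain 2, shared)
#' @export
vennCounts <- function(x) {
    stats::setNames(x@vennCounts,
                    c(paste0("unique_", x@strains), "shared"))
}
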