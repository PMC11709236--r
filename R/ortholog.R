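#' Consolidate duplicated trout genes onto mammalian orthologues
#'
#' Salmonid genome duplication maps many trout genes onto one mammalian
#' orthologue ID. Per strain, the copy with the largest absolute log2 fold
#' change is selected (ties break toward the larger raw log2FC, then
#' lexicographic gene ID); the additive total log2FC over all copies is also
#' recorded. An orthologue is a \code{mismatch} when the selected copies of
#' the two strains differ in expression sign; such orthologues are flagged
#' and retained, never removed.
#'
#' @param shared a [SharedDEGSet-class] or a data.frame with columns
#'   \code{gene}, \code{log2FC1}, \code{log2FC2} (per-strain fold changes of
#'   genes significant in both strains).
#' @param map data.frame with columns \code{gene} and \code{ortholog}; genes
#'   absent from the map are dropped with a message.
#' @param comparison label stored in the result (taken from \code{shared}
#'   when it is a [SharedDEGSet-class]).
#' @param strains optional two strain labels for the result metadata.
#' @return a [ConsolidatedTable-class], one row per orthologue ID.
#' @examples
#' sh <- data.frame(gene = c("t1", "t2", "t3"),
#'                  log2FC1 = c(3, -1, 2), log2FC2 = c(0.5, -2.5, 1.8))
#' mp <- data.frame(gene = c("t1", "t2", "t3"),
#'                  ortholog = c("X", "X", "Y"))
#' consolidateOrthologs(sh, mp, comparison = "HvL")
#' @export
consolidateOrthologs <- function(shared, map, comparison = NULL,
                                 strains = NULL) {
    if (is(shared, "SharedDEGSet")) {
        if (is.null(comparison)) comparison <- shared@comparison
        if (is.null(strains)) strains <- shared@strains
        shared <- as.data.frame(shared@table)
    }
    if (is.null(comparison)) comparison <- NA_character_
    if (is.null(strains)) strains <- c("strain1", "strain2")
    if (NROW(map) == 0L) stop("orthologue map is empty")
    if (anyDuplicated(map$gene))
        stop("a trout gene may appear at most once in the map")
    hit <- shared$gene %in% map$gene
    nUnmapped <- sum(!hit)
    if (nUnmapped > 0)
        message(nUnmapped, " gene(s) without an orthologue mapping dropped")
    shared <- shared[hit, , drop = FALSE]
    orth <- map$ortholog[match(shared$gene, map$gene)]

    if (nrow(shared) == 0L) {
        empty <- data.frame(ortholog = character(), nCopies = integer(),
                            isDuplicated = logical(), selGene1 = character(),
                            selLFC1 = numeric(), selGene2 = character(),
                            selLFC2 = numeric(), addLFC1 = numeric(),
                            addLFC2 = numeric(), mismatch = logical(),
                            addOpposite1 = logical(), addOpposite2 = logical())
        return(new("ConsolidatedTable", S4Vectors::DataFrame(empty),
                   comparison = comparison, strains = strains,
                   nMappedDEG = 0L, nUniqueMappedIDs = 0L,
                   nUnmapped = as.integer(nUnmapped)))
    }
    g <- shared$gene
    l1 <- shared$log2FC1; l2 <- shared$log2FC2
    ## selection per strain: within each orthologue, order by |log2FC|
    ## descending, then raw log2FC descending, then gene ID; the first row
    ## per orthologue is the selected copy
    ord1 <- order(orth, -abs(l1), -l1, g)
    i1 <- ord1[!duplicated(orth[ord1])]
    ord2 <- order(orth, -abs(l2), -l2, g)
    i2 <- ord2[!duplicated(orth[ord2])]
    ids <- orth[i1]                       # sorted unique orthologue IDs
    nCopies <- as.integer(table(orth)[ids])
    a1 <- rowsum(l1, orth)[ids, 1]
    a2 <- rowsum(l2, orth)[ids, 1]
    tab <- data.frame(
        ortholog = ids, nCopies = nCopies, isDuplicated = nCopies >= 2L,
        selGene1 = g[i1], selLFC1 = l1[i1],
        selGene2 = g[i2], selLFC2 = l2[i2],
        addLFC1 = unname(a1), addLFC2 = unname(a2),
        mismatch = sign(l1[i1]) != sign(l2[i2]),
        addOpposite1 = a1 != 0 & sign(a1) != sign(l1[i1]),
        addOpposite2 = a2 != 0 & sign(a2) != sign(l2[i2]),
        row.names = NULL)
    new("ConsolidatedTable", S4Vectors::DataFrame(tab),
        comparison = comparison, strains = strains,
        nMappedDEG = nrow(shared), nUniqueMappedIDs = nrow(tab),
        nUnmapped = as.integer(nUnmapped))
}

#' Summarize cross-strain mismatch rates after consolidation
#'
#' Counts duplicated orthologues whose selected copies disagree in sign
#' between strains, and expresses the mismatch count against three
#' denominators: unique duplicated IDs, all mapped DEG records, and unique
#' mapped orthologue IDs. Percentages are rounded half-up to one decimal.
#'
#' @param tab a [ConsolidatedTable-class] for one comparison.
#' @return list with counts (\code{nMappedDEG}, \code{nDuplicateRecords},
#'   \code{nUniqueDuplicatedIDs}, \code{nUniqueMappedIDs},
#'   \code{nMismatches}) and rates (\code{pctOfDuplicated},
#'   \code{pctOfMappedRecords}, \code{pctOfUniqueMapped}).
#' @export
summarizeMismatches <- function(tab) {
    dup <- tab$isDuplicated
    nDupRecords <- sum(tab$nCopies[dup])
    nDupIDs <- sum(dup)
    nMis <- sum(tab$mismatch[dup])
    pct <- function(num, den) if (den > 0) roundHalfUp(100 * num / den, 1) else 0
    list(comparison = tab@comparison,
         nMappedDEG = tab@nMappedDEG,
         nDuplicateRecords = as.integer(nDupRecords),
         nUniqueDuplicatedIDs = as.integer(nDupIDs),
         nUniqueMappedIDs = tab@nUniqueMappedIDs,
         nMismatches = as.integer(nMis),
         pctOfDuplicated = pct(nMis, nDupIDs),
         pctOfMappedRecords = pct(nMis, tab@nMappedDEG),
         pctOfUniqueMapped = pct(nMis, tab@nUniqueMappedIDs))
}
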