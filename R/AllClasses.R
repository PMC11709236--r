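#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom S4Vectors DFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

#' Container for a thermal-tolerance count experiment
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] subclass holding an
#' integer gene-by-sample count matrix (assay \code{"counts"}), per-gene
#' lengths in bp (\code{rowData()$gene_length}) and per-sample metadata
#' (\code{colData()} columns \code{strain}, \code{group}, \code{lib_size}).
#' Library sizes are always the realized column sums of the count matrix.
#'
#' @slot .. see \code{SummarizedExperiment}.
#' @export
setClass("ThermalExperiment", contains = "SummarizedExperiment")

setValidity("ThermalExperiment", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cts <- assay(object, "counts")
        if (any(cts < 0)) msg <- c(msg, "counts must be non-negative")
        if (any(abs(cts - round(cts)) > 1e-8))
            msg <- c(msg, "counts must be integers")
    }
    rd <- rowData(object)
    if (!"gene_length" %in% colnames(rd))
        msg <- c(msg, "rowData column 'gene_length' is required")
    else if (any(rd$gene_length <= 0, na.rm = TRUE))
        msg <- c(msg, "gene lengths must be positive")
    cd <- colData(object)
    need <- setdiff(c("strain", "group", "lib_size"), colnames(cd))
    if (length(need))
        msg <- c(msg, paste("colData missing:", paste(need, collapse = ", ")))
    if (!length(msg) && "counts" %in% SummarizedExperiment::assayNames(object)) {
        cs <- colSums(assay(object, "counts"))
        if (any(abs(cs - cd$lib_size) > 1e-6))
            msg <- c(msg, "lib_size must equal column sums of counts")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a ThermalExperiment
#'
#' @param counts integer matrix, genes in rows, samples in columns. Row and
#'   column names are required (gene and sample identifiers).
#' @param geneLength numeric vector of gene lengths in bp, one per row.
#' @param strain,group character/factor vectors, one per sample.
#' @return A [ThermalExperiment-class] object; \code{lib_size} is computed
#'   from the column sums.
#' @examples
#' cts <- matrix(rpois(12, 40), 3, 4,
#'               dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' te <- ThermalExperiment(cts, geneLength = c(500, 1000, 2000),
#'                         strain = rep("Alma", 4),
#'                         group = c("C", "C", "H", "H"))
#' librarySizes(te)
#' @export
ThermalExperiment <- function(counts, geneLength, strain, group) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)) || is.null(colnames(counts)))
        stop("'counts' must have row (gene) and column (sample) names")
    se <- SummarizedExperiment(
        assays = list(counts = counts),
        rowData = S4Vectors::DataFrame(gene_length = as.numeric(geneLength),
                                       row.names = rownames(counts)),
        colData = S4Vectors::DataFrame(strain = as.character(strain),
                                       group = as.character(group),
                                       lib_size = colSums(counts),
                                       row.names = colnames(counts)))
    new("ThermalExperiment", se)
}

#' Per-gene differential expression results
#'
#' A \code{DFrame} subclass with one row per gene and columns \code{gene},
#' \code{log2FC}, \code{pvalue}, \code{qvalue}, \code{passedFilter},
#' \code{significant}. Genes failing the mean-expression filter carry
#' \code{qvalue = NA} and are never called significant. The comparison label
#' (\code{"HvC"}, \code{"LvC"} or \code{"HvL"}), strain, q-value cut-off and
#' filter threshold travel in the slots.
#'
#' @export
setClass("DEGTable", contains = "DFrame",
         representation(strain = "character", comparison = "character",
                        qCut = "numeric", filterThreshold = "numeric"))

setValidity("DEGTable", function(object) {
    msg <- character()
    need <- setdiff(c("gene", "log2FC", "pvalue", "qvalue",
                      "passedFilter", "significant"), colnames(object))
    if (length(need))
        return(paste("missing columns:", paste(need, collapse = ", ")))
    ok <- object$passedFilter
    q <- object$qvalue
    if (any(!is.na(q) & (q < 0 | q > 1))) msg <- c(msg, "qvalue outside [0,1]")
    if (any(ok & !is.na(q) & q < object$pvalue - 1e-12, na.rm = TRUE))
        msg <- c(msg, "qvalue below pvalue within the filtered set")
    if (any(!ok & object$significant))
        msg <- c(msg, "filtered-out genes must not be significant")
    if (any(!ok & !is.na(q)))
        msg <- c(msg, "filtered-out genes must carry qvalue = NA")
    if (length(msg)) msg else TRUE
})

#' Cross-strain shared differentially expressed genes
#'
#' Holds, for one comparison, the per-strain significant gene sets, the
#' shared set with per-strain directions and average log2 fold change
#' (ranking order), Venn counts (unique to strain 1, unique to strain 2,
#' shared) and per-strain proportions (shared fraction, fraction upregulated
#' in the focal group). Direction-discordant shared genes are flagged but
#' retained.
#'
#' @export
setClass("SharedDEGSet",
         representation(comparison = "character", strains = "character",
                        table = "DFrame", vennCounts = "integer",
                        sharedProportion = "numeric",
                        upProportion = "numeric",
                        strainSets = "list"))

setValidity("SharedDEGSet", function(object) {
    msg <- character()
    tab <- object@table
    if (length(object@strains) != 2L) msg <- c(msg, "exactly two strains")
    if (length(object@vennCounts) != 3L) msg <- c(msg, "vennCounts has 3 cells")
    shared <- tab$gene
    for (s in seq_along(object@strainSets))
        if (!all(shared %in% object@strainSets[[s]]))
            msg <- c(msg, "shared set must be a subset of each strain set")
    un <- length(unique(unlist(object@strainSets)))
    if (length(object@vennCounts) == 3L && sum(object@vennCounts) != un)
        msg <- c(msg, "Venn counts must sum to the union size")
    if (any(object@sharedProportion < 0 | object@sharedProportion > 1))
        msg <- c(msg, "proportions must lie in [0,1]")
    if (length(msg)) msg else TRUE
})

#' Orthologue-level consolidated expression table
#'
#' One row per mammalian orthologue ID after duplicate-copy selection: the
#' selected trout gene and its log2FC per strain (the copy with the largest
#' absolute fold change), copy number, additive total log2FC per strain, a
#' cross-strain \code{mismatch} flag (selected copies differ in sign) and
#' per-strain \code{addOpposite} flags (additive total opposes the selected
#' copy). Record counts used as rate denominators travel in the slots.
#'
#' @export
setClass("ConsolidatedTable", contains = "DFrame",
         representation(comparison = "character", strains = "character",
                        nMappedDEG = "integer", nUniqueMappedIDs = "integer",
                        nUnmapped = "integer"))

setValidity("ConsolidatedTable", function(object) {
    need <- setdiff(c("ortholog", "nCopies", "isDuplicated",
                      "selGene1", "selLFC1", "selGene2", "selLFC2",
                      "addLFC1", "addLFC2", "mismatch",
                      "addOpposite1", "addOpposite2"), colnames(object))
    if (length(need))
        return(paste("missing columns:", paste(need, collapse = ", ")))
    msg <- character()
    if (anyDuplicated(object$ortholog))
        msg <- c(msg, "one record per orthologue ID")
    if (any(object$isDuplicated != (object$nCopies >= 2L)))
        msg <- c(msg, "isDuplicated must mirror nCopies >= 2")
    if (length(msg)) msg else TRUE
})

#' GO-slim count table with backward-elimination G-test outcome
#'
#' Per namespace (BP/CC/MF): term counts and percent counts for the focal and
#' reference gene groups, the percent difference used for ranking, and the
#' elimination trace — removal step, 2x2 partition G at removal, its p-value
#' and the enriched group — plus the initial and residual heterogeneity G.
#'
#' @export
setClass("SlimGTest",
         representation(namespace = "character", groups = "character",
                        alpha = "numeric", table = "DFrame",
                        initialG = "numeric", initialDf = "integer",
                        initialP = "numeric", residualG = "numeric",
                        residualDf = "integer", residualP = "numeric"))

setValidity("SlimGTest", function(object) {
    tab <- object@table
    msg <- character()
    steps <- tab$removalStep[!is.na(tab$removalStep)]
    if (length(steps) && !identical(sort(steps), seq_along(steps)))
        msg <- c(msg, "removal steps must be consecutive integers from 1")
    if (any(tab$partitionG < -1e-9, na.rm = TRUE))
        msg <- c(msg, "partition G must be non-negative")
    if (length(msg)) msg else TRUE
})

setMethod("show", "ThermalExperiment", function(object) {
    callNextMethod()
    cat("strains:", paste(unique(colData(object)$strain), collapse = ", "),
        "| groups:", paste(unique(colData(object)$group), collapse = ", "),
        "\n")
})

setMethod("show", "DEGTable", function(object) {
    cat(sprintf("DEGTable: %s, %s | %d genes, %d pass filter, %d significant (q <= %g)\n",
                object@strain, object@comparison, nrow(object),
                sum(object$passedFilter), sum(object$significant),
                object@qCut))
    callNextMethod()
})

setMethod("show", "SharedDEGSet", function(object) {
    cat(sprintf("SharedDEGSet: %s across %s\n", object@comparison,
                paste(object@strains, collapse = " / ")))
    cat(sprintf("  Venn (unique %s, unique %s, shared): %s\n",
                object@strains[1], object@strains[2],
                paste(object@vennCounts, collapse = ", ")))
    cat(sprintf("  shared proportion: %s\n",
                paste(sprintf("%s=%.3f", object@strains,
                              object@sharedProportion), collapse = ", ")))
})

setMethod("show", "ConsolidatedTable", function(object) {
    cat(sprintf("ConsolidatedTable: %s | %d orthologues (%d duplicated), %d mapped DEG records\n",
                object@comparison, nrow(object), sum(object$isDuplicated),
                object@nMappedDEG))
    callNextMethod()
})

setMethod("show", "SlimGTest", function(object) {
    nrem <- sum(!is.na(object@table$removalStep))
    cat(sprintf("SlimGTest [%s]: %d terms, %d removed (alpha = %g)\n",
                object@namespace, nrow(object@table), nrem, object@alpha))
    cat(sprintf("  initial G = %.3f (df %d, p = %.3g); residual G = %.3f (df %d, p = %.3g)\n",
                object@initialG, object@initialDf, object@initialP,
                object@residualG, object@residualDf, object@residualP))
})
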