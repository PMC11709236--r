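#' @describeIn testDE Negative-binomial Wald test between two groups.
#'
#' For each gene, counts are library-size normalized (size factor = library
#' size / mean library size), the NB dispersion is estimated by method of
#' moments, floored at 1e-8 and shrunk 50/50 toward the mean dispersion of
#' the filtered gene set, and the log2 fold change of the group means (0.5
#' pseudo-count) is tested with a Wald statistic referred to the standard
#' normal distribution. Genes whose mean
#' normalized count across the tested samples falls below
#' \code{filterThreshold} are excluded before Benjamini-Hochberg correction
#' and carry \code{qvalue = NA} (filtered FDR correction).
#'
#' @param groupA reference group label (e.g. \code{"C"}).
#' @param groupB focal group label; positive log2FC means up in this group.
#' @param strain optional strain label to subset samples first.
#' @param filterThreshold minimum mean normalized count (default 1).
#' @param qCut significance cut-off on the BH-adjusted q value (default 0.01).
#' @param comparison label stored in the result (default
#'   \code{"<groupB>v<groupA>"}).
#' @export
setMethod("testDE", "ThermalExperiment",
          function(x, groupA, groupB, strain = NULL, filterThreshold = 1,
                   qCut = 0.01, comparison = NULL) {
    cd <- colData(x)
    if (!is.null(strain)) {
        if (!strain %in% cd$strain) stop("strain not in metadata: ", strain)
        x <- x[, cd$strain == strain]
        cd <- colData(x)
    }
    for (g in c(groupA, groupB))
        if (!g %in% cd$group) stop("group absent from metadata: ", g)
    selA <- cd$group == groupA
    selB <- cd$group == groupB
    if (sum(selA) < 2L || sum(selB) < 2L)
        stop("at least 2 replicates per group are required")
    cts <- assay(x, "counts")[, selA | selB, drop = FALSE]
    grpB <- cd$group[selA | selB] == groupB
    lib <- colSums(cts)
    sf <- lib / mean(lib)
    y <- sweep(cts, 2, sf, "/")
    nA <- sum(!grpB); nB <- sum(grpB)
    mA <- rowMeans(y[, !grpB, drop = FALSE])
    mB <- rowMeans(y[, grpB, drop = FALSE])
    vA <- apply(y[, !grpB, drop = FALSE], 1, stats::var)
    vB <- apply(y[, grpB, drop = FALSE], 1, stats::var)
    invSA <- mean(1 / sf[!grpB]); invSB <- mean(1 / sf[grpB])

    meanAll <- rowMeans(y)
    passed <- meanAll >= filterThreshold

    ## method-of-moments dispersion, pooled across groups by df
    phiFrom <- function(v, m, invS)
        ifelse(m > 0, (v - m * invS) / m^2, NA_real_)
    phiA <- phiFrom(vA, mA, invSA); phiB <- phiFrom(vB, mB, invSB)
    wA <- ifelse(is.na(phiA), 0, nA - 1); wB <- ifelse(is.na(phiB), 0, nB - 1)
    phiRaw <- (ifelse(is.na(phiA), 0, phiA) * wA +
               ifelse(is.na(phiB), 0, phiB) * wB) /
              pmax(wA + wB, 1)
    phiRaw <- pmax(phiRaw, 1e-8)
    phiGlobal <- if (any(passed)) mean(phiRaw[passed]) else 1e-8
    phi <- 0.5 * phiRaw + 0.5 * phiGlobal

    lfc <- log2((mB + 0.5) / (mA + 0.5))
    varLnA <- invSA / (nA * (mA + 0.5)) + phi / nA
    varLnB <- invSB / (nB * (mB + 0.5)) + phi / nB
    se <- sqrt(varLnA + varLnB) / log(2)
    z <- ifelse(se > 0, lfc / se, 0)
    p <- 2 * stats::pnorm(-abs(z))
    p[mA == mB] <- 1

    q <- rep(NA_real_, length(p))
    q[passed] <- stats::p.adjust(p[passed], method = "BH")
    tab <- S4Vectors::DataFrame(
        gene = rownames(cts), log2FC = unname(lfc), pvalue = unname(p),
        qvalue = unname(q), passedFilter = unname(passed),
        significant = unname(passed & !is.na(q) & q <= qCut),
        row.names = rownames(cts))
    new("DEGTable", tab,
        strain = if (is.null(strain)) NA_character_ else strain,
        comparison = if (is.null(comparison)) paste0(groupB, "v", groupA)
                     else comparison,
        qCut = qCut, filterThreshold = filterThreshold)
})
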