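#' Per-group GO-slim term counts
#'
#' Counts, for two disjoint gene groups (typically the genes upregulated in
#' each side of a comparison), how many annotations each GO-slim term
#' receives per group, within each namespace. A gene with k terms
#' contributes k counts. Terms with zero counts in both groups are dropped;
#' tables are sorted by the percent-count difference, descending, which is
#' the ranking used to read off which side a term leans toward.
#'
#' @param genesFocal,genesRef character vectors of gene IDs (disjoint).
#' @param annot data.frame with columns \code{gene}, \code{namespace},
#'   \code{term}.
#' @param groups labels for the two columns (default
#'   \code{c("focal", "reference")}).
#' @return named list (one element per namespace present) of data.frames
#'   with columns \code{term}, \code{nFocal}, \code{nRef}, \code{pctFocal},
#'   \code{pctRef}, \code{pctDiff}.
#' @export
countSlim <- function(genesFocal, genesRef, annot,
                      groups = c("focal", "reference")) {
    if (length(genesFocal) == 0L && length(genesRef) == 0L)
        stop("both gene sets are empty")
    if (length(intersect(genesFocal, genesRef)))
        stop("gene sets must be disjoint")
    out <- list()
    for (ns in sort(unique(annot$namespace))) {
        a <- annot[annot$namespace == ns, , drop = FALSE]
        terms <- sort(unique(a$term))
        nF <- table(factor(a$term[a$gene %in% genesFocal], levels = terms))
        nR <- table(factor(a$term[a$gene %in% genesRef], levels = terms))
        tab <- data.frame(term = terms, nFocal = as.integer(nF),
                          nRef = as.integer(nR))
        tab <- tab[tab$nFocal + tab$nRef > 0, , drop = FALSE]
        if (!nrow(tab)) next
        NF <- sum(tab$nFocal); NR <- sum(tab$nRef)
        tab$pctFocal <- if (NF > 0) 100 * tab$nFocal / NF else 0
        tab$pctRef <- if (NR > 0) 100 * tab$nRef / NR else 0
        tab$pctDiff <- tab$pctFocal - tab$pctRef
        tab <- tab[order(-tab$pctDiff, tab$term), , drop = FALSE]
        rownames(tab) <- NULL
        attr(tab, "groups") <- groups
        out[[ns]] <- tab
    }
    out
}

xlogx <- function(x) ifelse(x > 0, x * log(x), 0)

#' Heterogeneity G statistic for a terms-by-groups count table
#'
#' Likelihood-ratio statistic G = 2 sum O ln(O/E) with expectations from the
#' row and column margins; zero cells contribute 0. Degrees of freedom are
#' R - 1 for the two-column table; p comes from the chi-square upper tail.
#'
#' @param mat numeric matrix with R rows (terms) and 2 columns (groups).
#' @param correction \code{"none"} (default; the additive decomposition over
#'   row partitions is exact only without correction) or \code{"williams"}.
#' @return list with \code{G}, \code{df}, \code{p}.
#' @examples
#' gStatistic(rbind(c(30, 10), c(10, 30)))  # G approx 20.93
#' @export
gStatistic <- function(mat, correction = c("none", "williams")) {
    correction <- match.arg(correction)
    mat <- as.matrix(mat)
    if (nrow(mat) < 2L) stop("single-row table is untestable")
    rt <- rowSums(mat); ct <- colSums(mat); N <- sum(mat)
    if (sum(rt > 0) < 2L) stop("need at least 2 rows with positive totals")
    if (any(ct <= 0)) stop("both column totals must be positive")
    G <- 2 * (sum(xlogx(mat)) - sum(xlogx(rt)) - sum(xlogx(ct)) + xlogx(N))
    G <- max(G, 0)
    df <- nrow(mat) - 1L
    if (correction == "williams") {
        q <- 1 + (N * sum(1 / rt[rt > 0]) - 1) * (N * sum(1 / ct) - 1) /
            (6 * N * df * (ncol(mat) - 1L))
        G <- G / q
    }
    list(G = G, df = as.integer(df), p = stats::pchisq(G, df, lower.tail = FALSE))
}

## Partition G of each row against the pooled remainder (2x2), vectorized.
## By the additive decomposition, G_full = G_partition(i) + G_without(i).
partitionG <- function(mat) {
    a <- mat[, 1]; b <- mat[, 2]
    CA <- sum(a); CB <- sum(b); N <- CA + CB
    ri <- a + b
    2 * (xlogx(a) + xlogx(b) + xlogx(CA - a) + xlogx(CB - b) -
         xlogx(ri) - xlogx(N - ri) - xlogx(CA) - xlogx(CB) + xlogx(N))
}

#' Backward-elimination heterogeneity G-test for GO-slim overrepresentation
#'
#' While the overall heterogeneity G over the remaining terms is significant
#' at \code{alpha} and more than one term remains, the term with the largest
#' 2x2 partition G (term versus pooled remainder) is removed and recorded
#' with its removal step, partition G and enriched group (the sign of its
#' percent-count difference in the table current at removal). By the exact
#' additive decomposition of G over row partitions, each removal subtracts
#' the partition G from the residual, so removed terms are exactly the ones
#' carrying the heterogeneity. Terms never removed are not significant.
#'
#' @param tab a per-namespace table from [countSlim()] (columns \code{term},
#'   \code{nFocal}, \code{nRef}).
#' @param alpha stopping level in (0, 1), default 0.05.
#' @param namespace label stored in the result.
#' @param groups two group labels (focal first); defaults taken from the
#'   table when present.
#' @return a [SlimGTest-class].
#' @examples
#' tab <- data.frame(term = paste0("T", 1:5),
#'                   nFocal = c(80, 20, 20, 20, 20),
#'                   nRef   = c(20, 20, 20, 20, 20))
#' backwardEliminate(tab, alpha = 0.05)
#' @export
backwardEliminate <- function(tab, alpha = 0.05, namespace = NA_character_,
                              groups = NULL) {
    if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
        alpha <= 0 || alpha >= 1)
        stop("alpha must lie strictly between 0 and 1")
    if (is.null(groups))
        groups <- attr(tab, "groups") %||% c("focal", "reference")
    keep <- tab$nFocal + tab$nRef > 0
    tab <- tab[keep, , drop = FALSE]
    m <- as.matrix(tab[, c("nFocal", "nRef")])
    rownames(m) <- tab$term
    init <- if (nrow(m) >= 2L && all(colSums(m) > 0)) gStatistic(m)
            else list(G = 0, df = 0L, p = 1)
    res <- data.frame(term = tab$term,
                      nFocal = tab$nFocal, nRef = tab$nRef,
                      removalStep = NA_integer_, partitionG = NA_real_,
                      pAtRemoval = NA_real_,
                      enrichedGroup = NA_character_)
    cur <- init
    step <- 0L
    while (nrow(m) > 1L && all(colSums(m) > 0) && cur$p < alpha) {
        pg <- partitionG(m)
        pct <- 100 * (m[, 1] / sum(m[, 1]) - m[, 2] / sum(m[, 2]))
        ord <- order(-pg, -abs(pct), rownames(m))
        i <- ord[1]
        step <- step + 1L
        j <- match(rownames(m)[i], res$term)
        res$removalStep[j] <- step
        res$partitionG[j] <- pg[i]
        res$pAtRemoval[j] <- stats::pchisq(pg[i], 1L, lower.tail = FALSE)
        res$enrichedGroup[j] <- if (pct[i] >= 0) groups[1] else groups[2]
        m <- m[-i, , drop = FALSE]
        cur <- if (nrow(m) >= 2L && all(colSums(m) > 0)) gStatistic(m)
               else list(G = 0, df = 0L, p = 1)
    }
    ## final percent columns on the full input table, for reporting
    NF <- sum(res$nFocal); NR <- sum(res$nRef)
    res$pctFocal <- if (NF > 0) 100 * res$nFocal / NF else 0
    res$pctRef <- if (NR > 0) 100 * res$nRef / NR else 0
    res$pctDiff <- res$pctFocal - res$pctRef
    res <- res[order(!is.na(res$removalStep) * 0, res$removalStep,
                     -res$pctDiff, res$term, na.last = TRUE), , drop = FALSE]
    res <- res[order(res$removalStep, -res$pctDiff, res$term,
                     na.last = TRUE), , drop = FALSE]
    rownames(res) <- NULL
    new("SlimGTest", namespace = namespace, groups = groups, alpha = alpha,
        table = S4Vectors::DataFrame(res),
        initialG = init$G, initialDf = init$df, initialP = init$p,
        residualG = cur$G, residualDf = cur$df, residualP = cur$p)
}

#' Removed (overrepresented) terms of a backward-elimination outcome
#' @param x a [SlimGTest-class]
#' @return data.frame of removed terms in removal order
#' @export
removedTerms <- function(x) {
    tab <- as.data.frame(x@table)
    tab <- tab[!is.na(tab$removalStep), , drop = FALSE]
    tab[order(tab$removalStep), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
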