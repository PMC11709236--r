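#' Correlation-matrix PCA of samples
#'
#' Principal component analysis of samples-as-observations on centred and
#' unit-scaled expression values (correlation-matrix PCA). Genes with zero
#' variance across samples are dropped with a warning before scaling. The
#' number of retained components is the smallest k whose cumulative percent
#' variance reaches \code{varianceTarget}.
#'
#' @param expr numeric gene-by-sample matrix (e.g. from
#'   [normalizeExpression()]), optionally restricted to significant genes.
#' @param varianceTarget cumulative variance fraction for retention
#'   (default 0.843).
#' @return list with \code{scores} (samples x components),
#'   \code{eigenvalues}, \code{percentVariance}, \code{nRetained}.
#' @export
runPCA <- function(expr, varianceTarget = 0.843) {
    if (ncol(expr) < 2L) stop("at least 2 samples are required")
    v <- apply(expr, 1, stats::var)
    if (any(v == 0)) {
        warning(sum(v == 0), " zero-variance gene(s) dropped before scaling")
        expr <- expr[v > 0, , drop = FALSE]
    }
    if (nrow(expr) < 2L) stop("fewer than 2 non-constant genes")
    pc <- stats::prcomp(t(expr), center = TRUE, scale. = TRUE)
    ev <- pc$sdev^2
    pct <- 100 * ev / sum(ev)
    k <- which(cumsum(pct) >= 100 * varianceTarget)[1]
    if (is.na(k)) k <- length(ev)
    list(scores = pc$x, eigenvalues = ev, percentVariance = pct,
         nRetained = as.integer(k))
}
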