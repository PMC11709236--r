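#' @describeIn normalizeExpression TPM/RPKM from a count container.
#'
#' TPM for gene g in sample s is \code{1e6 * (c/L) / sum(c'/L')}; RPKM is
#' \code{1e9 * c / (L * N)} with N the sample's library size. TPM columns
#' therefore each sum to one million.
#'
#' @export
setMethod("normalizeExpression", "ThermalExperiment", function(x, unit) {
    unit <- match.arg(unit, c("TPM", "RPKM"))
    cts <- assay(x, "counts")
    len <- geneLengths(x)
    if (anyNA(len)) {
        bad <- rownames(cts)[is.na(len)]
        stop("missing gene length for: ", paste(utils::head(bad, 5),
                                                collapse = ", "))
    }
    N <- librarySizes(x)
    if (any(N == 0)) {
        bad <- colnames(cts)[N == 0]
        stop("zero library size for sample(s): ",
             paste(utils::head(bad, 5), collapse = ", "))
    }
    rate <- cts / len
    out <- if (unit == "TPM") sweep(rate, 2, colSums(rate), "/") * 1e6
           else 1e9 * sweep(rate, 2, N, "/")
    attr(out, "unit") <- unit
    out
})
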