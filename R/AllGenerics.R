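#' Gene lengths of a count container
#' @param x a [ThermalExperiment-class]
#' @return numeric vector of gene lengths (bp)
#' @export
setGeneric("geneLengths", function(x) standardGeneric("geneLengths"))

#' Realized library sizes (column sums)
#' @param x a [ThermalExperiment-class]
#' @return named numeric vector of per-sample total counts
#' @export
setGeneric("librarySizes", function(x) standardGeneric("librarySizes"))

#' Length/depth-normalized expression values
#' @param x a [ThermalExperiment-class]
#' @param unit \code{"TPM"} or \code{"RPKM"}
#' @return numeric matrix with a \code{unit} attribute
#' @export
setGeneric("normalizeExpression",
           function(x, unit = c("TPM", "RPKM"))
               standardGeneric("normalizeExpression"))

#' Two-group negative-binomial differential expression test
#' @param x a [ThermalExperiment-class]
#' @param ... passed to methods
#' @return a [DEGTable-class]
#' @export
setGeneric("testDE", function(x, ...) standardGeneric("testDE"))

#' @rdname geneLengths
#' @export
setMethod("geneLengths", "ThermalExperiment", function(x)
    stats::setNames(rowData(x)$gene_length, rownames(x)))

#' @rdname librarySizes
#' @export
setMethod("librarySizes", "ThermalExperiment", function(x)
    stats::setNames(colData(x)$lib_size, colnames(x)))
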