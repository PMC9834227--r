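#' @include AllClasses.R
NULL

#' Accessors for GenotypeMatrices
#'
#' @param x a [GenotypeMatrices-class] object
#' @return \code{refUmis}/\code{altUmis}: sparse variants x cells UMI count
#'   matrices; \code{genotypeCalls}: character matrix over
#'   REF/ALT/NO_CALL; \code{bothAlleles}: logical matrix flagging cells with
#'   both alleles observed; \code{variantSites}: the GRanges of variant
#'   sites; \code{cellBarcodes}: the cell barcode vector.
#' @name GenotypeMatrices-accessors
#' @aliases refUmis altUmis genotypeCalls bothAlleles variantSites
#'   cellBarcodes
NULL

#' @rdname GenotypeMatrices-accessors
#' @export
setGeneric("refUmis", function(x) standardGeneric("refUmis"))

#' @rdname GenotypeMatrices-accessors
#' @export
setGeneric("altUmis", function(x) standardGeneric("altUmis"))

#' @rdname GenotypeMatrices-accessors
#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))

#' @rdname GenotypeMatrices-accessors
#' @export
setGeneric("bothAlleles", function(x) standardGeneric("bothAlleles"))

#' @rdname GenotypeMatrices-accessors
#' @export
setGeneric("variantSites", function(x) standardGeneric("variantSites"))

#' @rdname GenotypeMatrices-accessors
#' @export
setGeneric("cellBarcodes", function(x) standardGeneric("cellBarcodes"))

#' @rdname GenotypeMatrices-accessors
setMethod("refUmis", "GenotypeMatrices", function(x)
    SummarizedExperiment::assay(x, "refUmis"))

#' @rdname GenotypeMatrices-accessors
setMethod("altUmis", "GenotypeMatrices", function(x)
    SummarizedExperiment::assay(x, "altUmis"))

#' @rdname GenotypeMatrices-accessors
setMethod("genotypeCalls", "GenotypeMatrices", function(x)
    SummarizedExperiment::assay(x, "calls"))

#' @rdname GenotypeMatrices-accessors
setMethod("bothAlleles", "GenotypeMatrices", function(x)
    SummarizedExperiment::assay(x, "both"))

#' @rdname GenotypeMatrices-accessors
setMethod("variantSites", "GenotypeMatrices", function(x)
    SummarizedExperiment::rowRanges(x))

#' @rdname GenotypeMatrices-accessors
setMethod("cellBarcodes", "GenotypeMatrices", function(x) colnames(x))

#' Accessors for TranscriptSet
#'
#' @param x a [TranscriptSet-class]
#' @return \code{txData}: per-transcript DataFrame; \code{txExons}:
#'   GRangesList of exons; \code{txLengths}: named vector of spliced
#'   lengths; \code{canonicalTx}: named character vector gene_id ->
#'   canonical transcript_id.
#' @name TranscriptSet-accessors
#' @aliases txData txExons txLengths canonicalTx
NULL

#' @rdname TranscriptSet-accessors
#' @export
setGeneric("txData", function(x) standardGeneric("txData"))

#' @rdname TranscriptSet-accessors
#' @export
setGeneric("txExons", function(x) standardGeneric("txExons"))

#' @rdname TranscriptSet-accessors
#' @export
setGeneric("txLengths", function(x) standardGeneric("txLengths"))

#' @rdname TranscriptSet-accessors
#' @export
setGeneric("canonicalTx", function(x) standardGeneric("canonicalTx"))

#' @rdname TranscriptSet-accessors
setMethod("txData", "TranscriptSet", function(x) x@txData)

#' @rdname TranscriptSet-accessors
setMethod("txExons", "TranscriptSet", function(x) x@exons)

#' @rdname TranscriptSet-accessors
setMethod("txLengths", "TranscriptSet", function(x)
    stats::setNames(x@txData$length, x@txData$transcript_id))

#' @rdname TranscriptSet-accessors
setMethod("canonicalTx", "TranscriptSet", function(x) {
    td <- x@txData[x@txData$canonical, ]
    stats::setNames(as.character(td$transcript_id), td$gene_id)
})
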