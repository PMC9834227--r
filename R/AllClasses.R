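#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges GRangesList seqnames start end width strand
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowRanges colData
NULL

## ---------------------------------------------------------------------------
## SimConfig
## ---------------------------------------------------------------------------

#' Simulation configuration
#'
#' Parameters of the synthetic droplet snRNA-seq experiment: a small genome
#' with one canonical transcript per gene, a cell population with named cell
#' types assigned to germ layers, per-(gene, cell type) negative-binomial
#' expression, end-biased read capture at the kit-specific read length
#' (91 nt for 3' chemistry, 90 nt for 5'), internal poly-A mispriming,
#' per-base sequencing error, and a mosaic variant carried by a Bernoulli
#' fraction of cells.
#'
#' @slot nCells number of cells (nuclei) to simulate.
#' @slot cellTypes data.frame with columns \code{name}, \code{germ_layer},
#'   \code{proportion}; proportions sum to 1.
#' @slot nGenes number of genes; one canonical transcript each.
#' @slot transcriptLengthRange integer length-2, range of spliced transcript
#'   lengths in nt.
#' @slot nExonsRange integer length-2, range of exon counts per transcript.
#' @slot readLength emitted read length in nt (91 for 3', 90 for 5' kits).
#' @slot kitEnd \code{"three_prime"} or \code{"five_prime"}.
#' @slot captureDecay exponential scale (nt) of the capture-offset from the
#'   annotated end; 0 means capture exactly at the end.
#' @slot misprimingRate probability, per eligible internal A-rich site and
#'   per captured molecule, of priming at that site instead of the end.
#' @slot errorRate per-base substitution error probability.
#' @slot mosaicFraction fraction of (eligible) cells carrying the alt allele.
#' @slot mosaicCellTypes cell types eligible to be mutant;
#'   \code{character(0)} means all types.
#' @slot umiDupRate mean number of extra (duplicate) reads per molecule.
#' @slot exprMean NULL (drawn at simulation time), a scalar, a length-nGenes
#'   vector, or an nGenes x nCellTypes matrix of negative-binomial means.
#' @slot exprDispersion negative-binomial size (dispersion) parameter.
#' @slot aRunGenes indices of genes that receive an internal A-homopolymer.
#' @slot aRunLength length (nt) of the inserted A run.
#' @slot aRunTxCoord 0-based spliced position of the run start, or NA for
#'   the transcript midpoint.
#' @slot seed RNG seed; with the seed fixed all outputs are bit-reproducible.
#'
#' @seealso [simConfig()], [makeReference()], [simulateCells()],
#'   [simulateReads()]
#' @export
setClass("SimConfig",
    representation(
        nCells = "integer",
        cellTypes = "data.frame",
        nGenes = "integer",
        transcriptLengthRange = "integer",
        nExonsRange = "integer",
        readLength = "integer",
        kitEnd = "character",
        captureDecay = "numeric",
        misprimingRate = "numeric",
        errorRate = "numeric",
        mosaicFraction = "numeric",
        mosaicCellTypes = "character",
        umiDupRate = "numeric",
        exprMean = "ANY",
        exprDispersion = "numeric",
        aRunGenes = "integer",
        aRunLength = "integer",
        aRunTxCoord = "integer",
        seed = "integer"
    )
)

setValidity("SimConfig", function(object) {
    msg <- character(0)
    ct <- object@cellTypes
    if (!all(c("name", "germ_layer", "proportion") %in% names(ct)))
        msg <- c(msg, "cellTypes needs columns name, germ_layer, proportion")
    else {
        if (abs(sum(ct$proportion) - 1) > 1e-6)
            msg <- c(msg, "cellTypes$proportion must sum to 1")
        if (anyDuplicated(ct$name))
            msg <- c(msg, "cellTypes$name must be unique")
    }
    if (object@nCells < 1L) msg <- c(msg, "nCells must be >= 1")
    if (object@nGenes < 1L) msg <- c(msg, "nGenes must be >= 1")
    if (object@readLength < 1L) msg <- c(msg, "readLength must be > 0")
    for (nm in c("misprimingRate", "errorRate", "mosaicFraction")) {
        v <- slot(object, nm)
        if (v < 0 || v > 1) msg <- c(msg, paste0(nm, " must be in [0, 1]"))
    }
    if (object@captureDecay < 0) msg <- c(msg, "captureDecay must be >= 0")
    if (object@umiDupRate < 0) msg <- c(msg, "umiDupRate must be >= 0")
    if (object@transcriptLengthRange[1] < object@readLength)
        msg <- c(msg, "transcripts must be at least readLength nt long")
    if (length(object@mosaicCellTypes) &&
        !all(object@mosaicCellTypes %in% ct$name))
        msg <- c(msg, "mosaicCellTypes must name configured cell types")
    if (is.matrix(object@exprMean) &&
        !identical(dim(object@exprMean),
                   c(object@nGenes, nrow(ct))))
        msg <- c(msg, "exprMean matrix must be nGenes x nCellTypes")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## SimTruth
## ---------------------------------------------------------------------------

#' Ground truth of a simulated experiment
#'
#' Truth surface written alongside the simulated BAM so downstream stages can
#' be checked by parameter recovery: which barcode belongs to which cell type
#' and germ layer and whether the cell carries the variant; where each read's
#' molecule was captured (annotated transcript end or an internal poly-A site)
#' and which allele its template carried; and the realized cell-level variant
#' allele fraction.
#'
#' @slot cellTable data.frame: barcode, cell_type, germ_layer, is_mutant.
#' @slot readTable data.frame: read id, gene, origin
#'   (\code{"transcript_end"} or \code{"internal_polyA@<pos>"}), allele
#'   carried at each variant covered (NA when none).
#' @slot variantTable data.frame: variant id, true cell-level VAF.
#' @export
setClass("SimTruth",
    representation(
        cellTable = "data.frame",
        readTable = "data.frame",
        variantTable = "data.frame"
    )
)

## ---------------------------------------------------------------------------
## TranscriptSet
## ---------------------------------------------------------------------------

#' Canonical transcript models
#'
#' A set of stranded exon structures, one or more transcripts per gene with
#' exactly one flagged canonical per gene (the MANE transcript when a MANE
#' list is supplied, else the longest). This is the coordinate system for
#' spliced distance-to-end computations.
#'
#' @slot exons GRangesList of exons per transcript, names are transcript ids,
#'   exons sorted by genomic start.
#' @slot txData DataFrame with one row per transcript: transcript_id,
#'   gene_id, chrom, strand, length (spliced nt), canonical (logical).
#' @seealso [loadAnnotation()], [genomicToTranscript()], [distanceToEnds()]
#' @export
setClass("TranscriptSet",
    representation(exons = "GRangesList", txData = "DataFrame")
)

setValidity("TranscriptSet", function(object) {
    msg <- character(0)
    td <- object@txData
    need <- c("transcript_id", "gene_id", "chrom", "strand", "length",
              "canonical")
    if (!all(need %in% colnames(td)))
        msg <- c(msg, paste("txData needs columns:",
                            paste(need, collapse = ", ")))
    else {
        if (!identical(names(object@exons), as.character(td$transcript_id)))
            msg <- c(msg, "exons names must match txData$transcript_id")
        if (any(td$length <= 0))
            msg <- c(msg, "transcript lengths must be positive")
        ncanon <- table(td$gene_id[td$canonical])
        genes <- unique(td$gene_id)
        if (!all(genes %in% names(ncanon)) || any(ncanon != 1L))
            msg <- c(msg, "each gene must have exactly one canonical transcript")
    }
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## GenotypeMatrices
## ---------------------------------------------------------------------------

#' Per-cell ref/alt UMI counts and genotype calls
#'
#' A SummarizedExperiment with variants as rows (rowRanges carry the variant
#' sites: ref, alt, gene_id, patient_id, role, in_population_db) and cell
#' barcodes as columns. Assays: \code{refUmis} and \code{altUmis} (sparse
#' UMI counts after per-UMI consensus) and \code{calls} (three-way
#' \code{"REF"}/\code{"ALT"}/\code{"NO_CALL"}), plus a logical \code{both}
#' mask flagging cells where both alleles were observed.
#'
#' @seealso [countAlleles()], [callGenotypes()], [annotateCalls()]
#' @export
setClass("GenotypeMatrices", contains = "RangedSummarizedExperiment")

setValidity("GenotypeMatrices", function(object) {
    msg <- character(0)
    an <- SummarizedExperiment::assayNames(object)
    need <- c("refUmis", "altUmis", "calls", "both")
    if (!all(need %in% an))
        return(paste("assays must include:", paste(need, collapse = ", ")))
    r <- SummarizedExperiment::assay(object, "refUmis")
    a <- SummarizedExperiment::assay(object, "altUmis")
    cl <- SummarizedExperiment::assay(object, "calls")
    if (min(r) < 0 || min(a) < 0)
        msg <- c(msg, "UMI counts must be non-negative")
    if (!all(cl %in% c("REF", "ALT", "NO_CALL")))
        msg <- c(msg, "calls must be REF, ALT or NO_CALL")
    uncov <- (as.matrix(r) + as.matrix(a)) == 0
    if (!all(cl[uncov] == "NO_CALL"))
        msg <- c(msg, "calls must be NO_CALL wherever refUmis + altUmis = 0")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

#' @export
#' @rdname SimConfig-class
#' @param object a \code{SimConfig}
setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@nCells, "cells,", object@nGenes, "genes,",
        nrow(object@cellTypes), "cell types\n")
    cat("  kit:", object@kitEnd, " read length:", object@readLength, "nt\n")
    cat("  mispriming:", object@misprimingRate,
        " error:", object@errorRate,
        " mosaic:", object@mosaicFraction, "\n")
    cat("  seed:", object@seed, "\n")
})

#' @export
#' @rdname TranscriptSet-class
#' @param object a \code{TranscriptSet}
setMethod("show", "TranscriptSet", function(object) {
    td <- object@txData
    cat("TranscriptSet:", nrow(td), "transcripts,",
        length(unique(td$gene_id)), "genes,",
        sum(td$canonical), "canonical\n")
})

#' @export
#' @rdname GenotypeMatrices-class
#' @param object a \code{GenotypeMatrices}
setMethod("show", "GenotypeMatrices", function(object) {
    cat("GenotypeMatrices:", nrow(object), "variants x",
        ncol(object), "cells\n")
    cl <- SummarizedExperiment::assay(object, "calls")
    tab <- table(factor(cl, levels = c("REF", "ALT", "NO_CALL")))
    cat("  calls: REF", tab[["REF"]], " ALT", tab[["ALT"]],
        " NO_CALL", tab[["NO_CALL"]], "\n")
})
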