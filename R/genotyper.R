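#' @include AllClasses.R io.R
NULL

#' Allele-counting parameters
#'
#' @param minMapq minimum mapping quality (default 30, excludes
#'   multimappers in a spliced-alignment context).
#' @param minBaseq minimum base quality at the variant position (default
#'   20).
#' @param barcodes optional cell-barcode whitelist; when NULL any CB tag is
#'   accepted and the observed barcodes define the matrix columns.
#' @param umiConsensus \code{"majority"} (ties discarded) or \code{"any"}
#'   (a single alt-supporting read makes the UMI vote alt).
#' @param callPolicy \code{"alt_dominant"} or \code{"consensus"}; see
#'   [callGenotypes()].
#' @param primaryOnly drop secondary and supplementary alignments (default
#'   TRUE).
#' @return a named list of class \code{CountingParams}
#' @export
countingParams <- function(minMapq = 30L, minBaseq = 20L, barcodes = NULL,
                           umiConsensus = c("majority", "any"),
                           callPolicy = c("alt_dominant", "consensus"),
                           primaryOnly = TRUE) {
    stopifnot(minMapq >= 0, minBaseq >= 0)
    structure(list(minMapq = as.integer(minMapq),
                   minBaseq = as.integer(minBaseq),
                   barcodes = barcodes,
                   umiConsensus = match.arg(umiConsensus),
                   callPolicy = match.arg(callPolicy),
                   primaryOnly = isTRUE(primaryOnly)),
              class = "CountingParams")
}

#' Three-way genotype calls from UMI counts
#'
#' Under \code{alt_dominant}, a cell is ALT when it has at least one
#' alt-supporting UMI, REF when it has only ref UMIs, and NO_CALL without
#' coverage. Under \code{consensus} a cell with both alleles observed is
#' still reported ALT — a true mosaic carrier transcribes both alleles and
#' the three-way scheme has no "both" category — but is flagged in the
#' \code{both} mask for audit. The two policies therefore produce the same
#' call matrix and differ only in intent; both are retained because the
#' upstream tool exposes both scoring modes.
#'
#' @param ref,alt variants x cells UMI count matrices
#' @param policy \code{"alt_dominant"} or \code{"consensus"}
#' @return list with \code{calls} (character matrix REF/ALT/NO_CALL) and
#'   \code{both} (logical matrix)
#' @export
callGenotypes <- function(ref, alt, policy = c("alt_dominant", "consensus")) {
    policy <- match.arg(policy)
    ref <- as.matrix(ref); alt <- as.matrix(alt)
    stopifnot(identical(dim(ref), dim(alt)))
    calls <- matrix("NO_CALL", nrow(ref), ncol(ref), dimnames = dimnames(ref))
    calls[ref > 0] <- "REF"
    calls[alt > 0] <- "ALT"
    list(calls = calls, both = ref > 0 & alt > 0)
}

## Internal constructor: wraps count matrices + variant sites into the
## SummarizedExperiment-based container, deriving calls and the both mask.
newGenotypeMatrices <- function(ref, alt, variants, barcodes,
                                policy = "alt_dominant") {
    vids <- variantIds(variants)
    dimnames(ref) <- dimnames(alt) <- list(vids, barcodes)
    cg <- callGenotypes(ref, alt, policy)
    names(variants) <- vids
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(refUmis = ref, altUmis = alt,
                      calls = cg$calls, both = cg$both),
        rowRanges = variants)
    methods::new("GenotypeMatrices", se)
}

#' Count ref/alt UMIs per cell at a priori variant positions
#'
#' For every (cell, variant) pair, reads overlapping the variant position
#' are binned by (CB, UB) tag pair; after per-UMI consensus each UMI
#' contributes at most one allele vote, and the votes are summed into
#' sparse ref/alt UMI count matrices with a derived three-way
#' REF/ALT/NO_CALL call. Reads lacking CB or UB tags, secondary and
#' supplementary alignments, reads below the mapping- or base-quality
#' thresholds, reads whose base at the position is neither ref nor alt,
#' and reads whose alignment skips the position (deletion or splice) are
#' discarded.
#'
#' @param bamPath coordinate-sorted, indexed BAM with CB/UB tags
#' @param variants GRanges of variant sites (see [makeVariantSites()])
#' @param params a [countingParams()] list
#' @return a [GenotypeMatrices-class]
#' @export
countAlleles <- function(bamPath, variants, params = countingParams()) {
    baiA <- paste0(bamPath, ".bai")
    baiB <- sub("\\.bam$", ".bai", bamPath)
    if (!file.exists(baiA) && !file.exists(baiB))
        stop("BAM index not found for ", bamPath,
             "; index the BAM first (e.g. Rsamtools::indexBam)")
    hdr <- Rsamtools::scanBamHeader(bamPath)[[1]]$targets
    nv <- length(variants)
    chrom <- as.character(GenomicRanges::seqnames(variants))
    pos <- GenomicRanges::start(variants)

    perVar <- vector("list", nv)
    for (i in seq_len(nv)) {
        if (!chrom[i] %in% names(hdr)) {
            warning("variant chromosome ", chrom[i],
                    " absent from BAM header; emitting NO_CALL column")
            perVar[[i]] <- data.frame(cb = character(0), allele = character(0))
            next
        }
        perVar[[i]] <- .pileupAlleles(bamPath, chrom[i], pos[i],
                                      variants$ref[i], variants$alt[i],
                                      params)
    }

    obs <- unique(unlist(lapply(perVar, function(d) d$cb)))
    axis <- if (!is.null(params$barcodes)) params$barcodes else sort(obs)
    axisKey <- normalizeBarcodes(axis)
    ref <- Matrix::Matrix(0, nv, length(axis), sparse = TRUE)
    alt <- Matrix::Matrix(0, nv, length(axis), sparse = TRUE)
    for (i in seq_len(nv)) {
        d <- perVar[[i]]
        if (!nrow(d)) next
        j <- match(normalizeBarcodes(d$cb), axisKey)
        keep <- !is.na(j)
        for (k in which(keep & d$allele == "ref"))
            ref[i, j[k]] <- ref[i, j[k]] + d$n[k]
        for (k in which(keep & d$allele == "alt"))
            alt[i, j[k]] <- alt[i, j[k]] + d$n[k]
    }
    newGenotypeMatrices(ref, alt, variants, axis, params$callPolicy)
}

## Pileup at one site: returns data.frame(cb, allele in {ref, alt}, n UMIs).
## Internal.
.pileupAlleles <- function(bamPath, chrom, pos, refBase, altBase, params) {
    empty <- data.frame(cb = character(0), allele = character(0),
                        n = integer(0))
    which <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
    sbp <- Rsamtools::ScanBamParam(
        which = which,
        what = c("flag", "pos", "mapq", "cigar", "seq", "qual"),
        tag = c("CB", "UB"))
    res <- Rsamtools::scanBam(bamPath, param = sbp)[[1]]
    n <- length(res$pos)
    if (n == 0L) return(empty)

    flag <- res$flag
    keep <- !bitwAnd(flag, 4L)                       # mapped
    if (params$primaryOnly)
        keep <- keep & !bitwAnd(flag, 256L) & !bitwAnd(flag, 2048L)
    mapq <- res$mapq
    keep <- keep & !is.na(mapq) & mapq >= params$minMapq
    cb <- res$tag$CB; ub <- res$tag$UB
    if (is.null(cb)) cb <- rep(NA_character_, n)
    if (is.null(ub)) ub <- rep(NA_character_, n)
    keep <- keep & !is.na(cb) & !is.na(ub) & !is.na(res$cigar)
    idx <- which(keep)
    if (!length(idx)) return(empty)

    cig <- res$cigar[idx]
    rstart <- res$pos[idx]
    refR <- GenomicAlignments::cigarRangesAlongReferenceSpace(
        cig, pos = rstart, ops = c("M", "=", "X"))
    qryR <- GenomicAlignments::cigarRangesAlongQuerySpace(
        cig, ops = c("M", "=", "X"))
    grp <- rep(seq_along(idx), S4Vectors::elementNROWS(refR))
    ur <- IRanges::IRanges(unlist(IRanges::start(refR)),
                           unlist(IRanges::end(refR)))
    uq <- unlist(IRanges::start(qryR))
    hit <- IRanges::start(ur) <= pos & IRanges::end(ur) >= pos
    if (!any(hit)) return(empty)
    rd <- grp[hit]                                   # read index within idx
    qpos <- uq[hit] + (pos - IRanges::start(ur)[hit])

    seqs <- res$seq[idx][rd]
    bases <- as.character(Biostrings::subseq(seqs, qpos, qpos))
    quals <- as(res$qual[idx][rd], "IntegerList")
    bq <- vapply(seq_along(rd), function(k) quals[[k]][qpos[k]], integer(1))

    ok <- bq >= params$minBaseq & bases %in% c(refBase, altBase)
    if (!any(ok)) return(empty)
    rd <- rd[ok]; bases <- bases[ok]
    cbv <- cb[idx][rd]; ubv <- ub[idx][rd]

    key <- paste(cbv, ubv, sep = "\t")
    isAlt <- bases == altBase
    nAlt <- tapply(isAlt, key, sum)
    nTot <- tapply(isAlt, key, length)
    nRef <- nTot - nAlt
    vote <- if (params$umiConsensus == "majority") {
        ifelse(nAlt > nRef, "alt", ifelse(nRef > nAlt, "ref", NA))
    } else {
        ifelse(nAlt >= 1, "alt", "ref")
    }
    ok2 <- !is.na(vote)
    if (!any(ok2)) return(empty)
    umiCb <- vapply(strsplit(names(nAlt)[ok2], "\t"), `[`, character(1), 1)
    d <- data.frame(cb = umiCb, allele = vote[ok2], stringsAsFactors = FALSE)
    out <- stats::aggregate(list(n = rep(1L, nrow(d))),
                            by = list(cb = d$cb, allele = d$allele), FUN = sum)
    out
}

#' Join genotype calls to per-cell metadata
#'
#' Inner join on cell barcode after suffix normalization on both sides
#' (Cell Ranger's \code{"-1"} and similar). Unmatched barcodes on either
#' side are reported with counts; zero overlap is an error, usually a
#' barcode-suffix mismatch.
#'
#' @param gm a [GenotypeMatrices-class]
#' @param cellMeta data.frame with a \code{barcode} column plus labels
#'   (e.g. \code{cluster}); extra columns are carried through.
#' @param kit optional kit label (\code{"3p"}/\code{"5p"}) stamped on every
#'   row.
#' @return long-form data.frame: barcode, variant_id, call, ref_umis,
#'   alt_umis, metadata columns, kit.
#' @export
annotateCalls <- function(gm, cellMeta, kit = NA_character_) {
    stopifnot("barcode" %in% names(cellMeta))
    bcs <- cellBarcodes(gm)
    keyM <- normalizeBarcodes(bcs)
    keyC <- normalizeBarcodes(cellMeta$barcode)
    j <- match(keyM, keyC)
    if (!any(!is.na(j)))
        stop("no overlapping barcodes between genotype matrix and ",
             "metadata; check for a barcode suffix mismatch (e.g. \"-1\")")
    nUnmatchedM <- sum(is.na(j))
    nUnmatchedC <- sum(!keyC %in% keyM)
    if (nUnmatchedM || nUnmatchedC)
        message(nUnmatchedM, " matrix barcode(s) and ", nUnmatchedC,
                " metadata barcode(s) had no match and were dropped")
    keep <- which(!is.na(j))
    calls <- genotypeCalls(gm)
    ref <- as.matrix(refUmis(gm)); alt <- as.matrix(altUmis(gm))
    vids <- rownames(calls)
    out <- do.call(rbind, lapply(seq_along(vids), function(i) {
        data.frame(barcode = bcs[keep],
                   variant_id = vids[i],
                   call = calls[i, keep],
                   ref_umis = ref[i, keep],
                   alt_umis = alt[i, keep],
                   cellMeta[j[keep], setdiff(names(cellMeta), "barcode"),
                            drop = FALSE],
                   kit = kit,
                   row.names = NULL,
                   stringsAsFactors = FALSE)
    }))
    out
}
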