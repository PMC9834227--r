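#' @include AllClasses.R
NULL

## Internal builder shared by loadAnnotation() and makeReference().
## `exons` is a named GRangesList (one element per transcript, any order of
## exons), `gene` a named character vector transcript_id -> gene_id,
## `canonical` a character vector of canonical transcript ids (one per gene).
newTranscriptSet <- function(exons, gene, canonical) {
    exons <- GenomicRanges::GRangesList(lapply(exons, BiocGenerics::sort))
    txid <- names(exons)
    chrom <- vapply(exons, function(g)
        as.character(GenomicRanges::seqnames(g)[1]), character(1))
    strand <- vapply(exons, function(g)
        as.character(GenomicRanges::strand(g)[1]), character(1))
    len <- vapply(exons, function(g)
        sum(GenomicRanges::width(g)), integer(1))
    td <- S4Vectors::DataFrame(
        transcript_id = txid,
        gene_id = as.character(gene[txid]),
        chrom = chrom,
        strand = strand,
        length = len,
        canonical = txid %in% canonical,
        row.names = txid
    )
    methods::new("TranscriptSet", exons = exons, txData = td)
}

#' Load transcript models from a GTF and pick one canonical per gene
#'
#' Exon features are grouped by \code{transcript_id}. The canonical
#' transcript of each gene is the one named in \code{maneIds} when supplied
#' (the MANE transcript); when the MANE id is absent from the GTF a warning
#' is emitted and the fallback rule applies: the longest transcript by
#' spliced length, ties broken by lexicographically smallest transcript id.
#'
#' @param gtfPath path to a GTF/GFF file with exon features carrying
#'   \code{transcript_id} and \code{gene_id} attributes.
#' @param maneIds optional character vector of canonical (MANE) transcript
#'   ids.
#' @return a [TranscriptSet-class]
#' @export
loadAnnotation <- function(gtfPath, maneIds = NULL) {
    gr <- rtracklayer::import(gtfPath)
    ex <- gr[gr$type == "exon"]
    if (length(ex) == 0L) stop("no exon features in ", gtfPath)
    allGenes <- unique(stats::na.omit(gr$gene_id))
    exGenes <- unique(ex$gene_id)
    orphan <- setdiff(allGenes, exGenes)
    if (length(orphan))
        warning("skipping gene(s) with no exon records: ",
                paste(orphan, collapse = ", "))
    exl <- GenomicRanges::split(GenomicRanges::granges(ex), ex$transcript_id)
    gene <- vapply(split(as.character(ex$gene_id), ex$transcript_id),
                   function(x) x[1], character(1))
    len <- vapply(exl, function(g) sum(GenomicRanges::width(g)), integer(1))
    canonical <- vapply(split(names(exl), gene[names(exl)]), function(txs) {
        if (!is.null(maneIds)) {
            hit <- intersect(maneIds, txs)
            if (length(hit)) return(hit[1])
            warning("no MANE transcript found for gene ",
                    gene[txs[1]], "; falling back to longest transcript")
        }
        l <- len[txs]
        cand <- txs[l == max(l)]
        sort(cand)[1]
    }, character(1))
    newTranscriptSet(as.list(exl), gene, unname(canonical))
}

## Plus-strand spliced coordinate (0-based) of a 1-based genomic position,
## NA when not exonic. Internal.
plusSplicedCoord <- function(ex, pos) {
    st <- GenomicRanges::start(ex); en <- GenomicRanges::end(ex)
    w <- GenomicRanges::width(ex)
    cumBefore <- c(0L, cumsum(w))[-(length(w) + 1L)]
    out <- rep(NA_integer_, length(pos))
    for (i in seq_along(st)) {
        hit <- !is.na(pos) & pos >= st[i] & pos <= en[i]
        out[hit] <- cumBefore[i] + (pos[hit] - st[i])
    }
    out
}

#' Map genomic positions to spliced transcript coordinates
#'
#' Transcript coordinates are 0-based along the mature mRNA: position 0 is
#' the first transcribed base (the cap site). On the minus strand the
#' spliced coordinate runs against the genomic axis.
#'
#' @param ts a [TranscriptSet-class]
#' @param txId a transcript id in \code{ts}
#' @param pos integer vector of 1-based genomic positions (VCF convention)
#' @return integer vector of 0-based transcript coordinates, NA where the
#'   position is not exonic; the \code{"status"} attribute distinguishes
#'   \code{"exonic"}, \code{"intronic"} (inside the transcript span but not
#'   in an exon) and \code{"outside"} (beyond the transcript span).
#' @export
genomicToTranscript <- function(ts, txId, pos) {
    ex <- ts@exons[[txId]]
    if (is.null(ex)) stop("unknown transcript: ", txId)
    td <- ts@txData[txId, ]
    pc <- plusSplicedCoord(ex, pos)
    L <- td$length
    out <- if (td$strand == "-") ifelse(is.na(pc), NA_integer_,
                                        L - 1L - pc) else pc
    span <- range(c(GenomicRanges::start(ex), GenomicRanges::end(ex)))
    status <- ifelse(!is.na(out), "exonic",
                     ifelse(pos >= span[1] & pos <= span[2],
                            "intronic", "outside"))
    attr(out, "status") <- status
    out
}

#' Project spliced transcript coordinates back to the genome
#'
#' Inverse of [genomicToTranscript()] on exonic positions.
#'
#' @inheritParams genomicToTranscript
#' @param txCoord integer vector of 0-based spliced coordinates
#' @return integer vector of 1-based genomic positions
#' @export
transcriptToGenomic <- function(ts, txId, txCoord) {
    ex <- ts@exons[[txId]]
    if (is.null(ex)) stop("unknown transcript: ", txId)
    td <- ts@txData[txId, ]
    L <- td$length
    if (any(txCoord < 0 | txCoord >= L, na.rm = TRUE))
        stop("txCoord out of range [0, length)")
    pc <- if (td$strand == "-") L - 1L - txCoord else txCoord
    w <- GenomicRanges::width(ex)
    cumBefore <- c(0L, cumsum(w))[-(length(w) + 1L)]
    idx <- findInterval(pc, cumBefore)
    GenomicRanges::start(ex)[idx] + (pc - cumBefore[idx])
}

#' Spliced distances to the transcript ends
#'
#' \code{dist_5p = tx_coord} (a variant at the cap site has distance 0) and
#' \code{dist_3p = length - 1 - tx_coord}, so the two always sum to
#' \code{length - 1}.
#'
#' @inheritParams genomicToTranscript
#' @param txCoord 0-based spliced coordinate(s), not intronic
#' @return data.frame with columns \code{dist_5p}, \code{dist_3p}
#' @export
distanceToEnds <- function(ts, txId, txCoord) {
    L <- ts@txData[txId, "length"]
    data.frame(dist_5p = as.integer(txCoord),
               dist_3p = as.integer(L - 1L - txCoord))
}

#' Map genomic sub-intervals of a transcript to genomic alignment blocks
#'
#' Converts a closed 0-based spliced interval \code{[start0, end0]} of a
#' transcript into the ordered genomic blocks it occupies (one block per
#' exon touched). Used to write spliced alignments and by tests to verify
#' that no read base maps to an intron.
#'
#' @inheritParams genomicToTranscript
#' @param start0,end0 0-based inclusive spliced interval bounds
#' @return GRanges of blocks in genomic order
#' @export
splicedBlocks <- function(ts, txId, start0, end0) {
    ex <- ts@exons[[txId]]
    td <- ts@txData[txId, ]
    L <- td$length
    if (start0 < 0 || end0 >= L || start0 > end0)
        stop("invalid spliced interval")
    if (td$strand == "-") {
        tmp <- L - 1L - end0
        end0 <- L - 1L - start0
        start0 <- tmp
    }
    w <- GenomicRanges::width(ex)
    cumBefore <- c(0L, cumsum(w))[-(length(w) + 1L)]
    st <- GenomicRanges::start(ex)
    keep <- which(cumBefore + w - 1L >= start0 & cumBefore <= end0)
    lo <- pmax(start0, cumBefore[keep])
    hi <- pmin(end0, cumBefore[keep] + w[keep] - 1L)
    GenomicRanges::GRanges(
        td$chrom,
        IRanges::IRanges(start = st[keep] + (lo - cumBefore[keep]),
                         end = st[keep] + (hi - cumBefore[keep])),
        strand = td$strand
    )
}

#' Per-variant spliced coordinates and end distances
#'
#' Maps each variant to the canonical transcript of its \code{gene_id} and
#' computes spliced coordinates and distances to both transcript ends.
#'
#' @param variants GRanges of variant sites (see [readVariantSites()]),
#'   with a \code{gene_id} metadata column.
#' @param ts a [TranscriptSet-class]
#' @return DataFrame with one row per variant: \code{variant_id},
#'   \code{transcript_id}, \code{tx_coord} (NA when not exonic),
#'   \code{dist_5p}, \code{dist_3p}, and \code{status} in
#'   \code{"exonic"}, \code{"intronic"}, \code{"outside"},
#'   \code{"no_transcript"}.
#' @export
variantDistances <- function(variants, ts) {
    canon <- canonicalTx(ts)
    n <- length(variants)
    out <- S4Vectors::DataFrame(
        variant_id = variantIds(variants),
        transcript_id = rep(NA_character_, n),
        tx_coord = rep(NA_integer_, n),
        dist_5p = rep(NA_integer_, n),
        dist_3p = rep(NA_integer_, n),
        status = rep("no_transcript", n)
    )
    if (n == 0L) return(out)
    gid <- as.character(variants$gene_id)
    pos <- GenomicRanges::start(variants)
    for (i in seq_len(n)) {
        txId <- canon[gid[i]]
        if (is.na(txId)) next
        out$transcript_id[i] <- txId
        tc <- genomicToTranscript(ts, txId, pos[i])
        out$status[i] <- attr(tc, "status")[1]
        if (!is.na(tc)) {
            d <- distanceToEnds(ts, txId, tc)
            out$tx_coord[i] <- tc
            out$dist_5p[i] <- d$dist_5p
            out$dist_3p[i] <- d$dist_3p
        }
    }
    out
}

#' Partition variants into exonic (with distances) and dropped
#'
#' Intronic variants, variants outside their transcript span, and variants
#' whose gene has no transcript in the annotation are dropped with a reason;
#' retained variants carry \code{transcript_id}, \code{tx_coord},
#' \code{dist_5p} and \code{dist_3p} metadata columns.
#'
#' @inheritParams variantDistances
#' @return list with elements \code{retained} (GRanges) and \code{dropped}
#'   (GRanges with a \code{reason} column)
#' @export
filterIntronic <- function(variants, ts) {
    vd <- variantDistances(variants, ts)
    keep <- vd$status == "exonic"
    retained <- variants[keep]
    if (length(retained)) {
        S4Vectors::mcols(retained)$transcript_id <- vd$transcript_id[keep]
        S4Vectors::mcols(retained)$tx_coord <- vd$tx_coord[keep]
        S4Vectors::mcols(retained)$dist_5p <- vd$dist_5p[keep]
        S4Vectors::mcols(retained)$dist_3p <- vd$dist_3p[keep]
    }
    dropped <- variants[!keep]
    if (length(dropped))
        S4Vectors::mcols(dropped)$reason <- ifelse(
            vd$status[!keep] == "no_transcript", "no transcript",
            vd$status[!keep])
    list(retained = retained, dropped = dropped)
}
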