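#' @include AllClasses.R annotation.R
NULL

#' Extract spliced (sense-strand mRNA) transcript sequences
#'
#' Concatenates exon sequences in transcript order, reverse-complementing
#' minus-strand transcripts, so position i of the result is spliced
#' coordinate i of the mature mRNA.
#'
#' @param genome DNAStringSet of chromosome sequences
#' @param ts a [TranscriptSet-class]
#' @return DNAStringSet named by transcript id
#' @export
transcriptSequences <- function(genome, ts) {
    td <- ts@txData
    seqs <- vapply(seq_len(nrow(td)), function(i) {
        ex <- ts@exons[[i]]
        chromSeq <- genome[[td$chrom[i]]]
        parts <- Biostrings::extractAt(
            chromSeq, IRanges::IRanges(GenomicRanges::start(ex),
                                       GenomicRanges::end(ex)))
        s <- paste(as.character(parts), collapse = "")
        if (td$strand[i] == "-")
            s <- as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(s)))
        s
    }, character(1))
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- td$transcript_id
    out
}

#' Scan an mRNA sequence for internal poly-A capture sites
#'
#' Reports every maximal A-homopolymer of at least \code{minRun} nt and
#' every \code{window}-nt window with A-fraction at least \code{minFrac};
#' overlapping hits are merged into one site spanning their union. Sites
#' overlapping the final \code{window} nt of the sequence are excluded:
#' that is the genuine poly-A context at the annotated 3' end. The
#' thresholds are package defaults, not values from any reference dataset,
#' and are fully configurable.
#'
#' @param txSeq a DNAString, DNAStringSet element or character mRNA
#'   sequence over A/C/G/T/N (sense strand)
#' @param minRun minimal A-run length (default 6)
#' @param window window width in nt (default 10)
#' @param minFrac minimal A fraction within a window (default 0.8)
#' @return data.frame with one row per site: \code{tx_coord} (0-based
#'   spliced position of the site's first base), \code{width},
#'   \code{run_length} (longest A run inside the site) and
#'   \code{window_A_fraction} (A fraction over the merged site)
#' @export
scanPolyA <- function(txSeq, minRun = 6L, window = 10L, minFrac = 0.8) {
    s <- as.character(txSeq)
    emptyRes <- data.frame(tx_coord = integer(0), width = integer(0),
                           run_length = integer(0),
                           window_A_fraction = numeric(0))
    L <- nchar(s)
    if (L == 0L) return(emptyRes)

    isA <- strsplit(s, "")[[1]] == "A"
    r <- rle(isA)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runHits <- IRanges::IRanges(starts[r$values & r$lengths >= minRun],
                                ends[r$values & r$lengths >= minRun])

    winHits <- IRanges::IRanges()
    if (L >= window) {
        aCount <- cumsum(isA)
        wa <- aCount[window:L] - c(0L, aCount)[1:(L - window + 1L)]
        p <- which(wa / window >= minFrac)
        if (length(p)) winHits <- IRanges::IRanges(p, p + window - 1L)
    }

    hits <- IRanges::reduce(c(runHits, winHits))
    if (!length(hits)) return(emptyRes)
    # drop sites in the genuine 3' poly-A context
    hits <- hits[IRanges::end(hits) < L - window + 1L]
    if (!length(hits)) return(emptyRes)

    aCount <- cumsum(isA)
    siteStats <- lapply(seq_along(hits), function(i) {
        lo <- IRanges::start(hits)[i]; hi <- IRanges::end(hits)[i]
        rr <- rle(isA[lo:hi])
        re <- lo - 1L + cumsum(rr$lengths)
        rs <- re - rr$lengths + 1L
        runs <- which(rr$values)
        runLen <- if (length(runs)) max(rr$lengths[runs]) else 0L
        # the site is anchored at the first base of its longest A-run
        # (where the poly-dT would anneal); pure-window sites anchor at
        # the merged interval start
        anchor <- if (runLen >= minRun)
            rs[runs[which.max(rr$lengths[runs])]] else lo
        # best A fraction of any window inside the site (the whole site
        # when shorter than one window)
        frac <- if (hi - lo + 1L < window)
            mean(isA[lo:hi])
        else {
            p <- lo:(hi - window + 1L)
            max((aCount[p + window - 1L] - c(0L, aCount)[p]) / window)
        }
        c(anchor = anchor, runLen = runLen, frac = frac)
    })
    st <- do.call(rbind, siteStats)
    data.frame(tx_coord = as.integer(st[, "anchor"]) - 1L,
               width = IRanges::width(hits),
               run_length = as.integer(st[, "runLen"]),
               window_A_fraction = unname(st[, "frac"]),
               row.names = NULL)
}

#' Scan every canonical transcript for internal poly-A sites
#'
#' @param genome DNAStringSet of chromosome sequences
#' @param ts a [TranscriptSet-class]
#' @param canonicalOnly scan only canonical transcripts (default TRUE)
#' @inheritParams scanPolyA
#' @return data.frame of sites with a \code{transcript_id} column
#' @export
misprimingSites <- function(genome, ts, canonicalOnly = TRUE,
                            minRun = 6L, window = 10L, minFrac = 0.8) {
    td <- ts@txData
    if (canonicalOnly) td <- td[td$canonical, ]
    seqs <- transcriptSequences(genome, ts)
    res <- lapply(td$transcript_id, function(tx) {
        sites <- scanPolyA(seqs[[tx]], minRun, window, minFrac)
        if (nrow(sites)) cbind(transcript_id = tx, sites)
        else cbind(transcript_id = character(0), sites)
    })
    do.call(rbind, res)
}

#' Effective capture distance of a variant given internal poly-A sites
#'
#' The kit-relevant annotated-end distance (\code{dist_3p} for 3'
#' chemistry, \code{dist_5p} for 5') is compared against routes through
#' internal poly-A capture sites. In 3' chemistry a site is usable for a
#' variant strictly upstream of it within \code{readLength} nt (the read
#' extends upstream from the capture site); in 5' chemistry, for a variant
#' at or downstream of the site within the read. The effective distance is
#' the minimum over the annotated end and all usable sites, and is never
#' larger than the annotated-end distance.
#'
#' @param variantDistance one row of [variantDistances()] output (or any
#'   list with \code{tx_coord}, \code{dist_5p}, \code{dist_3p})
#' @param sites data.frame of sites on the same transcript (from
#'   [scanPolyA()] / [misprimingSites()])
#' @param kitEnd \code{"three_prime"} or \code{"five_prime"}
#' @param readLength read length in nt (91 for 3', 90 for 5')
#' @return list with \code{site} (row index into \code{sites}, or NA when
#'   the annotated end wins) and \code{effective_distance} (nt)
#' @export
nearestCaptureSite <- function(variantDistance, sites,
                               kitEnd = c("three_prime", "five_prime"),
                               readLength = 91L) {
    kitEnd <- match.arg(kitEnd)
    tc <- variantDistance$tx_coord
    if (is.null(tc) || is.na(tc))
        return(list(site = NA_integer_,
                    effective_distance = NA_integer_))
    annot <- if (kitEnd == "three_prime") variantDistance$dist_3p
             else variantDistance$dist_5p
    best <- annot
    bestSite <- NA_integer_
    if (!is.null(sites) && nrow(sites)) {
        for (i in seq_len(nrow(sites))) {
            a <- sites$tx_coord[i]
            d <- if (kitEnd == "three_prime") a - tc else tc - a
            usable <- if (kitEnd == "three_prime")
                d >= 1 && d <= readLength
            else d >= 0 && d <= readLength - 1
            if (usable && d < best) {
                best <- d
                bestSite <- i
            }
        }
    }
    list(site = bestSite, effective_distance = as.integer(best))
}
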