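## Fixture builders and the independent brute-force pileup oracle.
## The oracle deliberately shares nothing with the package's counting
## path: it scans every record of the BAM without an index, parses
## CIGARs with its own regex walker, and re-derives the per-UMI
## consensus by enumeration.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(Rsamtools)
})

## Write alignment records to an indexed, coordinate-sorted BAM.
## records: data.frame qname, flag, chrom, pos, mapq, cigar, seq, qual,
## cb, ub (cb/ub NA = tag omitted).
writeFixtureBam <- function(records, chromLengths, bamPath) {
    hdr <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:%s\tLN:%d", names(chromLengths),
                     as.integer(chromLengths)))
    body <- character(0)
    if (nrow(records)) {
        body <- vapply(seq_len(nrow(records)), function(i) {
            r <- records[i, ]
            tags <- character(0)
            if (!is.na(r$cb)) tags <- c(tags, paste0("CB:Z:", r$cb))
            if (!is.na(r$ub)) tags <- c(tags, paste0("UB:Z:", r$ub))
            paste(c(r$qname, r$flag, r$chrom, r$pos, r$mapq, r$cigar,
                    "*", 0L, 0L, r$seq, r$qual, tags), collapse = "\t")
        }, character(1))
    }
    sam <- tempfile(fileext = ".sam")
    writeLines(c(hdr, body), sam)
    tmp <- tempfile(fileext = ".bam")
    Rsamtools::asBam(sam, sub("\\.bam$", "", tmp), overwrite = TRUE,
                     indexDestination = FALSE)
    Rsamtools::sortBam(tmp, sub("\\.bam$", "", bamPath))
    Rsamtools::indexBam(bamPath)
    unlink(c(sam, tmp))
    bamPath
}

## One fixture read with sensible defaults.
fxRead <- function(qname, pos, cigar, seq, cb, ub, flag = 0L,
                   mapq = 60L, qual = NULL, chrom = "c1") {
    if (is.null(qual)) qual <- strrep("F", nchar(seq))
    data.frame(qname = qname, flag = flag, chrom = chrom, pos = pos,
               mapq = mapq, cigar = cigar, seq = seq, qual = qual,
               cb = cb, ub = ub, stringsAsFactors = FALSE)
}

## --- independent oracle ---------------------------------------------------

## Hand-rolled CIGAR walk: returns c(qpos, base intchar qual) at refPos or
## NULL when the read does not align a base there.
.walkCigar <- function(cigar, alnStart, refPos, seq, qual) {
    ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
    rp <- alnStart
    qp <- 1L
    for (o in ops) {
        len <- as.integer(substr(o, 1L, nchar(o) - 1L))
        op <- substr(o, nchar(o), nchar(o))
        if (op %in% c("M", "=", "X")) {
            if (refPos >= rp && refPos <= rp + len - 1L) {
                q <- qp + (refPos - rp)
                return(list(base = substr(seq, q, q),
                            qual = utf8ToInt(substr(qual, q, q)) - 33L))
            }
            rp <- rp + len
            qp <- qp + len
        } else if (op %in% c("I", "S")) {
            qp <- qp + len
        } else if (op %in% c("D", "N")) {
            if (refPos >= rp && refPos <= rp + len - 1L) return(NULL)
            rp <- rp + len
        }
        # H and P consume nothing relevant
    }
    NULL
}

## Brute-force ref/alt UMI counting; returns list(ref=, alt=) dense
## matrices (variants x barcodes).
bruteForceCounts <- function(bamPath, variants, barcodes = NULL,
                             minMapq = 30L, minBaseq = 20L,
                             consensus = "majority", primaryOnly = TRUE) {
    p <- Rsamtools::ScanBamParam(
        what = c("flag", "rname", "pos", "mapq", "cigar", "seq", "qual"),
        tag = c("CB", "UB"))
    r <- Rsamtools::scanBam(bamPath, param = p)[[1]]
    n <- length(r$pos)
    seqs <- as.character(r$seq)
    quals <- as.character(r$qual)
    cb <- r$tag$CB
    ub <- r$tag$UB
    if (is.null(cb)) cb <- rep(NA_character_, n)
    if (is.null(ub)) ub <- rep(NA_character_, n)

    vids <- paste0(as.character(seqnames(variants)), ":", start(variants),
                   "_", variants$ref, ">", variants$alt)
    votes <- vector("list", length(variants))
    for (v in seq_along(variants)) {
        vchrom <- as.character(seqnames(variants))[v]
        vpos <- start(variants)[v]
        acc <- list()
        for (i in seq_len(n)) {
            if (is.na(r$pos[i])) next
            if (bitwAnd(r$flag[i], 4L)) next
            if (primaryOnly &&
                (bitwAnd(r$flag[i], 256L) || bitwAnd(r$flag[i], 2048L)))
                next
            if (is.na(r$mapq[i]) || r$mapq[i] < minMapq) next
            if (is.na(cb[i]) || is.na(ub[i])) next
            if (as.character(r$rname[i]) != vchrom) next
            hit <- .walkCigar(r$cigar[i], r$pos[i], vpos, seqs[i],
                              quals[i])
            if (is.null(hit)) next
            if (hit$qual < minBaseq) next
            allele <- if (hit$base == variants$ref[v]) "ref"
                      else if (hit$base == variants$alt[v]) "alt"
                      else next
            key <- paste(cb[i], ub[i], sep = "\t")
            acc[[key]] <- c(acc[[key]], allele)
        }
        votes[[v]] <- acc
    }

    obs <- unique(unlist(lapply(votes, function(a)
        vapply(strsplit(names(a), "\t"), `[`, character(1), 1))))
    axis <- if (!is.null(barcodes)) barcodes else sort(obs)
    ref <- matrix(0, length(variants), length(axis),
                  dimnames = list(vids, axis))
    alt <- ref
    for (v in seq_along(votes)) {
        for (key in names(votes[[v]])) {
            b <- strsplit(key, "\t")[[1]][1]
            if (!b %in% axis) next
            a <- votes[[v]][[key]]
            nAlt <- sum(a == "alt"); nRef <- sum(a == "ref")
            call <- if (consensus == "majority") {
                if (nAlt > nRef) "alt" else if (nRef > nAlt) "ref" else NA
            } else {
                if (nAlt >= 1) "alt" else "ref"
            }
            if (is.na(call)) next
            if (call == "alt") alt[v, b] <- alt[v, b] + 1
            else ref[v, b] <- ref[v, b] + 1
        }
    }
    list(ref = ref, alt = alt)
}

## Random fixture BAM around given variants; exercises splices, indels,
## soft clips, low mapq, low baseq, missing tags, secondary flags, and
## off-target bases. Returns the record data.frame.
randomFixtureRecords <- function(variants, nReads = 120L,
                                 chromLen = 2000L) {
    cbPool <- sprintf("BC%02d", 1:8)
    ubPool <- sprintf("U%03d", 1:6)
    recs <- lapply(seq_len(nReads), function(i) {
        v <- variants[sample(length(variants), 1L)]
        vpos <- start(v)
        tmplChoice <- sample(5L, 1L)
        off <- sample(0:39, 1L)
        pos <- max(1L, vpos - off)
        cigar <- switch(tmplChoice,
            "40M",
            "20M50N20M",
            "5S35M",
            "18M2D20M",
            "20M2I18M")
        qlen <- switch(tmplChoice, 40L, 40L, 40L, 38L, 40L)
        seq <- paste(sample(c("A", "C", "G", "T"), qlen, replace = TRUE),
                     collapse = "")
        # place a deliberate allele at the variant if the M-walk covers it
        hit <- .walkCigar(cigar, pos, vpos, seq, strrep("F", qlen))
        if (!is.null(hit)) {
            base <- sample(c(v$ref, v$alt, "N"), 1L,
                           prob = c(0.45, 0.45, 0.1))
            # find qpos again to substitute
            q <- NULL
            ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]",
                                              cigar))[[1]]
            rp <- pos; qp <- 1L
            for (o in ops) {
                len <- as.integer(substr(o, 1L, nchar(o) - 1L))
                opc <- substr(o, nchar(o), nchar(o))
                if (opc %in% c("M", "=", "X")) {
                    if (vpos >= rp && vpos <= rp + len - 1L)
                        q <- qp + (vpos - rp)
                    rp <- rp + len; qp <- qp + len
                } else if (opc %in% c("I", "S")) qp <- qp + len
                else if (opc %in% c("D", "N")) rp <- rp + len
            }
            if (!is.null(q)) substr(seq, q, q) <- base
        }
        qual <- strrep("F", qlen)
        if (stats::runif(1) < 0.1 && !is.null(hit)) {
            # low base quality at a random position
            p <- sample(qlen, 1L)
            substr(qual, p, p) <- "#"
        }
        fxRead(
            qname = sprintf("q%05d", i),
            pos = pos, cigar = cigar, seq = seq,
            cb = if (stats::runif(1) < 0.05) NA_character_
                 else sample(cbPool, 1L),
            ub = if (stats::runif(1) < 0.05) NA_character_
                 else sample(ubPool, 1L),
            flag = sample(c(0L, 16L, 256L, 2048L), 1L,
                          prob = c(0.6, 0.3, 0.05, 0.05)),
            mapq = sample(c(60L, 255L, 10L), 1L,
                          prob = c(0.7, 0.15, 0.15)),
            qual = qual)
    })
    do.call(rbind, recs)
}

## Small two-variant site set on the fixture chromosome.
fixtureVariants <- function() {
    makeVariantSites(data.frame(
        chrom = "c1", pos = c(500L, 1000L),
        ref = c("A", "C"), alt = c("G", "T"),
        gene_id = c("gA", "gB"), patient_id = "p1",
        role = c("germline", "null_set"),
        in_population_db = FALSE))
}
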