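#' @include AllClasses.R
NULL

#' Stable identifier for a variant site
#'
#' @param variants GRanges of variant sites
#' @return character vector "chrom:pos_ref>alt"
#' @export
variantIds <- function(variants) {
    if (length(variants) == 0L) return(character(0))
    paste0(as.character(GenomicRanges::seqnames(variants)), ":",
           GenomicRanges::start(variants), "_",
           variants$ref, ">", variants$alt)
}

#' Construct variant sites from a data.frame
#'
#' @param df data.frame with columns \code{chrom}, \code{pos} (1-based),
#'   \code{ref}, \code{alt} and optionally \code{gene_id},
#'   \code{patient_id}, \code{role} (one of \code{somatic_candidate},
#'   \code{germline}, \code{null_set}) and \code{in_population_db}.
#' @return GRanges with one range per variant and the above metadata
#' @export
makeVariantSites <- function(df) {
    stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(df)))
    if (any(df$ref == df$alt)) stop("ref and alt must differ")
    if (any(nchar(df$ref) != 1L | nchar(df$alt) != 1L))
        stop("only single-nucleotide substitutions are supported")
    if (any(df$pos < 1L)) stop("pos must be >= 1 (VCF convention)")
    gr <- GenomicRanges::GRanges(df$chrom,
                                 IRanges::IRanges(df$pos, width = 1L))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        ref = as.character(df$ref),
        alt = as.character(df$alt),
        gene_id = if ("gene_id" %in% names(df))
            as.character(df$gene_id) else NA_character_,
        patient_id = if ("patient_id" %in% names(df))
            as.character(df$patient_id) else NA_character_,
        role = if ("role" %in% names(df))
            as.character(df$role) else "germline",
        in_population_db = if ("in_population_db" %in% names(df))
            as.logical(df$in_population_db) else NA
    )
    names(gr) <- variantIds(gr)
    gr
}

#' Read a priori variant sites from a VCF
#'
#' Sites-only VCF 4.x is sufficient. Gene assignment, patient, role and the
#' population-database (gnomAD-presence) flag are taken from INFO fields
#' \code{GENE}, \code{PATIENT}, \code{ROLE} and \code{INDB} when present.
#'
#' @param vcfPath path to a VCF file
#' @return GRanges of variant sites (see [makeVariantSites()])
#' @export
readVariantSites <- function(vcfPath) {
    vcf <- VariantAnnotation::readVcf(vcfPath, genome = "unknown")
    rr <- SummarizedExperiment::rowRanges(vcf)
    info <- VariantAnnotation::info(vcf)
    alt <- as.character(unlist(rr$ALT))
    getInfo <- function(field, default) {
        if (field %in% colnames(info)) {
            v <- info[[field]]
            if (is(v, "List")) v <- vapply(v, function(x)
                if (length(x)) as.character(x[1]) else NA_character_,
                character(1))
            v
        } else rep(default, length(rr))
    }
    df <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(rr)),
        pos = GenomicRanges::start(rr),
        ref = as.character(rr$REF),
        alt = alt,
        gene_id = getInfo("GENE", NA_character_),
        patient_id = getInfo("PATIENT", NA_character_),
        role = getInfo("ROLE", "germline"),
        stringsAsFactors = FALSE
    )
    df$in_population_db <- if ("INDB" %in% colnames(info))
        as.logical(info$INDB) else NA
    makeVariantSites(df)
}

#' Write variant sites to a minimal sites-only VCF 4.2
#'
#' @param variants GRanges of variant sites
#' @param path output path
#' @param contigLengths optional named integer vector for contig header
#'   lines
#' @return \code{path}, invisibly
#' @export
writeVariantSites <- function(variants, path, contigLengths = NULL) {
    hdr <- c("##fileformat=VCFv4.2",
        "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene id\">",
        "##INFO=<ID=PATIENT,Number=1,Type=String,Description=\"Patient id\">",
        paste0("##INFO=<ID=ROLE,Number=1,Type=String,Description=",
               "\"somatic_candidate, germline or null_set\">"),
        paste0("##INFO=<ID=INDB,Number=0,Type=Flag,Description=",
               "\"Present in population database (gnomAD)\">"))
    if (!is.null(contigLengths))
        hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                              names(contigLengths), contigLengths))
    hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    lines <- hdr
    if (length(variants)) {
        info <- paste0("GENE=", variants$gene_id,
                       ";PATIENT=", variants$patient_id,
                       ";ROLE=", variants$role)
        info <- ifelse(!is.na(variants$in_population_db) &
                           variants$in_population_db,
                       paste0(info, ";INDB"), info)
        lines <- c(lines, paste(
            as.character(GenomicRanges::seqnames(variants)),
            GenomicRanges::start(variants),
            variantIds(variants),
            variants$ref, variants$alt, ".", "PASS", info,
            sep = "\t"))
    }
    writeLines(lines, path)
    invisible(path)
}

#' Write / read a gene-by-cell count matrix in MatrixMarket layout
#'
#' The conventional single-cell trio: \code{matrix.mtx},
#' \code{features.tsv}, \code{barcodes.tsv}.
#'
#' @param counts sparse (or dense) genes x cells matrix with dimnames
#' @param dir output directory (created if needed)
#' @return \code{dir} (write) or the counts matrix (read)
#' @export
writeMtxCounts <- function(counts, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    m <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
    Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
    writeLines(rownames(counts), file.path(dir, "features.tsv"))
    writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
    invisible(dir)
}

#' @rdname writeMtxCounts
#' @export
readMtxCounts <- function(dir) {
    m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
    m <- methods::as(m, "CsparseMatrix")
    dimnames(m) <- list(readLines(file.path(dir, "features.tsv")),
                        readLines(file.path(dir, "barcodes.tsv")))
    m
}

#' Write a TranscriptSet as GTF
#'
#' Emits transcript and exon features with \code{gene_id} and
#' \code{transcript_id} attributes; round-trips through
#' [loadAnnotation()].
#'
#' @param ts a [TranscriptSet-class]
#' @param path output GTF path
#' @return \code{path}, invisibly
#' @export
writeAnnotationGtf <- function(ts, path) {
    td <- ts@txData
    recs <- lapply(seq_len(nrow(td)), function(i) {
        ex <- ts@exons[[i]]
        tx <- range(ex)
        S4Vectors::mcols(tx) <- S4Vectors::DataFrame(
            type = "transcript",
            gene_id = td$gene_id[i], transcript_id = td$transcript_id[i])
        S4Vectors::mcols(ex) <- S4Vectors::DataFrame(
            type = rep("exon", length(ex)),
            gene_id = rep(td$gene_id[i], length(ex)),
            transcript_id = rep(td$transcript_id[i], length(ex)))
        c(tx, ex)
    })
    gr <- do.call(c, recs)
    gr$source <- "dropGeno"
    rtracklayer::export(gr, path, format = "gtf")
    invisible(path)
}

## SAM text -> coordinate-sorted, indexed BAM. Internal.
samToSortedBam <- function(samPath, bamPath) {
    tmp <- tempfile(fileext = ".bam")
    Rsamtools::asBam(samPath, sub("\\.bam$", "", tmp),
                     overwrite = TRUE, indexDestination = FALSE)
    Rsamtools::sortBam(tmp, sub("\\.bam$", "", bamPath))
    Rsamtools::indexBam(bamPath)
    unlink(tmp)
    invisible(bamPath)
}

## Write alignment records with CB/UB tags as SAM text. `aln` is a
## data.frame: qname, flag, chrom, pos (1-based), mapq, cigar, seq, cb, ub.
## Internal.
writeTaggedSam <- function(aln, chromLengths, samPath) {
    hdr <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:%s\tLN:%d", names(chromLengths),
                     as.integer(chromLengths)))
    lines <- hdr
    if (nrow(aln)) {
        qual <- vapply(nchar(aln$seq), function(n)
            strrep("F", n), character(1))
        lines <- c(lines, paste(
            aln$qname, aln$flag, aln$chrom, aln$pos, aln$mapq, aln$cigar,
            "*", 0L, 0L, aln$seq, qual,
            paste0("CB:Z:", aln$cb), paste0("UB:Z:", aln$ub),
            sep = "\t"))
    }
    writeLines(lines, samPath)
    invisible(samPath)
}

#' Strip the numeric droplet suffix from cell barcodes
#'
#' Cell Ranger appends \code{"-1"} (or another lane index) to barcodes;
#' genotype matrices and metadata may disagree on the suffix, so both sides
#' are normalized before joining.
#'
#' @param x character vector of barcodes
#' @return barcodes without a trailing \code{-<digits>} suffix
#' @export
normalizeBarcodes <- function(x) sub("-[0-9]+$", "", x)

#' Write / read genotype matrices in the single-cell genotyping layout
#'
#' Two MatrixMarket matrices (\code{ref.mtx}, \code{alt.mtx}) sharing
#' \code{barcodes.tsv} and \code{variants.tsv}, plus a calls matrix TSV.
#'
#' @param gm a [GenotypeMatrices-class]
#' @param dir output directory
#' @return \code{dir} (write) or a [GenotypeMatrices-class] (read)
#' @export
writeGenotypeMatrices <- function(gm, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    asGeneral <- function(m)
        methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix")
    Matrix::writeMM(asGeneral(refUmis(gm)), file.path(dir, "ref.mtx"))
    Matrix::writeMM(asGeneral(altUmis(gm)), file.path(dir, "alt.mtx"))
    writeLines(cellBarcodes(gm), file.path(dir, "barcodes.tsv"))
    v <- variantSites(gm)
    utils::write.table(
        data.frame(variant_id = variantIds(v),
                   chrom = as.character(GenomicRanges::seqnames(v)),
                   pos = GenomicRanges::start(v),
                   ref = v$ref, alt = v$alt, gene_id = v$gene_id,
                   patient_id = v$patient_id, role = v$role,
                   in_population_db = v$in_population_db),
        file.path(dir, "variants.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    calls <- genotypeCalls(gm)
    utils::write.table(calls, file.path(dir, "calls.tsv"),
                       sep = "\t", quote = FALSE)
    invisible(dir)
}

#' @rdname writeGenotypeMatrices
#' @export
readGenotypeMatrices <- function(dir) {
    ref <- methods::as(Matrix::readMM(file.path(dir, "ref.mtx")),
                       "CsparseMatrix")
    alt <- methods::as(Matrix::readMM(file.path(dir, "alt.mtx")),
                       "CsparseMatrix")
    barcodes <- readLines(file.path(dir, "barcodes.tsv"))
    vdf <- utils::read.table(file.path(dir, "variants.tsv"),
                             header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    variants <- makeVariantSites(vdf)
    newGenotypeMatrices(ref, alt, variants, barcodes)
}
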