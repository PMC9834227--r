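#' @include AllClasses.R annotation.R mispriming.R io.R
NULL

#' Default brain cell-type table
#'
#' The nine cortical cell types used throughout, with their embryonic germ
#' layers (microglia and lymphocytes are mesoderm-derived; the neural and
#' glial types are ectoderm-derived; the mitochondrial cluster is a
#' technical cluster with no layer) and realistic snRNA-seq proportions.
#'
#' @return data.frame with columns name, germ_layer, proportion
#' @export
defaultCellTypes <- function() {
    data.frame(
        name = c("Excitatory Neurons", "Oligodendrocytes", "Astrocytes",
                 "OPCs", "Microglia", "MGE-Derived Interneurons",
                 "CGE-Derived Interneurons", "Lymphocytes",
                 "Mitochondrial"),
        germ_layer = c("ectoderm", "ectoderm", "ectoderm", "ectoderm",
                       "mesoderm", "ectoderm", "ectoderm", "mesoderm",
                       "unknown"),
        proportion = c(0.30, 0.25, 0.12, 0.08, 0.08, 0.06, 0.05, 0.01,
                       0.05),
        stringsAsFactors = FALSE
    )
}

#' Build a simulation configuration
#'
#' Defaults describe a desk-scale droplet snRNA-seq experiment: the nine
#' brain cell types with realistic proportions, kit-specific read lengths
#' (91 nt for 3' chemistry, 90 nt for 5'), capture exactly at the
#' annotated transcript end (\code{captureDecay = 0}), a small per-base
#' error rate, and a 5\% mosaic variant. See [SimConfig-class] for the
#' meaning of every field.
#'
#' @param nCells number of cells
#' @param cellTypes data.frame (name, germ_layer, proportion)
#' @param nGenes number of genes (one canonical transcript each)
#' @param transcriptLengthRange range of spliced transcript lengths (nt)
#' @param nExonsRange range of exons per transcript
#' @param kitEnd \code{"three_prime"} or \code{"five_prime"}
#' @param readLength read length; NULL picks the kit default (91/90)
#' @param captureDecay exponential scale (nt) of capture offset from the
#'   end; 0 = capture exactly at the end
#' @param misprimingRate per-site, per-molecule internal poly-A priming
#'   probability
#' @param errorRate per-base substitution error probability
#' @param mosaicFraction fraction of eligible cells carrying the variant
#' @param mosaicCellTypes cell types eligible for the mutant flag
#'   (default: all)
#' @param umiDupRate mean extra duplicate reads per molecule
#' @param exprMean NULL, scalar, length-nGenes vector, or nGenes x nTypes
#'   matrix of negative-binomial means
#' @param exprDispersion negative-binomial size parameter
#' @param aRunGenes gene indices receiving an internal A-homopolymer
#' @param aRunLength homopolymer length (nt)
#' @param aRunTxCoord 0-based spliced start of the run (NA = midpoint)
#' @param seed RNG seed
#' @return a [SimConfig-class]
#' @export
simConfig <- function(nCells = 1000L,
                      cellTypes = defaultCellTypes(),
                      nGenes = 20L,
                      transcriptLengthRange = c(500L, 3000L),
                      nExonsRange = c(1L, 4L),
                      kitEnd = c("three_prime", "five_prime"),
                      readLength = NULL,
                      captureDecay = 0,
                      misprimingRate = 0,
                      errorRate = 0.001,
                      mosaicFraction = 0.05,
                      mosaicCellTypes = character(0),
                      umiDupRate = 0.3,
                      exprMean = NULL,
                      exprDispersion = 2,
                      aRunGenes = integer(0),
                      aRunLength = 10L,
                      aRunTxCoord = NA_integer_,
                      seed = 1L) {
    kitEnd <- match.arg(kitEnd)
    if (is.null(readLength))
        readLength <- if (kitEnd == "three_prime") 91L else 90L
    methods::new("SimConfig",
        nCells = as.integer(nCells),
        cellTypes = cellTypes,
        nGenes = as.integer(nGenes),
        transcriptLengthRange = as.integer(transcriptLengthRange),
        nExonsRange = as.integer(nExonsRange),
        readLength = as.integer(readLength),
        kitEnd = kitEnd,
        captureDecay = as.numeric(captureDecay),
        misprimingRate = as.numeric(misprimingRate),
        errorRate = as.numeric(errorRate),
        mosaicFraction = as.numeric(mosaicFraction),
        mosaicCellTypes = as.character(mosaicCellTypes),
        umiDupRate = as.numeric(umiDupRate),
        exprMean = exprMean,
        exprDispersion = as.numeric(exprDispersion),
        aRunGenes = as.integer(aRunGenes),
        aRunLength = as.integer(aRunLength),
        aRunTxCoord = as.integer(aRunTxCoord),
        seed = as.integer(seed))
}

## random DNA of length n as a character scalar. Internal.
.randomDna <- function(n)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

#' Generate a miniature genome and annotation
#'
#' Genes are laid out in tandem on a single chromosome with alternating
#' strands and random intron/exon structure inside the configured ranges;
#' one transcript per gene, flagged canonical. Genes listed in
#' \code{aRunGenes} receive an internal A-homopolymer at the configured
#' spliced position (written to the genome so that the spliced mRNA
#' carries the run, across exon boundaries if necessary).
#'
#' @param config a [SimConfig-class]
#' @return list with \code{genome} (DNAStringSet, one chromosome) and
#'   \code{annotation} (a [TranscriptSet-class])
#' @export
makeReference <- function(config) {
    methods::validObject(config)
    set.seed(config@seed)
    nG <- config@nGenes
    lr <- config@transcriptLengthRange
    er <- config@nExonsRange
    gap <- 500L

    geneIds <- sprintf("gene%03d", seq_len(nG))
    txIds <- sprintf("tx%03d", seq_len(nG))
    exonsList <- vector("list", nG)
    geneMap <- stats::setNames(geneIds, txIds)
    chromParts <- character(0)
    offset <- 0L

    for (i in seq_len(nG)) {
        L <- if (lr[1] == lr[2]) lr[1] else sample(lr[1]:lr[2], 1L)
        nEx <- if (er[1] == er[2]) er[1] else sample(er[1]:er[2], 1L)
        # gene 1 is forced multi-exon (when allowed) so spliced-distance
        # code is always exercised
        if (i == 1L && er[2] >= 2L && L >= 2L * 50L) nEx <- max(nEx, 2L)
        nEx <- min(nEx, max(1L, L %/% 50L))
        # random composition of L into nEx exon widths, each >= 50 nt
        w <- rep(L %/% nEx, nEx)
        w[seq_len(L %% nEx)] <- w[seq_len(L %% nEx)] + 1L
        intr <- if (nEx > 1L) sample(100:500, nEx - 1L, replace = TRUE)
                else integer(0)
        strand <- if (i %% 2L == 1L) "+" else "-"

        starts <- integer(nEx)
        cur <- offset + gap + 1L
        for (k in seq_len(nEx)) {
            starts[k] <- cur
            cur <- cur + w[k] + if (k < nEx) intr[k] else 0L
        }
        exonsList[[i]] <- GenomicRanges::GRanges(
            "chrS", IRanges::IRanges(starts, width = w), strand = strand)
        span <- cur - 1L - offset
        chromParts <- c(chromParts, .randomDna(gap + span))
        offset <- offset + gap + span
    }
    chromParts <- c(chromParts, .randomDna(gap))
    chromSeq <- paste(chromParts, collapse = "")
    names(exonsList) <- txIds
    ts <- newTranscriptSet(exonsList, geneMap, txIds)

    # inject internal A-homopolymers on the spliced strand
    chromVec <- strsplit(chromSeq, "")[[1]]
    for (gi in config@aRunGenes) {
        tx <- txIds[gi]
        L <- ts@txData[tx, "length"]
        p0 <- config@aRunTxCoord
        if (is.na(p0)) p0 <- as.integer((L - config@aRunLength) %/% 2L)
        if (p0 < 0L || p0 + config@aRunLength > L)
            stop("A-run does not fit inside transcript ", tx)
        coords <- p0:(p0 + config@aRunLength - 1L)
        gpos <- transcriptToGenomic(ts, tx, coords)
        base <- if (ts@txData[tx, "strand"] == "-") "T" else "A"
        chromVec[gpos] <- base
    }
    genome <- Biostrings::DNAStringSet(paste(chromVec, collapse = ""))
    names(genome) <- "chrS"
    list(genome = genome, annotation = ts)
}

#' Simulate the cell population and expression counts
#'
#' Cell types are drawn from the configured proportions, the mutant flag
#' is Bernoulli(\code{mosaicFraction}) independently per eligible cell,
#' and counts are drawn per (gene, cell) from the configured
#' negative-binomial model. With the seed fixed the output is
#' bit-reproducible.
#'
#' @param config a [SimConfig-class]
#' @return list with \code{counts} (sparse genes x cells matrix) and
#'   \code{cellTable} (barcode, cell_type, germ_layer, is_mutant)
#' @export
simulateCells <- function(config) {
    methods::validObject(config)
    set.seed(config@seed + 1L)
    ct <- config@cellTypes
    n <- config@nCells
    nG <- config@nGenes

    type <- sample(ct$name, n, replace = TRUE, prob = ct$proportion)
    barcode <- character(n)
    repeat {
        todo <- which(barcode == "" | duplicated(barcode))
        if (!length(todo)) break
        barcode[todo] <- vapply(todo, function(i) paste0(
            paste(sample(c("A", "C", "G", "T"), 12L, replace = TRUE),
                  collapse = ""), "-1"), character(1))
    }
    eligible <- if (length(config@mosaicCellTypes))
        type %in% config@mosaicCellTypes else rep(TRUE, n)
    is_mutant <- eligible & stats::runif(n) < config@mosaicFraction

    em <- config@exprMean
    mu <- if (is.null(em)) {
        matrix(stats::rlnorm(nG, meanlog = -0.5, sdlog = 1), nG, nrow(ct))
    } else if (is.matrix(em)) {
        em
    } else if (length(em) == 1L) {
        matrix(em, nG, nrow(ct))
    } else {
        stopifnot(length(em) == nG)
        matrix(em, nG, nrow(ct))
    }
    typeIdx <- match(type, ct$name)
    counts <- matrix(0L, nG, n)
    for (g in seq_len(nG))
        counts[g, ] <- stats::rnbinom(n, size = config@exprDispersion,
                                      mu = mu[g, typeIdx])
    dimnames(counts) <- list(sprintf("gene%03d", seq_len(nG)), barcode)
    cellTable <- data.frame(
        barcode = barcode,
        cell_type = type,
        germ_layer = ct$germ_layer[typeIdx],
        is_mutant = is_mutant,
        stringsAsFactors = FALSE)
    list(counts = methods::as(counts, "CsparseMatrix"),
         cellTable = cellTable)
}

#' Place variant sites at chosen spliced positions
#'
#' Convenience constructor for simulated experiments: each row of
#' \code{spec} names a gene and a 0-based spliced coordinate on its
#' canonical transcript; the genomic position is projected back through
#' the exon structure, ref is read from the genome and alt is a
#' deterministic substitution (A>G, C>T, G>A, T>C).
#'
#' @param ts a [TranscriptSet-class]
#' @param genome DNAStringSet
#' @param spec data.frame with columns \code{gene_id}, \code{tx_coord} and
#'   optionally \code{role}, \code{patient_id}, \code{in_population_db}
#' @return GRanges of variant sites
#' @export
placeVariants <- function(ts, genome, spec) {
    canon <- canonicalTx(ts)
    sub <- c(A = "G", C = "T", G = "A", T = "C")
    rows <- lapply(seq_len(nrow(spec)), function(i) {
        tx <- canon[[spec$gene_id[i]]]
        td <- ts@txData[tx, ]
        pos <- transcriptToGenomic(ts, tx, spec$tx_coord[i])
        ref <- as.character(Biostrings::subseq(genome[[td$chrom]],
                                               pos, pos))
        data.frame(chrom = td$chrom, pos = pos, ref = ref,
                   alt = unname(sub[ref]),
                   gene_id = spec$gene_id[i],
                   patient_id = if ("patient_id" %in% names(spec))
                       spec$patient_id[i] else "simP1",
                   role = if ("role" %in% names(spec)) spec$role[i]
                          else "germline",
                   in_population_db =
                       if ("in_population_db" %in% names(spec))
                           spec$in_population_db[i] else FALSE,
                   stringsAsFactors = FALSE)
    })
    makeVariantSites(do.call(rbind, rows))
}

#' Simulate barcode/UMI-tagged end-biased reads into a BAM
#'
#' Each count in the expression matrix is one captured molecule. A
#' molecule is captured at the annotated kit end (possibly offset by an
#' exponential of scale \code{captureDecay}), or — with probability
#' \code{1 - (1 - misprimingRate)^nSites} — at one of the internal poly-A
#' sites found by [scanPolyA()] on its transcript, chosen uniformly. The
#' read covers \code{readLength} nt upstream of the capture site (3'
#' chemistry) or downstream (5'), spliced through the exon structure into
#' genomic alignment blocks. Molecules from mutant cells carry the alt
#' base at variant positions before per-base error is applied; every read
#' carries CB and UB tags, and UMI duplicates are emitted at rate
#' \code{umiDupRate}.
#'
#' @param counts genes x cells molecule counts (from [simulateCells()])
#' @param cellTable the cell table from [simulateCells()]
#' @param genome DNAStringSet from [makeReference()]
#' @param ts the [TranscriptSet-class] from [makeReference()]
#' @param variants GRanges of variant sites; every variant must fall in an
#'   exon of a simulated transcript
#' @param config the [SimConfig-class]
#' @param bamPath output BAM path (coordinate-sorted and indexed)
#' @return a [SimTruth-class]; the BAM is written to \code{bamPath}
#' @export
simulateReads <- function(counts, cellTable, genome, ts, variants, config,
                          bamPath) {
    methods::validObject(config)
    set.seed(config@seed + 2L)
    RL <- config@readLength
    kit <- config@kitEnd
    canon <- canonicalTx(ts)

    if (length(variants)) {
        vd <- variantDistances(variants, ts)
        if (any(vd$status != "exonic"))
            stop("variant(s) not covered by any simulated transcript ",
                 "exon: ",
                 paste(vd$variant_id[vd$status != "exonic"],
                       collapse = ", "),
                 "; adjust the variant positions or the annotation")
        chromSeq <- genome[[1]]
        gref <- as.character(Biostrings::extractAt(
            chromSeq, IRanges::IRanges(GenomicRanges::start(variants),
                                       width = 1L)))
        if (any(gref != variants$ref))
            stop("variant ref allele(s) disagree with the genome sequence")
    }

    txSeqs <- transcriptSequences(genome, ts)
    genes <- rownames(counts)
    alnList <- list()
    readList <- list()
    readCounter <- 0L

    for (g in genes) {
        tx <- canon[[g]]
        if (is.null(tx) || is.na(tx)) stop("no canonical transcript for ", g)
        td <- ts@txData[tx, ]
        L <- td$length
        cnt <- counts[g, ]
        cells <- rep(which(cnt > 0), cnt[cnt > 0])
        nMol <- length(cells)
        if (nMol == 0L) next

        sites <- scanPolyA(txSeqs[[tx]])
        # a site must leave room for a full-length read
        if (nrow(sites)) {
            sOk <- if (kit == "three_prime") sites$tx_coord >= RL
                   else sites$tx_coord <= L - RL
            sites <- sites[sOk, , drop = FALSE]
        }
        nSites <- nrow(sites)

        pMis <- if (nSites > 0L)
            1 - (1 - config@misprimingRate)^nSites else 0
        misprimed <- stats::runif(nMol) < pMis
        siteIdx <- rep(NA_integer_, nMol)
        if (any(misprimed))
            siteIdx[misprimed] <- sample.int(nSites, sum(misprimed),
                                             replace = TRUE)

        off <- if (config@captureDecay > 0)
            pmin(as.integer(stats::rexp(nMol, 1 / config@captureDecay)),
                 L - RL)
        else integer(nMol)

        # capture site and read interval in 0-based spliced coords
        if (kit == "three_prime") {
            cap <- ifelse(misprimed, sites$tx_coord[siteIdx] - 1L,
                          L - 1L - off)
            txStart <- cap - RL + 1L
        } else {
            cap <- ifelse(misprimed, sites$tx_coord[siteIdx], off)
            txStart <- cap
        }
        txEnd <- txStart + RL - 1L

        uStarts <- sort(unique(txStart))
        tmpl <- vector("list", length(uStarts))
        for (k in seq_along(uStarts)) {
            s0 <- uStarts[k]
            blocks <- splicedBlocks(ts, tx, s0, s0 + RL - 1L)
            bs <- GenomicRanges::start(blocks)
            be <- GenomicRanges::end(blocks)
            cig <- paste0(be[1] - bs[1] + 1L, "M")
            if (length(bs) > 1L)
                for (b in 2:length(bs))
                    cig <- paste0(cig, bs[b] - be[b - 1L] - 1L, "N",
                                  be[b] - bs[b] + 1L, "M")
            seqParts <- as.character(Biostrings::extractAt(
                genome[[td$chrom]], IRanges::IRanges(bs, be)))
            tmpl[[k]] <- list(pos = bs[1], cigar = cig,
                              seq = paste(seqParts, collapse = ""),
                              blockStart = bs, blockEnd = be)
        }
        tIdx <- match(txStart, uStarts)

        seqV <- vapply(tmpl, `[[`, character(1), "seq")
        molSeq <- seqV[tIdx]
        molAllele <- rep(NA_character_, nMol)
        molVariant <- rep(NA_character_, nMol)
        gVar <- if (length(variants))
            which(variants$gene_id == g) else integer(0)
        for (vi in gVar) {
            P <- GenomicRanges::start(variants)[vi]
            offIn <- vapply(tmpl, function(t) {
                hit <- which(t$blockStart <= P & t$blockEnd >= P)
                if (!length(hit)) return(NA_integer_)
                before <- if (hit > 1L)
                    sum(t$blockEnd[seq_len(hit - 1L)] -
                        t$blockStart[seq_len(hit - 1L)] + 1L) else 0L
                as.integer(before + (P - t$blockStart[hit]) + 1L)
            }, integer(1))
            covered <- !is.na(offIn[tIdx])
            if (!any(covered)) next
            mut <- cellTable$is_mutant[cells] & covered
            refc <- !cellTable$is_mutant[cells] & covered
            molAllele[mut] <- "alt"
            molAllele[refc] <- "ref"
            molVariant[covered] <- variantIds(variants[vi])
            if (any(mut)) {
                o <- offIn[tIdx[mut]]
                molSeq[mut] <- paste0(
                    substr(molSeq[mut], 1L, o - 1L),
                    variants$alt[vi],
                    substr(molSeq[mut], o + 1L, RL))
            }
        }

        umiM <- matrix(sample(c("A", "C", "G", "T"), 10L * nMol,
                              replace = TRUE), nrow = nMol)
        umis <- do.call(paste0, as.data.frame(umiM,
                                              stringsAsFactors = FALSE))
        nReads <- 1L + stats::rpois(nMol, config@umiDupRate)
        rIdx <- rep(seq_len(nMol), nReads)
        readSeq <- molSeq[rIdx]

        if (config@errorRate > 0) {
            nErr <- stats::rbinom(length(rIdx), RL, config@errorRate)
            for (r in which(nErr > 0)) {
                pos <- sample.int(RL, nErr[r])
                for (p in pos) {
                    old <- substr(readSeq[r], p, p)
                    newb <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
                    substr(readSeq[r], p, p) <- newb
                }
            }
        }

        flag <- if (kit == "five_prime") {
            if (td$strand == "-") 16L else 0L
        } else {
            if (td$strand == "+") 16L else 0L
        }
        qname <- sprintf("r%08d", readCounter + seq_along(rIdx))
        readCounter <- readCounter + length(rIdx)

        origin <- ifelse(misprimed,
                         paste0("internal_polyA@", sites$tx_coord[siteIdx]),
                         "transcript_end")
        posV <- vapply(tmpl, `[[`, numeric(1), "pos")
        cigV <- vapply(tmpl, `[[`, character(1), "cigar")
        alnList[[g]] <- data.frame(
            qname = qname, flag = flag, chrom = unname(td$chrom),
            pos = posV[tIdx[rIdx]],
            mapq = 255L,
            cigar = cigV[tIdx[rIdx]],
            seq = readSeq,
            cb = cellTable$barcode[cells][rIdx],
            ub = umis[rIdx],
            stringsAsFactors = FALSE)
        readList[[g]] <- data.frame(
            read_id = qname, gene = g,
            barcode = cellTable$barcode[cells][rIdx],
            origin = origin[rIdx],
            variant_id = molVariant[rIdx],
            allele = molAllele[rIdx],
            stringsAsFactors = FALSE)
    }

    aln <- if (length(alnList)) do.call(rbind, alnList) else
        data.frame(qname = character(0), flag = integer(0),
                   chrom = character(0), pos = numeric(0),
                   mapq = integer(0), cigar = character(0),
                   seq = character(0), cb = character(0),
                   ub = character(0))
    chromLengths <- stats::setNames(Biostrings::width(genome),
                                    names(genome))
    sam <- tempfile(fileext = ".sam")
    writeTaggedSam(aln, chromLengths, sam)
    samToSortedBam(sam, bamPath)
    unlink(sam)

    readTable <- if (length(readList)) do.call(rbind, readList) else
        data.frame(read_id = character(0), gene = character(0),
                   barcode = character(0), origin = character(0),
                   variant_id = character(0), allele = character(0))
    rownames(readTable) <- NULL
    trueVaf <- mean(cellTable$is_mutant)
    variantTable <- data.frame(
        variant_id = variantIds(variants),
        true_vaf = rep(trueVaf, length(variants)),
        stringsAsFactors = FALSE)
    methods::new("SimTruth", cellTable = cellTable,
                 readTable = readTable, variantTable = variantTable)
}

#' Write / read simulation ground truth as TSV
#'
#' Three tab-separated files (\code{truth_cells.tsv},
#' \code{truth_reads.tsv}, \code{truth_variants.tsv}) that round-trip
#' losslessly through [readTruth()].
#'
#' @param truth a [SimTruth-class]
#' @param dir output directory
#' @return \code{dir} (write) or a [SimTruth-class] (read)
#' @export
writeTruth <- function(truth, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(df, f) utils::write.table(
        df, file.path(dir, f), sep = "\t", quote = FALSE,
        row.names = FALSE, na = "NA")
    wt(truth@cellTable, "truth_cells.tsv")
    wt(truth@readTable, "truth_reads.tsv")
    wt(truth@variantTable, "truth_variants.tsv")
    invisible(dir)
}

#' @rdname writeTruth
#' @export
readTruth <- function(dir) {
    rt <- function(f, classes) utils::read.table(
        file.path(dir, f), sep = "\t", header = TRUE,
        colClasses = classes, stringsAsFactors = FALSE)
    methods::new("SimTruth",
        cellTable = rt("truth_cells.tsv",
                       c("character", "character", "character", "logical")),
        readTable = rt("truth_reads.tsv",
                       c("character", "character", "character",
                         "character", "character", "character")),
        variantTable = rt("truth_variants.tsv",
                          c("character", "numeric")))
}

#' Simulate a complete dataset to disk
#'
#' Runs [makeReference()], [simulateCells()] and [simulateReads()] and
#' writes the full external surface: genome FASTA, annotation GTF, VCF of
#' injected variants, coordinate-sorted indexed BAM with CB/UB tags,
#' MatrixMarket counts trio, a cluster TSV (truth cell types standing in
#' for cluster labels), and the truth tables.
#'
#' @param config a [SimConfig-class]
#' @param variantSpec data.frame for [placeVariants()] (gene_id, tx_coord,
#'   role, ...); NULL places one germline variant 50 nt from the kit end
#'   of the first gene
#' @param outdir output directory
#' @return (invisibly) list of the in-memory objects and output paths
#' @export
simulateDataset <- function(config, variantSpec = NULL, outdir) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    ref <- makeReference(config)
    cells <- simulateCells(config)
    ts <- ref$annotation
    if (is.null(variantSpec)) {
        L1 <- ts@txData$length[1]
        tc <- if (config@kitEnd == "three_prime") L1 - 1L - 50L else 50L
        variantSpec <- data.frame(gene_id = ts@txData$gene_id[1],
                                  tx_coord = tc,
                                  role = "somatic_candidate")
    }
    variants <- placeVariants(ts, ref$genome, variantSpec)

    fa <- file.path(outdir, "genome.fa")
    Biostrings::writeXStringSet(ref$genome, fa)
    gtf <- file.path(outdir, "annotation.gtf")
    writeAnnotationGtf(ts, gtf)
    vcf <- file.path(outdir, "variants.vcf")
    writeVariantSites(variants, vcf,
                      stats::setNames(Biostrings::width(ref$genome),
                                      names(ref$genome)))
    bam <- file.path(outdir, "possorted.bam")
    truth <- simulateReads(cells$counts, cells$cellTable, ref$genome, ts,
                           variants, config, bam)
    countsDir <- file.path(outdir, "counts")
    writeMtxCounts(cells$counts, countsDir)
    clusters <- file.path(outdir, "clusters.tsv")
    utils::write.table(
        data.frame(barcode = cells$cellTable$barcode,
                   cluster = cells$cellTable$cell_type),
        clusters, sep = "\t", quote = FALSE, row.names = FALSE)
    truthDir <- file.path(outdir, "truth")
    writeTruth(truth, truthDir)

    invisible(list(genome = ref$genome, annotation = ts,
                   counts = cells$counts, cellTable = cells$cellTable,
                   variants = variants, truth = truth,
                   paths = list(genome = fa, gtf = gtf, vcf = vcf,
                                bam = bam, counts = countsDir,
                                clusters = clusters, truth = truthDir)))
}
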