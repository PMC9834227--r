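test_that("reference construction honours the configured geometry", {
    # minimal case: one single-exon 1,000 nt gene
    cfg1 <- simConfig(nCells = 5, nGenes = 1,
                      transcriptLengthRange = c(1000L, 1000L),
                      nExonsRange = c(1L, 1L), seed = 1)
    ref1 <- makeReference(cfg1)
    expect_gte(sum(Biostrings::width(ref1$genome)), 1000L)
    td1 <- as.data.frame(txData(ref1$annotation))
    expect_equal(nrow(td1), 1L)
    expect_equal(td1$length, 1000L)
    expect_true(td1$canonical)
    expect_equal(length(txExons(ref1$annotation)[[1]]), 1L)

    # an internal 10-A run lands at the requested spliced coordinate
    cfg2 <- simConfig(nCells = 5, nGenes = 2,
                      transcriptLengthRange = c(2000L, 2000L),
                      aRunGenes = 1L, aRunLength = 10L,
                      aRunTxCoord = 500L, seed = 2)
    ref2 <- makeReference(cfg2)
    seqs <- transcriptSequences(ref2$genome, ref2$annotation)
    expect_equal(as.character(Biostrings::subseq(seqs[["tx001"]],
                                                 501, 510)),
                 strrep("A", 10))

    # spliced length equals the sum of exon lengths
    cfg3 <- simConfig(nCells = 5, nGenes = 3,
                      transcriptLengthRange = c(500L, 500L),
                      nExonsRange = c(2L, 2L), seed = 3)
    ref3 <- makeReference(cfg3)
    for (tx in names(txExons(ref3$annotation))) {
        ex <- txExons(ref3$annotation)[[tx]]
        expect_equal(length(ex), 2L)
        expect_equal(sum(GenomicRanges::width(ex)), 500L)
        expect_equal(unname(txData(ref3$annotation)[tx, "length"]), 500L)
    }
    # exons lie within the chromosome
    allEx <- unlist(txExons(ref3$annotation))
    expect_true(all(GenomicRanges::end(allEx) <=
                    Biostrings::width(ref3$genome)[1]))
})

test_that("mosaic flags follow the configured fraction", {
    base <- function(f, n = 200L, seed = 5)
        simConfig(nCells = n, nGenes = 2, mosaicFraction = f, seed = seed)
    expect_equal(sum(simulateCells(base(0))$cellTable$is_mutant), 0L)
    expect_equal(sum(simulateCells(base(1))$cellTable$is_mutant), 200L)
    big <- simulateCells(simConfig(nCells = 10000L, nGenes = 1,
                                   mosaicFraction = 0.05, seed = 6))
    f <- mean(big$cellTable$is_mutant)
    sd3 <- 3 * sqrt(0.05 * 0.95 / 10000)
    expect_lt(abs(f - 0.05), sd3)
    # restriction to cell types is absolute
    restr <- simulateCells(simConfig(nCells = 500L, nGenes = 1,
                                     mosaicFraction = 0.5,
                                     mosaicCellTypes = "Microglia",
                                     seed = 7))
    ct <- restr$cellTable
    expect_true(all(!ct$is_mutant[ct$cell_type != "Microglia"]))
    expect_gt(sum(ct$is_mutant[ct$cell_type == "Microglia"]), 0L)
})

test_that("expression model and barcodes behave", {
    cfg <- simConfig(nCells = 300L, nGenes = 4, exprMean = c(0, 1, 5, 20),
                     seed = 8)
    cells <- simulateCells(cfg)
    expect_false(any(duplicated(cells$cellTable$barcode)))
    m <- Matrix::rowMeans(cells$counts)
    expect_equal(unname(m[1]), 0)
    expect_true(all(diff(m) > 0))        # means ordered as configured
})

test_that("simulation is bit-reproducible under a fixed seed", {
    run <- function() {
        cfg <- simConfig(nCells = 40L, nGenes = 3, exprMean = 2, seed = 9)
        d <- tempfile()
        sim <- simulateDataset(cfg, NULL, d)
        unname(tools::md5sum(c(sim$paths$bam, sim$paths$genome,
                               sim$paths$gtf, sim$paths$vcf,
                               file.path(sim$paths$truth,
                                         "truth_reads.tsv"))))
    }
    expect_identical(run(), run())
})

test_that("read geometry: length exact, exon-confined, end-anchored", {
    cfg <- simConfig(nCells = 60L, nGenes = 3, exprMean = 3,
                     transcriptLengthRange = c(600L, 1200L),
                     nExonsRange = c(2L, 3L), errorRate = 0, seed = 10)
    ref <- makeReference(cfg)
    cells <- simulateCells(cfg)
    v <- placeVariants(ref$annotation, ref$genome,
                       data.frame(gene_id = "gene001", tx_coord = 50L))
    bam <- tempfile(fileext = ".bam")
    simulateReads(cells$counts, cells$cellTable, ref$genome,
                  ref$annotation, v, cfg, bam)
    p <- Rsamtools::ScanBamParam(what = c("rname", "pos", "cigar", "seq"),
                                 tag = c("CB", "UB"))
    r <- Rsamtools::scanBam(bam, param = p)[[1]]
    expect_gt(length(r$pos), 0L)
    # emitted read length is exactly readLength
    expect_true(all(Biostrings::width(r$seq) == 91L))
    qwidth <- GenomicAlignments::cigarWidthAlongQuerySpace(r$cigar)
    expect_true(all(qwidth == 91L))
    # every aligned base falls inside an exon of the read's transcript
    allEx <- BiocGenerics::unlist(txExons(ref$annotation))
    refBlocks <- GenomicAlignments::cigarRangesAlongReferenceSpace(
        r$cigar, pos = r$pos, ops = "M")
    cov <- IRanges::coverage(IRanges::reduce(BiocGenerics::unlist(refBlocks)))
    exCov <- IRanges::coverage(IRanges::reduce(GenomicRanges::ranges(allEx)))
    outside <- cov > 0L & exCov == 0L
    expect_equal(sum(S4Vectors::runValue(outside)), 0L)
    # all tags present
    expect_false(any(is.na(r$tag$CB)))
    expect_false(any(is.na(r$tag$UB)))
})

test_that("with zero error no non-mutant cell ever shows the alt base", {
    cfg <- simConfig(nCells = 80L, nGenes = 2, exprMean = 3,
                     errorRate = 0, mosaicFraction = 0.3, seed = 12)
    ref <- makeReference(cfg)
    cells <- simulateCells(cfg)
    L <- txData(ref$annotation)$length[1]
    v <- placeVariants(ref$annotation, ref$genome,
                       data.frame(gene_id = "gene001",
                                  tx_coord = L - 1L - 40L))
    bam <- tempfile(fileext = ".bam")
    truth <- simulateReads(cells$counts, cells$cellTable, ref$genome,
                           ref$annotation, v, cfg, bam)
    gm <- countAlleles(bam, v,
                       countingParams(barcodes = cells$cellTable$barcode))
    calls <- genotypeCalls(gm)[1, ]
    mut <- stats::setNames(truth@cellTable$is_mutant,
                           truth@cellTable$barcode)
    expect_true(all(calls[!mut[names(calls)]] != "ALT"))
    covered <- (as.matrix(refUmis(gm)) + as.matrix(altUmis(gm)))[1, ] >= 1
    expect_true(all(calls[mut[names(calls)] & covered] == "ALT"))
})

test_that("capture-offset decay shifts read starts toward the ends", {
    cfg <- simConfig(nCells = 150L, nGenes = 1, exprMean = 8,
                     transcriptLengthRange = c(2000L, 2000L),
                     nExonsRange = c(1L, 1L), captureDecay = 120,
                     errorRate = 0, seed = 13)
    ref <- makeReference(cfg)
    cells <- simulateCells(cfg)
    v <- placeVariants(ref$annotation, ref$genome,
                       data.frame(gene_id = "gene001", tx_coord = 100L))
    bam <- tempfile(fileext = ".bam")
    truth <- simulateReads(cells$counts, cells$cellTable, ref$genome,
                           ref$annotation, v, cfg, bam)
    r <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
        what = c("pos")))[[1]]
    ex <- txExons(ref$annotation)[[1]]
    # 3' kit, plus strand: read end offset from the transcript 3' end
    offs <- GenomicRanges::end(ex) - (r$pos + 91L - 1L)
    bins <- table(cut(offs, c(-1, 120, 240, 1e5)))
    expect_true(bins[1] > bins[2])
    expect_true(bins[2] > bins[3])
})

test_that("truth tables round-trip and reject bad variant configs", {
    cfg <- simConfig(nCells = 25L, nGenes = 2, exprMean = 2, seed = 14)
    ref <- makeReference(cfg)
    cells <- simulateCells(cfg)
    v <- placeVariants(ref$annotation, ref$genome,
                       data.frame(gene_id = "gene001", tx_coord = 30L))
    bam <- tempfile(fileext = ".bam")
    truth <- simulateReads(cells$counts, cells$cellTable, ref$genome,
                           ref$annotation, v, cfg, bam)
    d <- tempfile()
    writeTruth(truth, d)
    back <- readTruth(d)
    expect_equal(back@cellTable, truth@cellTable)
    expect_equal(back@readTable, truth@readTable)
    expect_equal(back@variantTable, truth@variantTable)
    # every barcode in the BAM appears in the cell table
    r <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
        what = character(0), tag = "CB"))[[1]]
    expect_true(all(r$tag$CB %in% truth@cellTable$barcode))

    # a variant outside every exon is rejected with a clear message
    ex1 <- txExons(ref$annotation)[[1]]
    intronPos <- GenomicRanges::end(ex1)[1] + 1L
    vBad <- makeVariantSites(data.frame(
        chrom = "chrS", pos = intronPos, ref = "A", alt = "G",
        gene_id = "gene001"))
    expect_error(simulateReads(cells$counts, cells$cellTable, ref$genome,
                               ref$annotation, vBad, cfg,
                               tempfile(fileext = ".bam")),
                 "not covered by any simulated transcript")
})

test_that("empty truth writes header-only files", {
    empty <- methods::new("SimTruth",
        cellTable = data.frame(barcode = character(0),
                               cell_type = character(0),
                               germ_layer = character(0),
                               is_mutant = logical(0)),
        readTable = data.frame(read_id = character(0),
                               gene = character(0),
                               barcode = character(0),
                               origin = character(0),
                               variant_id = character(0),
                               allele = character(0)),
        variantTable = data.frame(variant_id = character(0),
                                  true_vaf = numeric(0)))
    d <- tempfile()
    writeTruth(empty, d)
    expect_equal(length(readLines(file.path(d, "truth_cells.tsv"))), 1L)
    back <- readTruth(d)
    expect_equal(nrow(back@cellTable), 0L)
})

test_that("config validation rejects inconsistent parameters", {
    expect_error(simConfig(nCells = 10, misprimingRate = 1.5),
                 "misprimingRate")
    expect_error(simConfig(nCells = 10,
                           transcriptLengthRange = c(50L, 60L)),
                 "readLength")
    ct <- defaultCellTypes(); ct$proportion[1] <- 0.9
    expect_error(simConfig(cellTypes = ct), "sum to 1")
    expect_error(simConfig(mosaicCellTypes = "NotAType"),
                 "mosaicCellTypes")
})
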