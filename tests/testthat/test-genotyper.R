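test_that("empty BAM with known barcodes yields all NO_CALL", {
    bam <- tempfile(fileext = ".bam")
    writeFixtureBam(fxRead("x", 1, "1M", "A", "B1", "U1")[0, ],
                    c(c1 = 2000L), bam)
    v <- fixtureVariants()[1]
    gm <- countAlleles(bam, v,
                       countingParams(barcodes = c("B1", "B2", "B3")))
    expect_equal(unname(genotypeCalls(gm)[1, ]),
                 rep("NO_CALL", 3))
    expect_equal(sum(refUmis(gm)) + sum(altUmis(gm)), 0)
})

test_that("per-cell UMI counting matches the hand-derived 4-read fixture", {
    # cell A: two UMIs each one alt read; cell B: one ref UMI; cell C: none
    v <- fixtureVariants()[1]            # c1:500 A>G
    seqAlt <- paste0(strrep("T", 10), "G", strrep("T", 29))
    seqRef <- paste0(strrep("T", 10), "A", strrep("T", 29))
    recs <- rbind(
        fxRead("r1", 490, "40M", seqAlt, "A", "U1"),
        fxRead("r2", 490, "40M", seqAlt, "A", "U2"),
        fxRead("r3", 490, "40M", seqRef, "B", "U1"))
    bam <- tempfile(fileext = ".bam")
    writeFixtureBam(recs, c(c1 = 2000L), bam)
    gm <- countAlleles(bam, v,
                       countingParams(barcodes = c("A", "B", "C")))
    expect_equal(unname(as.matrix(altUmis(gm))[1, ]), c(2, 0, 0))
    expect_equal(unname(as.matrix(refUmis(gm))[1, ]), c(0, 1, 0))
    expect_equal(unname(genotypeCalls(gm)[1, ]),
                 c("ALT", "REF", "NO_CALL"))
})

test_that("majority consensus resolves multi-read UMIs and drops ties", {
    v <- fixtureVariants()[1]
    seqAlt <- paste0(strrep("T", 10), "G", strrep("T", 29))
    seqRef <- paste0(strrep("T", 10), "A", strrep("T", 29))
    recs <- rbind(
        # UMI U1: alt, alt, ref -> one alt UMI
        fxRead("m1", 490, "40M", seqAlt, "A", "U1"),
        fxRead("m2", 490, "40M", seqAlt, "A", "U1"),
        fxRead("m3", 490, "40M", seqRef, "A", "U1"),
        # UMI U2: alt, ref -> tie, discarded
        fxRead("m4", 490, "40M", seqAlt, "A", "U2"),
        fxRead("m5", 490, "40M", seqRef, "A", "U2"))
    bam <- tempfile(fileext = ".bam")
    writeFixtureBam(recs, c(c1 = 2000L), bam)
    gm <- countAlleles(bam, v, countingParams(barcodes = "A"))
    expect_equal(as.numeric(altUmis(gm)[1, 1]), 1)
    expect_equal(as.numeric(refUmis(gm)[1, 1]), 0)
    # under "any", the tied UMI votes alt too
    gmAny <- countAlleles(bam, v, countingParams(barcodes = "A",
                                                 umiConsensus = "any"))
    expect_equal(as.numeric(altUmis(gmAny)[1, 1]), 2)
})

test_that("quality and flag filters exclude reads", {
    v <- fixtureVariants()[1]
    seqAlt <- paste0(strrep("T", 10), "G", strrep("T", 29))
    lowQual <- paste0(strrep("F", 10), "#", strrep("F", 29))
    recs <- rbind(
        fxRead("f1", 490, "40M", seqAlt, "A", "U1", mapq = 10L),
        fxRead("f2", 490, "40M", seqAlt, "A", "U2", qual = lowQual),
        fxRead("f3", 490, "40M", seqAlt, "A", "U3", flag = 256L),
        fxRead("f4", 490, "40M", seqAlt, "A", "U4", flag = 2048L),
        fxRead("f5", 490, "40M", seqAlt, NA, "U5"),
        fxRead("f6", 490, "40M", seqAlt, "A", NA),
        # deletion spanning the variant position
        fxRead("f7", 495, "4M2D36M", strrep("T", 40), "A", "U7"),
        # splice spanning the variant position
        fxRead("f8", 495, "4M10N36M", strrep("T", 40), "A", "U8"))
    bam <- tempfile(fileext = ".bam")
    writeFixtureBam(recs, c(c1 = 2000L), bam)
    gm <- countAlleles(bam, v, countingParams(barcodes = "A"))
    expect_equal(sum(refUmis(gm)) + sum(altUmis(gm)), 0)
    expect_equal(unname(genotypeCalls(gm)[1, 1]), "NO_CALL")
})

test_that("bases that are neither ref nor alt are ignored", {
    v <- fixtureVariants()[1]            # A>G
    seqOther <- paste0(strrep("T", 10), "C", strrep("T", 29))
    bam <- tempfile(fileext = ".bam")
    writeFixtureBam(fxRead("o1", 490, "40M", seqOther, "A", "U1"),
                    c(c1 = 2000L), bam)
    gm <- countAlleles(bam, v, countingParams(barcodes = "A"))
    expect_equal(sum(refUmis(gm)) + sum(altUmis(gm)), 0)
})

test_that("missing BAM index and absent chromosome are handled", {
    v <- fixtureVariants()[1]
    bam <- tempfile(fileext = ".bam")
    writeFixtureBam(fxRead("x", 1, "1M", "A", "B1", "U1")[0, ],
                    c(c1 = 2000L), bam)
    file.remove(paste0(bam, ".bai"))
    expect_error(countAlleles(bam, v), "index")

    bam2 <- tempfile(fileext = ".bam")
    writeFixtureBam(fxRead("x", 1, "1M", "A", "B1", "U1")[0, ],
                    c(c1 = 2000L), bam2)
    vOff <- makeVariantSites(data.frame(chrom = "chrMissing", pos = 5,
                                        ref = "A", alt = "G"))
    expect_warning(
        gm <- countAlleles(bam2, vOff,
                           countingParams(barcodes = c("B1", "B2"))),
        "absent from BAM header")
    expect_equal(unname(genotypeCalls(gm)[1, ]), rep("NO_CALL", 2))
})

test_that("call policies follow their definitions", {
    ref <- matrix(c(0, 3, 3, 2), 1)
    alt <- matrix(c(0, 1, 0, 0), 1)
    cg <- callGenotypes(ref, alt, "alt_dominant")
    expect_equal(unname(cg$calls[1, ]),
                 c("NO_CALL", "ALT", "REF", "REF"))
    expect_equal(unname(cg$both[1, ]), c(FALSE, TRUE, FALSE, FALSE))
    cgC <- callGenotypes(ref, alt, "consensus")
    expect_equal(cg$calls, cgC$calls)    # both policies report ALT, flagged
})

test_that("count_alleles matches the brute-force oracle on random fixtures", {
    v <- fixtureVariants()
    for (seed in 1:3) {
        set.seed(seed)
        recs <- randomFixtureRecords(v, nReads = 150L)
        bam <- tempfile(fileext = ".bam")
        writeFixtureBam(recs, c(c1 = 2000L), bam)
        oracle <- bruteForceCounts(bam, v)
        gm <- countAlleles(bam, v,
                           countingParams(barcodes = colnames(oracle$ref)))
        expect_equal(unname(as.matrix(refUmis(gm))), unname(oracle$ref))
        expect_equal(unname(as.matrix(altUmis(gm))), unname(oracle$alt))
    }
})

test_that("read order never changes counts", {
    v <- fixtureVariants()
    set.seed(42)
    recs <- randomFixtureRecords(v, nReads = 100L)
    bamA <- tempfile(fileext = ".bam")
    bamB <- tempfile(fileext = ".bam")
    writeFixtureBam(recs, c(c1 = 2000L), bamA)
    writeFixtureBam(recs[sample(nrow(recs)), ], c(c1 = 2000L), bamB)
    bcs <- sort(unique(stats::na.omit(recs$cb)))
    gmA <- countAlleles(bamA, v, countingParams(barcodes = bcs))
    gmB <- countAlleles(bamB, v, countingParams(barcodes = bcs))
    expect_equal(as.matrix(refUmis(gmA)), as.matrix(refUmis(gmB)))
    expect_equal(as.matrix(altUmis(gmA)), as.matrix(altUmis(gmB)))
})

test_that("UMI counts are bounded by distinct (CB,UB) pairs at the site", {
    v <- fixtureVariants()
    set.seed(7)
    recs <- randomFixtureRecords(v, nReads = 200L)
    bam <- tempfile(fileext = ".bam")
    writeFixtureBam(recs, c(c1 = 2000L), bam)
    gm <- countAlleles(bam, v)
    tot <- Matrix::rowSums(refUmis(gm)) + Matrix::rowSums(altUmis(gm))
    nPairs <- length(unique(paste(recs$cb, recs$ub)))
    expect_true(all(tot <= nPairs))
})

test_that("annotateCalls joins on normalized barcodes", {
    v <- fixtureVariants()[1]
    seqAlt <- paste0(strrep("T", 10), "G", strrep("T", 29))
    recs <- rbind(fxRead("r1", 490, "40M", seqAlt, "AAAC-1", "U1"),
                  fxRead("r2", 490, "40M", seqAlt, "AAAG-1", "U1"))
    bam <- tempfile(fileext = ".bam")
    writeFixtureBam(recs, c(c1 = 2000L), bam)
    gm <- countAlleles(bam, v)

    # disjoint barcode sets -> explicit error
    expect_error(annotateCalls(gm, data.frame(barcode = c("TTTT", "GGGG"))),
                 "suffix")
    # suffix-mismatched but matching barcodes join; superset tolerated
    meta <- data.frame(barcode = c("AAAC", "AAAG", "AAAT"),
                       cluster = c("k1", "k2", "k3"))
    expect_message(ann <- annotateCalls(gm, meta, kit = "3p"),
                   "no match")
    expect_equal(nrow(ann), 2L)
    expect_setequal(ann$cluster, c("k1", "k2"))
    expect_true(all(ann$kit == "3p"))
    # exact match: one row per (variant, barcode)
    meta2 <- data.frame(barcode = c("AAAC-1", "AAAG-1"), cluster = "k")
    ann2 <- annotateCalls(gm, meta2)
    expect_equal(nrow(ann2), 2L)
})

test_that("genotype matrices round-trip through the MTX layout", {
    v <- fixtureVariants()
    set.seed(11)
    recs <- randomFixtureRecords(v, nReads = 80L)
    bam <- tempfile(fileext = ".bam")
    writeFixtureBam(recs, c(c1 = 2000L), bam)
    gm <- countAlleles(bam, v)
    d <- tempfile()
    writeGenotypeMatrices(gm, d)
    gm2 <- readGenotypeMatrices(d)
    expect_equal(as.matrix(refUmis(gm)), as.matrix(refUmis(gm2)))
    expect_equal(as.matrix(altUmis(gm)), as.matrix(altUmis(gm2)))
    expect_equal(genotypeCalls(gm), genotypeCalls(gm2))
})
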