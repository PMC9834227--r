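test_that("QC metrics compute totals and percentages", {
    m <- Matrix::Matrix(0, 2, 3, sparse = TRUE,
                        dimnames = list(c("MT-g1", "g2"),
                                        c("b1", "b2", "b3")))
    m["MT-g1", "b1"] <- 5
    m["g2", "b1"] <- 95
    m["g2", "b2"] <- 10
    qc <- qcMetrics(m)
    expect_equal(qc$n_umis, c(100L, 10L, 0L))
    expect_equal(qc$n_genes_detected[1], 2L)
    expect_equal(qc$pct_mito[1], 5.0)
    expect_equal(qc$pct_mito[2], 0)
    expect_true(is.na(qc$pct_mito[3]))   # zero-count cell undefined
    # no mitochondrial genes present -> 0
    m2 <- m; rownames(m2) <- c("gA", "gB")
    expect_equal(qcMetrics(m2)$pct_mito[1:2], c(0, 0))
    # empty matrix -> empty output
    expect_equal(nrow(qcMetrics(m[, 0])), 0L)
})

test_that("mitochondrial filter keeps the boundary", {
    qc <- data.frame(barcode = c("a", "b", "c", "d"),
                     pct_mito = c(5.0, 5.1, 0, NA))
    expect_equal(filterCells(qc), c("a", "c"))
    qcClean <- data.frame(barcode = letters[1:3], pct_mito = c(0, 1, 2))
    expect_equal(filterCells(qcClean), letters[1:3])
})

test_that("log-normalization matches its closed form", {
    m <- Matrix::Matrix(c(1, 9999, 2, 9998), 2, sparse = TRUE)
    rownames(m) <- c("g1", "g2"); colnames(m) <- c("c1", "c2")
    ln <- logNormalize(m)
    expect_equal(ln[1, 1], log(2))       # count 1 in a 10,000-total cell
    expect_equal(ln[1, 2], log(1 + 1e4 * 2 / 1e4))
    # doubling all counts of a cell changes nothing
    m2 <- m; m2[, 1] <- m[, 1] * 2
    expect_equal(logNormalize(m2)[, 1], ln[, 1])
    # monotone within a cell
    expect_true(ln[2, 1] > ln[1, 1])
    # count 0 -> 0
    m3 <- m; m3[1, 1] <- 0
    expect_equal(logNormalize(m3)[1, 1], 0)
    # zero-total cell is an error pointing at filtering
    m4 <- m; m4[, 2] <- 0
    expect_error(logNormalize(m4), "filterCells")
})

test_that("concordance recovers identity and decays under permutation", {
    set.seed(21)
    m <- Matrix::Matrix(matrix(rpois(200 * 30, 5), 200, 30),
                        sparse = TRUE)
    rownames(m) <- sprintf("g%03d", 1:200)
    colnames(m) <- sprintf("c%02d", 1:30)
    self <- concordance(m, m)
    expect_equal(self$r, 1)
    expect_equal(self$r2, 1)
    perm <- m[sample(nrow(m)), ]
    rownames(perm) <- rownames(m)
    expect_lt(abs(concordance(m, perm)$r), 0.3)
    expect_error(concordance(m[1:2, ], m[1:2, ]), "3 shared genes")
})

test_that("concordance matches the closed-form Pearson on 3 genes", {
    a <- Matrix::Matrix(matrix(c(10, 20, 70,
                                 10, 20, 70), 3), sparse = TRUE)
    b <- Matrix::Matrix(matrix(c(20, 10, 70,
                                 20, 10, 70), 3), sparse = TRUE)
    rownames(a) <- rownames(b) <- c("g1", "g2", "g3")
    colnames(a) <- colnames(b) <- c("c1", "c2")
    got <- concordance(a, b)
    ma <- Matrix::rowMeans(logNormalize(a))
    mb <- Matrix::rowMeans(logNormalize(b))
    byHand <- sum((ma - mean(ma)) * (mb - mean(mb))) /
        sqrt(sum((ma - mean(ma))^2) * sum((mb - mean(mb))^2))
    expect_equal(got$r, byHand)
})

test_that("cluster-level concordance returns a correlation matrix", {
    set.seed(22)
    m <- Matrix::Matrix(matrix(rpois(100 * 40, 4), 100, 40),
                        sparse = TRUE)
    rownames(m) <- sprintf("g%03d", 1:100)
    colnames(m) <- sprintf("c%02d", 1:40)
    cl <- rep(c("k1", "k2"), each = 20)
    cc <- concordance(m, m, by = "cluster", clustersA = cl,
                      clustersB = cl)
    expect_equal(dim(cc), c(2L, 2L))
    expect_equal(unname(diag(cc)), c(1, 1))
})

test_that("proportion expressing uses a strict CPM threshold", {
    # 4-cell cluster, 3 cells above 1 CPM
    m <- Matrix::Matrix(matrix(0, 2, 4), sparse = TRUE)
    rownames(m) <- c("g1", "g2"); colnames(m) <- paste0("c", 1:4)
    m["g2", ] <- 1e6
    m["g1", 1:3] <- 100                  # well above 1 CPM
    pr <- proportionExpressing(m, rep("k1", 4))
    expect_equal(pr["g1", "k1"], 0.75)
    # all-zero gene scores 0 everywhere
    m2 <- m; m2["g1", ] <- 0
    expect_equal(proportionExpressing(m2, rep("k1", 4))["g1", "k1"], 0)
    # exactly at the threshold does not count (strict >)
    m3 <- Matrix::Matrix(matrix(c(1, 999999, 0, 1), 2), sparse = TRUE)
    rownames(m3) <- c("g1", "g2"); colnames(m3) <- c("c1", "c2")
    # g1 in c1: 1 count of 1e6 total = exactly 1 CPM
    expect_equal(proportionExpressing(m3, c("k", "k"),
                                      cpmThreshold = 1)["g1", "k"], 0)
})

test_that("marker score matches its closed forms", {
    # perfectly binary marker
    expect_equal(as.numeric(markerScore(c(k1 = 1, k2 = 0, k3 = 0, k4 = 0),
                                        "k1")), 1)
    # evenly distributed expression
    expect_equal(as.numeric(markerScore(c(k1 = 0.4, k2 = 0.4, k3 = 0.4),
                                        "k1")), 0)
    # no expression at all
    expect_equal(as.numeric(markerScore(c(k1 = 0, k2 = 0), "k1")), 0)
    # the worked three-cluster case
    s <- markerScore(c(m = 0.8, o1 = 0.2, o2 = 0.4), "m")
    expect_equal(as.numeric(s), 0.52)
    # invariant to permuting the non-marked clusters
    s2 <- markerScore(c(m = 0.8, o2 = 0.4, o1 = 0.2), "m")
    expect_equal(as.numeric(s), as.numeric(s2))
    # dominated marker: raw value escapes [0,1], result is clamped
    sBad <- markerScore(c(m = 0.1, o = 0.9), "m")
    expect_true(as.numeric(sBad) >= 0 && as.numeric(sBad) <= 1)
    expect_true(attr(sBad, "raw") < 0 || attr(sBad, "raw") > 1)
    expect_error(markerScore(c(a = 1, b = 0), "zz"), "unknown")
})

test_that("top markers are selected by fold change with name ties", {
    fc <- data.frame(cluster = "k1",
                     gene = sprintf("g%02d", 1:12),
                     avg_log2FC = c(rep(3, 2), rep(2, 9), 1))
    top <- topMarkersPerCluster(fc, n = 10)
    expect_equal(nrow(top), 10L)
    # rank-10 tie among the nine 2.0 genes resolves lexicographically
    tied <- sort(fc$gene[fc$avg_log2FC == 2])
    expect_equal(top$gene[3:10], tied[1:8])
    expect_warning(topMarkersPerCluster(fc[1:3, ], n = 10), "only")
    expect_equal(nrow(topMarkersPerCluster(fc, n = 0)), 0L)
})

test_that("a cell-type-restricted gene earns a high marker score", {
    # one gene expressed only in one cell type at high mean, >= 200
    # cells per cluster
    ct <- data.frame(name = c("kA", "kB", "kC"),
                     germ_layer = "ectoderm",
                     proportion = c(1 / 3, 1 / 3, 1 / 3))
    mu <- matrix(c(8, 0, 0,
                   4, 4, 4), 2, 3, byrow = TRUE)
    cfg <- simConfig(nCells = 900L, cellTypes = ct, nGenes = 2,
                     exprMean = mu, seed = 23)
    cells <- simulateCells(cfg)
    expect_true(all(table(cells$cellTable$cell_type) >= 200))
    pr <- proportionExpressing(cells$counts, cells$cellTable$cell_type)
    s <- markerScore(stats::setNames(pr[1, ], colnames(pr)), "kA")
    expect_gte(as.numeric(s), 0.9)
})
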