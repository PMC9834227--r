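#' @include AllClasses.R
NULL

#' Per-cell quality metrics
#'
#' Total UMIs, genes detected, and the percentage of counts assigned to
#' mitochondrial and ribosomal genes — the standard nucleus-quality
#' surface. Cells with zero total counts report undefined (NA)
#' percentages.
#'
#' @param counts genes x cells count matrix with gene names as rownames
#' @param mitoGenes explicit mitochondrial gene names, or NULL to use
#'   \code{mitoPattern}
#' @param riboGenes explicit ribosomal gene names, or NULL to use
#'   \code{riboPattern}
#' @param mitoPattern,riboPattern regex on gene names (defaults
#'   \code{"^MT-"} and \code{"^RP[SL]"})
#' @return data.frame: barcode, n_umis, n_genes_detected, pct_mito,
#'   pct_ribo
#' @export
qcMetrics <- function(counts, mitoGenes = NULL, riboGenes = NULL,
                      mitoPattern = "^MT-", riboPattern = "^RP[SL]") {
    if (ncol(counts) == 0L)
        return(data.frame(barcode = character(0), n_umis = integer(0),
                          n_genes_detected = integer(0),
                          pct_mito = numeric(0), pct_ribo = numeric(0)))
    genes <- rownames(counts)
    if (is.null(mitoGenes)) mitoGenes <- grep(mitoPattern, genes,
                                              value = TRUE)
    if (is.null(riboGenes)) riboGenes <- grep(riboPattern, genes,
                                              value = TRUE)
    tot <- Matrix::colSums(counts)
    nGenes <- Matrix::colSums(counts > 0)
    sumOf <- function(set) {
        if (!length(set)) return(rep(0, ncol(counts)))
        Matrix::colSums(counts[genes %in% set, , drop = FALSE])
    }
    pct <- function(x) ifelse(tot == 0, NA_real_, 100 * x / tot)
    data.frame(barcode = colnames(counts),
               n_umis = as.integer(tot),
               n_genes_detected = as.integer(nGenes),
               pct_mito = pct(sumOf(mitoGenes)),
               pct_ribo = pct(sumOf(riboGenes)),
               row.names = NULL,
               stringsAsFactors = FALSE)
}

#' Filter cells on mitochondrial percentage
#'
#' Cells with greater than \code{maxPctMito} percent mitochondrial counts
#' are removed; the boundary is kept (exactly 5\% is retained under the
#' default). Cells with undefined percentages (zero total counts) are
#' removed.
#'
#' @param qc output of [qcMetrics()]
#' @param maxPctMito threshold in percent (default 5)
#' @return character vector of retained barcodes
#' @export
filterCells <- function(qc, maxPctMito = 5) {
    keep <- !is.na(qc$pct_mito) & qc$pct_mito <= maxPctMito
    qc$barcode[keep]
}

#' Log-normalize counts
#'
#' \code{ln(1 + scaleFactor * count / cellTotal)}: counts are normalized
#' to per-cell depth, scaled (default 10,000) and natural-log
#' transformed. Zero-total cells are an error; filter first.
#'
#' @param counts genes x cells count matrix
#' @param scaleFactor scale applied after depth normalization (default
#'   1e4)
#' @return sparse matrix of log-normalized expression
#' @export
logNormalize <- function(counts, scaleFactor = 1e4) {
    tot <- Matrix::colSums(counts)
    if (any(tot == 0))
        stop("cells with zero total counts present; run filterCells() ",
             "(or drop empty cells) before normalizing")
    m <- methods::as(counts, "CsparseMatrix")
    norm <- m %*% Matrix::Diagonal(x = scaleFactor / tot)
    out <- log1p(norm)
    dimnames(out) <- dimnames(counts)
    out
}

#' Mean log-normalized expression per gene
#'
#' The per-gene mean over cells of [logNormalize()] output; the
#' expression covariate used when stratifying variant detection by
#' expression level.
#'
#' @inheritParams logNormalize
#' @return named numeric vector over genes
#' @export
meanLogNormExpr <- function(counts, scaleFactor = 1e4) {
    ln <- logNormalize(counts, scaleFactor)
    stats::setNames(Matrix::rowMeans(ln), rownames(counts))
}

#' Cross-dataset expression concordance
#'
#' With \code{by = "gene"}: mean log-normalized expression per gene is
#' correlated between the two datasets over their shared gene universe
#' (the intersection, reported); Pearson r and r^2 are returned both over
#' all shared genes and over genes expressed in at least one dataset.
#' With \code{by = "cluster"}: per-cluster gene means are computed in
#' each dataset and the full cluster-by-cluster Pearson correlation
#' matrix is returned.
#'
#' @param countsA,countsB genes x cells count matrices (raw counts; both
#'   are log-normalized internally)
#' @param by \code{"gene"} or \code{"cluster"}
#' @param clustersA,clustersB cluster label vectors (one per cell),
#'   required for \code{by = "cluster"}
#' @return for \code{"gene"}: list(n_shared, r, r2, r_expressed,
#'   r2_expressed, table); for \code{"cluster"}: a correlation matrix
#'   (clusters of A x clusters of B)
#' @export
concordance <- function(countsA, countsB, by = c("gene", "cluster"),
                        clustersA = NULL, clustersB = NULL) {
    by <- match.arg(by)
    shared <- intersect(rownames(countsA), rownames(countsB))
    if (length(shared) < 3L)
        stop("fewer than 3 shared genes between the datasets")
    a <- countsA[shared, , drop = FALSE]
    b <- countsB[shared, , drop = FALSE]
    if (by == "gene") {
        ma <- meanLogNormExpr(a)
        mb <- meanLogNormExpr(b)
        r <- stats::cor(ma, mb)
        expressed <- ma > 0 | mb > 0
        rE <- if (sum(expressed) >= 3L)
            stats::cor(ma[expressed], mb[expressed]) else NA_real_
        list(n_shared = length(shared), r = r, r2 = r^2,
             r_expressed = rE, r2_expressed = rE^2,
             table = data.frame(gene = shared, mean_a = unname(ma),
                                mean_b = unname(mb)))
    } else {
        stopifnot(!is.null(clustersA), !is.null(clustersB))
        lnA <- logNormalize(a); lnB <- logNormalize(b)
        clMeans <- function(ln, cl) {
            sapply(sort(unique(cl)), function(k)
                Matrix::rowMeans(ln[, cl == k, drop = FALSE]))
        }
        stats::cor(clMeans(lnA, clustersA), clMeans(lnB, clustersB))
    }
}

#' Proportion of cells expressing each gene per cluster
#'
#' The fraction of cells in each cluster with expression strictly greater
#' than \code{cpmThreshold} counts per million (a cell exactly at the
#' threshold does not count). Empty clusters give NA.
#'
#' @param counts genes x cells count matrix
#' @param clusters cluster label per cell
#' @param cpmThreshold CPM cutoff (default 1)
#' @return genes x clusters matrix of proportions
#' @export
proportionExpressing <- function(counts, clusters, cpmThreshold = 1) {
    stopifnot(length(clusters) == ncol(counts))
    tot <- Matrix::colSums(counts)
    cpm <- methods::as(counts, "CsparseMatrix") %*%
        Matrix::Diagonal(x = ifelse(tot == 0, 0, 1e6 / tot))
    expressed <- cpm > cpmThreshold
    levs <- sort(unique(clusters))
    out <- sapply(levs, function(k) {
        idx <- clusters == k
        if (!any(idx)) return(rep(NA_real_, nrow(counts)))
        Matrix::rowMeans(expressed[, idx, drop = FALSE])
    })
    rownames(out) <- rownames(counts)
    out
}

#' Marker efficacy score
#'
#' For a gene and its marked cluster k, with p_i the proportion of cells
#' in cluster i expressing the gene (> 1 CPM), the score is
#' sum_j (p_k - p_j)^2 / sum_j (p_k - p_j) over the other clusters j.
#' A zero difference sum (evenly distributed or absent expression) scores
#' 0; 1 is perfectly binary expression in the marked cluster. The raw
#' value can leave [0, 1] when a non-marked cluster expresses the gene
#' more than the marked one; it is clamped, with the raw value kept in
#' the \code{"raw"} attribute.
#'
#' @param p named proportions per cluster (one gene)
#' @param markedCluster the cluster the gene is supposed to mark
#' @return score in [0, 1] with attribute \code{raw}
#' @export
markerScore <- function(p, markedCluster) {
    if (!markedCluster %in% names(p))
        stop("unknown marked cluster: ", markedCluster)
    if (length(p) < 2L) stop("need at least 2 clusters")
    d <- p[[markedCluster]] - p[names(p) != markedCluster]
    s <- sum(d)
    raw <- if (s == 0) 0 else sum(d^2) / s
    out <- min(max(raw, 0), 1)
    attr(out, "raw") <- raw
    out
}

#' Marker scores for a table of (gene, marked cluster) pairs
#'
#' @param prop genes x clusters proportion matrix from
#'   [proportionExpressing()]
#' @param markers data.frame with columns \code{gene} and \code{cluster}
#' @return data.frame gene, cluster, score, raw
#' @export
markerScores <- function(prop, markers) {
    do.call(rbind, lapply(seq_len(nrow(markers)), function(i) {
        g <- markers$gene[i]
        s <- markerScore(stats::setNames(prop[g, ], colnames(prop)),
                         markers$cluster[i])
        data.frame(gene = g, cluster = markers$cluster[i],
                   score = as.numeric(s), raw = attr(s, "raw"),
                   stringsAsFactors = FALSE)
    }))
}

#' Top marker genes per cluster from a differential table
#'
#' Selects the top n genes per cluster by average log2 fold change, ties
#' broken by gene name; the differential test itself is an input, not
#' computed here. Clusters with fewer than n genes return all of them
#' with a warning.
#'
#' @param fcTable data.frame with columns \code{cluster}, \code{gene},
#'   \code{avg_log2FC}
#' @param n markers per cluster (default 10)
#' @return data.frame subset of \code{fcTable}, ordered within cluster
#' @export
topMarkersPerCluster <- function(fcTable, n = 10L) {
    stopifnot(all(c("cluster", "gene", "avg_log2FC") %in% names(fcTable)))
    if (n == 0L) return(fcTable[0, ])
    out <- do.call(rbind, lapply(split(fcTable, fcTable$cluster),
        function(d) {
            d <- d[order(-d$avg_log2FC, d$gene), ]
            if (nrow(d) < n)
                warning("cluster ", d$cluster[1], " has only ", nrow(d),
                        " genes (< ", n, ")")
            utils::head(d, n)
        }))
    rownames(out) <- NULL
    out
}
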