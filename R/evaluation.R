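#' @include AllClasses.R genotyper.R mispriming.R
NULL

#' Per-variant detection fraction
#'
#' A cell detects a variant position when it has at least one UMI covering
#' it (\code{refUmis + altUmis >= 1}); the detection fraction is the
#' proportion of all cells in the matrix with coverage. Computed per
#' dataset (per patient, per kit): combine datasets upstream only
#' deliberately.
#'
#' @param gm a [GenotypeMatrices-class]
#' @return named numeric vector, one fraction per variant
#' @export
detectionFraction <- function(gm) {
    if (ncol(gm) == 0L) stop("genotype matrix has zero cells")
    cov <- (as.matrix(refUmis(gm)) + as.matrix(altUmis(gm))) >= 1
    rowMeans(cov)
}

#' Assemble per-variant detection records
#'
#' Joins the detection fraction to the kit-matched transcript-end distance,
#' the mispriming-aware effective distance, and the mean log-normalized
#' expression of the variant's gene.
#'
#' @param gm a [GenotypeMatrices-class]
#' @param distances output of [variantDistances()] for the same variants
#' @param kit \code{"3p"} or \code{"5p"}; selects \code{dist_3p} or
#'   \code{dist_5p} as the kit-relevant distance
#' @param exprMeans optional named vector of mean log-normalized expression
#'   per gene (see [meanLogNormExpr()])
#' @param sites optional data.frame of internal poly-A sites with a
#'   \code{transcript_id} column (see [misprimingSites()])
#' @param readLength read length for site usability (default 91 for 3p,
#'   90 for 5p)
#' @return data.frame, one row per variant: variant_id, kit, n_cells,
#'   n_covered, detection_fraction, dist_relevant, effective_distance,
#'   mean_lognorm_expr
#' @export
detectionRecords <- function(gm, distances, kit = c("3p", "5p"),
                             exprMeans = NULL, sites = NULL,
                             readLength = NULL) {
    kit <- match.arg(kit)
    if (is.null(readLength)) readLength <- if (kit == "3p") 91L else 90L
    kitEnd <- if (kit == "3p") "three_prime" else "five_prime"
    v <- variantSites(gm)
    frac <- detectionFraction(gm)
    nCells <- ncol(gm)
    distRel <- if (kit == "3p") distances$dist_3p else distances$dist_5p
    eff <- distRel
    if (!is.null(sites)) {
        for (i in seq_along(v)) {
            if (is.na(distances$tx_coord[i])) next
            si <- sites[sites$transcript_id == distances$transcript_id[i], ,
                        drop = FALSE]
            eff[i] <- nearestCaptureSite(
                distances[i, ], si, kitEnd, readLength)$effective_distance
        }
    }
    expr <- if (is.null(exprMeans)) NA_real_
            else unname(exprMeans[as.character(v$gene_id)])
    data.frame(
        variant_id = variantIds(v),
        gene_id = as.character(v$gene_id),
        role = as.character(v$role),
        kit = kit,
        n_cells = nCells,
        n_covered = as.integer(round(frac * nCells)),
        detection_fraction = unname(frac),
        dist_relevant = distRel,
        effective_distance = eff,
        mean_lognorm_expr = expr,
        stringsAsFactors = FALSE)
}

#' Detection summarized by distance from the kit-relevant transcript end
#'
#' For each stratum (within \code{near} bp of the end, within \code{far}
#' bp, beyond \code{far}), the fraction of variant positions detected in
#' at least \code{detectThreshold} of cells. Distance strata are
#' cumulative for the two inner strata (within 100 bp is a subset of
#' within 1,000 bp), matching how detection-by-distance is conventionally
#' reported. Empty strata give NA, not 0.
#'
#' @param records output of [detectionRecords()]
#' @param near,far stratum bounds in nt (defaults 100 and 1,000)
#' @param detectThreshold detection fraction that counts as "identified"
#'   (default 0.05)
#' @param useEffective stratify on \code{effective_distance} instead of
#'   the annotated \code{dist_relevant}
#' @return data.frame: stratum, n_variants, n_detected, fraction_detected
#' @export
stratifyByDistance <- function(records, near = 100L, far = 1000L,
                               detectThreshold = 0.05,
                               useEffective = FALSE) {
    d <- if (useEffective) records$effective_distance
         else records$dist_relevant
    det <- records$detection_fraction >= detectThreshold
    strata <- list(
        c(sprintf("within_%d", near), NA),
        c(sprintf("within_%d", far), NA),
        c(sprintf("beyond_%d", far), NA))
    sel <- list(d <= near, d <= far, d > far)
    out <- do.call(rbind, lapply(seq_along(sel), function(i) {
        s <- sel[[i]]
        n <- sum(s)
        data.frame(stratum = strata[[i]][1],
                   n_variants = n,
                   n_detected = sum(det & s),
                   fraction_detected = if (n == 0L) NA_real_
                                       else sum(det & s) / n)
    }))
    out
}

#' Detection summarized by gene expression level
#'
#' For each expression threshold, the fraction of variant positions in
#' genes with mean log-normalized expression above the threshold that are
#' detected in at least \code{detectThreshold} of cells. Thresholds form
#' overlapping "greater than" strata (e.g. > 0.1 and > 5).
#'
#' @param records output of [detectionRecords()] with
#'   \code{mean_lognorm_expr} populated
#' @param exprThresholds numeric vector of lower bounds (default
#'   \code{c(0.1, 5)})
#' @param detectThreshold detection fraction counting as detected
#' @return data.frame: expr_threshold, n_variants, n_detected,
#'   fraction_detected
#' @export
stratifyByExpression <- function(records, exprThresholds = c(0.1, 5),
                                 detectThreshold = 0.05) {
    det <- records$detection_fraction >= detectThreshold
    e <- records$mean_lognorm_expr
    out <- do.call(rbind, lapply(exprThresholds, function(t) {
        s <- !is.na(e) & e > t
        n <- sum(s)
        data.frame(expr_threshold = t,
                   n_variants = n,
                   n_detected = sum(det & s),
                   fraction_detected = if (n == 0L) NA_real_
                                       else sum(det & s) / n)
    }))
    out
}

#' False-positive rate on null variants
#'
#' Null-set variants are positions genuinely absent from the assayed
#' sample (e.g. another patient's private variants, absent from
#' population databases), so any ALT call is a false positive. The
#' primary rate is per-variant (variants with at least one ALT cell /
#' null variants); the per-cell-call count is also reported, and each
#' offending variant is flagged when its alt evidence is a single
#' nucleus.
#'
#' @param gm a [GenotypeMatrices-class]; only variants with
#'   \code{role == "null_set"} are used
#' @return list: n_null_variants, n_variants_with_alt, per_variant_fpr,
#'   n_cell_alt_calls, offenders (data.frame variant_id, n_alt_cells,
#'   single_nucleus)
#' @export
falsePositiveRate <- function(gm) {
    keep <- variantSites(gm)$role == "null_set"
    if (!any(keep))
        stop("no null_set variants in the genotype matrix")
    calls <- genotypeCalls(gm)[keep, , drop = FALSE]
    nAltCells <- rowSums(calls == "ALT")
    hasAlt <- nAltCells > 0
    offenders <- data.frame(
        variant_id = rownames(calls)[hasAlt],
        n_alt_cells = as.integer(nAltCells[hasAlt]),
        single_nucleus = nAltCells[hasAlt] == 1L,
        row.names = NULL)
    list(n_null_variants = sum(keep),
         n_variants_with_alt = sum(hasAlt),
         per_variant_fpr = sum(hasAlt) / sum(keep),
         n_cell_alt_calls = as.integer(sum(nAltCells)),
         offenders = offenders)
}

#' Per-cluster variant allele fraction
#'
#' VAF is computed over genotyped cells only
#' (\code{n_alt / (n_alt + n_ref)}; NO_CALL excluded from the
#' denominator); the fraction of all cells that are ALT
#' (\code{vaf_of_all}) is also reported for comparison with bulk VAF.
#' Clusters with zero genotyped cells report an undefined (NA) VAF.
#'
#' @param annotated long-form output of [annotateCalls()] with a
#'   \code{cluster} column
#' @param variantId restrict to one variant (default: all, one block per
#'   variant)
#' @return data.frame: variant_id, cluster, n_alt, n_ref, n_nocall, vaf,
#'   vaf_of_all; the overall (all clusters pooled) row has
#'   cluster == "ALL"
#' @export
perClusterVaf <- function(annotated, variantId = NULL) {
    stopifnot("cluster" %in% names(annotated))
    if (!is.null(variantId))
        annotated <- annotated[annotated$variant_id %in% variantId, ]
    if (!nrow(annotated)) stop("no rows to summarize")
    one <- function(df, cl) {
        nAlt <- sum(df$call == "ALT")
        nRef <- sum(df$call == "REF")
        nNo <- sum(df$call == "NO_CALL")
        data.frame(variant_id = df$variant_id[1], cluster = cl,
                   n_alt = nAlt, n_ref = nRef, n_nocall = nNo,
                   vaf = if (nAlt + nRef == 0L) NA_real_
                         else nAlt / (nAlt + nRef),
                   vaf_of_all = nAlt / nrow(df),
                   stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, lapply(split(annotated, annotated$variant_id),
        function(v) {
            rows <- lapply(split(v, v$cluster), function(d)
                one(d, d$cluster[1]))
            rbind(do.call(rbind, rows), one(v, "ALL"))
        }))
    rownames(out) <- NULL
    out
}

#' Fraction of cells genotyped per kit
#'
#' The fraction of cells with a call other than NO_CALL, per kit and per
#' variant — the cross-chemistry comparison for a variant near one
#' transcript end.
#'
#' @param gmList named list of [GenotypeMatrices-class], one per kit
#'   (names e.g. \code{"3p"}, \code{"5p"})
#' @return data.frame: kit, variant_id, n_cells, n_genotyped, fraction
#' @export
kitGenotypedFraction <- function(gmList) {
    stopifnot(length(names(gmList)) == length(gmList))
    out <- do.call(rbind, lapply(names(gmList), function(kit) {
        gm <- gmList[[kit]]
        calls <- genotypeCalls(gm)
        data.frame(kit = kit,
                   variant_id = rownames(calls),
                   n_cells = ncol(calls),
                   n_genotyped = rowSums(calls != "NO_CALL"),
                   fraction = rowMeans(calls != "NO_CALL"),
                   row.names = NULL,
                   stringsAsFactors = FALSE)
    }))
    out
}
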