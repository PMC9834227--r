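#' @include AllClasses.R
NULL

#' Default germ-layer map for cortical cell types
#'
#' Microglia and lymphocytes are mesoderm-derived; neurons, interneurons,
#' astrocytes, oligodendrocytes and OPCs are ectoderm-derived (neural
#' lineage); the mitochondrial cluster is a technical cluster mapped to
#' unknown.
#'
#' @return named character vector cell type -> germ layer
#' @export
defaultGermLayerMap <- function() {
    c("Microglia" = "mesoderm",
      "Lymphocytes" = "mesoderm",
      "Excitatory Neurons" = "ectoderm",
      "MGE-Derived Interneurons" = "ectoderm",
      "CGE-Derived Interneurons" = "ectoderm",
      "Astrocytes" = "ectoderm",
      "Oligodendrocytes" = "ectoderm",
      "OPCs" = "ectoderm",
      "Mitochondrial" = "unknown")
}

#' Classify the developmental origin of a somatic variant
#'
#' A germ layer carries the variant when the ALT cells summed over its
#' cell types reach \code{minAltCellsPerLayer} (a guard against
#' single-nucleus false positives; this minimum-evidence threshold is a
#' package parameter, not a rule from any reference analysis). Variants
#' with ALT evidence in two or more distinct layers must predate
#' gastrulation; exactly one layer is lineage-restricted; none is
#' insufficient evidence. Clusters mapped to \code{"unknown"} (or absent
#' from the map) are excluded and reported.
#'
#' @param vafTable per-cluster table from [perClusterVaf()] (columns
#'   \code{cluster}, \code{n_alt}; the \code{"ALL"} row is ignored)
#' @param germMap named character vector cell type -> germ layer (default
#'   [defaultGermLayerMap()])
#' @param minAltCellsPerLayer ALT cells required per layer (default 2)
#' @return list: classification (\code{"pre_gastrulation"},
#'   \code{"lineage_restricted"} or \code{"insufficient_evidence"}),
#'   layers_with_alt, n_alt_per_layer, excluded_clusters
#' @export
classifyOrigin <- function(vafTable, germMap = defaultGermLayerMap(),
                           minAltCellsPerLayer = 2L) {
    vafTable <- vafTable[vafTable$cluster != "ALL", , drop = FALSE]
    if (!nrow(vafTable)) stop("empty per-cluster VAF table")
    layer <- unname(germMap[vafTable$cluster])
    excluded <- vafTable$cluster[is.na(layer) | layer == "unknown"]
    keep <- !is.na(layer) & layer != "unknown"
    nAlt <- tapply(vafTable$n_alt[keep], layer[keep], sum)
    nAlt <- nAlt[!is.na(nAlt)]
    withAlt <- names(nAlt)[nAlt >= minAltCellsPerLayer]
    classification <- if (length(withAlt) >= 2L) "pre_gastrulation"
        else if (length(withAlt) == 1L) "lineage_restricted"
        else "insufficient_evidence"
    list(classification = classification,
         layers_with_alt = withAlt,
         n_alt_per_layer = as.list(nAlt),
         excluded_clusters = as.character(excluded))
}
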