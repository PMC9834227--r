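#' @include AllClasses.R simulate.R genotyper.R annotation.R mispriming.R
#' @include evaluation.R expression_qc.R lineage.R
NULL

.runConfigSchema <- function() {
    list(
        top = c("seed", "outdir", "simulate", "genotype", "mispriming",
                "evaluate", "lineage", "stages"),
        simulate = c("n_cells", "cell_types", "n_genes",
                     "transcript_length_range", "n_exons_range",
                     "kit_end", "read_length", "capture_decay",
                     "mispriming_rate", "error_rate", "mosaic_fraction",
                     "mosaic_cell_types", "umi_dup_rate", "expr_mean",
                     "expr_dispersion", "a_run_genes", "a_run_length",
                     "a_run_tx_coord", "variants"),
        genotype = c("min_mapq", "min_baseq", "umi_consensus",
                     "call_policy"),
        mispriming = c("min_run", "window", "min_frac"),
        evaluate = c("detect_threshold", "near", "far",
                     "expr_thresholds"),
        lineage = c("min_alt_cells_per_layer")
    )
}

.checkKeys <- function(given, allowed, where) {
    bad <- setdiff(names(given), allowed)
    if (length(bad))
        stop("unknown configuration key(s) in ", where, ": ",
             paste(bad, collapse = ", "))
}

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or accepts an equivalent named list), rejects
#' unknown keys naming them, checks parameter ranges, fills defaults,
#' and resolves \code{outdir} to an absolute path. \code{outdir} is the
#' single required key.
#'
#' @param config path to a YAML file, or a named list
#' @return a validated config list of class \code{RunConfig}
#' @seealso [runAll()], [writeRunConfig()]
#' @export
validateRunConfig <- function(config) {
    if (is.character(config)) {
        if (!file.exists(config))
            stop("config file not found: ", config)
        config <- yaml::read_yaml(config)
        if (is.null(config)) config <- list()
    }
    sch <- .runConfigSchema()
    .checkKeys(config, sch$top, "top level")
    for (sec in c("simulate", "genotype", "mispriming", "evaluate",
                  "lineage"))
        if (!is.null(config[[sec]]))
            .checkKeys(config[[sec]], sch[[sec]], sec)

    if (is.null(config$outdir))
        stop("required key missing: outdir")
    config$outdir <- normalizePath(config$outdir, mustWork = FALSE)
    if (is.null(config$seed)) config$seed <- 1L
    config$seed <- as.integer(config$seed)

    def <- function(sec, key, val) {
        if (is.null(config[[sec]][[key]])) config[[sec]][[key]] <<- val
    }
    def("simulate", "n_cells", 300L)
    def("simulate", "n_genes", 8L)
    def("simulate", "kit_end", "three_prime")
    def("simulate", "capture_decay", 0)
    def("simulate", "mispriming_rate", 0)
    def("simulate", "error_rate", 0.001)
    def("simulate", "mosaic_fraction", 0.05)
    def("simulate", "umi_dup_rate", 0.3)
    def("simulate", "expr_dispersion", 2)
    def("genotype", "min_mapq", 30L)
    def("genotype", "min_baseq", 20L)
    def("genotype", "umi_consensus", "majority")
    def("genotype", "call_policy", "alt_dominant")
    def("mispriming", "min_run", 6L)
    def("mispriming", "window", 10L)
    def("mispriming", "min_frac", 0.8)
    def("evaluate", "detect_threshold", 0.05)
    def("evaluate", "near", 100L)
    def("evaluate", "far", 1000L)
    if (is.null(config$evaluate$expr_thresholds))
        config$evaluate$expr_thresholds <- c(0.1, 5)
    def("lineage", "min_alt_cells_per_layer", 2L)
    if (is.null(config$stages))
        config$stages <- c("simulate", "genotype", "annotate",
                           "mispriming", "evaluate", "lineage")

    for (key in c("mispriming_rate", "error_rate", "mosaic_fraction")) {
        v <- config$simulate[[key]]
        if (v < 0 || v > 1)
            stop("parameter out of range [0, 1]: simulate/", key)
    }
    if (config$mispriming$min_frac < 0 || config$mispriming$min_frac > 1)
        stop("parameter out of range [0, 1]: mispriming/min_frac")
    structure(config, class = "RunConfig")
}

#' Write a run configuration back to YAML
#'
#' Validated configs round-trip: \code{validateRunConfig(writeRunConfig(x,
#' f))} reproduces \code{x}.
#'
#' @param config a validated config (see [validateRunConfig()])
#' @param path output YAML path
#' @return \code{path}, invisibly
#' @export
writeRunConfig <- function(config, path) {
    yaml::write_yaml(unclass(config), path)
    invisible(path)
}

## SimConfig from the simulate: section of a run config. Internal.
.simConfigFromRun <- function(sim, seed) {
    args <- list(seed = seed)
    pick <- function(yamlKey, argName, cast = identity) {
        if (!is.null(sim[[yamlKey]])) args[[argName]] <<- cast(sim[[yamlKey]])
    }
    pick("n_cells", "nCells", as.integer)
    pick("n_genes", "nGenes", as.integer)
    pick("transcript_length_range", "transcriptLengthRange", as.integer)
    pick("n_exons_range", "nExonsRange", as.integer)
    pick("kit_end", "kitEnd")
    pick("read_length", "readLength", as.integer)
    pick("capture_decay", "captureDecay", as.numeric)
    pick("mispriming_rate", "misprimingRate", as.numeric)
    pick("error_rate", "errorRate", as.numeric)
    pick("mosaic_fraction", "mosaicFraction", as.numeric)
    pick("mosaic_cell_types", "mosaicCellTypes", as.character)
    pick("umi_dup_rate", "umiDupRate", as.numeric)
    pick("expr_mean", "exprMean", as.numeric)
    pick("expr_dispersion", "exprDispersion", as.numeric)
    pick("a_run_genes", "aRunGenes", as.integer)
    pick("a_run_length", "aRunLength", as.integer)
    pick("a_run_tx_coord", "aRunTxCoord", as.integer)
    if (!is.null(sim$cell_types))
        args$cellTypes <- as.data.frame(do.call(rbind, lapply(
            sim$cell_types, as.data.frame)))
    do.call(simConfig, args)
}

#' Run the full pipeline
#'
#' Chains simulate -> genotype -> annotate -> mispriming -> evaluate ->
#' lineage under one seed, writing every stage's outputs under
#' \code{outdir} and a machine-readable JSON manifest (stage, parameters,
#' outputs with MD5 checksums, timings). A failing stage halts the run
#' with the stage named. Rerunning with the same seed reproduces the
#' checksums of all deterministic outputs.
#'
#' @param config a validated config from [validateRunConfig()] (or a path
#'   / list accepted by it)
#' @return the manifest, invisibly (also written to
#'   \code{outdir/manifest.json})
#' @export
runAll <- function(config) {
    if (!inherits(config, "RunConfig")) config <- validateRunConfig(config)
    outdir <- config$outdir
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    manifest <- list(package = "dropGeno",
                     version = as.character(utils::packageVersion("dropGeno")),
                     seed = config$seed,
                     stages = list())
    state <- new.env(parent = emptyenv())

    addStage <- function(name, params, fun) {
        if (!name %in% config$stages) return(invisible(NULL))
        t0 <- Sys.time()
        outputs <- tryCatch(fun(), error = function(e)
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))
        files <- sort(unlist(lapply(outputs, function(p) {
            if (dir.exists(p)) list.files(p, recursive = TRUE,
                                          full.names = TRUE) else p
        })))
        rel <- sub(paste0("^", gsub("([][{}()+*^$.|\\\\?])", "\\\\\\1",
                                    outdir), "/?"), "", files)
        sums <- unname(tools::md5sum(files))
        manifest$stages[[length(manifest$stages) + 1L]] <<- list(
            stage = name,
            params = params,
            outputs = lapply(seq_along(files), function(i)
                list(path = rel[i], md5 = sums[i])),
            elapsed_s = round(as.numeric(difftime(Sys.time(), t0,
                                                  units = "secs")), 3))
        invisible(NULL)
    }

    addStage("simulate", config$simulate, function() {
        sc <- .simConfigFromRun(config$simulate, config$seed)
        vs <- if (!is.null(config$simulate$variants))
            as.data.frame(do.call(rbind, lapply(config$simulate$variants,
                                                as.data.frame)))
        else NULL
        state$sim <- simulateDataset(sc, vs, file.path(outdir, "sim"))
        state$simConfig <- sc
        file.path(outdir, "sim")
    })

    addStage("genotype", config$genotype, function() {
        sim <- state$sim
        params <- countingParams(
            minMapq = config$genotype$min_mapq,
            minBaseq = config$genotype$min_baseq,
            barcodes = sim$cellTable$barcode,
            umiConsensus = config$genotype$umi_consensus,
            callPolicy = config$genotype$call_policy)
        state$gm <- countAlleles(sim$paths$bam,
                                 readVariantSites(sim$paths$vcf), params)
        d <- file.path(outdir, "genotype")
        writeGenotypeMatrices(state$gm, d)
        d
    })

    addStage("annotate", list(), function() {
        sim <- state$sim
        ts <- loadAnnotation(sim$paths$gtf)
        state$ts <- ts
        state$distances <- variantDistances(variantSites(state$gm), ts)
        d <- file.path(outdir, "annotate")
        dir.create(d, showWarnings = FALSE)
        utils::write.table(as.data.frame(state$distances),
                           file.path(d, "distances.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        d
    })

    addStage("mispriming", config$mispriming, function() {
        sim <- state$sim
        genome <- Biostrings::readDNAStringSet(sim$paths$genome)
        names(genome) <- sub(" .*", "", names(genome))
        state$sites <- misprimingSites(
            genome, state$ts,
            minRun = config$mispriming$min_run,
            window = config$mispriming$window,
            minFrac = config$mispriming$min_frac)
        kitEnd <- state$simConfig@kitEnd
        eff <- vapply(seq_len(nrow(state$distances)), function(i) {
            si <- state$sites[state$sites$transcript_id ==
                                  state$distances$transcript_id[i], ,
                              drop = FALSE]
            nearestCaptureSite(state$distances[i, ], si, kitEnd,
                               state$simConfig@readLength
                               )$effective_distance
        }, integer(1))
        d <- file.path(outdir, "mispriming")
        dir.create(d, showWarnings = FALSE)
        utils::write.table(state$sites, file.path(d, "sites.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(
            data.frame(variant_id = state$distances$variant_id,
                       effective_distance = eff),
            file.path(d, "effective_distances.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
        state$effective <- eff
        d
    })

    addStage("evaluate", config$evaluate, function() {
        sim <- state$sim
        kit <- if (state$simConfig@kitEnd == "three_prime") "3p" else "5p"
        exprMeans <- meanLogNormExpr(
            sim$counts[, Matrix::colSums(sim$counts) > 0, drop = FALSE])
        rec <- detectionRecords(state$gm, state$distances, kit,
                                exprMeans = exprMeans,
                                sites = state$sites,
                                readLength = state$simConfig@readLength)
        ds <- stratifyByDistance(rec, config$evaluate$near,
                                 config$evaluate$far,
                                 config$evaluate$detect_threshold)
        es <- stratifyByExpression(rec, config$evaluate$expr_thresholds,
                                   config$evaluate$detect_threshold)
        meta <- data.frame(barcode = sim$cellTable$barcode,
                           cluster = sim$cellTable$cell_type)
        ann <- annotateCalls(state$gm, meta, kit)
        vaf <- perClusterVaf(ann)
        kf <- kitGenotypedFraction(stats::setNames(list(state$gm), kit))
        d <- file.path(outdir, "evaluate")
        dir.create(d, showWarnings = FALSE)
        wt <- function(df, f) utils::write.table(
            df, file.path(d, f), sep = "\t", quote = FALSE,
            row.names = FALSE)
        wt(rec, "detection_records.tsv")
        wt(ds, "distance_strata.tsv")
        wt(es, "expression_strata.tsv")
        wt(vaf, "cluster_vaf.tsv")
        wt(kf, "kit_genotyped.tsv")
        if (any(variantSites(state$gm)$role == "null_set")) {
            fpr <- falsePositiveRate(state$gm)
            jsonlite::write_json(fpr[c("n_null_variants",
                                       "n_variants_with_alt",
                                       "per_variant_fpr",
                                       "n_cell_alt_calls")],
                                 file.path(d, "fpr.json"),
                                 auto_unbox = TRUE, digits = NA)
        }
        state$vaf <- vaf
        d
    })

    addStage("lineage", config$lineage, function() {
        d <- file.path(outdir, "lineage")
        dir.create(d, showWarnings = FALSE)
        rows <- lapply(split(state$vaf, state$vaf$variant_id),
            function(v) {
                lc <- classifyOrigin(
                    v, minAltCellsPerLayer =
                        config$lineage$min_alt_cells_per_layer)
                data.frame(variant_id = v$variant_id[1],
                           classification = lc$classification,
                           layers_with_alt = paste(lc$layers_with_alt,
                                                   collapse = ","),
                           excluded_clusters =
                               paste(lc$excluded_clusters,
                                     collapse = ","))
            })
        utils::write.table(do.call(rbind, rows),
                           file.path(d, "classification.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        d
    })

    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(manifest)
}
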