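#' @include io.R
NULL

.PIPELINE_STAGES <- c("simulate", "cellrates", "partition", "scale",
                      "bulkrate", "detect")

.log <- function(level, logLevel, fmt, ...) {
    if (logLevel == "quiet") return(invisible())
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in canonical order — \code{simulate} (forward
#' simulation of symbioses and their nanoSIMS measurements),
#' \code{cellrates} (single-cell biomass, fixation and growth),
#' \code{partition} (host-symbiont N and C mass balance), \code{scale}
#' (census abundances and volumetric rates), \code{bulkrate} (bulk endpoint
#' rates) and \code{detect} (genome presence calls and qPCR transform) —
#' writing one TSV per stage plus a JSON run manifest into \code{outDir}.
#' Identical configuration and seed give byte-identical outputs.
#'
#' Configuration sections (all optional; see \code{\link{readPipelineConfig}}):
#' \code{[labeling]}, \code{[biomass]}, \code{[sim]} for the simulator;
#' \code{[cellrates] roi_file} to analyse a measured ROI table instead of a
#' simulated one; \code{[census] file} (TSV: taxon, count, volume_l) and
#' \code{[scale] bulk_rate_nmol_l_d} for scaling; \code{[bulk] file} (TSV:
#' station, element, replicate_id, a_pn_t0, a_pn_t, pn_conc_umol_l, t_days);
#' \code{[coverage] file} (TSV: sample_id, genome_id, mean_coverage,
#' observed_breadth), \code{[detect] theta} and \code{[qpcr] file} (TSV:
#' sample_id, lat, lon, nifh_copies).
#'
#' @param outDir output directory (created if missing).
#' @param stages character vector of stage names, any subset of the canonical
#'   six; executed in canonical order.
#' @param config a configuration list, as returned by
#'   \code{\link{readPipelineConfig}}.
#' @param configPath alternatively, path to a configuration file.
#' @param seed integer seed overriding the configured simulator seed.
#' @param logLevel \code{"info"} or \code{"quiet"}.
#' @return the run manifest, invisibly (also written to
#'   \code{manifest.json}).
#' @examples
#' out <- file.path(tempdir(), "run1")
#' runPipeline(out, stages = c("simulate", "cellrates", "partition"),
#'             config = list(sim = list(fixed_geometry = TRUE)),
#'             seed = 1, logLevel = "quiet")
#' @export
runPipeline <- function(outDir,
                        stages = c("simulate", "cellrates", "partition"),
                        config = list(), configPath = NULL, seed = NULL,
                        logLevel = c("info", "quiet")) {
    logLevel <- match.arg(logLevel)
    if (!is.null(configPath))
        config <- readPipelineConfig(configPath)
    bad <- setdiff(stages, .PIPELINE_STAGES)
    if (length(bad))
        .validationError("unknown stage(s): %s (known: %s)",
                         paste(bad, collapse = ", "),
                         paste(.PIPELINE_STAGES, collapse = ", "))
    stages <- .PIPELINE_STAGES[.PIPELINE_STAGES %in% stages]
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

    labeling <- .labelingFromConfig(config)
    biomass <- .biomassFromConfig(config)
    outputs <- character()
    inputs <- character()
    experiment <- NULL
    partition <- NULL

    for (stage in stages) {
        .log("info", logLevel, "stage %s", stage)
        if (stage == "simulate") {
            simCfg <- .simFromConfig(config, seed = seed)
            sim <- simulateSymbioses(simCfg)
            experiment <- sim$experiment
            outputs <- c(outputs,
                         writeRoiTable(experiment, file.path(outDir, "rois.tsv")),
                         .writeTsv(sim$truthCells,
                                   file.path(outDir, "truth_cells.tsv")),
                         .writeTsv(sim$truthSymbioses,
                                   file.path(outDir, "truth_symbioses.tsv")))
        } else if (stage == "cellrates") {
            if (!is.null(config$cellrates$roi_file)) {
                inputs <- c(inputs, config$cellrates$roi_file)
                experiment <- readRoiTable(config$cellrates$roi_file,
                                           labeling, biomass)
            } else if (is.null(experiment)) {
                roiPath <- file.path(outDir, "rois.tsv")
                experiment <- readRoiTable(roiPath, labeling, biomass)
            }
            outputs <- c(outputs,
                         .writeTsv(as.data.frame(cellRates(experiment)),
                                   file.path(outDir, "cell_rates.tsv")))
        } else if (stage == "partition") {
            if (is.null(experiment))
                experiment <- readRoiTable(file.path(outDir, "rois.tsv"),
                                           labeling, biomass)
            partition <- partitionSymbioses(experiment)
            outputs <- c(outputs,
                         .writeTsv(as.data.frame(partition),
                                   file.path(outDir, "partition.tsv")))
        } else if (stage == "scale") {
            if (is.null(config$census$file))
                .validationError("stage 'scale' needs [census] file = \"...\"")
            inputs <- c(inputs, config$census$file)
            census <- .readTsv(config$census$file,
                               c("taxon", "count", "volume_l"), "census")
            if (is.null(partition)) {
                pPath <- file.path(outDir, "partition.tsv")
                partition <- .readTsv(pPath, "f_total_n_fmol_d", "partition")
            }
            perSym <- mean(partition$f_total_n_fmol_d)
            ab <- abundanceFromCount(census$count, census$volume_l,
                                     taxon = census$taxon)
            ab$per_symbiosis_rate_fmol_d <- perSym
            ab$volumetric_rate_nmol_l_d <- volumetricRate(perSym,
                                                          ab$abundance_per_l)
            bulk <- config$scale$bulk_rate_nmol_l_d
            ab$contribution_percent <- if (!is.null(bulk))
                contributionPercent(ab$volumetric_rate_nmol_l_d, bulk)
            else NA_real_
            outputs <- c(outputs,
                         .writeTsv(ab, file.path(outDir, "scaling.tsv")))
        } else if (stage == "bulkrate") {
            if (is.null(config$bulk$file))
                .validationError("stage 'bulkrate' needs [bulk] file = \"...\"")
            inputs <- c(inputs, config$bulk$file)
            be <- .readTsv(config$bulk$file,
                           c("station", "element", "replicate_id", "a_pn_t0",
                             "a_pn_t", "pn_conc_umol_l", "t_days"), "bulk")
            aSrc <- ifelse(tolower(be$element) == "n",
                           labeling@aSourceN, labeling@aSourceC)
            be$rate_nmol_l_d <- bulkFixationRate(be$a_pn_t0, be$a_pn_t, aSrc,
                                                 be$pn_conc_umol_l, be$t_days)
            groups <- split(be, paste(be$station, be$element, sep = "|"))
            summ <- do.call(rbind, lapply(groups, function(g) {
                s <- replicateSummary(g$rate_nmol_l_d)
                data.frame(station = g$station[1], element = g$element[1],
                           mean_rate_nmol_l_d = s$mean, sd_rate_nmol_l_d = s$sd,
                           n_replicates = s$n, stringsAsFactors = FALSE)
            }))
            rownames(summ) <- NULL
            outputs <- c(outputs,
                         .writeTsv(be, file.path(outDir, "bulk_replicates.tsv")),
                         .writeTsv(summ, file.path(outDir, "bulk_rates.tsv")))
        } else if (stage == "detect") {
            if (is.null(config$coverage$file))
                .validationError("stage 'detect' needs [coverage] file = \"...\"")
            inputs <- c(inputs, config$coverage$file)
            cov <- .readTsv(config$coverage$file,
                            c("sample_id", "genome_id", "mean_coverage",
                              "observed_breadth"), "coverage")
            theta <- if (!is.null(config$detect$theta)) config$detect$theta
                     else 0.95
            cov$expected_breadth <- expectedBreadth(cov$mean_coverage)
            cov$present <- detectPresence(cov$mean_coverage,
                                          cov$observed_breadth, theta)
            outputs <- c(outputs,
                         .writeTsv(cov, file.path(outDir, "detection.tsv")))
            if (!is.null(config$qpcr$file)) {
                inputs <- c(inputs, config$qpcr$file)
                qp <- .readTsv(config$qpcr$file,
                               c("sample_id", "nifh_copies"), "qPCR")
                tr <- qpcrTransform(qp$nifh_copies, sampleId = qp$sample_id)
                extra <- setdiff(colnames(qp), colnames(tr))
                out <- cbind(tr, qp[, extra, drop = FALSE])
                outputs <- c(outputs,
                             .writeTsv(out, file.path(outDir, "qpcr_map.tsv")))
            }
        }
    }

    manifest <- list(
        tool = "diazoSIP",
        version = as.character(utils::packageVersion("diazoSIP")),
        seed = if (!is.null(seed)) seed else config$sim$seed,
        stages = stages,
        config = config,
        input_digests = as.list(tools::md5sum(unique(inputs))),
        outputs = as.list(tools::md5sum(unique(outputs))))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null",
                         digits = NA)
    .log("info", logLevel, "wrote %d output file(s) to %s",
         length(unique(outputs)), outDir)
    invisible(manifest)
}
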