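#' @include synthetic-data.R
NULL

.validationError <- function(fmt, ...) {
    stop(errorCondition(sprintf(fmt, ...),
                        class = c("diazoSIP_validation", "error")))
}

.readTsv <- function(path, required, what) {
    if (!file.exists(path))
        .validationError("%s input not found: %s", what, path)
    df <- utils::read.delim(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE, check.names = FALSE)
    missing <- setdiff(required, colnames(df))
    if (length(missing))
        .validationError("%s table '%s' is missing column(s): %s",
                         what, basename(path), paste(missing, collapse = ", "))
    df
}

.writeTsv <- function(df, path) {
    df <- as.data.frame(df)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    invisible(path)
}

#' Read a nanoSIMS ROI table
#'
#' Reads the canonical tab-separated ROI dialect (header: roi_id,
#' symbiosis_id, compartment, ratio_c, ratio_n, counts_c_total,
#' counts_n_total, length_um, width_um, diameter_um; empty fields allowed
#' where inapplicable) and returns a validated \code{\link{SipExperiment}}.
#'
#' @param path path to the TSV file.
#' @param labeling a \code{\link{LabelingConfig}}.
#' @param biomass a \code{\link{BiomassParams}}.
#' @return a \code{SipExperiment}.
#' @export
readRoiTable <- function(path, labeling = LabelingConfig(),
                         biomass = BiomassParams()) {
    df <- .readTsv(path, .ROI_COLUMNS, "ROI")
    for (cn in setdiff(.ROI_COLUMNS, c("roi_id", "symbiosis_id", "compartment")))
        df[[cn]] <- as.numeric(df[[cn]])
    SipExperiment(df, labeling = labeling, biomass = biomass)
}

#' Write a ROI table
#'
#' @param x a \code{SipExperiment}.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writeRoiTable <- function(x, path) {
    stopifnot(is(x, "SipExperiment"))
    .writeTsv(as.data.frame(roiData(x)), path)
}

#' Read a pipeline configuration file
#'
#' Parses the flat-section subset of TOML used by the pipeline: \code{[section]}
#' headers followed by \code{key = value} lines, where values are double-quoted
#' strings, booleans (\code{true}/\code{false}) or numbers. Full-line and
#' trailing \code{#} comments are ignored.
#'
#' @param path path to the configuration file.
#' @return a named list of sections, each a named list of values.
#' @export
readPipelineConfig <- function(path) {
    if (!file.exists(path))
        .validationError("config file not found: %s", path)
    lines <- readLines(path, warn = FALSE)
    cfg <- list()
    section <- NULL
    for (i in seq_along(lines)) {
        line <- lines[i]
        ## strip comments (quote-aware only for the simple one-quote-pair case)
        if (!grepl('"', line)) line <- sub("#.*$", "", line)
        line <- trimws(line)
        if (line == "") next
        if (grepl("^\\[[A-Za-z0-9_.-]+\\]$", line)) {
            section <- gsub("^\\[|\\]$", "", line)
            if (is.null(cfg[[section]])) cfg[[section]] <- list()
            next
        }
        m <- regmatches(line, regexec("^([A-Za-z0-9_.-]+)\\s*=\\s*(.+)$", line))[[1]]
        if (length(m) != 3L)
            .validationError("config line %d is not 'key = value': %s", i, line)
        key <- m[2]; raw <- trimws(m[3])
        val <- if (grepl('^".*"$', raw)) {
            gsub('^"|"$', "", raw)
        } else if (raw %in% c("true", "false")) {
            raw == "true"
        } else {
            num <- suppressWarnings(as.numeric(raw))
            if (is.na(num))
                .validationError("config line %d has an unparseable value: %s",
                                 i, raw)
            num
        }
        if (is.null(section))
            cfg[[key]] <- val
        else
            cfg[[section]][[key]] <- val
    }
    cfg
}

.labelingFromConfig <- function(cfg) {
    lc <- cfg$labeling
    if (is.null(lc)) return(LabelingConfig())
    get <- function(key, default) if (!is.null(lc[[key]])) lc[[key]] else default
    LabelingConfig(aSourceN = get("a_source_n", 0.05),
                   aSourceC = get("a_source_c", 0.05),
                   aNatN = get("a_nat_n", 0.003663),
                   aNatC = get("a_nat_c", 0.011056),
                   tDays = get("t_days", 1))
}

.biomassFromConfig <- function(cfg) {
    bc <- cfg$biomass
    if (is.null(bc)) return(BiomassParams())
    get <- function(key, default) if (!is.null(bc[[key]])) bc[[key]] else default
    BiomassParams(hostAllomA = get("host_allom_a", 0.288),
                  hostAllomB = get("host_allom_b", 0.811),
                  symbiontCDensity = get("symbiont_c_density", 112),
                  cnHost = get("cn_host", 6.625),
                  cnSymbiont = get("cn_symbiont", 5))
}

.simFromConfig <- function(cfg, seed = NULL) {
    sc <- cfg$sim
    get <- function(key, default)
        if (!is.null(sc[[key]])) sc[[key]] else default
    SimConfig(nSymbioses = get("n_symbioses", 16),
              symbiontsPerHost = get("symbionts_per_host", 4),
              growthHostMean = get("growth_host_mean", 0.8),
              growthHostSd = get("growth_host_sd", 0.1),
              growthSymMean = get("growth_sym_mean", 0.6),
              growthSymSd = get("growth_sym_sd", 0.3),
              fTotalN = get("f_total_n_fmol_d", 650),
              transferFractionN = get("transfer_fraction_n", 0.99),
              carbonTransfer = get("carbon_transfer", 0.01),
              labeling = .labelingFromConfig(cfg),
              biomass = .biomassFromConfig(cfg),
              noise = get("noise", "none"),
              countsCTotal = get("counts_c_total", 1e7),
              countsNTotal = get("counts_n_total", 1e6),
              fixedGeometry = isTRUE(get("fixed_geometry", FALSE)),
              seed = if (!is.null(seed)) seed else get("seed", 1))
}
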