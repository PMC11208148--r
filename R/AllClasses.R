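#' @include AllGenerics.R
NULL

## canonical ROI table header; empty fields allowed where inapplicable
.ROI_COLUMNS <- c("roi_id", "symbiosis_id", "compartment", "ratio_c", "ratio_n",
                  "counts_c_total", "counts_n_total",
                  "length_um", "width_um", "diameter_um")

#' Isotope-labeling configuration
#'
#' Tracer source atom fractions, natural-abundance atom fractions and the
#' incubation duration of a stable-isotope-probing experiment. Atom fractions
#' are the heavy-isotope share of an element, \eqn{A = R/(1+R)} for isotope
#' ratio \eqn{R}. Defaults for natural abundance are the standard reference
#' values 0.011056 (\eqn{^{13}}C, VPDB) and 0.003663 (\eqn{^{15}}N, air).
#'
#' @slot aSourceN atom fraction \eqn{^{15}}N of the N2 pool after tracer addition.
#' @slot aSourceC atom fraction \eqn{^{13}}C of the DIC pool after tracer addition.
#' @slot aNatN natural \eqn{^{15}}N atom fraction.
#' @slot aNatC natural \eqn{^{13}}C atom fraction.
#' @slot tDays incubation duration in days.
#' @export
setClass("LabelingConfig",
         representation(aSourceN = "numeric", aSourceC = "numeric",
                        aNatN = "numeric", aNatC = "numeric",
                        tDays = "numeric"),
         prototype(aSourceN = 0.05, aSourceC = 0.05,
                   aNatN = 0.003663, aNatC = 0.011056, tDays = 1))

setValidity("LabelingConfig", function(object) {
    msg <- character()
    for (s in c("aSourceN", "aSourceC", "aNatN", "aNatC", "tDays"))
        if (length(slot(object, s)) != 1L || !is.finite(slot(object, s)))
            msg <- c(msg, sprintf("'%s' must be a single finite number", s))
    if (length(msg)) return(msg)
    if (!(object@aNatN < object@aSourceN && object@aSourceN <= 1))
        msg <- c(msg, "need aNatN < aSourceN <= 1")
    if (!(object@aNatC < object@aSourceC && object@aSourceC <= 1))
        msg <- c(msg, "need aNatC < aSourceC <= 1")
    if (object@aNatN < 0 || object@aNatC < 0)
        msg <- c(msg, "natural atom fractions must be non-negative")
    if (object@tDays <= 0)
        msg <- c(msg, "tDays must be > 0")
    if (length(msg)) msg else TRUE
})

#' @param aSourceN,aSourceC,aNatN,aNatC,tDays see slots.
#' @rdname LabelingConfig-class
#' @return a validated \code{LabelingConfig}.
#' @examples
#' LabelingConfig(aSourceN = 0.05, aSourceC = 0.05)
#' @export
LabelingConfig <- function(aSourceN = 0.05, aSourceC = 0.05,
                           aNatN = 0.003663, aNatC = 0.011056, tDays = 1) {
    new("LabelingConfig", aSourceN = aSourceN, aSourceC = aSourceC,
        aNatN = aNatN, aNatC = aNatC, tDays = tDays)
}

setMethod("show", "LabelingConfig", function(object) {
    cat("LabelingConfig\n",
        sprintf("  15N: source %.6f, natural %.6f\n", object@aSourceN, object@aNatN),
        sprintf("  13C: source %.6f, natural %.6f\n", object@aSourceC, object@aNatC),
        sprintf("  incubation: %g d\n", object@tDays), sep = "")
})

#' Biovolume-to-biomass conversion parameters
#'
#' Host (diatom) carbon follows the Menden-Deuer--Lessard allometry
#' \eqn{pg\,C = a V^b} with defaults a = 0.288, b = 0.811; symbiont carbon uses
#' a constant carbon density (fg C per um^3). Nitrogen follows from a
#' compartment-specific molar C:N ratio (defaults: Redfield 6.625 for the
#' host, 5.0 for the protein-rich symbiont).
#'
#' @slot hostAllomA,hostAllomB allometric coefficients (pg C from um^3).
#' @slot symbiontCDensity symbiont carbon density, fg C um^-3.
#' @slot cnHost,cnSymbiont molar C:N ratios.
#' @export
setClass("BiomassParams",
         representation(hostAllomA = "numeric", hostAllomB = "numeric",
                        symbiontCDensity = "numeric",
                        cnHost = "numeric", cnSymbiont = "numeric"),
         prototype(hostAllomA = 0.288, hostAllomB = 0.811,
                   symbiontCDensity = 112, cnHost = 6.625, cnSymbiont = 5))

setValidity("BiomassParams", function(object) {
    vals <- c(object@hostAllomA, object@hostAllomB, object@symbiontCDensity,
              object@cnHost, object@cnSymbiont)
    if (length(vals) != 5L || any(!is.finite(vals)) || any(vals <= 0))
        "all biomass parameters must be single positive finite numbers"
    else TRUE
})

#' @param hostAllomA,hostAllomB,symbiontCDensity,cnHost,cnSymbiont see slots.
#' @rdname BiomassParams-class
#' @return a validated \code{BiomassParams}.
#' @export
BiomassParams <- function(hostAllomA = 0.288, hostAllomB = 0.811,
                          symbiontCDensity = 112,
                          cnHost = 6.625, cnSymbiont = 5) {
    new("BiomassParams", hostAllomA = hostAllomA, hostAllomB = hostAllomB,
        symbiontCDensity = symbiontCDensity,
        cnHost = cnHost, cnSymbiont = cnSymbiont)
}

setMethod("show", "BiomassParams", function(object) {
    cat("BiomassParams\n",
        sprintf("  host: pg C = %.3f * V^%.3f, C:N = %.3f\n",
                object@hostAllomA, object@hostAllomB, object@cnHost),
        sprintf("  symbiont: %.0f fg C um^-3, C:N = %.2f\n",
                object@symbiontCDensity, object@cnSymbiont), sep = "")
})

#' Single-cell stable-isotope-probing experiment
#'
#' Container for one nanoSIMS measurement campaign: a table of regions of
#' interest (ROIs), each a host or symbiont cell with its two isotope ratios
#' (\eqn{^{13}C/^{12}C} and \eqn{^{12}C^{15}N/^{12}C^{14}N}), optional total
#' ion counts and cell dimensions, plus the labeling configuration and biomass
#' conversion parameters needed to turn ratios into rates.
#'
#' @slot rois \code{DataFrame} with the canonical ROI columns (see
#'   \code{\link{readRoiTable}}).
#' @slot labeling a \code{\link{LabelingConfig}}.
#' @slot biomass a \code{\link{BiomassParams}}.
#' @export
setClass("SipExperiment",
         representation(rois = "DataFrame", labeling = "LabelingConfig",
                        biomass = "BiomassParams"))

setValidity("SipExperiment", function(object) {
    df <- object@rois
    missing <- setdiff(.ROI_COLUMNS, colnames(df))
    if (length(missing))
        return(sprintf("ROI table is missing column(s): %s",
                       paste(missing, collapse = ", ")))
    if (nrow(df) == 0L) return(TRUE)
    msg <- character()
    comp <- as.character(df$compartment)
    if (!all(comp %in% c("host", "symbiont")))
        msg <- c(msg, "compartment must be 'host' or 'symbiont'")
    for (rc in c("ratio_c", "ratio_n")) {
        v <- df[[rc]]
        if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0))
            msg <- c(msg, sprintf("'%s' must be finite and >= 0", rc))
    }
    host <- comp == "host"
    if (any(host)) {
        L <- df$length_um[host]; W <- df$width_um[host]
        if (any(is.na(L) | is.na(W) | L <= 0 | W <= 0))
            msg <- c(msg, "host ROIs need positive length_um and width_um")
    }
    if (any(!host)) {
        d <- df$diameter_um[!host]
        if (any(is.na(d) | d <= 0))
            msg <- c(msg, "symbiont ROIs need positive diameter_um")
    }
    if (anyDuplicated(df$roi_id))
        msg <- c(msg, "roi_id values must be unique")
    hostsPerSym <- tapply(host, as.character(df$symbiosis_id), sum)
    if (any(hostsPerSym > 1))
        msg <- c(msg, "each symbiosis may contain at most one host ROI")
    if (length(msg)) msg else TRUE
})

#' @param rois a \code{DataFrame} or data.frame with the canonical ROI columns.
#' @param labeling a \code{LabelingConfig}.
#' @param biomass a \code{BiomassParams}.
#' @rdname SipExperiment-class
#' @return a validated \code{SipExperiment}.
#' @examples
#' sim <- simulateSymbioses(SimConfig(nSymbioses = 2, fixedGeometry = TRUE))
#' sim$experiment
#' @export
SipExperiment <- function(rois, labeling = LabelingConfig(),
                          biomass = BiomassParams()) {
    if (is.data.frame(rois)) rois <- S4Vectors::DataFrame(rois)
    for (cn in setdiff(.ROI_COLUMNS, colnames(rois)))
        rois[[cn]] <- NA_real_
    rois <- rois[, .ROI_COLUMNS]
    new("SipExperiment", rois = rois, labeling = labeling, biomass = biomass)
}

setMethod("show", "SipExperiment", function(object) {
    df <- object@rois
    nh <- sum(df$compartment == "host")
    cat(sprintf("SipExperiment: %d ROIs (%d hosts, %d symbionts) in %d symbioses\n",
                nrow(df), nh, nrow(df) - nh,
                length(unique(as.character(df$symbiosis_id)))))
    cat(sprintf("  labeling: 15N source %.4g, 13C source %.4g, t = %g d\n",
                object@labeling@aSourceN, object@labeling@aSourceC,
                object@labeling@tDays))
})

#' @rdname roiData
#' @export
setMethod("roiData", "SipExperiment", function(x) x@rois)

#' @rdname roiData
#' @export
setReplaceMethod("roiData", "SipExperiment", function(x, value) {
    if (is.data.frame(value)) value <- S4Vectors::DataFrame(value)
    x@rois <- value
    validObject(x)
    x
})

#' @rdname labelingConfig
#' @export
setMethod("labelingConfig", "SipExperiment", function(x) x@labeling)

#' @rdname biomassParams
#' @export
setMethod("biomassParams", "SipExperiment", function(x) x@biomass)

#' Configuration of the symbiosis forward simulator
#'
#' Defines the study conditions that the simulator emulates: host geometry
#' drawn uniformly from the observed 20--58 um length and 3--8 um width range,
#' k symbionts per host (typically 4, up to 8 in dividing hosts), carbon-based
#' growth rates of 0.8 +/- 0.1 (host) and 0.6 +/- 0.3 (symbiont) divisions per
#' day truncated at \code{growthMin}, a whole-symbiosis N2-fixation rate of
#' 650 fmol N per day at the reference host size, a nitrogen transfer fraction
#' of 0.99 and a carbon transfer fraction of 0.01, over a 1-day incubation with
#' 5 atom\% tracer pools. Optional Poisson ion-counting noise.
#'
#' @slot nSymbioses number of host-symbiont units to simulate.
#' @slot symbiontsPerHost symbionts per host (1--8).
#' @slot hostLengthRange,hostWidthRange uniform sampling ranges, um.
#' @slot growthHostMean,growthHostSd,growthSymMean,growthSymSd,growthMin
#'   truncated-normal growth distributions, divisions per day.
#' @slot fTotalN whole-symbiosis N2-fixation rate at the reference host
#'   geometry, fmol N per day; scaled by host N content for other hosts.
#' @slot transferFractionN fraction of fixed N recovered in the host (phi).
#' @slot carbonTransfer fraction of total fixed C acquired by symbionts (psi).
#' @slot labeling a \code{LabelingConfig}.
#' @slot biomass a \code{BiomassParams}.
#' @slot noise \code{"none"} or \code{"poisson"}.
#' @slot countsCTotal,countsNTotal total ion counts per ROI under Poisson noise.
#' @slot fixedGeometry if TRUE, all hosts are 40 x 5 um, growth rates sit at
#'   the distribution means and no geometry or growth is sampled.
#' @slot seed integer seed for all sampling.
#' @export
setClass("SimConfig",
         representation(nSymbioses = "integer", symbiontsPerHost = "integer",
                        hostLengthRange = "numeric", hostWidthRange = "numeric",
                        growthHostMean = "numeric", growthHostSd = "numeric",
                        growthSymMean = "numeric", growthSymSd = "numeric",
                        growthMin = "numeric",
                        fTotalN = "numeric", transferFractionN = "numeric",
                        carbonTransfer = "numeric",
                        labeling = "LabelingConfig", biomass = "BiomassParams",
                        noise = "character",
                        countsCTotal = "numeric", countsNTotal = "numeric",
                        fixedGeometry = "logical", seed = "integer"),
         prototype(nSymbioses = 16L, symbiontsPerHost = 4L,
                   hostLengthRange = c(20, 58), hostWidthRange = c(3, 8),
                   growthHostMean = 0.8, growthHostSd = 0.1,
                   growthSymMean = 0.6, growthSymSd = 0.3, growthMin = 0.05,
                   fTotalN = 650, transferFractionN = 0.99,
                   carbonTransfer = 0.01,
                   noise = "none", countsCTotal = 1e7, countsNTotal = 1e6,
                   fixedGeometry = FALSE, seed = 1L))

setValidity("SimConfig", function(object) {
    msg <- character()
    if (object@nSymbioses < 1L) msg <- c(msg, "nSymbioses must be >= 1")
    if (object@symbiontsPerHost < 1L || object@symbiontsPerHost > 8L)
        msg <- c(msg, "symbiontsPerHost must be in 1..8")
    if (object@transferFractionN < 0 || object@transferFractionN > 1)
        msg <- c(msg, "transferFractionN must be in [0, 1]")
    if (object@carbonTransfer < 0 || object@carbonTransfer >= 1)
        msg <- c(msg, "carbonTransfer must be in [0, 1)")
    if (!object@noise %in% c("none", "poisson"))
        msg <- c(msg, "noise must be 'none' or 'poisson'")
    if (object@fTotalN <= 0) msg <- c(msg, "fTotalN must be > 0")
    if (any(c(object@countsCTotal, object@countsNTotal) <= 0))
        msg <- c(msg, "ion-count totals must be > 0")
    if (diff(object@hostLengthRange) < 0 || any(object@hostLengthRange <= 0) ||
        diff(object@hostWidthRange) < 0 || any(object@hostWidthRange <= 0))
        msg <- c(msg, "geometry ranges must be positive and increasing")
    if (object@growthMin <= 0) msg <- c(msg, "growthMin must be > 0")
    if (length(msg)) msg else TRUE
})

#' @param nSymbioses,symbiontsPerHost,hostLengthRange,hostWidthRange see slots.
#' @param growthHostMean,growthHostSd,growthSymMean,growthSymSd,growthMin see slots.
#' @param fTotalN,transferFractionN,carbonTransfer see slots.
#' @param labeling,biomass,noise,countsCTotal,countsNTotal,fixedGeometry,seed see slots.
#' @rdname SimConfig-class
#' @return a validated \code{SimConfig}.
#' @examples
#' SimConfig(nSymbioses = 4, fixedGeometry = TRUE)
#' @export
SimConfig <- function(nSymbioses = 16, symbiontsPerHost = 4,
                      hostLengthRange = c(20, 58), hostWidthRange = c(3, 8),
                      growthHostMean = 0.8, growthHostSd = 0.1,
                      growthSymMean = 0.6, growthSymSd = 0.3, growthMin = 0.05,
                      fTotalN = 650, transferFractionN = 0.99,
                      carbonTransfer = 0.01,
                      labeling = LabelingConfig(),
                      biomass = BiomassParams(),
                      noise = c("none", "poisson"),
                      countsCTotal = 1e7, countsNTotal = 1e6,
                      fixedGeometry = FALSE, seed = 1) {
    noise <- match.arg(noise)
    new("SimConfig", nSymbioses = as.integer(nSymbioses),
        symbiontsPerHost = as.integer(symbiontsPerHost),
        hostLengthRange = hostLengthRange, hostWidthRange = hostWidthRange,
        growthHostMean = growthHostMean, growthHostSd = growthHostSd,
        growthSymMean = growthSymMean, growthSymSd = growthSymSd,
        growthMin = growthMin, fTotalN = fTotalN,
        transferFractionN = transferFractionN, carbonTransfer = carbonTransfer,
        labeling = labeling, biomass = biomass, noise = noise,
        countsCTotal = countsCTotal, countsNTotal = countsNTotal,
        fixedGeometry = fixedGeometry, seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
    cat(sprintf("SimConfig: %d symbioses x %d symbionts, noise = %s%s\n",
                object@nSymbioses, object@symbiontsPerHost, object@noise,
                if (object@fixedGeometry) " (fixed geometry)" else ""))
    cat(sprintf("  phi = %.3f, psi = %.3f, f_total_N = %g fmol d^-1 (reference host)\n",
                object@transferFractionN, object@carbonTransfer, object@fTotalN))
    cat(sprintf("  growth: host %g +/- %g, symbiont %g +/- %g div d^-1, seed %d\n",
                object@growthHostMean, object@growthHostSd,
                object@growthSymMean, object@growthSymSd, object@seed))
})

#' @rdname labelingConfig
#' @export
setMethod("labelingConfig", "SimConfig", function(x) x@labeling)

#' @rdname biomassParams
#' @export
setMethod("biomassParams", "SimConfig", function(x) x@biomass)
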