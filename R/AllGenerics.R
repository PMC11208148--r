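#' @include AllGenerics.R
NULL

#' Per-ROI measurement table of a \code{SipExperiment}
#'
#' @param x a \code{SipExperiment}.
#' @return a \code{\link[S4Vectors]{DataFrame}} with one row per ROI.
#' @export
setGeneric("roiData", function(x) standardGeneric("roiData"))

#' @rdname roiData
#' @param value replacement ROI table.
#' @export
setGeneric("roiData<-", function(x, value) standardGeneric("roiData<-"))

#' Labeling configuration of an object
#'
#' @param x a \code{SipExperiment} or \code{SimConfig}.
#' @return the \code{LabelingConfig}.
#' @export
setGeneric("labelingConfig", function(x) standardGeneric("labelingConfig"))

#' Biomass conversion parameters of an object
#'
#' @param x a \code{SipExperiment} or \code{SimConfig}.
#' @return the \code{BiomassParams}.
#' @export
setGeneric("biomassParams", function(x) standardGeneric("biomassParams"))

#' Single-cell biomass, fixation and growth estimates
#'
#' @param x a \code{SipExperiment}.
#' @param ... further arguments passed to methods.
#' @return a \code{DataFrame}, one row per ROI.
#' @export
setGeneric("cellRates", function(x, ...) standardGeneric("cellRates"))

#' Host-symbiont element partitioning per symbiosis
#'
#' @param x a \code{SipExperiment}.
#' @param ... further arguments passed to methods.
#' @return a \code{DataFrame}, one row per symbiosis.
#' @export
setGeneric("partitionSymbioses",
           function(x, ...) standardGeneric("partitionSymbioses"))
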