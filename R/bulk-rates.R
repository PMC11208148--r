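#' @include census-scaling.R
NULL

#' Bulk fixation rate from incubation endpoints
#'
#' Two-point (dawn-to-dawn) estimator on the particulate pool: the change in
#' atom fraction of particulate N (or C) over the incubation, relative to the
#' labeled source pool, times the particulate concentration:
#' \deqn{rate = \frac{A_{PN,t} - A_{PN,0}}{A_{source} - A_{PN,0}}
#'       \cdot \frac{[PN] \cdot 1000}{t}}
#' with concentration in umol l^-1 and the result in nmol l^-1 d^-1. Negative
#' apparent enrichment is clamped to zero with a warning, as in
#' \code{\link{fixationRate}}.
#'
#' @param aPnT0,aPnT atom fraction of the particulate pool at start and end.
#' @param aSource atom fraction of the labeled substrate pool; > \code{aPnT0}.
#' @param pnConcUmolL particulate N (or C) concentration at the endpoint,
#'   umol l^-1, > 0.
#' @param tDays incubation duration, days.
#' @return bulk fixation rate, nmol l^-1 d^-1.
#' @examples
#' bulkFixationRate(0.003663, 0.004663, 0.05, 1, 1)   # ~21.6 nmol N l^-1 d^-1
#' @export
bulkFixationRate <- function(aPnT0, aPnT, aSource, pnConcUmolL, tDays) {
    if (any(aSource <= aPnT0))
        stop("aSource must exceed the initial particulate atom fraction")
    if (any(pnConcUmolL <= 0))
        stop("particulate concentration must be > 0")
    if (any(tDays <= 0))
        stop("tDays must be > 0")
    x <- .clampExcess((aPnT - aPnT0) / (aSource - aPnT0), "particulate")
    x * pnConcUmolL * 1000 / tDays
}

#' Summarize replicate incubations
#'
#' @param rates numeric vector of replicate rates (n >= 1).
#' @return list with \code{mean}, \code{sd} (NA for a single replicate) and
#'   \code{n}.
#' @examples
#' replicateSummary(c(10, 20, 30))
#' @export
replicateSummary <- function(rates) {
    if (length(rates) == 0L || any(!is.finite(rates)))
        stop("need at least one finite replicate rate")
    list(mean = mean(rates),
         sd = if (length(rates) > 1L) stats::sd(rates) else NA_real_,
         n = length(rates))
}
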