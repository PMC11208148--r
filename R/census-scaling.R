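#' @include mass-balance.R
NULL

#' Abundance with exact Poisson confidence interval from a census count
#'
#' Microscopy census counts are small (tens of cells per filter piece), so the
#' exact (Garwood) Poisson interval is used instead of a normal approximation:
#' for a count k at confidence 1 - alpha, the bounds are the gamma quantiles
#' \eqn{qgamma(\alpha/2, k)} and \eqn{qgamma(1-\alpha/2, k+1)}, divided by the
#' examined volume. For k = 0 the upper bound is 3.689/volume at 95\%.
#'
#' @param count non-negative integer count of cells or symbioses.
#' @param volumeL volume of water examined, litres, > 0.
#' @param taxon optional taxon label.
#' @param conf confidence level (default 0.95).
#' @return data.frame with \code{taxon}, \code{count}, \code{volume_l},
#'   \code{abundance_per_l}, \code{ci_low}, \code{ci_high}.
#' @examples
#' abundanceFromCount(50, 0.025)   # 2000 per litre
#' @export
abundanceFromCount <- function(count, volumeL, taxon = NA_character_,
                               conf = 0.95) {
    if (any(!is.finite(count)) || any(count < 0) ||
        any(abs(count - round(count)) > 1e-8))
        stop("count must be a non-negative integer")
    if (any(volumeL <= 0))
        stop("volumeL must be > 0")
    n <- max(length(count), length(volumeL), length(taxon))
    count <- rep_len(count, n); volumeL <- rep_len(volumeL, n)
    taxon <- rep_len(taxon, n)
    alpha <- 1 - conf
    lo <- ifelse(count == 0, 0, stats::qgamma(alpha / 2, count))
    hi <- stats::qgamma(1 - alpha / 2, count + 1)
    data.frame(taxon = taxon, count = count, volume_l = volumeL,
               abundance_per_l = count / volumeL,
               ci_low = lo / volumeL, ci_high = hi / volumeL,
               stringsAsFactors = FALSE)
}

#' Cell count from summed trichome length
#'
#' Filamentous diazotrophs such as \emph{Trichodesmium} are censused by
#' measuring the total (summed) length of all free trichomes and dividing by
#' the mean cell length.
#'
#' @param totalTrichomeLengthUm summed trichome length, um.
#' @param meanCellLengthUm mean length of a single cell, um, > 0.
#' @return real-valued cell count.
#' @examples
#' trichomeCellCount(3000, 10)   # 300 cells
#' @export
trichomeCellCount <- function(totalTrichomeLengthUm, meanCellLengthUm) {
    if (any(totalTrichomeLengthUm < 0))
        stop("total trichome length must be >= 0")
    if (any(meanCellLengthUm <= 0))
        stop("mean cell length must be > 0")
    totalTrichomeLengthUm / meanCellLengthUm
}

#' Volumetric fixation rate from a per-unit rate and abundance
#'
#' Scales a per-cell or per-symbiosis rate (fmol d^-1) by in situ abundance
#' (per litre) to a volumetric rate, converting fmol to nmol (factor 1e-6).
#'
#' @param perUnitRateFmolD rate per cell or symbiosis, fmol d^-1.
#' @param abundancePerL abundance, individuals per litre.
#' @return volumetric rate, nmol l^-1 d^-1.
#' @examples
#' volumetricRate(650, 2000)   # 1.3 nmol N l^-1 d^-1
#' @export
volumetricRate <- function(perUnitRateFmolD, abundancePerL) {
    if (any(perUnitRateFmolD < 0) || any(abundancePerL < 0))
        stop("rate and abundance must be non-negative")
    perUnitRateFmolD * abundancePerL * 1e-6
}

#' Percent contribution of a volumetric rate to the bulk rate
#'
#' @param volumetric volumetric rate, nmol l^-1 d^-1.
#' @param bulk bulk rate in the same units, > 0 (otherwise NA is returned).
#' @return contribution in percent.
#' @examples
#' contributionPercent(1.3, 40)   # 3.25 %
#' @export
contributionPercent <- function(volumetric, bulk) {
    if (any(volumetric < 0))
        stop("volumetric rate must be non-negative")
    n <- max(length(volumetric), length(bulk))
    volumetric <- rep_len(volumetric, n)
    bulk <- rep_len(bulk, n)
    ifelse(is.finite(bulk) & bulk > 0, 100 * volumetric / bulk, NA_real_)
}
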