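#' @include AllClasses.R
NULL

#' Convert an isotope ratio to an atom fraction
#'
#' The atom fraction (heavy-isotope share of the element) of a measured
#' isotope ratio R is \eqn{A = R/(1+R)}. Both the carbon ratio
#' \eqn{^{13}C/^{12}C} and the CN-derived nitrogen ratio
#' \eqn{^{12}C^{15}N/^{12}C^{14}N} convert this way.
#'
#' @param r numeric vector of isotope ratios, all >= 0.
#' @return atom fractions in [0, 1), same length as \code{r}.
#' @seealso \code{\link{atomFractionToRatio}} for the inverse.
#' @examples
#' ratioToAtomFraction(0.0111802)  # ~natural 13C atom fraction
#' @export
ratioToAtomFraction <- function(r) {
    if (!is.numeric(r) || any(!is.finite(r)))
        stop("isotope ratios must be finite numbers")
    if (any(r < 0))
        stop("isotope ratios must be >= 0")
    r / (1 + r)
}

#' Convert an atom fraction to an isotope ratio
#'
#' Inverse of \code{\link{ratioToAtomFraction}}: \eqn{R = A/(1-A)}.
#'
#' @param a numeric vector of atom fractions in [0, 1).
#' @return isotope ratios >= 0.
#' @export
atomFractionToRatio <- function(a) {
    if (!is.numeric(a) || any(!is.finite(a)) || any(a < 0) || any(a >= 1))
        stop("atom fractions must lie in [0, 1)")
    a / (1 - a)
}

#' Cell biovolume from measured dimensions
#'
#' Hosts (pennate diatoms measured by length and width only) are modeled as
#' elliptic cylinders with height equal to width, \eqn{V = (\pi/4) L W^2};
#' symbionts (cocci) as spheres, \eqn{V = (\pi/6) d^3}.
#'
#' @param compartment character vector, \code{"host"} or \code{"symbiont"}.
#' @param length_um,width_um host dimensions in um (ignored for symbionts).
#' @param diameter_um symbiont diameter in um (ignored for hosts).
#' @return biovolume in um^3.
#' @examples
#' roiBiovolume("host", length_um = 40, width_um = 5)     # 785.4 um^3
#' roiBiovolume("symbiont", diameter_um = 1.5)            # 1.767 um^3
#' @export
roiBiovolume <- function(compartment, length_um = NA_real_,
                         width_um = NA_real_, diameter_um = NA_real_) {
    n <- length(compartment)
    if (!all(compartment %in% c("host", "symbiont")))
        stop("compartment must be 'host' or 'symbiont'")
    length_um <- rep_len(length_um, n)
    width_um <- rep_len(width_um, n)
    diameter_um <- rep_len(diameter_um, n)
    host <- compartment == "host"
    if (any(host & (is.na(length_um) | is.na(width_um))))
        stop("host ROIs require length_um and width_um")
    if (any(!host & is.na(diameter_um)))
        stop("symbiont ROIs require diameter_um")
    if (any(host & (length_um <= 0 | width_um <= 0), na.rm = TRUE) ||
        any(!host & diameter_um <= 0, na.rm = TRUE))
        stop("cell dimensions must be > 0")
    ifelse(host,
           pi / 4 * length_um * width_um^2,
           pi / 6 * diameter_um^3)
}

#' Carbon and nitrogen content from biovolume
#'
#' Host carbon follows the Menden-Deuer--Lessard allometry
#' \eqn{pg\,C = a V^b}; symbiont carbon uses a constant carbon density.
#' Nitrogen is derived from carbon through the compartment C:N ratio.
#' 1 pg C = 1000/12 fmol C.
#'
#' @param v biovolume in um^3, > 0.
#' @param compartment \code{"host"} or \code{"symbiont"} (vectorized).
#' @param params a \code{\link{BiomassParams}}.
#' @return data.frame with columns \code{biovolume_um3}, \code{c_content_fmol},
#'   \code{n_content_fmol}, \code{cn_ratio}.
#' @examples
#' biomassFromVolume(785.398, "host")      # ~5345 fmol C, ~807 fmol N
#' biomassFromVolume(1.767, "symbiont")    # ~16.5 fmol C
#' @export
biomassFromVolume <- function(v, compartment, params = BiomassParams()) {
    if (any(!is.finite(v)) || any(v <= 0))
        stop("biovolume must be finite and > 0")
    n <- max(length(v), length(compartment))
    v <- rep_len(v, n)
    compartment <- rep_len(compartment, n)
    if (!all(compartment %in% c("host", "symbiont")))
        stop("compartment must be 'host' or 'symbiont'")
    host <- compartment == "host"
    cFmol <- ifelse(host,
                    params@hostAllomA * v^params@hostAllomB * 1000 / 12,
                    params@symbiontCDensity * v / 12)
    cn <- ifelse(host, params@cnHost, params@cnSymbiont)
    data.frame(biovolume_um3 = v, c_content_fmol = cFmol,
               n_content_fmol = cFmol / cn, cn_ratio = cn)
}

.clampExcess <- function(x, what) {
    if (any(x < 0)) {
        warning(sprintf(
            "%d %s enrichment(s) below the initial value; clamped to zero",
            sum(x < 0), what), call. = FALSE)
        x <- pmax(x, 0)
    }
    x
}

#' Cell-specific fixation rate from isotope incorporation
#'
#' Linear-incorporation estimator: the excess atom fraction relative to the
#' source pool, times elemental content, per unit time:
#' \deqn{rate = \frac{A_{meas} - A_{init}}{A_{source} - A_{init}}
#'   \cdot \frac{content}{t}}
#' Apparent negative enrichment (measurement noise below the initial value) is
#' clamped to zero with a warning.
#'
#' @param aMeas measured atom fraction.
#' @param aInit atom fraction at the start of the incubation.
#' @param aSource atom fraction of the labeled substrate pool; must exceed
#'   \code{aInit}.
#' @param contentFmol elemental content of the cell, fmol.
#' @param tDays incubation duration, days.
#' @return fixation rate in fmol per day.
#' @examples
#' fixationRate(0.0268, 0.003663, 0.05, 800, 1)  # ~399.5 fmol d^-1
#' @export
fixationRate <- function(aMeas, aInit, aSource, contentFmol, tDays) {
    if (any(aSource <= aInit))
        stop("aSource must exceed aInit")
    if (any(tDays <= 0))
        stop("tDays must be > 0")
    x <- .clampExcess((aMeas - aInit) / (aSource - aInit), "isotope")
    x * contentFmol / tDays
}

#' New-biomass fraction under exponential labeling
#'
#' Forward model relating a carbon-based growth rate g (divisions per day) to
#' the fraction x of cell carbon synthesized during the incubation:
#' \eqn{x = 1 - 2^{-g t}}.
#'
#' @param g growth rate, divisions per day.
#' @param tDays incubation duration, days.
#' @return new-carbon fraction in [0, 1).
#' @export
growthToNewFraction <- function(g, tDays = 1) {
    if (any(g < 0) || any(tDays <= 0))
        stop("need g >= 0 and tDays > 0")
    -expm1(-g * tDays * log(2))
}

#' Carbon-based growth rate from isotope enrichment
#'
#' Inverts the exponential-labeling model: with the labeled fraction
#' \eqn{x = (A_{meas} - A_{nat})/(A_{source} - A_{nat})}, the growth rate is
#' \deqn{g = -\ln(1 - x) / (t \ln 2)}
#' in divisions per day, the exact inverse of
#' \code{\link{growthToNewFraction}}. Enrichment at or above the source pool
#' (x >= 1) is a saturation error; apparent negative enrichment is clamped to
#' zero with a warning.
#'
#' @param aMeas measured atom fraction.
#' @param aNat natural-abundance atom fraction.
#' @param aSource source-pool atom fraction; must exceed \code{aNat}.
#' @param tDays incubation duration, days.
#' @return growth rate, divisions per day.
#' @examples
#' growthRate(0.5, 0, 1, 1)   # half the carbon is new: one doubling per day
#' @export
growthRate <- function(aMeas, aNat, aSource, tDays) {
    if (any(aSource <= aNat))
        stop("aSource must exceed aNat")
    if (any(tDays <= 0))
        stop("tDays must be > 0")
    x <- (aMeas - aNat) / (aSource - aNat)
    if (any(x >= 1))
        stop("enrichment at or above the source pool: growth rate saturated")
    x <- .clampExcess(x, "growth")
    -log1p(-x) / (tDays * log(2))
}

#' @rdname cellRates
#' @details For each ROI, biovolume and C/N content are derived from the
#'   measured dimensions, both isotope ratios are converted to atom fractions,
#'   and three quantities are estimated: the N2-fixation rate (fmol N d^-1)
#'   and CO2-fixation rate (fmol C d^-1) by linear incorporation, and the
#'   carbon-based growth rate (divisions d^-1) by exponential-labeling
#'   inversion. For symbionts the carbon source is taken to carry the full DIC
#'   source enrichment (freshly fixed host carbon passed on without isotopic
#'   dilution).
#' @examples
#' sim <- simulateSymbioses(SimConfig(nSymbioses = 2, fixedGeometry = TRUE))
#' cellRates(sim$experiment)
#' @export
setMethod("cellRates", "SipExperiment", function(x, ...) {
    df <- roiData(x)
    lab <- labelingConfig(x)
    comp <- as.character(df$compartment)
    vol <- roiBiovolume(comp, df$length_um, df$width_um, df$diameter_um)
    bm <- biomassFromVolume(vol, comp, biomassParams(x))
    aC <- ratioToAtomFraction(df$ratio_c)
    aN <- ratioToAtomFraction(df$ratio_n)
    out <- S4Vectors::DataFrame(
        roi_id = df$roi_id,
        symbiosis_id = df$symbiosis_id,
        compartment = comp,
        biovolume_um3 = bm$biovolume_um3,
        c_content_fmol = bm$c_content_fmol,
        n_content_fmol = bm$n_content_fmol,
        a_c = aC,
        a_n = aN,
        fix_rate_n_fmol_d = fixationRate(aN, lab@aNatN, lab@aSourceN,
                                         bm$n_content_fmol, lab@tDays),
        fix_rate_c_fmol_d = fixationRate(aC, lab@aNatC, lab@aSourceC,
                                         bm$c_content_fmol, lab@tDays),
        growth_div_d = growthRate(aC, lab@aNatC, lab@aSourceC, lab@tDays))
    out
})
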