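#' @include genome-detect.R
NULL

## inverse-CDF sampler for a normal truncated below at `lo`
.rtruncnorm <- function(n, mean, sd, lo) {
    u <- stats::runif(n, stats::pnorm(lo, mean, sd), 1)
    stats::qnorm(u, mean, sd)
}

#' Forward-simulate host-symbiont symbioses and their nanoSIMS measurements
#'
#' Generates a \code{\link{SipExperiment}} (the ROI isotope-ratio table) plus
#' per-cell and per-symbiosis truth tables, under a forward model that is the
#' exact inverse of the package's estimators, so that in the noise-free case
#' every estimator recovers its configured truth to floating-point precision.
#'
#' The forward model, per symbiosis: host geometry (sampled or fixed at the
#' 40 x 5 um reference) sets host carbon by allometry and nitrogen by the host
#' C:N ratio. Carbon labeling follows exponential growth,
#' \eqn{x = 1 - 2^{-gt}}, so each cell's \eqn{^{13}}C atom fraction is
#' \eqn{A_{nat} + x (A_{source} - A_{nat})}; symbionts are assumed to receive
#' freshly fixed host carbon at the full DIC source enrichment. Total symbiont
#' carbon is set from the carbon transfer fraction psi,
#' \eqn{C_{sym} = \frac{\psi}{1-\psi} \bar x_{host} C_{host} / \bar x_{sym}},
#' split equally among the k symbionts, and each symbiont's diameter is the
#' one that returns exactly this carbon at the configured carbon density.
#' Nitrogen: the whole-symbiosis fixation rate scales with host N content
#' relative to the reference host (label conservation: a host cannot carry
#' more tracer N than its N pool), a fraction phi of it appears in the host
#' and the rest is split equally among symbionts; atom fractions follow from
#' the linear-incorporation model. A symbiont whose nitrogen new-fraction
#' would reach the source pool (possible only in the far tail of the sampled
#' growth distribution) is capped at 0.999 and flagged. Under Poisson noise,
#' heavy-isotope ion counts are drawn as Poisson(A * total counts) and the
#' measured ratios recomputed from them.
#'
#' Sampling order (fixed for reproducibility): host lengths for all
#' symbioses, host widths, host growth rates, symbiont growth rates (by
#' symbiosis, then symbiont index), then Poisson ion counts (carbon then
#' nitrogen, in ROI order).
#'
#' @param config a \code{\link{SimConfig}}.
#' @return list with \code{experiment} (a \code{SipExperiment}),
#'   \code{truthCells} (per-ROI true contents, rates and growth) and
#'   \code{truthSymbioses} (per-symbiosis phi, psi, total fixation and the
#'   implied symbiont carbon density).
#' @examples
#' sim <- simulateSymbioses(SimConfig(nSymbioses = 2, fixedGeometry = TRUE))
#' head(sim$truthCells)
#' @export
simulateSymbioses <- function(config = SimConfig()) {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    set.seed(config@seed)
    n <- config@nSymbioses
    k <- config@symbiontsPerHost
    lab <- config@labeling
    bp <- config@biomass
    t <- lab@tDays
    phi <- config@transferFractionN
    psi <- config@carbonTransfer

    if (config@fixedGeometry) {
        hostL <- rep(40, n); hostW <- rep(5, n)
        gHost <- rep(config@growthHostMean, n)
        gSym <- matrix(config@growthSymMean, nrow = n, ncol = k)
    } else {
        hostL <- stats::runif(n, config@hostLengthRange[1], config@hostLengthRange[2])
        hostW <- stats::runif(n, config@hostWidthRange[1], config@hostWidthRange[2])
        gHost <- .rtruncnorm(n, config@growthHostMean, config@growthHostSd,
                             config@growthMin)
        gSym <- matrix(.rtruncnorm(n * k, config@growthSymMean,
                                   config@growthSymSd, config@growthMin),
                       nrow = n, ncol = k, byrow = TRUE)
    }

    hostBm <- biomassFromVolume(roiBiovolume(rep("host", n), hostL, hostW),
                                rep("host", n), bp)
    refBm <- biomassFromVolume(roiBiovolume("host", 40, 5), "host", bp)
    fTot <- config@fTotalN * hostBm$n_content_fmol / refBm$n_content_fmol

    xHost <- growthToNewFraction(gHost, t)
    xSym <- growthToNewFraction(gSym, t)

    ## symbiont carbon from psi; equal split; diameter implied by density
    cSymTotal <- psi / (1 - psi) * xHost * hostBm$c_content_fmol /
        rowMeans(xSym)
    cSymEach <- cSymTotal / k
    dSym <- (6 * cSymEach * 12 / (pi * bp@symbiontCDensity))^(1 / 3)
    nSymEach <- cSymEach / bp@cnSymbiont

    ## nitrogen label fractions
    xHostN <- phi * fTot * t / hostBm$n_content_fmol
    if (any(xHostN >= 1))
        stop("configuration error: host 15N atom fraction would reach the source pool")
    rateSymN <- (1 - phi) * fTot / k
    xSymN <- matrix(rateSymN * t, nrow = n, ncol = k) / nSymEach
    saturated <- xSymN >= 1
    if (any(saturated)) {
        ## deterministic (unsampled) violation is a configuration error;
        ## a sampled far-tail growth draw is capped instead
        if (config@fixedGeometry)
            stop("configuration error: symbiont 15N atom fraction would reach the source pool")
        warning(sprintf("%d symbiont(s) saturated in 15N; capped at x = 0.999",
                        sum(saturated)), call. = FALSE)
        xSymN[saturated] <- 0.999
    }

    aOf <- function(x, nat, src) nat + x * (src - nat)
    aHostC <- aOf(xHost, lab@aNatC, lab@aSourceC)
    aSymC <- aOf(xSym, lab@aNatC, lab@aSourceC)
    aHostN <- aOf(xHostN, lab@aNatN, lab@aSourceN)
    aSymN <- aOf(xSymN, lab@aNatN, lab@aSourceN)

    symIdx <- sprintf("sym%04d", seq_len(n))
    hostIds <- paste0(symIdx, "_host")
    symIds <- matrix(paste0(rep(symIdx, each = k), "_symb",
                            rep(seq_len(k), n)),
                     nrow = n, ncol = k, byrow = TRUE)

    ## assemble ROI rows: per symbiosis, host first then its symbionts
    ord <- function(hostVal, symMat) {
        out <- numeric(0)
        for (i in seq_len(n))
            out <- c(out, hostVal[i], symMat[i, ])
        out
    }
    ordChr <- function(hostVal, symMat) {
        out <- character(0)
        for (i in seq_len(n))
            out <- c(out, hostVal[i], symMat[i, ])
        out
    }
    roi <- data.frame(
        roi_id = ordChr(hostIds, symIds),
        symbiosis_id = rep(symIdx, each = k + 1L),
        compartment = rep(c("host", rep("symbiont", k)), n),
        a_c_true = ord(aHostC, aSymC),
        a_n_true = ord(aHostN, aSymN),
        length_um = rep(NA_real_, n * (k + 1L)),
        width_um = rep(NA_real_, n * (k + 1L)),
        diameter_um = rep(NA_real_, n * (k + 1L)),
        stringsAsFactors = FALSE)
    isHost <- roi$compartment == "host"
    roi$length_um[isHost] <- hostL
    roi$width_um[isHost] <- hostW
    roi$diameter_um[!isHost] <- rep(dSym, each = k)

    if (config@noise == "poisson") {
        heavyC <- stats::rpois(nrow(roi), roi$a_c_true * config@countsCTotal)
        heavyN <- stats::rpois(nrow(roi), roi$a_n_true * config@countsNTotal)
        roi$ratio_c <- heavyC / (config@countsCTotal - heavyC)
        roi$ratio_n <- heavyN / (config@countsNTotal - heavyN)
        roi$counts_c_total <- config@countsCTotal
        roi$counts_n_total <- config@countsNTotal
    } else {
        roi$ratio_c <- atomFractionToRatio(roi$a_c_true)
        roi$ratio_n <- atomFractionToRatio(roi$a_n_true)
        roi$counts_c_total <- NA_real_
        roi$counts_n_total <- NA_real_
    }

    truthCells <- data.frame(
        roi_id = roi$roi_id,
        symbiosis_id = roi$symbiosis_id,
        compartment = roi$compartment,
        c_content_fmol = ord(hostBm$c_content_fmol,
                             matrix(cSymEach, n, k)),
        n_content_fmol = ord(hostBm$n_content_fmol,
                             matrix(nSymEach, n, k)),
        growth_div_d = ord(gHost, gSym),
        fix_rate_c_fmol_d = ord(xHost * hostBm$c_content_fmol / t,
                                xSym * matrix(cSymEach, n, k) / t),
        fix_rate_n_fmol_d = ord(phi * fTot,
                                xSymN * matrix(nSymEach, n, k) / t),
        a_c = roi$a_c_true,
        a_n = roi$a_n_true,
        saturated_n = ord(rep(FALSE, n), saturated) > 0,
        stringsAsFactors = FALSE)

    fSymNReal <- rowSums(xSymN * nSymEach) / t
    truthSymbioses <- data.frame(
        symbiosis_id = symIdx,
        n_symbionts = k,
        f_total_n_fmol_d = phi * fTot + fSymNReal,
        transfer_fraction_n = phi * fTot / (phi * fTot + fSymNReal),
        carbon_transfer_fraction = psi,
        growth_host_div_d = gHost,
        growth_sym_mean_div_d = rowMeans(gSym),
        implied_symbiont_density_fg_um3 = bp@symbiontCDensity,
        stringsAsFactors = FALSE)

    exper <- SipExperiment(roi[, .ROI_COLUMNS], labeling = lab, biomass = bp)
    list(experiment = exper, truthCells = truthCells,
         truthSymbioses = truthSymbioses)
}
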