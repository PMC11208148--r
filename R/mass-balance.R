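#' @include isotope-core.R
NULL

#' Partition fixed nitrogen between host and symbionts
#'
#' The host carries no nitrogenase, so all its excess \eqn{^{15}}N is
#' attributed to transfer from the symbionts. Total symbiosis fixation is the
#' symbiont-retained rate plus the host-recovered rate; the transfer fraction
#' is \eqn{\varphi = (F_{total} - F_{sym}) / F_{total}} and the amplification
#' factor \eqn{F_{total}/F_{sym}} says how much more nitrogen the symbionts
#' fix than they keep for their own growth.
#'
#' @param fHostN host-recovered N rate, fmol N d^-1.
#' @param fSymN summed symbiont-retained N rate, fmol N d^-1.
#' @return list with \code{f_total_n}, \code{f_sym_n},
#'   \code{transfer_fraction_n} (NA when nothing is fixed) and
#'   \code{amplification_n} (Inf when the symbionts retain nothing).
#' @examples
#' partitionNitrogen(643.5, 6.5)   # phi = 0.99, amplification = 100
#' @export
partitionNitrogen <- function(fHostN, fSymN) {
    if (any(fHostN < 0) || any(fSymN < 0))
        stop("rates must be non-negative (clamp upstream)")
    fTot <- fHostN + fSymN
    phi <- ifelse(fTot > 0, fHostN / fTot, NA_real_)
    amp <- ifelse(fTot > 0, ifelse(fSymN > 0, fTot / fSymN, Inf), NA_real_)
    list(f_total_n = fTot, f_sym_n = fSymN,
         transfer_fraction_n = phi, amplification_n = amp)
}

#' Partition fixed carbon between host and symbionts
#'
#' The carbon transfer fraction \eqn{\psi} is the share of total fixed carbon
#' that ends up in the heterotrophic symbionts:
#' \eqn{\psi = F_{sym,C} / (F_{host,C} + F_{sym,C})}.
#'
#' @param fHostC host CO2-fixation rate, fmol C d^-1.
#' @param fSymC summed symbiont C-uptake rate, fmol C d^-1.
#' @return list with \code{f_total_c} and \code{carbon_transfer_fraction}
#'   (NA when nothing is fixed).
#' @examples
#' partitionCarbon(2256, 22.79)    # psi ~ 0.01
#' @export
partitionCarbon <- function(fHostC, fSymC) {
    if (any(fHostC < 0) || any(fSymC < 0))
        stop("rates must be non-negative (clamp upstream)")
    fTot <- fHostC + fSymC
    psi <- ifelse(fTot > 0, fSymC / fTot, NA_real_)
    list(f_total_c = fTot, carbon_transfer_fraction = psi)
}

#' Mass-balanced growth rate of a whole symbiosis
#'
#' Combines member cells into one virtual cell: the carbon-content-weighted
#' mean \eqn{^{13}}C atom fraction \eqn{\bar A = \sum A_i C_i / \sum C_i} is
#' fed through \code{\link{growthRate}}.
#'
#' @param aC per-cell \eqn{^{13}}C atom fractions.
#' @param cContentFmol per-cell carbon contents, fmol.
#' @param labeling a \code{\link{LabelingConfig}}.
#' @return growth rate of the combined symbiosis, divisions per day.
#' @export
symbiosisGrowth <- function(aC, cContentFmol, labeling = LabelingConfig()) {
    if (length(aC) != length(cContentFmol) || length(aC) == 0L)
        stop("need matching non-empty atom-fraction and content vectors")
    if (any(cContentFmol <= 0))
        stop("carbon contents must be > 0")
    aBar <- sum(aC * cContentFmol) / sum(cContentFmol)
    growthRate(aBar, labeling@aNatC, labeling@aSourceC, labeling@tDays)
}

#' @rdname partitionSymbioses
#' @details Groups ROIs by \code{symbiosis_id}; each symbiosis must contain
#'   exactly one host and at least one symbiont. Symbiont rates are summed
#'   within the symbiosis before computing the transfer fraction phi, the
#'   amplification factor, and the carbon transfer fraction psi. Growth is
#'   reported for the host, as the symbiont mean, and mass-balanced across the
#'   whole symbiosis (carbon-content-weighted enrichment). The returned object
#'   carries pooled-total statistics (phi and psi computed on summed rates
#'   across all symbioses) in \code{metadata()}.
#' @examples
#' sim <- simulateSymbioses(SimConfig(nSymbioses = 2, fixedGeometry = TRUE))
#' partitionSymbioses(sim$experiment)
#' @export
setMethod("partitionSymbioses", "SipExperiment", function(x, ...) {
    rates <- cellRates(x)
    lab <- labelingConfig(x)
    ids <- unique(as.character(rates$symbiosis_id))
    rows <- lapply(ids, function(id) {
        sub <- rates[as.character(rates$symbiosis_id) == id, ]
        isHost <- sub$compartment == "host"
        if (sum(isHost) != 1L)
            stop(sprintf("symbiosis '%s' needs exactly one host ROI", id))
        if (sum(!isHost) < 1L)
            stop(sprintf("symbiosis '%s' needs at least one symbiont ROI", id))
        host <- sub[isHost, ]
        sym <- sub[!isHost, ]
        pn <- partitionNitrogen(host$fix_rate_n_fmol_d,
                                sum(sym$fix_rate_n_fmol_d))
        pc <- partitionCarbon(host$fix_rate_c_fmol_d,
                              sum(sym$fix_rate_c_fmol_d))
        data.frame(
            symbiosis_id = id,
            n_symbionts = nrow(sym),
            f_total_n_fmol_d = pn$f_total_n,
            f_sym_n_fmol_d = pn$f_sym_n,
            f_host_n_fmol_d = host$fix_rate_n_fmol_d,
            transfer_fraction_n = pn$transfer_fraction_n,
            amplification_n = pn$amplification_n,
            f_total_c_fmol_d = pc$f_total_c,
            f_sym_c_fmol_d = sum(sym$fix_rate_c_fmol_d),
            carbon_transfer_fraction = pc$carbon_transfer_fraction,
            growth_host_div_d = host$growth_div_d,
            growth_sym_mean_div_d = mean(sym$growth_div_d),
            growth_symbiosis_div_d = symbiosisGrowth(sub$a_c,
                                                     sub$c_content_fmol, lab),
            stringsAsFactors = FALSE)
    })
    out <- S4Vectors::DataFrame(do.call(rbind, rows))
    hostTot <- sum(out$f_host_n_fmol_d)
    symTot <- sum(out$f_sym_n_fmol_d)
    pooledN <- partitionNitrogen(hostTot, symTot)
    pooledC <- partitionCarbon(sum(out$f_total_c_fmol_d) - sum(out$f_sym_c_fmol_d),
                               sum(out$f_sym_c_fmol_d))
    S4Vectors::metadata(out) <- list(
        pooled_transfer_fraction_n = pooledN$transfer_fraction_n,
        pooled_amplification_n = pooledN$amplification_n,
        pooled_carbon_transfer_fraction = pooledC$carbon_transfer_fraction)
    out
})
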