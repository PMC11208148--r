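# Hand-built two-member symbiosis with known atom fractions, used by
# mass-balance tests. Atom fractions are chosen, converted to ratios, and the
# estimator must reproduce the implied rates from first principles.
makeManualExperiment <- function(aHostC, aHostN, aSymC, aSymN,
                                 labeling = LabelingConfig()) {
    k <- length(aSymC)
    rois <- data.frame(
        roi_id = c("s1_host", paste0("s1_symb", seq_len(k))),
        symbiosis_id = "s1",
        compartment = c("host", rep("symbiont", k)),
        ratio_c = atomFractionToRatio(c(aHostC, aSymC)),
        ratio_n = atomFractionToRatio(c(aHostN, aSymN)),
        counts_c_total = NA_real_, counts_n_total = NA_real_,
        length_um = c(40, rep(NA, k)),
        width_um = c(5, rep(NA, k)),
        diameter_um = c(NA, rep(1.5, k)),
        stringsAsFactors = FALSE)
    SipExperiment(rois, labeling = labeling)
}

relErr <- function(est, truth) {
    abs(est - truth) / pmax(abs(truth), .Machine$double.eps)
}
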