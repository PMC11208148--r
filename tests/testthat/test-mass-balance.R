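test_that("nitrogen partition yields transfer fraction and amplification", {
    p <- partitionNitrogen(643.5, 6.5)
    expect_equal(p$f_total_n, 650)
    expect_equal(p$transfer_fraction_n, 0.99)
    expect_equal(p$amplification_n, 100)
    # amplification = 1/(1 - phi) identity
    expect_equal(p$amplification_n, 1 / (1 - p$transfer_fraction_n))

    expect_equal(partitionNitrogen(10, 0)$transfer_fraction_n, 1)
    expect_identical(partitionNitrogen(10, 0)$amplification_n, Inf)
    expect_equal(partitionNitrogen(0, 10)$transfer_fraction_n, 0)
    expect_true(is.na(partitionNitrogen(0, 0)$transfer_fraction_n))
    expect_error(partitionNitrogen(-1, 5), "non-negative")
})

test_that("carbon partition yields the symbiont share of total fixed carbon", {
    p <- partitionCarbon(2256, 22.79)
    expect_equal(p$f_total_c, 2278.79)
    expect_equal(p$carbon_transfer_fraction, 22.79 / 2278.79)
    expect_equal(p$carbon_transfer_fraction, 0.0100, tolerance = 1e-3)
    expect_equal(partitionCarbon(100, 0)$carbon_transfer_fraction, 0)
    expect_equal(partitionCarbon(0, 5)$carbon_transfer_fraction, 1)
    expect_true(is.na(partitionCarbon(0, 0)$carbon_transfer_fraction))
})

test_that("symbiosis growth is the carbon-weighted combined rate", {
    lab <- LabelingConfig()
    aOf <- function(x) lab@aNatC + x * (lab@aSourceC - lab@aNatC)
    # all members identical -> same as the single-cell rate
    expect_equal(symbiosisGrowth(rep(aOf(0.3), 3), c(10, 5, 1), lab),
                 growthRate(aOf(0.3), lab@aNatC, lab@aSourceC, lab@tDays))
    # vanishing symbiont carbon -> host growth
    gH <- symbiosisGrowth(aOf(c(0.4257, 0.34)), c(1000, 1e-9), lab)
    expect_equal(gH, growthRate(aOf(0.4257), lab@aNatC, lab@aSourceC, 1),
                 tolerance = 1e-8)
    # 2.9% symbiont carbon weight: weighted-mean oracle
    w <- c(0.971, 0.029)
    xComb <- sum(w * c(0.4257, 0.3402))
    expect_equal(symbiosisGrowth(aOf(c(0.4257, 0.3402)), w * 100, lab),
                 -log1p(-xComb) / log(2))
    expect_equal(symbiosisGrowth(aOf(c(0.4257, 0.3402)), w * 100, lab),
                 0.793, tolerance = 2e-3)
    expect_error(symbiosisGrowth(numeric(0), numeric(0)), "non-empty")
})

test_that("partitionSymbioses balances a hand-built symbiosis", {
    lab <- LabelingConfig()
    aOf <- function(x, nat, src) nat + x * (src - nat)
    # host: x_c = 0.4, x_n = 0.6; two symbionts at x_c = 0.3, x_n = 0.45
    ex <- makeManualExperiment(
        aHostC = aOf(0.4, lab@aNatC, lab@aSourceC),
        aHostN = aOf(0.6, lab@aNatN, lab@aSourceN),
        aSymC = rep(aOf(0.3, lab@aNatC, lab@aSourceC), 2),
        aSymN = rep(aOf(0.45, lab@aNatN, lab@aSourceN), 2))
    p <- partitionSymbioses(ex)
    expect_equal(nrow(p), 1L)
    expect_equal(p$n_symbionts, 2L)

    bmH <- biomassFromVolume(pi / 4 * 40 * 25, "host")
    bmS <- biomassFromVolume(pi / 6 * 1.5^3, "symbiont")
    fHostN <- 0.6 * bmH$n_content_fmol
    fSymN <- 2 * 0.45 * bmS$n_content_fmol
    expect_equal(p$f_total_n_fmol_d, fHostN + fSymN)
    expect_equal(p$transfer_fraction_n, fHostN / (fHostN + fSymN))
    expect_equal(p$amplification_n, (fHostN + fSymN) / fSymN)
    fHostC <- 0.4 * bmH$c_content_fmol
    fSymC <- 2 * 0.3 * bmS$c_content_fmol
    expect_equal(p$carbon_transfer_fraction, fSymC / (fHostC + fSymC))
    expect_equal(p$growth_host_div_d, -log1p(-0.4) / log(2))
    expect_equal(p$growth_sym_mean_div_d, -log1p(-0.3) / log(2))
})

test_that("total fixation is additive in content-weighted enrichment", {
    # the estimator is linear in enrichment x content, so summing member
    # rates equals one rate computed from the pooled (weighted-mean)
    # enrichment and the pooled content
    sim <- simulateSymbioses(SimConfig(nSymbioses = 5, seed = 11))
    cr <- cellRates(sim$experiment)
    lab <- labelingConfig(sim$experiment)
    for (id in unique(cr$symbiosis_id)) {
        sub <- cr[cr$symbiosis_id == id, ]
        aBar <- sum(sub$a_n * sub$n_content_fmol) / sum(sub$n_content_fmol)
        pooled <- fixationRate(aBar, lab@aNatN, lab@aSourceN,
                               sum(sub$n_content_fmol), lab@tDays)
        expect_equal(sum(sub$fix_rate_n_fmol_d), pooled, tolerance = 1e-12)
    }
})

test_that("pooled statistics match per-symbiosis values on homogeneous data", {
    sim <- simulateSymbioses(SimConfig(nSymbioses = 8, fixedGeometry = TRUE))
    p <- partitionSymbioses(sim$experiment)
    md <- S4Vectors::metadata(p)
    expect_equal(md$pooled_transfer_fraction_n, 0.99, tolerance = 1e-12)
    expect_equal(md$pooled_amplification_n, 100, tolerance = 1e-9)
    expect_equal(md$pooled_carbon_transfer_fraction, 0.01, tolerance = 1e-12)
})

test_that("malformed symbioses are rejected", {
    sim <- simulateSymbioses(SimConfig(nSymbioses = 2, fixedGeometry = TRUE))
    rois <- as.data.frame(roiData(sim$experiment))
    # drop all symbionts of the first symbiosis
    broken <- rois[!(rois$symbiosis_id == "sym0001" &
                     rois$compartment == "symbiont"), ]
    expect_error(partitionSymbioses(SipExperiment(broken)),
                 "at least one symbiont")
    # a second host in one symbiosis fails validity up front
    dup <- rois
    dup$compartment[dup$roi_id == "sym0001_symb1"] <- "host"
    dup$length_um[dup$roi_id == "sym0001_symb1"] <- 30
    dup$width_um[dup$roi_id == "sym0001_symb1"] <- 4
    expect_error(SipExperiment(dup), "at most one host")
})
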