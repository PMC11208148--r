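test_that("ratio/atom-fraction conversions are exact inverses and correct", {
    expect_identical(ratioToAtomFraction(0), 0)
    expect_identical(ratioToAtomFraction(1), 0.5)
    # natural 13C ratio evaluates to the natural atom fraction
    expect_equal(ratioToAtomFraction(0.0111802), 0.011056, tolerance = 1e-6 / 0.011)
    expect_error(ratioToAtomFraction(-0.1), "ratios")
    expect_error(atomFractionToRatio(1), "\\[0, 1\\)")

    a <- seq(0, 0.999, length.out = 200)
    expect_equal(ratioToAtomFraction(atomFractionToRatio(a)), a,
                 tolerance = 1e-12)
    r <- c(0, 10^seq(-6, 3, length.out = 100))
    expect_true(all(diff(ratioToAtomFraction(r)) > 0))
    expect_true(all(ratioToAtomFraction(r) >= 0 & ratioToAtomFraction(r) < 1))
})

test_that("biovolume uses elliptic-cylinder hosts and spherical symbionts", {
    expect_equal(roiBiovolume("host", length_um = 40, width_um = 5),
                 pi / 4 * 40 * 25)
    expect_equal(roiBiovolume("host", length_um = 40, width_um = 5),
                 785.398, tolerance = 1e-5)
    expect_equal(roiBiovolume("symbiont", diameter_um = 1.5),
                 pi / 6 * 1.5^3)
    expect_equal(roiBiovolume("symbiont", diameter_um = 1.5),
                 1.767, tolerance = 1e-3)
    expect_error(roiBiovolume("host", length_um = 0, width_um = 5),
                 "dimensions")
    expect_error(roiBiovolume("host", length_um = 40), "length_um and width_um")
    expect_error(roiBiovolume("symbiont"), "diameter_um")
})

test_that("biomass conversion follows host allometry and symbiont density", {
    v <- 785.398
    host <- biomassFromVolume(v, "host")
    pgC <- 0.288 * v^0.811
    expect_equal(host$c_content_fmol, pgC * 1000 / 12)
    expect_equal(host$c_content_fmol, 5345, tolerance = 1e-3)
    expect_equal(host$n_content_fmol, pgC * 1000 / 12 / 6.625)
    expect_equal(host$n_content_fmol, 806.8, tolerance = 1e-3)

    sym <- biomassFromVolume(1.767, "symbiont")
    expect_equal(sym$c_content_fmol, 112 * 1.767 / 12)
    expect_equal(sym$c_content_fmol, 16.49, tolerance = 1e-3)
    expect_equal(sym$n_content_fmol, 3.30, tolerance = 1e-2)

    # C:N of 1 makes carbon and nitrogen content identical
    one <- biomassFromVolume(123, "host", BiomassParams(cnHost = 1))
    expect_identical(one$c_content_fmol, one$n_content_fmol)
    expect_error(biomassFromVolume(0, "host"), "> 0")
    expect_error(biomassFromVolume(-1, "symbiont"), "> 0")
})

test_that("fixation rate is the linear-incorporation estimator", {
    expect_equal(fixationRate(0.003663, 0.003663, 0.05, 800, 1), 0)
    # direct arithmetic oracle
    expect_equal(fixationRate(0.0268, 0.003663, 0.05, 800, 1),
                 (0.0268 - 0.003663) / (0.05 - 0.003663) * 800)
    expect_equal(fixationRate(0.0268, 0.003663, 0.05, 800, 1),
                 399.5, tolerance = 1e-3)
    # linear in content
    expect_equal(fixationRate(0.02, 0.003663, 0.05, 1600, 1),
                 2 * fixationRate(0.02, 0.003663, 0.05, 800, 1))
    expect_error(fixationRate(0.02, 0.05, 0.05, 800, 1), "aSource")
    expect_warning(r <- fixationRate(0.001, 0.003663, 0.05, 800, 1),
                   "clamped")
    expect_identical(r, 0)
})

test_that("fixation rate is invariant under affine rescaling of atom fractions", {
    base <- fixationRate(0.0268, 0.003663, 0.05, 800, 1)
    for (sc in c(0.5, 2, 10)) {
        for (sh in c(-0.001, 0, 0.01)) {
            expect_equal(fixationRate(sc * 0.0268 + sh, sc * 0.003663 + sh,
                                      sc * 0.05 + sh, 800, 1),
                         base, tolerance = 1e-12)
        }
    }
})

test_that("growth rate inverts the exponential-labeling forward model", {
    expect_equal(growthRate(0, 0, 1, 1), 0)
    expect_equal(growthRate(0.5, 0, 1, 1), 1)
    expect_equal(growthRate(0.75, 0, 1, 1), 2)
    expect_error(growthRate(1, 0, 1, 1), "saturat")
    expect_warning(g <- growthRate(0.001, 0.003663, 0.05, 1), "clamped")
    expect_identical(g, 0)

    # round trip growth -> label fraction -> growth, over rates and durations
    lab <- LabelingConfig()
    for (t in c(0.5, 1, 3)) {
        g <- seq(0, 5, length.out = 101)
        x <- growthToNewFraction(g, t)
        a <- lab@aNatC + x * (lab@aSourceC - lab@aNatC)
        expect_true(all(relErr(growthRate(a, lab@aNatC, lab@aSourceC, t), g)
                        < 1e-9 | g == 0))
    }

    # strictly increasing in measured enrichment
    a <- seq(0.012, 0.0499, length.out = 50)
    expect_true(all(diff(growthRate(a, 0.011056, 0.05, 1)) > 0))
    a2 <- seq(0.004, 0.0499, length.out = 50)
    r <- fixationRate(a2, 0.003663, 0.05, 100, 1)
    expect_true(all(diff(r) > 0))
})

test_that("cellRates reproduces per-cell truth on noise-free simulations", {
    sim <- simulateSymbioses(SimConfig(nSymbioses = 6, seed = 42))
    cr <- cellRates(sim$experiment)
    tc <- sim$truthCells
    expect_identical(as.character(cr$roi_id), tc$roi_id)
    expect_true(all(relErr(cr$c_content_fmol, tc$c_content_fmol) < 1e-9))
    expect_true(all(relErr(cr$n_content_fmol, tc$n_content_fmol) < 1e-9))
    expect_true(all(relErr(cr$fix_rate_n_fmol_d, tc$fix_rate_n_fmol_d) < 1e-9))
    expect_true(all(relErr(cr$fix_rate_c_fmol_d, tc$fix_rate_c_fmol_d) < 1e-9))
    expect_true(all(relErr(cr$growth_div_d, tc$growth_div_d) < 1e-9))
})
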