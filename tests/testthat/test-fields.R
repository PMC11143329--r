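test_that("electrode geometry follows the registry", {
    el <- buildElectrode("medtronic-3389", c(0, 0, 0), c(0, 0, 1))
    expect_equal(contactCenters(el)[, 3], c(0.75, 2.75, 4.75, 6.75))
    expect_equal(contactCenters(el)[, 1], rep(0, 4))
    expect_error(buildElectrode("medtronic-3389", c(0, 0, 0), c(0, 0, 2)),
                 "unit vector")
    expect_error(buildElectrode("no-such-lead", c(0, 0, 0), c(0, 0, 1)),
                 "unknown electrode model")
    # rotating a directional lead by 120 degrees maps segment a onto b
    c0 <- buildElectrode("bsc-vercise-cartesia", c(0, 0, 0), c(0, 0, 1),
                         rotation = 0)
    c120 <- buildElectrode("bsc-vercise-cartesia", c(0, 0, 0), c(0, 0, 1),
                           rotation = 120)
    expect_equal(contactCenters(c120)[2, ], contactCenters(c0)[3, ],
                 tolerance = 1e-9)
    expect_equal(contactCenters(c120)[4, ], contactCenters(c0)[2, ],
                 tolerance = 1e-9)
})

test_that("point-source field matches the closed form", {
    el <- buildElectrode("medtronic-3389", c(0, 0, 0), c(0, 0, 1))
    g <- simulateEField(el, StimulationSetting(c(-3, 0, 0, 0)))
    # |E| at r = 3 mm from a 3 mA source in sigma = 0.2 S/m:
    # 0.003 / (4 pi 0.2 (0.003)^2) ~ 132.6 V/m = 0.1326 V/mm
    src <- contactCenters(el)[1, ]
    d <- dim(gridValues(g))
    coords <- as.matrix(expand.grid(
        gridOrigin(g)[1] + (seq_len(d[1]) - 1) * gridSpacing(g)[1],
        gridOrigin(g)[2] + (seq_len(d[2]) - 1) * gridSpacing(g)[2],
        gridOrigin(g)[3] + (seq_len(d[3]) - 1) * gridSpacing(g)[3]))
    r <- sqrt(colSums((t(coords) - src)^2))
    keep <- r >= 0.5
    expected <- pointSourceMagnitude(3, 0.2, r[keep])
    expect_lt(max(abs(as.numeric(gridValues(g))[keep] - expected) /
                  expected), 0.01)
    expect_equal(pointSourceMagnitude(3, 0.2, 3), 0.13263, tolerance = 1e-4)
    # radius at which |E| = 1.5 V/mm
    rStar <- sqrt(0.003 / (4 * pi * 0.2 * 1500)) * 1000
    expect_equal(rStar, 0.892, tolerance = 1e-3)
    expect_equal(pointSourceMagnitude(3, 0.2, rStar), 1.5, tolerance = 1e-9)
})

test_that("field superposition and linearity hold voxelwise", {
    el <- buildElectrode("medtronic-3389", c(0, 0, 0), c(0, 0, 1))
    g1 <- simulateEField(el, StimulationSetting(c(-2, 0, 0, 0)))
    g2 <- simulateEField(el, StimulationSetting(c(0, 0, 0, -1)))
    g12 <- simulateEField(el, StimulationSetting(c(-2, 0, 0, -1)))
    gd <- simulateEField(el, StimulationSetting(c(-4, 0, 0, 0)))
    # doubling the current doubles every voxel magnitude
    expect_equal(gridValues(gd), 2 * gridValues(g1), tolerance = 1e-12)
    # vector superposition: co-directed cathodic sources along one axis add
    # to at least the in-between difference and at most the sum
    expect_true(all(gridValues(g12) <= gridValues(g1) + gridValues(g2) + 1e-9))
    expect_true(all(gridValues(g12) >=
                    abs(gridValues(g1) - gridValues(g2)) - 1e-9))
    expect_warning(z <- simulateEField(el, StimulationSetting(c(0, 0, 0, 0))),
                   "all-zero")
    expect_true(all(gridValues(z) == 0))
})

test_that("peak sampling along streamlines behaves geometrically", {
    el <- buildElectrode("medtronic-3389", c(0, 0, 0), c(0, 0, 1))
    g <- simulateEField(el, StimulationSetting(c(-3, 0, 0, 0)))
    # streamline passing at a closest approach of 3 mm (grid-aligned)
    sl <- cbind(3, seq(-5, 5, by = 0.5), 0.75)
    expect_equal(peakFieldAlong(g, sl), 0.1326, tolerance = 0.02)
    expect_equal(peakFieldAlong(g, sl[rev(seq_len(nrow(sl))), ]),
                 peakFieldAlong(g, sl))              # order invariance
    far <- cbind(100 + 0:5, 0, 0)
    expect_equal(peakFieldAlong(g, far), 0)          # outside the grid
    # monotone in current magnitude
    g2 <- simulateEField(el, StimulationSetting(c(-4, 0, 0, 0)))
    expect_gte(peakFieldAlong(g2, sl), peakFieldAlong(g, sl))
})

test_that("mirroring negates x and is an involution", {
    p <- rbind(c(10, -12, -7), c(1, 2, 3))
    expect_equal(mirror(p)[1, ], c(-10, -12, -7))
    expect_equal(mirror(mirror(p)), p, tolerance = 1e-9)
    tiny <- tinyStudy()
    g <- cohortFields(tiny$cohort)[[1]]
    gm <- mirror(g)
    expect_equal(provenance(gm), "mirrored")
    gmm <- mirror(gm)
    expect_equal(gridOrigin(gmm), gridOrigin(g), tolerance = 1e-9)
    expect_equal(gridValues(gmm), gridValues(g), tolerance = 0,
                 ignore_attr = TRUE)
    # a grid symmetric about x = 0 is unchanged
    sym <- EFieldGrid(array(rep(c(1, 2, 1), 9), c(3, 3, 3)),
                      origin = c(-1, 0, 0), spacing = c(1, 1, 1))
    ms <- mirror(sym)
    expect_equal(gridOrigin(ms), gridOrigin(sym))
    expect_equal(gridValues(ms), gridValues(sym), ignore_attr = TRUE)
})

test_that("jitter translates grids by a seeded Gaussian displacement", {
    spec <- jitterSpec(fwhm = 2)
    expect_equal(spec$sigma, 0.84932, tolerance = 1e-4)
    g <- EFieldGrid(array(1, c(3, 3, 3)), c(0, 0, 0), c(1, 1, 1))
    j1 <- jitterField(g, jitterSpec(2, seed = 11))
    j2 <- jitterField(g, jitterSpec(2, seed = 11))
    expect_equal(gridOrigin(j1), gridOrigin(j2))       # seed determinism
    expect_equal(gridValues(j1), gridValues(g), ignore_attr = TRUE)
    expect_equal(provenance(j1), "jittered")
    # vanishing width leaves the grid in place
    j0 <- jitterField(g, jitterSpec(1e-12, seed = 1))
    expect_equal(gridOrigin(j0), gridOrigin(g), tolerance = 1e-9)
    # displacements across seeds have roughly the configured SD
    d <- t(vapply(1:200, function(s)
        gridOrigin(jitterField(g, jitterSpec(2, seed = s))), numeric(3)))
    expect_equal(sd(as.numeric(d)), 0.84932, tolerance = 0.15)
})

test_that("peak matrices carry mirrored columns equivalent to mirrored grids", {
    tiny <- tinyStudy()
    tg <- Tractogram(streamlines(tiny$atlas)[1:10])
    fields <- cohortFields(tiny$cohort)[1:2]
    P <- computePeakMatrix(tg, fields)
    expect_equal(dim(P), c(10L, 4L))
    expect_equal(attr(P, "fieldIndex"), c(1L, 2L, 1L, 2L))
    # mirrored column equals sampling the explicitly mirrored grid
    gm <- mirror(fields[[1]])
    direct <- vapply(streamlines(tg), function(s) peakFieldAlong(gm, s),
                     numeric(1))
    expect_equal(unname(P[, 3]), direct, tolerance = 1e-9)
})
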