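# Shared synthetic studies, built once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

# Small study for unit tests: 24 patients, 5 x 40 x 2 = 400 streamlines.
tinyStudy <- function() {
    if (!is.null(.fixtures$tiny)) return(.fixtures$tiny)
    sc <- synthConfig(nPatients = 24L, streamlinesPerBundle = 40L)
    at <- generateAtlas(sc, seed = 7)
    co <- generateCohort(at$tractogram, at$truth, sc, seed = 7)
    peaks <- computePeakMatrix(at$tractogram, cohortFields(co))
    model <- suppressWarnings(
        buildTractModel(co, at$tractogram, peaks = peaks))
    maps <- fitCohortMaps(co, model, peaks = peaks)
    .fixtures$tiny <- list(sc = sc, atlas = at$tractogram, truth = at$truth,
                           cohort = co, peaks = peaks, model = model,
                           maps = maps)
    .fixtures$tiny
}

# Full default study (n = 120, 2000 streamlines) for the acceptance suite.
defaultStudy <- function() {
    if (!is.null(.fixtures$default)) return(.fixtures$default)
    sc <- synthConfig()
    at <- generateAtlas(sc, seed = 1)
    co <- generateCohort(at$tractogram, at$truth, sc, seed = 1)
    peaks <- computePeakMatrix(at$tractogram, cohortFields(co))
    model <- buildTractModel(co, at$tractogram, peaks = peaks)
    maps <- fitCohortMaps(co, model, peaks = peaks)
    .fixtures$default <- list(sc = sc, atlas = at$tractogram,
                              truth = at$truth, cohort = co, peaks = peaks,
                              model = model, maps = maps)
    .fixtures$default
}

# Three-streamline toy tractogram with labels.
toyTractogram <- function() {
    Tractogram(list(cbind(c(0, 1, 2), c(0, 0.5, 1), c(0, 0, 0)),
                    cbind(c(-3, -2), c(1, 1), c(2, 2.5)),
                    cbind(c(10, 11, 12, 13), c(-12, -12, -12, -12),
                          c(-7, -6.5, -6, -5.5))),
               bundleLabels = c("a", "b", "a"), spaceTag = "toy")
}

# Point-source closed form (V/mm) for currents (mA) at mm distances.
pointSourceMagnitude <- function(I_mA, sigma, r_mm) {
    abs(I_mA) * 1e-3 / (4 * pi * sigma * (r_mm * 1e-3)^2) / 1000
}
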