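#' Synthetic study configuration
#'
#' Defines the synthetic study conditions: a five-bundle pathway atlas with
#' a rostrocaudal (dorsoventral along the lead axis) symptom gradient near
#' a nominal subthalamic target, bilateral four-contact electrodes with
#' monopolar cathodic settings, and improvements generated as a noisy
#' saturating function of field-bundle overlap. Baselines are calibrated so
#' the summed global baseline has mean about 44.6 and SD about 14.3 points.
#'
#' @param nPatients Cohort size (default 120).
#' @param streamlinesPerBundle Streamlines per bundle per hemisphere
#'   (default 200).
#' @param bundleSpacing Spacing of bundle spines along the gradient axis,
#'   mm (default 1.5).
#' @param target Nominal right-hemisphere target, mm (default
#'   (12, -13, -6); the left side is its mirror).
#' @param scatterSigma Per-streamline parallel scatter SD, mm (default 0.8).
#' @param placementSigma Electrode placement jitter SD, mm (default 1.0).
#' @param ampRange Monopolar amplitude range, mA (default 1 to 4).
#' @param noiseSigma Improvement noise SD, percent points (default 10).
#' @param betaMax Maximal symptom response, percent (default 70).
#' @param eRef Activation reference field magnitude, V/mm (default 0.2).
#' @param baselineMeans,baselineSds Per-symptom baseline moments (points)
#'   of the underlying normals; the tremor mean is set below its target
#'   because flooring at zero truncates a substantial left tail (the
#'   realized tremor mean is about 4.6 and the realized summed baseline
#'   about 44.6).
#' @param baselineShared Shared-severity loading as a fraction of each SD
#'   (default 0.5), giving the summed baseline an SD near 14.3.
#' @return List of class "SynthConfig".
#' @export
synthConfig <- function(nPatients = 120L, streamlinesPerBundle = 200L,
                        bundleSpacing = 1.5, target = c(12, -13, -6),
                        scatterSigma = 0.8, placementSigma = 1.0,
                        ampRange = c(1, 4), noiseSigma = 10, betaMax = 70,
                        eRef = 0.2,
                        baselineMeans = c(tremor = 3.9, bradykinesia = 18.5,
                                          rigidity = 9.0, axial = 12.5),
                        baselineSds = c(tremor = 5.24, bradykinesia = 7.5,
                                        rigidity = 4.0, axial = 5.5),
                        baselineShared = 0.5) {
    stopifnot(scatterSigma > 0, placementSigma > 0, noiseSigma >= 0,
              eRef > 0, betaMax >= 0)
    structure(list(nPatients = as.integer(nPatients),
                   streamlinesPerBundle = as.integer(streamlinesPerBundle),
                   bundleSpacing = bundleSpacing, target = target,
                   scatterSigma = scatterSigma,
                   placementSigma = placementSigma, ampRange = ampRange,
                   noiseSigma = noiseSigma, betaMax = betaMax, eRef = eRef,
                   baselineMeans = baselineMeans, baselineSds = baselineSds,
                   baselineShared = baselineShared,
                   bundles = c("tremor", "bradykinesia", "axial",
                               "rigidity", "distractor")),
              class = "SynthConfig")
}

# Bundle spine z-offsets along the lead axis, ventral (caudal) to dorsal:
# tremor deepest, then bradykinesia, axial, rigidity, distractor. Centered
# so contacts of a lead with tip ~5 mm below the target straddle them.
.bundleZ <- function(config) {
    k <- seq_along(config$bundles) - 3L            # -2 .. 2
    config$target[3] - 0.75 + k * config$bundleSpacing
}

# Smooth spine through the subthalamic region: runs anterior-posterior with
# a gentle lateral and dorsal sweep away from the target.
.bundleSpine <- function(config, z0) {
    y <- seq(-33, 7, by = 2)
    x <- config$target[1] + 3 * ((y - config$target[2]) / 20)^2
    z <- z0 + 2 * ((y - config$target[2]) / 25)^2
    cbind(x, y, z)
}

#' Generate a synthetic pathway atlas with ground truth
#'
#' Each bundle is a smooth spine plus Gaussian-scattered parallel
#' streamlines, resampled at 0.5 mm, mirrored into both hemispheres.
#' The returned ground truth records the bundle (symptom) of every
#' streamline, the per-symptom response gains, and the activation
#' reference.
#'
#' @param config A \code{\link{synthConfig}}.
#' @param seed Integer seed.
#' @return List with \code{tractogram} (a \linkS4class{Tractogram} with
#'   bundle labels) and \code{truth} (bundle assignment, beta, eRef).
#' @export
generateAtlas <- function(config = synthConfig(), seed = 1) {
    set.seed(deriveSeed(seed, "atlas"))
    zs <- .bundleZ(config)
    streamlines <- list()
    labels <- character()
    for (b in seq_along(config$bundles)) {
        spine <- .bundleSpine(config, zs[b])
        for (s in seq_len(config$streamlinesPerBundle)) {
            offset <- stats::rnorm(2L, 0, config$scatterSigma)
            sl <- spine
            sl[, 1] <- sl[, 1] + offset[1]
            sl[, 3] <- sl[, 3] + offset[2]
            streamlines[[length(streamlines) + 1L]] <- .resamplePolyline(sl, 0.5)
            labels <- c(labels, config$bundles[b])
        }
    }
    # mirror every bundle into the left hemisphere
    nR <- length(streamlines)
    for (i in seq_len(nR))
        streamlines[[nR + i]] <- mirror(streamlines[[i]])
    labels <- c(labels, labels[seq_len(nR)])
    beta <- stats::setNames(rep(config$betaMax, length(config$bundles)),
                            config$bundles)
    beta["distractor"] <- 0
    list(tractogram = Tractogram(streamlines, bundleLabels = labels,
                                 spaceTag = "synthetic-MNI"),
         truth = list(bundle = labels, beta = beta, eRef = config$eRef))
}

.symptomsOf <- function(config) setdiff(config$bundles, "distractor")

# Saturating activation of each bundle by a set of fields: for each field,
# the mean over the bundle's ipsilateral streamlines (a unilateral field
# can only reach its own hemisphere's copy; a field saturating the bundle
# thus reaches activation 1) of min(peak / eRef, 1), averaged over fields.
# `fiberSide`/`fieldSide` are the signs of the x coordinates.
.bundleActivation <- function(peakMatrix, truth, eRef, fiberSide, fieldSide) {
    bundles <- unique(truth$bundle)
    act <- vapply(bundles, function(b) {
        perField <- vapply(seq_len(ncol(peakMatrix)), function(f) {
            rows <- truth$bundle == b & fiberSide == fieldSide[f]
            mean(pmin(peakMatrix[rows, f] / eRef, 1))
        }, numeric(1))
        mean(perField)
    }, numeric(1))
    names(act) <- bundles
    act
}

.streamlineSides <- function(tractogram) {
    vapply(tractogram@streamlines, function(s) sign(mean(s[, 1])), numeric(1))
}

.gridSide <- function(grid) {
    d <- dim(grid@values)
    sign(grid@origin[1] + (d[1] - 1) * grid@spacing[1] / 2)
}

#' Simulate symptom improvements from field-bundle overlap
#'
#' The generative model the filtering/blending stack assumes: activation of
#' symptom bundle s is the mean saturating overlap \code{min(peak/eRef, 1)}
#' of its streamlines, averaged over the patient's fields; the improvement
#' is \code{clip(beta_s * activation_s + noise, -20, 100)} percent. Uses
#' the current RNG state (seed at the caller).
#'
#' @param fields List of the patient's \linkS4class{EFieldGrid}s.
#' @param atlas Tractogram from \code{\link{generateAtlas}}.
#' @param truth Ground truth from \code{\link{generateAtlas}}.
#' @param config A \code{\link{synthConfig}}.
#' @return Named numeric vector of percent improvements per symptom.
#' @export
simulateImprovements <- function(fields, atlas, truth,
                                 config = synthConfig()) {
    P <- computePeakMatrix(atlas, fields, mirrored = FALSE)
    act <- .bundleActivation(P, truth, config$eRef,
                             .streamlineSides(atlas),
                             vapply(fields, .gridSide, numeric(1)))
    syms <- .symptomsOf(config)
    imp <- truth$beta[syms] * act[syms] +
        stats::rnorm(length(syms), 0, config$noiseSigma)
    .clip(stats::setNames(imp, syms), -20, 100)
}

# Per-symptom baselines: truncated normals with a shared severity factor
# (loading baselineShared * SD) so the summed baseline matches the global
# mean/SD calibration. Rounded to whole points, floored at zero; profiles
# summing below 10 points (implausible for a surgical cohort) are redrawn.
.drawBaselines <- function(n, config) {
    syms <- names(config$baselineMeans)
    draw <- function(k) {
        z <- stats::rnorm(k)
        out <- matrix(0, k, length(syms), dimnames = list(NULL, syms))
        for (s in syms) {
            mu <- config$baselineMeans[[s]]
            sd <- config$baselineSds[[s]]
            lo <- config$baselineShared
            x <- mu + lo * sd * z + sd * sqrt(1 - lo^2) * stats::rnorm(k)
            out[, s] <- pmax(round(x), 0)
        }
        out
    }
    out <- draw(n)
    for (iter in seq_len(50L)) {
        low <- which(rowSums(out) < 10)
        if (!length(low)) break
        out[low, ] <- draw(length(low))
    }
    out
}

#' Generate a synthetic DBS cohort
#'
#' Places bilateral four-contact electrodes with Gaussian placement jitter
#' near the nominal target, draws a random active contact and a monopolar
#' cathodic amplitude per hemisphere, simulates the stimulation fields, and
#' generates baselines and improvements from the ground truth.
#'
#' @param atlas,truth Output of \code{\link{generateAtlas}}.
#' @param config A \code{\link{synthConfig}}.
#' @param seed Integer seed.
#' @param fieldConfig A \code{\link{fieldModelConfig}}.
#' @return A \linkS4class{DBSCohort}.
#' @export
generateCohort <- function(atlas, truth, config = synthConfig(), seed = 1,
                           fieldConfig = fieldModelConfig()) {
    set.seed(deriveSeed(seed, "cohort"))
    n <- config$nPatients
    syms <- .symptomsOf(config)
    baselines <- .drawBaselines(n, config)
    fields <- vector("list", 2L * n)
    electrodes <- vector("list", 2L * n)
    settings <- vector("list", 2L * n)
    fieldPatient <- integer(2L * n)
    imp <- matrix(NA_real_, n, length(syms), dimnames = list(NULL, syms))
    stk <- .stackStreamlines(atlas@streamlines, 0.5)
    fiberSide <- .streamlineSides(atlas)
    for (i in seq_len(n)) {
        patFields <- list()
        for (side in 1:2) {
            sgn <- if (side == 1L) 1 else -1
            tip <- c(sgn * config$target[1], config$target[2],
                     config$target[3] - 5) +
                stats::rnorm(3L, 0, config$placementSigma)
            el <- buildElectrode("medtronic-3389", tip, c(0, 0, 1))
            contact <- sample(4L, 1L)
            amp <- stats::runif(1L, config$ampRange[1], config$ampRange[2])
            cur <- numeric(4L)
            cur[contact] <- -amp
            st <- StimulationSetting(cur)
            g <- simulateEField(el, st, fieldConfig)
            j <- 2L * (i - 1L) + side
            fields[[j]] <- g
            electrodes[[j]] <- el
            settings[[j]] <- st
            fieldPatient[j] <- i
            patFields[[side]] <- list(grid = g)
        }
        # activation from the two native fields (no mirroring in the truth)
        pk <- vapply(patFields, function(f)
            cppPeaksGrid(stk$pts, stk$offsets, as.numeric(f$grid@values),
                         dim(f$grid@values), f$grid@origin, f$grid@spacing),
            numeric(length(atlas@streamlines)))
        act <- .bundleActivation(pk, truth, config$eRef, fiberSide,
                                 vapply(patFields, function(f)
                                     .gridSide(f$grid), numeric(1)))
        imp[i, ] <- .clip(truth$beta[syms] * act[syms] +
                              stats::rnorm(length(syms), 0, config$noiseSigma),
                          -20, 100)
    }
    pt <- data.frame(id = sprintf("P%03d", seq_len(n)),
                     center = "synthetic",
                     age = round(stats::rnorm(n, 60, 8)),
                     sex = sample(c("f", "m"), n, replace = TRUE))
    for (s in syms) {
        pt[[paste0("baseline_", s)]] <- baselines[, s]
        pt[[paste0("improvement_", s)]] <- imp[, s]
        pt[[paste0("post_", s)]] <- baselines[, s] * (1 - imp[, s] / 100)
    }
    glob <- rowSums(baselines[, syms, drop = FALSE])
    wimp <- rowSums(baselines[, syms] * imp) / pmax(glob, 1e-9)
    wimp[glob == 0] <- NA_real_
    pt$baseline_global <- glob
    pt$improvement_global <- wimp
    pt$post_global <- glob * (1 - wimp / 100)
    new("DBSCohort", patients = pt, fields = fields,
        fieldPatient = fieldPatient, electrodes = electrodes,
        settings = settings, symptoms = syms)
}

#' Generate synthetic monopolar-review data
#'
#' For each synthetic electrode, every contact is tested at each amplitude
#' (monopolar cathodic), and per-setting empirical improvements are drawn
#' from the ground-truth dose-response of that single field.
#'
#' @param atlas,truth Output of \code{\link{generateAtlas}}.
#' @param config A \code{\link{synthConfig}}.
#' @param nElectrodes Number of electrodes (default 10).
#' @param amplitudes Tested amplitudes, mA (default 1, 2, 3).
#' @param seed Integer seed.
#' @param fieldConfig A \code{\link{fieldModelConfig}}.
#' @return List, one entry per electrode: \code{fields} (per setting),
#'   \code{empirical} (matrix setting x symptom), \code{electrode}.
#' @export
generateMonopolarReview <- function(atlas, truth, config = synthConfig(),
                                    nElectrodes = 10L,
                                    amplitudes = c(1, 2, 3), seed = 1,
                                    fieldConfig = fieldModelConfig()) {
    set.seed(deriveSeed(seed, "monopolar"))
    syms <- .symptomsOf(config)
    stk <- .stackStreamlines(atlas@streamlines, 0.5)
    fiberSide <- .streamlineSides(atlas)
    out <- vector("list", nElectrodes)
    for (e in seq_len(nElectrodes)) {
        sgn <- if (e %% 2L == 0L) -1 else 1
        tip <- c(sgn * config$target[1], config$target[2],
                 config$target[3] - 5) +
            stats::rnorm(3L, 0, config$placementSigma)
        el <- buildElectrode("medtronic-3389", tip, c(0, 0, 1))
        fieldsE <- list()
        emp <- NULL
        for (contact in 1:4) for (amp in amplitudes) {
            cur <- numeric(4L)
            cur[contact] <- -amp
            g <- simulateEField(el, StimulationSetting(cur), fieldConfig)
            pk <- cppPeaksGrid(stk$pts, stk$offsets, as.numeric(g@values),
                               dim(g@values), g@origin, g@spacing)
            act <- .bundleActivation(cbind(pk), truth, config$eRef,
                                     fiberSide, .gridSide(g))
            impRow <- .clip(truth$beta[syms] * act[syms] +
                                stats::rnorm(length(syms), 0,
                                             config$noiseSigma),
                            -20, 100)
            fieldsE[[length(fieldsE) + 1L]] <- g
            emp <- rbind(emp, impRow)
        }
        rownames(emp) <- NULL
        colnames(emp) <- syms
        out[[e]] <- list(fields = fieldsE, empirical = emp, electrode = el)
    }
    out
}
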