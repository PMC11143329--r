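.pipelineCommands <- c("synth", "simulate-field", "filter", "blend",
                       "crossval", "permute", "jitter", "cleartune",
                       "monopolar-validate", "convert")

# Regenerate the configured synthetic study (atlas + cohort) from a seed.
.synthBundle <- function(config, seed) {
    sc <- do.call(synthConfig, config$synth %||% list())
    atlas <- generateAtlas(sc, seed = seed)
    cohort <- generateCohort(atlas$tractogram, atlas$truth, sc, seed = seed)
    list(sc = sc, atlas = atlas$tractogram, truth = atlas$truth,
         cohort = cohort)
}

.modelSummary <- function(model) {
    lapply(model@stats, function(st)
        list(screened = sum(st$screened),
             significant = sum(st$q < model@selection$alpha, na.rm = TRUE),
             selected = sum(st$selected),
             topRho = max(st$rho, na.rm = TRUE)))
}

#' Run a pipeline command with reproducibility metadata
#'
#' Config-driven orchestration over the package's functions. Every command
#' derives named sub-seeds from the global seed (so each stochastic stage
#' is independently reproducible), writes its artifacts under
#' \code{outDir}, and records a deterministic run manifest (command, config
#' hash, seeds, package version). Re-running an identical config reproduces
#' all stochastic outputs.
#'
#' Commands: \code{synth} (write synthetic atlas/cohort/truth),
#' \code{simulate-field}, \code{filter} (build and serialize the tract
#' model), \code{blend}/\code{crossval}, \code{permute}, \code{jitter}
#' (jitter-robustness analysis), \code{cleartune},
#' \code{monopolar-validate}, and \code{convert} (tractogram format
#' conversion).
#'
#' @param command One of the commands above.
#' @param config Named list or path to a YAML file. Recognized sections:
#'   \code{synth} (arguments of \code{\link{synthConfig}}), \code{screening},
#'   \code{selection}, \code{cv}, \code{cleartune}, \code{jitter}
#'   (\code{fwhm}, \code{nRepeats}), plus command-specific paths
#'   (\code{in}, \code{out}, \code{format}, \code{writeFields}).
#' @param seed Global integer seed.
#' @param outDir Output directory (default a fresh temporary directory).
#' @return List with \code{manifest} and command-specific results,
#'   invisibly for file-writing commands.
#' @export
runPipeline <- function(command, config = list(), seed = 1,
                        outDir = tempfile("fibertune-run-")) {
    if (!command %in% .pipelineCommands)
        .stopf("unknown command '%s'; usage: runPipeline(<%s>, config, seed)",
               command, paste(.pipelineCommands, collapse = "|"))
    if (is.character(config)) config <- yaml::read_yaml(config)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    subSeeds <- stats::setNames(
        lapply(c("atlas", "cohort", "cv", "permute", "jitter", "cleartune",
                 "monopolar"), function(nm) deriveSeed(seed, nm)),
        c("atlas", "cohort", "cv", "permute", "jitter", "cleartune",
          "monopolar"))
    manifest <- list(command = command,
                     config_hash = .hashObject(config),
                     seed = seed, sub_seeds = subSeeds,
                     package_version = as.character(
                         utils::packageVersion("fibertune")))
    screening <- do.call(screeningConfig, config$screening %||% list())
    selection <- do.call(selectionConfig, config$selection %||% list())
    result <- switch(command,
        "synth" = {
            sb <- .synthBundle(config, seed)
            writeTractogram(sb$atlas, file.path(outDir, "atlas.json"))
            utils::write.csv(patients(sb$cohort),
                             file.path(outDir, "cohort.csv"),
                             row.names = FALSE)
            jsonlite::write_json(sb$truth, file.path(outDir, "truth.json"),
                                 auto_unbox = TRUE, digits = NA)
            if (isTRUE(config$writeFields)) {
                fd <- file.path(outDir, "fields")
                dir.create(fd, showWarnings = FALSE)
                for (i in seq_along(sb$cohort@fields))
                    writeFieldGrid(sb$cohort@fields[[i]],
                                   file.path(fd, sprintf("field%03d.nii.gz", i)))
            }
            list(nStreamlines = nStreamlines(sb$atlas),
                 nPatients = nPatients(sb$cohort))
        },
        "simulate-field" = {
            el <- buildElectrode(config$electrode$model %||% "medtronic-3389",
                                 config$electrode$tip %||% c(12, -13, -11),
                                 config$electrode$direction %||% c(0, 0, 1))
            st <- StimulationSetting(config$setting %||% c(0, 0, -3, 0))
            g <- simulateEField(el, st)
            writeFieldGrid(g, file.path(outDir, "field.nii.gz"))
            list(maxMagnitude = max(gridValues(g)))
        },
        "filter" = {
            sb <- .synthBundle(config, seed)
            model <- buildTractModel(sb$cohort, sb$atlas, screening, selection)
            jsonlite::write_json(.modelSummary(model),
                                 file.path(outDir, "model.json"),
                                 auto_unbox = TRUE, digits = NA)
            list(model = model)
        },
        "blend" = ,
        "crossval" = {
            sb <- .synthBundle(config, seed)
            cv <- do.call(cvConfig, utils::modifyList(
                list(seed = subSeeds$cv), config$cv %||% list()))
            res <- crossvalidate(sb$cohort, sb$atlas, screening, selection, cv)
            utils::write.csv(res$estimates,
                             file.path(outDir, "cv-estimates.csv"),
                             row.names = FALSE)
            utils::write.csv(res$summary, file.path(outDir, "cv-summary.csv"),
                             row.names = FALSE)
            res
        },
        "permute" = {
            sb <- .synthBundle(config, seed)
            stat <- function(m) mean(abs(m@stats[[1]]$rho), na.rm = TRUE)
            res <- permutationTest(sb$cohort, sb$atlas, stat,
                                   nPerm = config$nPerm %||% 100,
                                   seed = subSeeds$permute,
                                   screening = screening,
                                   selection = selection)
            jsonlite::write_json(res[c("p", "observed")],
                                 file.path(outDir, "permutation.json"),
                                 auto_unbox = TRUE, digits = NA)
            res
        },
        "jitter" = {
            sb <- .synthBundle(config, seed)
            res <- jitterRobustness(sb$cohort, sb$atlas,
                                    fwhm = config$jitter$fwhm %||% 2,
                                    nRepeats = config$jitter$nRepeats %||% 50,
                                    seed = subSeeds$jitter,
                                    screening = screening)
            jsonlite::write_json(list(meanR = res$meanR),
                                 file.path(outDir, "jitter.json"),
                                 auto_unbox = TRUE, digits = NA)
            res
        },
        "cleartune" = {
            sb <- .synthBundle(config, seed)
            model <- buildTractModel(sb$cohort, sb$atlas, screening, selection)
            maps <- fitCohortMaps(sb$cohort, model)
            p <- config$patient %||% 1L
            bl <- vapply(sb$cohort@symptoms, function(s)
                patients(sb$cohort)[[paste0("baseline_", s)]][p], numeric(1))
            names(bl) <- sb$cohort@symptoms
            ct <- do.call(cleartuneConfig, utils::modifyList(
                list(seed = subSeeds$cleartune), config$cleartune %||% list()))
            sol <- suggestSettings(sb$cohort@electrodes[2L * p - 1:0],
                                   model, maps, baselines = bl, config = ct)
            jsonlite::write_json(
                lapply(sol, function(s) list(currents_mA = currents(s),
                                             blended = s@blended,
                                             Fval = s@objective$Fval)),
                file.path(outDir, "solution.json"),
                auto_unbox = TRUE, digits = NA)
            sol
        },
        "monopolar-validate" = {
            sb <- .synthBundle(config, seed)
            model <- buildTractModel(sb$cohort, sb$atlas, screening, selection)
            maps <- fitCohortMaps(sb$cohort, model)
            mr <- generateMonopolarReview(sb$atlas, sb$truth, sb$sc,
                                          seed = subSeeds$monopolar)
            w <- stats::setNames(rep(1, length(sb$cohort@symptoms)),
                                 sb$cohort@symptoms)
            elecs <- lapply(mr, function(e)
                list(fields = e$fields,
                     empirical = rowMeans(e$empirical)))
            res <- monopolarRankValidation(elecs, model, maps, w)
            jsonlite::write_json(res[c("R", "t", "p")],
                                 file.path(outDir, "monopolar.json"),
                                 auto_unbox = TRUE, digits = NA)
            res
        },
        "convert" = {
            tg <- readTractogram(config$`in`, config$informat %||% NULL)
            writeTractogram(tg, file.path(outDir, config$out %||%
                                          "converted.json"),
                            config$format %||% NULL)
            list(nStreamlines = nStreamlines(tg))
        })
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(list(manifest = manifest, result = result, outDir = outDir))
}

#' Fit per-symptom linear maps on a whole cohort
#'
#' Convenience wrapper: per symptom, computes each included patient's
#' averaged two-field fiber score against the model and fits the linear
#' map to the empirical improvements.
#'
#' @param cohort A \linkS4class{DBSCohort}.
#' @param model A \linkS4class{TractModel}.
#' @param symptoms Symptoms to map (default: all in the model).
#' @param peaks Optional cached peak matrix.
#' @param method Correlation type for fiber scores.
#' @return Named list of linear maps.
#' @export
fitCohortMaps <- function(cohort, model, symptoms = NULL, peaks = NULL,
                          method = "spearman") {
    symptoms <- symptoms %||% names(model@stats)
    if (is.null(peaks))
        peaks <- computePeakMatrix(model@tractogram, cohort@fields)
    colPatient <- cohort@fieldPatient[attr(peaks, "fieldIndex")]
    nativeCols <- which(!attr(peaks, "mirroredCol"))
    maps <- list()
    for (sym in symptoms) {
        st <- model@stats[[sym]]
        selIdx <- which(st$selected)
        if (!length(selIdx)) next
        inc <- which(applyExclusions(cohort@patients, sym))
        sc <- .patientFiberScores(peaks, colPatient, nativeCols, selIdx,
                                  st$rho[selIdx], inc, method)
        maps[[sym]] <- fitLinearMap(
            sc, cohort@patients[[paste0("improvement_", sym)]][inc])
    }
    maps
}

#' Jitter robustness of the streamline correlation maps
#'
#' Rebuilds the per-symptom streamline R maps after translating every
#' stimulation field by a random per-axis Gaussian displacement (given
#' FWHM), and correlates (Spearman, over the screened streamlines of the
#' unjittered model) each jittered map with the unjittered one. Reports
#' the mean over repeats and symptoms.
#'
#' @param cohort A \linkS4class{DBSCohort}.
#' @param tractogram A \linkS4class{Tractogram}.
#' @param fwhm Jitter FWHM, mm (default 2).
#' @param nRepeats Number of jittered recomputations (default 50).
#' @param seed Integer seed.
#' @param screening A \code{\link{screeningConfig}}.
#' @param symptoms Symptoms to evaluate (default: cohort symptoms).
#' @param minPatients Passed to the model fit.
#' @return List with \code{meanR}, \code{perRepeat} (repeat x symptom
#'   matrix of correlations).
#' @export
jitterRobustness <- function(cohort, tractogram, fwhm = 2, nRepeats = 50,
                             seed = 1, screening = screeningConfig(),
                             symptoms = NULL, minPatients = 10L) {
    symptoms <- symptoms %||% cohort@symptoms
    selection <- selectionConfig()
    sigma <- fwhm / (2 * sqrt(2 * log(2)))
    peaks0 <- computePeakMatrix(tractogram, cohort@fields)
    colPatient <- cohort@fieldPatient[attr(peaks0, "fieldIndex")]
    base <- suppressWarnings(
        .fitStats(peaks0, colPatient, cohort@patients, symptoms, screening,
                  selectionConfig(), minPatients = minPatients))
    perRepeat <- matrix(NA_real_, nRepeats, length(symptoms),
                        dimnames = list(NULL, symptoms))
    nf <- length(cohort@fields)
    for (r in seq_len(nRepeats)) {
        set.seed(deriveSeed(seed, paste0("jitter-", r)))
        shifts <- matrix(stats::rnorm(3L * nf, 0, sigma), nf, 3L)
        peaksJ <- computePeakMatrix(tractogram, cohort@fields,
                                    originShifts = shifts)
        statsJ <- suppressWarnings(
            .fitStats(peaksJ, colPatient, cohort@patients, symptoms,
                      screening, selection, minPatients = minPatients))
        for (sym in intersect(names(base), names(statsJ))) {
            scr <- base[[sym]]$screened
            a <- base[[sym]]$rho[scr]
            b <- statsJ[[sym]]$rho[scr]
            ok <- !is.na(a) & !is.na(b)
            if (sum(ok) >= 4L)
                perRepeat[r, sym] <- stats::cor(a[ok], b[ok],
                                                method = "spearman")
        }
    }
    list(meanR = mean(perRepeat, na.rm = TRUE), perRepeat = perRepeat)
}
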