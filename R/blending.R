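#' Cross-validation configuration
#'
#' @param k Number of folds (default 10; 5 and 7 are common alternatives).
#' @param nRepeats Repeats with freshly shuffled folds (default 1; model
#'   comparisons use many repeats).
#' @param seed Integer seed; each repeat derives its own sub-seed.
#' @return List of class "CVConfig".
#' @export
cvConfig <- function(k = 10, nRepeats = 1, seed = 1) {
    stopifnot(k >= 2, nRepeats >= 1)
    structure(list(k = k, nRepeats = nRepeats, seed = seed),
              class = "CVConfig")
}

# Rank (or Pearson) correlation between selected-streamline R values and
# their peaks; degenerate (constant peaks) scores are zero.
.fiberScoreValue <- function(rho, peaks, method = "spearman") {
    if (length(rho) < 2L || stats::var(peaks) == 0 || stats::var(rho) == 0)
        return(list(value = 0, degenerate = TRUE))
    list(value = stats::cor(rho, peaks, method = method), degenerate = FALSE)
}

#' Fiber score of a stimulation field against a symptom tract
#'
#' Correlates the model's per-streamline Spearman R values (over the union
#' of selected positive and negative fibers) with the peak magnitudes this
#' field produces along those fibers. Streamlines the field does not reach
#' enter with peak zero: their low rank is informative. A field whose peaks
#' are all identical yields a degenerate score of zero.
#'
#' @param field An \linkS4class{EFieldGrid}.
#' @param model A \linkS4class{TractModel}.
#' @param symptom Symptom name.
#' @param step Resampling step, mm.
#' @param method "spearman" (default, consistent with the rest of the
#'   statistics) or "pearson".
#' @param dropZero Drop zero-peak streamlines instead of keeping them
#'   (default FALSE).
#' @return List with \code{value} in [-1, 1] and \code{degenerate}.
#' @export
fiberScore <- function(field, model, symptom, step = 0.5,
                       method = c("spearman", "pearson"), dropZero = FALSE) {
    method <- match.arg(method)
    st <- streamlineStats(model, symptom)
    sel <- which(st$selected)
    if (!length(sel)) .stopf("no selected fibers for symptom '%s'", symptom)
    stk <- .stackStreamlines(model@tractogram@streamlines[sel], step)
    peaks <- cppPeaksGrid(stk$pts, stk$offsets, as.numeric(field@values),
                          dim(field@values), field@origin, field@spacing)
    rho <- st$rho[sel]
    if (dropZero) {
        keep <- peaks > 0
        peaks <- peaks[keep]
        rho <- rho[keep]
    }
    .fiberScoreValue(rho, peaks, method)
}

#' Fit the linear map from fiber scores to percent improvements
#'
#' Ordinary least squares on the training cohort. Zero score variance
#' yields a flagged constant map (slope 0, intercept = mean improvement).
#'
#' @param scores Training fiber scores.
#' @param improvements Training percent improvements.
#' @return List with \code{slope}, \code{intercept}, \code{degenerate}.
#' @export
fitLinearMap <- function(scores, improvements) {
    ok <- !is.na(scores) & !is.na(improvements)
    scores <- scores[ok]; improvements <- improvements[ok]
    if (length(scores) < 3L) .stopf("need >= 3 training points, got %d",
                                    length(scores))
    if (stats::var(scores) == 0)
        return(list(slope = 0, intercept = mean(improvements),
                    degenerate = TRUE))
    fit <- stats::lm.fit(cbind(1, scores), improvements)
    list(slope = unname(fit$coefficients[2]),
         intercept = unname(fit$coefficients[1]), degenerate = FALSE)
}

.applyMap <- function(map, score) {
    .clip(map$intercept + map$slope * score, -50, 100)
}

#' Baseline-weighted blend of per-symptom estimates
#'
#' Weights are the normalized baseline severities
#' \code{w_s = baseline_s / sum(baseline_s)}; symptoms with a missing
#' estimate are dropped and the weights renormalized over the rest.
#'
#' @param estimates Named numeric vector of per-symptom estimates.
#' @param baselines Named numeric vector of baseline scores (>= 0), same
#'   symptoms.
#' @return Single blended estimate.
#' @export
blendEstimate <- function(estimates, baselines) {
    baselines <- baselines[names(estimates)]
    ok <- !is.na(estimates) & !is.na(baselines) & baselines > 0
    if (!any(ok) || sum(baselines[ok]) == 0)
        .stopf("no symptom with a defined estimate and positive baseline")
    w <- baselines[ok] / sum(baselines[ok])
    sum(w * estimates[ok])
}

# Per-patient fiber scores over native-field columns of a cached peak
# matrix: for each patient the two hemisphere-field scores are averaged.
.patientFiberScores <- function(peaks, colPatient, nativeCols, selIdx, rho,
                                patientsIdx, method = "spearman") {
    vapply(patientsIdx, function(p) {
        cols <- nativeCols[colPatient[nativeCols] == p]
        mean(vapply(cols, function(cc)
            .fiberScoreValue(rho, peaks[selIdx, cc], method)$value,
            numeric(1)))
    }, numeric(1))
}

#' Estimate improvements for one patient
#'
#' Per symptom, the fiber scores of the two hemisphere fields are averaged,
#' mapped to a percent improvement through the symptom's linear map
#' (clipped to [-50, 100]), and blended with the patient's baseline
#' weights.
#'
#' @param fields List of the patient's two \linkS4class{EFieldGrid}s.
#' @param model A \linkS4class{TractModel}.
#' @param maps Named list of linear maps (from \code{\link{fitLinearMap}}),
#'   one per symptom.
#' @param baselines Named numeric vector of the patient's baseline
#'   subscores.
#' @param symptoms Symptoms to estimate (default: names of \code{maps}).
#' @param method Correlation type for fiber scores.
#' @return List with \code{fiberScores}, \code{estimates} (per symptom) and
#'   \code{blended}.
#' @export
predictPatient <- function(fields, model, maps, baselines,
                           symptoms = names(maps), method = "spearman") {
    fs <- vapply(symptoms, function(sym)
        mean(vapply(fields, function(f)
            fiberScore(f, model, sym, method = method)$value, numeric(1))),
        numeric(1))
    est <- vapply(symptoms, function(sym) .applyMap(maps[[sym]], fs[[sym]]),
                  numeric(1))
    names(est) <- names(fs) <- symptoms
    blended <- if (length(symptoms) > 1L)
        blendEstimate(est, baselines) else unname(est[1])
    list(fiberScores = fs, estimates = est, blended = blended)
}

# One cross-validation repeat over a cached peak matrix. Returns per-patient
# out-of-fold blended and single-tract estimates.
.cvRepeat <- function(peaks, cohort, symptoms, screening, selection, k,
                      minPatients, method) {
    n <- nPatients(cohort)
    pt <- cohort@patients
    colPatient <- cohort@fieldPatient[attr(peaks, "fieldIndex")]
    nativeCols <- which(!attr(peaks, "mirroredCol"))
    folds <- sample(rep(seq_len(k), length.out = n))
    blended <- single <- rep(NA_real_, n)
    perSym <- matrix(NA_real_, n, length(symptoms),
                     dimnames = list(NULL, symptoms))
    for (f in seq_len(k)) {
        trainP <- which(folds != f)
        testP <- which(folds == f)
        if (length(trainP) < 3L)
            .stopf("fold %d has fewer than 3 training patients", f)
        cols <- which(colPatient %in% trainP)
        trainTab <- pt
        # hide test-fold information from screening/correlation/selection
        stats <- suppressWarnings(
            .fitStats(peaks, colPatient, trainTab, unique(c(symptoms, "global")),
                      screening, selection, columns = cols,
                      minPatients = minPatients))
        maps <- list()
        selIdxList <- list()
        for (sym in names(stats)) {
            st <- stats[[sym]]
            selIdx <- which(st$selected)
            if (!length(selIdx)) next
            inc <- which(applyExclusions(pt, sym) & seq_len(n) %in% trainP)
            sc <- .patientFiberScores(peaks, colPatient, nativeCols, selIdx,
                                      st$rho[selIdx], inc, method)
            imp <- pt[[paste0("improvement_", sym)]][inc]
            if (length(sc) < 3L) next
            maps[[sym]] <- fitLinearMap(sc, imp)
            selIdxList[[sym]] <- selIdx
        }
        for (p in testP) {
            est <- rep(NA_real_, length(symptoms))
            names(est) <- symptoms
            for (sym in intersect(symptoms, names(maps))) {
                sc <- .patientFiberScores(peaks, colPatient, nativeCols,
                                          selIdxList[[sym]],
                                          stats[[sym]]$rho[selIdxList[[sym]]],
                                          p, method)
                est[sym] <- .applyMap(maps[[sym]], sc)
            }
            perSym[p, ] <- est
            base <- vapply(symptoms, function(s)
                pt[[paste0("baseline_", s)]][p], numeric(1))
            names(base) <- symptoms
            if (any(!is.na(est)))
                blended[p] <- blendEstimate(est, base)
            if (!is.null(maps[["global"]])) {
                scg <- .patientFiberScores(peaks, colPatient, nativeCols,
                                           selIdxList[["global"]],
                                           stats[["global"]]$rho[selIdxList[["global"]]],
                                           p, method)
                single[p] <- .applyMap(maps[["global"]], scg)
            }
        }
    }
    list(folds = folds, blended = blended, single = single, perSym = perSym)
}

#' k-fold cross-validation of the multi-tract and single-tract models
#'
#' For each repeat, patients are shuffled into k folds; the full model
#' (screening, correlation, FDR, selection, linear maps) is re-fit on every
#' training fold with no test-fold leakage, and each patient receives
#' exactly one out-of-fold blended estimate (and a single-tract estimate
#' from the global model). Reported R is the Spearman correlation between
#' out-of-fold estimates and empirical global improvements.
#'
#' @param cohort A \linkS4class{DBSCohort}.
#' @param tractogram A \linkS4class{Tractogram}.
#' @param screening,selection Configurations as in
#'   \code{\link{buildTractModel}}.
#' @param cv A \code{\link{cvConfig}}.
#' @param symptoms Symptoms to blend (default: the cohort's symptoms).
#' @param peaks Optional cached peak matrix.
#' @param minPatients Minimum included training patients per symptom.
#' @param method Correlation type for fiber scores.
#' @return List with \code{estimates} (per-patient data.frame of the last
#'   repeat), \code{summary} (per-repeat R and p for the blended and
#'   single-tract models).
#' @export
crossvalidate <- function(cohort, tractogram, screening = screeningConfig(),
                          selection = selectionConfig(), cv = cvConfig(),
                          symptoms = NULL, peaks = NULL, minPatients = 10L,
                          method = "spearman") {
    symptoms <- symptoms %||% cohort@symptoms
    if (nPatients(cohort) < cv$k) .stopf("need at least k = %d patients", cv$k)
    if (is.null(peaks))
        peaks <- computePeakMatrix(tractogram, cohort@fields)
    emp <- cohort@patients$improvement_global
    summary <- data.frame(repeatIdx = seq_len(cv$nRepeats), R = NA_real_,
                          p = NA_real_, Rsingle = NA_real_,
                          psingle = NA_real_)
    est <- NULL
    for (r in seq_len(cv$nRepeats)) {
        set.seed(deriveSeed(cv$seed, paste0("cv-repeat-", r)))
        rep_ <- .cvRepeat(peaks, cohort, symptoms, screening, selection,
                          cv$k, minPatients, method)
        okB <- !is.na(rep_$blended) & !is.na(emp)
        if (sum(okB) >= 4L) {
            ctB <- suppressWarnings(stats::cor.test(rep_$blended[okB],
                                                    emp[okB],
                                                    method = "spearman"))
            summary$R[r] <- unname(ctB$estimate)
            summary$p[r] <- ctB$p.value
        }
        okS <- !is.na(rep_$single) & !is.na(emp)
        if (sum(okS) >= 4L) {
            ctS <- suppressWarnings(stats::cor.test(rep_$single[okS],
                                                    emp[okS],
                                                    method = "spearman"))
            summary$Rsingle[r] <- unname(ctS$estimate)
            summary$psingle[r] <- ctS$p.value
        }
        est <- data.frame(id = cohort@patients$id, fold = rep_$folds,
                          estimate = rep_$blended, single = rep_$single,
                          empirical = emp)
    }
    list(estimates = est, summary = summary)
}

#' Compare the multi-tract and single-tract models across shuffled repeats
#'
#' Runs repeated k-fold cross-validation (fresh fold shuffle per repeat, a
#' documented sub-seed sequence) and compares, per repeat, the blended
#' four-symptom model's CV correlation with the single global-improvement
#' tract model's on identical folds, by paired t-test.
#'
#' @inheritParams crossvalidate
#' @return List with \code{T}, \code{p}, \code{fractionMultiHigher}, and the
#'   per-repeat \code{summary}.
#' @export
compareModels <- function(cohort, tractogram, screening = screeningConfig(),
                          selection = selectionConfig(),
                          cv = cvConfig(nRepeats = 20), symptoms = NULL,
                          peaks = NULL, minPatients = 10L,
                          method = "spearman") {
    res <- crossvalidate(cohort, tractogram, screening, selection, cv,
                         symptoms, peaks, minPatients, method)
    s <- res$summary
    ok <- !is.na(s$R) & !is.na(s$Rsingle)
    d <- s$R[ok] - s$Rsingle[ok]
    tt <- if (sum(ok) >= 2L && stats::sd(d) > 0)
        stats::t.test(s$R[ok], s$Rsingle[ok], paired = TRUE) else
        list(statistic = c(t = 0), p.value = 1)
    list(T = unname(tt$statistic), p = tt$p.value,
         fractionMultiHigher = mean(s$R[ok] >= s$Rsingle[ok]),
         summary = s)
}

#' Spatial similarity of two field grids
#'
#' Resamples \code{b} onto \code{a}'s lattice and correlates voxel values
#' where either grid is at or above the floor magnitude.
#'
#' @param a,b \linkS4class{EFieldGrid}s.
#' @param floor Magnitude floor, V/mm (default 0.05).
#' @param method "pearson" (default) or "spearman".
#' @return Correlation coefficient.
#' @export
efieldSimilarity <- function(a, b, floor = 0.05,
                             method = c("pearson", "spearman")) {
    method <- match.arg(method)
    d <- dim(a@values)
    coords <- as.matrix(expand.grid(
        a@origin[1] + (seq_len(d[1]) - 1) * a@spacing[1],
        a@origin[2] + (seq_len(d[2]) - 1) * a@spacing[2],
        a@origin[3] + (seq_len(d[3]) - 1) * a@spacing[3]))
    n <- nrow(coords)
    bv <- cppPeaksGrid(coords, 0:n, as.numeric(b@values), dim(b@values),
                       b@origin, b@spacing)
    av <- as.numeric(a@values)
    mask <- av >= floor | bv >= floor
    if (!any(mask)) .stopf("no voxels above the %.3g V/mm floor", floor)
    if (stats::var(av[mask]) == 0 || stats::var(bv[mask]) == 0) return(0)
    stats::cor(av[mask], bv[mask], method = method)
}

#' Rank validation on monopolar-review data
#'
#' For each electrode, estimates the improvement of every tested setting
#' with a fixed model and correlates (Spearman) estimated with empirical
#' improvements; a one-sample t-test then asks whether the per-electrode
#' correlations are positive on average. Supplying a symptom weight vector
#' concentrated on one symptom reproduces the symptom-specificity
#' cross-test.
#'
#' @param electrodes List, one entry per electrode, each a list with
#'   \code{fields} (list of \linkS4class{EFieldGrid}, one per tested
#'   setting) and \code{empirical} (numeric improvements, same length).
#' @param model A \linkS4class{TractModel}.
#' @param maps Named list of linear maps per symptom.
#' @param weights Named numeric symptom weights (normalized internally).
#' @param method Correlation type for fiber scores.
#' @return List with \code{R} (per-electrode Spearman), \code{t}, \code{p}
#'   (one-sided, positive mean), \code{flagged} (electrodes with constant
#'   estimates), and \code{estimates}.
#' @export
monopolarRankValidation <- function(electrodes, model, maps, weights,
                                    method = "spearman") {
    weights <- weights / sum(weights)
    hasFibers <- vapply(names(weights), function(sym)
        any(streamlineStats(model, sym)$selected), logical(1))
    if (!any(hasFibers)) .stopf("no weighted symptom has selected fibers")
    weights <- weights[hasFibers] / sum(weights[hasFibers])
    symptoms <- names(weights)
    R <- rep(NA_real_, length(electrodes))
    flagged <- logical(length(electrodes))
    estimates <- vector("list", length(electrodes))
    selCache <- .selectionCache(model, symptoms)
    for (e in seq_along(electrodes)) {
        el <- electrodes[[e]]
        if (length(el$fields) < 3L)
            .stopf("electrode %d has fewer than 3 settings", e)
        est <- vapply(el$fields, function(f) {
            es <- vapply(symptoms, function(sym) {
                sc <- selCache[[sym]]
                pk <- cppPeaksGrid(sc$pts, sc$offsets,
                                   as.numeric(f@values), dim(f@values),
                                   f@origin, f@spacing)
                .applyMap(maps[[sym]],
                          .fiberScoreValue(sc$rho, pk, method)$value)
            }, numeric(1))
            sum(weights * es)
        }, numeric(1))
        estimates[[e]] <- est
        if (stats::var(est) == 0) {
            flagged[e] <- TRUE
            next
        }
        R[e] <- suppressWarnings(stats::cor(est, el$empirical,
                                            method = "spearman"))
    }
    Rok <- R[!is.na(R)]
    if (length(Rok) >= 2L && stats::sd(Rok) > 0) {
        tt <- stats::t.test(Rok, mu = 0, alternative = "greater")
        t <- unname(tt$statistic)
        p <- tt$p.value
    } else {
        t <- NA_real_
        p <- NA_real_
    }
    list(R = R, t = t, p = p, flagged = flagged, estimates = estimates)
}
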