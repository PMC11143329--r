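#' Cleartune configuration
#'
#' Constraints and penalty of the current-steering optimizer: per-contact
#' cap 4 mA, total cap 5 mA, quadratic penalty \eqn{(A - A_o)^2 \lambda}
#' around the reference total amplitude \eqn{A_o = 3} mA with
#' \eqn{\lambda = 0.02}, pruning of contacts carrying less than 10 percent
#' of the total current, and a start at -3 mA on the third contact.
#'
#' @param Ao Reference total amplitude, mA (default 3).
#' @param lambda Penalty factor (default 0.02).
#' @param perContactCap Per-contact magnitude cap, mA (default 4).
#' @param totalCap Total magnitude cap, mA (default 5).
#' @param pruneFraction Relative lower bound per contact (default 0.1 of
#'   the total current; set \code{pruneAbsolute} for a fixed mA floor
#'   instead).
#' @param pruneAbsolute Optional absolute lower bound, mA; overrides the
#'   relative rule when non-NULL.
#' @param startContact 1-based index of the contact switched on at the
#'   start point (default 3).
#' @param startCurrent Start amplitude, mA magnitude (default 3).
#' @param evalBudget Objective evaluation budget (default 300).
#' @param seed Integer seed for the search.
#' @return List of class "CleartuneConfig".
#' @export
cleartuneConfig <- function(Ao = 3, lambda = 0.02, perContactCap = 4,
                            totalCap = 5, pruneFraction = 0.1,
                            pruneAbsolute = NULL, startContact = 3L,
                            startCurrent = 3, evalBudget = 300L, seed = 1L) {
    stopifnot(perContactCap > 0, totalCap > 0, Ao <= totalCap,
              pruneFraction >= 0, pruneFraction < 1, evalBudget >= 10L)
    structure(list(Ao = Ao, lambda = lambda, perContactCap = perContactCap,
                   totalCap = totalCap, pruneFraction = pruneFraction,
                   pruneAbsolute = pruneAbsolute,
                   startContact = as.integer(startContact),
                   startCurrent = startCurrent,
                   evalBudget = as.integer(evalBudget),
                   seed = as.integer(seed)),
              class = "CleartuneConfig")
}

#' Sanitize raw currents into a feasible cathodic setting
#'
#' In order: (1) clip each contact magnitude to the per-contact cap;
#' (2) zero contacts carrying less than \code{pruneFraction} of the total
#' current (avoids needlessly complex settings); (3) rescale
#' proportionally if the total exceeds the total cap. The operation is
#' idempotent. An all-zero result is allowed and flagged by the caller.
#'
#' @param raw Numeric vector of raw currents, mA, all <= 0.
#' @param config A \code{\link{cleartuneConfig}}.
#' @return Feasible currents (<= 0, caps respected).
#' @export
sanitizeCurrents <- function(raw, config = cleartuneConfig()) {
    stopifnot(all(raw <= 0))
    m <- pmin(abs(raw), config$perContactCap)
    tot <- sum(m)
    if (tot > 0) {
        floorC <- if (!is.null(config$pruneAbsolute)) config$pruneAbsolute
                  else config$pruneFraction * tot
        m[m < floorC & m > 0] <- 0
        tot <- sum(m)
        if (tot > config$totalCap) m <- m * config$totalCap / tot
    }
    -m
}

# Weighted fiber-score term of a candidate: analytic point-source peaks
# along the selected fibers of each symptom (no grid needed inside the
# optimizer loop).
.candidateScores <- function(cur, electrode, model, weights, fconfig,
                             selCache, method = "spearman") {
    act <- which(cur != 0)
    sources <- electrode@contactCenters[act, , drop = FALSE]
    amps <- abs(cur[act])
    out <- numeric(length(weights))
    names(out) <- names(weights)
    for (sym in names(weights)) {
        sc <- selCache[[sym]]
        peaks <- cppPeaksSources(sc$pts, sc$offsets, sources, amps,
                                 fconfig$sigma, fconfig$clampRadius)
        out[sym] <- .fiberScoreValue(sc$rho, peaks, method)$value
    }
    out
}

.selectionCache <- function(model, symptoms, step = 0.5) {
    out <- list()
    for (sym in symptoms) {
        st <- streamlineStats(model, sym)
        sel <- which(st$selected)
        if (!length(sel)) .stopf("no selected fibers for symptom '%s'", sym)
        stk <- .stackStreamlines(model@tractogram@streamlines[sel], step)
        out[[sym]] <- list(pts = stk$pts, offsets = stk$offsets,
                           rho = st$rho[sel])
    }
    out
}

#' Cleartune objective
#'
#' \deqn{Fval = S_{ff} + (A - A_o)^2 \lambda}
#' where \eqn{S_{ff}} is the negative weighted fiber score of the sanitized
#' candidate (so minimizing Fval maximizes the weighted score), \eqn{A} the
#' total current magnitude, and the quadratic penalty discourages totals
#' far from the 3 mA reference. All-zero candidates are invalid
#' (\code{Fval = +Inf}).
#'
#' @param rawCurrents Raw cathodic currents, mA (<= 0), one per contact.
#' @param electrode An \linkS4class{ElectrodeSpec}.
#' @param model A \linkS4class{TractModel}.
#' @param weights Named symptom weights (sum normalized internally).
#' @param config A \code{\link{cleartuneConfig}}.
#' @param fieldConfig A \code{\link{fieldModelConfig}}.
#' @param selCache Internal selection cache (recomputed when NULL).
#' @return List with \code{Fval}, \code{S_ff}, \code{penalty}, \code{A},
#'   \code{currents} (the sanitized setting) and \code{scores}.
#' @export
cleartuneObjective <- function(rawCurrents, electrode, model, weights,
                               config = cleartuneConfig(),
                               fieldConfig = fieldModelConfig(),
                               selCache = NULL) {
    weights <- weights / sum(weights)
    cur <- sanitizeCurrents(rawCurrents, config)
    A <- sum(abs(cur))
    penalty <- (A - config$Ao)^2 * config$lambda
    if (A == 0)
        return(list(Fval = Inf, S_ff = Inf, penalty = penalty, A = 0,
                    currents = cur, scores = NULL))
    if (is.null(selCache))
        selCache <- .selectionCache(model, names(weights))
    scores <- .candidateScores(cur, electrode, model, weights, fieldConfig,
                               selCache)
    S_ff <- -sum(weights * scores)
    list(Fval = S_ff + penalty, S_ff = S_ff, penalty = penalty, A = A,
         currents = cur, scores = scores)
}

#' Optimize per-contact currents for one electrode
#'
#' Seeded derivative-free global search over per-contact cathodic current
#' magnitudes: a coarse monopolar and contact-pair grid plus Latin
#' hypercube samples explore the space, then Nelder-Mead refines around the
#' best candidates, all on the sanitized objective so every evaluated
#' setting is feasible. Deterministic given the config seed.
#'
#' @inheritParams cleartuneObjective
#' @return A \linkS4class{CleartuneSolution} (estimates filled by
#'   \code{\link{suggestSettings}}; here the per-symptom raw fiber scores
#'   are stored as estimates when no maps are supplied).
#' @param maps Optional named list of linear maps used to convert the best
#'   candidate's fiber scores to percent improvements.
#' @param baselines Optional named baselines for blending the estimates.
#' @export
optimizeStimulation <- function(electrode, model, weights,
                                config = cleartuneConfig(),
                                fieldConfig = fieldModelConfig(),
                                maps = NULL, baselines = NULL) {
    weights <- weights / sum(weights)
    nC <- nrow(electrode@contactCenters)
    if (nC < 2L) .stopf("electrode must have >= 2 contacts")
    selCache <- .selectionCache(model, names(weights))
    evalObj <- function(raw) cleartuneObjective(raw, electrode, model,
                                                weights, config, fieldConfig,
                                                selCache)
    trace <- list()
    best <- list(Fval = Inf)
    consider <- function(raw) {
        o <- evalObj(-abs(raw))
        trace[[length(trace) + 1L]] <<- c(o$currents, Fval = o$Fval)
        if (o$Fval < best$Fval) best <<- o
        o$Fval
    }
    # start point: configured contact at the reference amplitude
    start <- numeric(nC)
    start[min(config$startContact, nC)] <- config$startCurrent
    consider(start)
    # monopolar grid (0.5 mA steps) and coarse two-contact grid
    for (c1 in seq_len(nC))
        for (a in seq(0.5, config$perContactCap, by = 0.5)) {
            g <- numeric(nC); g[c1] <- a
            consider(g)
        }
    amps2 <- seq(1, config$perContactCap, by = 1)
    for (c1 in seq_len(nC - 1L)) for (c2 in (c1 + 1L):nC)
        for (a1 in amps2) for (a2 in amps2) {
            if (a1 + a2 > config$totalCap) next
            g <- numeric(nC); g[c1] <- a1; g[c2] <- a2
            consider(g)
        }
    # Latin hypercube exploration of the full space
    set.seed(config$seed)
    nLhs <- max(config$evalBudget - length(trace), 20L)
    lh <- lhs::randomLHS(nLhs, nC) * config$perContactCap
    for (i in seq_len(nLhs)) consider(lh[i, ])
    # local refinement around the incumbent
    refineStart <- abs(best$currents)
    opt <- stats::optim(refineStart, function(m) consider(m),
                        method = "Nelder-Mead",
                        control = list(maxit = 100L, reltol = 1e-6))
    if (!is.finite(best$Fval)) .stopf("budget exhausted without a finite objective")
    est <- best$scores
    blended <- NA_real_
    if (!is.null(maps)) {
        est <- vapply(names(weights), function(sym)
            .applyMap(maps[[sym]], best$scores[[sym]]), numeric(1))
        blended <- if (!is.null(baselines)) blendEstimate(est, baselines)
                   else sum(weights * est)
    }
    traceDf <- as.data.frame(do.call(rbind, trace))
    names(traceDf) <- c(paste0("contact", seq_len(nC)), "Fval")
    new("CleartuneSolution",
        setting = StimulationSetting(best$currents),
        estimates = est, blended = blended,
        objective = best[c("Fval", "S_ff", "penalty", "A")],
        trace = traceDf)
}

#' Suggest stimulation settings for a patient
#'
#' Runs the optimizer independently for each of the patient's electrodes,
#' weighting symptoms by the patient's normalized baseline severities
#' unless an explicit weight override is given (e.g. to maximally weight a
#' single burdensome symptom).
#'
#' @param electrodes List of the patient's \linkS4class{ElectrodeSpec}s
#'   (typically two, one per hemisphere).
#' @param model A \linkS4class{TractModel}.
#' @param maps Named list of per-symptom linear maps.
#' @param baselines Named numeric baseline subscores (required unless
#'   \code{weights} is given).
#' @param weights Optional symptom weight override (normalized internally).
#' @param config A \code{\link{cleartuneConfig}}.
#' @param fieldConfig A \code{\link{fieldModelConfig}}.
#' @return List of \linkS4class{CleartuneSolution}, one per electrode.
#' @export
suggestSettings <- function(electrodes, model, maps, baselines = NULL,
                            weights = NULL, config = cleartuneConfig(),
                            fieldConfig = fieldModelConfig()) {
    if (is.null(weights)) {
        if (is.null(baselines))
            .stopf("baselines are required when no weight override is given")
        weights <- baselines[baselines > 0] / sum(baselines[baselines > 0])
    } else weights <- weights / sum(weights)
    weights <- weights[weights > 0]
    hasFibers <- vapply(names(weights), function(sym)
        any(streamlineStats(model, sym)$selected), logical(1))
    if (!all(hasFibers)) {
        if (!any(hasFibers))
            .stopf("no symptom in the weight vector has selected fibers")
        warning(sprintf("dropping symptom(s) without selected fibers: %s",
                        paste(names(weights)[!hasFibers], collapse = ", ")),
                call. = FALSE)
        weights <- weights[hasFibers] / sum(weights[hasFibers])
    }
    lapply(seq_along(electrodes), function(i) {
        cfg <- config
        cfg$seed <- deriveSeed(config$seed, paste0("electrode-", i))
        optimizeStimulation(electrodes[[i]], model, weights, cfg,
                            fieldConfig, maps = maps, baselines = baselines)
    })
}
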