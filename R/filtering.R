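#' Symptom definitions: UPDRS-III item groups
#'
#' Default mapping of motor-scale items to symptom domains: bradykinesia
#' (items 23-26: finger tapping, hand movement, rapid alternating, leg
#' agility; bilateral), rigidity (item 22: neck and four limbs), tremor
#' (items 20-21), axial (items 18, 19, 27-30: speech, facial expression,
#' arising, posture, postural stability, gait), gait (items 29-30), and
#' axial without the gait items.
#'
#' @return Named list of integer item-number vectors.
#' @export
symptomDefinitions <- function() {
    list(tremor = c(20L, 21L),
         bradykinesia = c(23L, 24L, 25L, 26L),
         rigidity = 22L,
         axial = c(18L, 19L, 27L, 28L, 29L, 30L),
         gait = c(29L, 30L),
         axial_nogait = c(18L, 19L, 27L, 28L))
}

# Columns of an item table that belong to one item number. Accepts "item22",
# "item22_left", "pre_item22_neck", ... (laterality/site suffixes allowed).
.itemColumns <- function(columns, itemNumber) {
    grep(sprintf("(^|_)item%d(_|$)", itemNumber), columns, value = TRUE)
}

#' Compute per-symptom subscores and percent improvements
#'
#' Sums the configured items per symptom at baseline and postoperatively and
#' derives the relative improvement \code{100 * (pre - post) / pre}. A
#' missing item propagates to a missing subscore; a zero baseline leaves the
#' improvement undefined (never zero).
#'
#' @param itemsPre,itemsPost data.frames (one row per patient) whose columns
#'   encode item numbers as \code{item<NN>} with optional site suffixes,
#'   e.g. \code{item23_right}.
#' @param definitions Named list of item numbers per symptom
#'   (default \code{\link{symptomDefinitions}()}).
#' @return data.frame with \code{baseline_<symptom>}, \code{post_<symptom>}
#'   and \code{improvement_<symptom>} columns.
#' @export
computeSubscores <- function(itemsPre, itemsPost,
                             definitions = symptomDefinitions()) {
    itemsPre <- as.data.frame(itemsPre)
    itemsPost <- as.data.frame(itemsPost)
    stopifnot(nrow(itemsPre) == nrow(itemsPost))
    out <- data.frame(row.names = seq_len(nrow(itemsPre)))
    for (sym in names(definitions)) {
        preCols <- unlist(lapply(definitions[[sym]], .itemColumns,
                                 columns = names(itemsPre)))
        postCols <- unlist(lapply(definitions[[sym]], .itemColumns,
                                  columns = names(itemsPost)))
        if (!length(preCols) || !length(postCols))
            .stopf("no item columns found for symptom '%s'", sym)
        pre <- rowSums(itemsPre[, preCols, drop = FALSE])   # NA propagates
        post <- rowSums(itemsPost[, postCols, drop = FALSE])
        imp <- ifelse(!is.na(pre) & pre > 0, 100 * (pre - post) / pre, NA_real_)
        out[[paste0("baseline_", sym)]] <- pre
        out[[paste0("post_", sym)]] <- post
        out[[paste0("improvement_", sym)]] <- imp
    }
    out
}

#' Per-symptom inclusion mask
#'
#' Tremor analyses exclude patients with a baseline tremor score below two
#' points and patients who improved to exactly 100 percent. For all other
#' symptoms patients are included whenever their improvement is defined.
#'
#' @param scores data.frame with \code{baseline_<symptom>} and
#'   \code{improvement_<symptom>} columns (e.g. from
#'   \code{\link{computeSubscores}} or a cohort table).
#' @param symptom Symptom name.
#' @return Logical inclusion vector, one entry per row.
#' @export
applyExclusions <- function(scores, symptom) {
    base <- scores[[paste0("baseline_", symptom)]]
    imp <- scores[[paste0("improvement_", symptom)]]
    if (is.null(imp)) .stopf("no improvement column for symptom '%s'", symptom)
    ok <- !is.na(imp)
    if (identical(symptom, "tremor"))
        ok <- ok & !is.na(base) & base >= 2 & imp < 100
    ok
}

#' Screening configuration
#'
#' A streamline enters the model only if it passes through a (small but
#' nonzero) fraction of the cohort's stimulation fields at a high peak
#' intensity; this drops streamlines never strongly modulated by any field,
#' which could otherwise pick up spurious sub-threshold correlations. Both
#' thresholds are strict inequalities.
#'
#' @param eThreshold Peak-intensity threshold, V/mm (default 1.5).
#' @param minFieldFraction Minimum fraction of fields exceeding the
#'   threshold (default 0.005, i.e. 0.5 percent, strict).
#' @return List of class "ScreeningConfig".
#' @export
screeningConfig <- function(eThreshold = 1.5, minFieldFraction = 0.005) {
    stopifnot(eThreshold > 0, minFieldFraction > 0)
    structure(list(eThreshold = eThreshold,
                   minFieldFraction = minFieldFraction),
              class = "ScreeningConfig")
}

#' Selection configuration
#'
#' @param nPos Positive-fiber quota (default 1500).
#' @param nNeg Negative-fiber quota (default 500).
#' @param significantOnly Restrict the candidate pool to FDR-significant
#'   streamlines (default TRUE).
#' @param alpha FDR significance level (default 0.05).
#' @return List of class "SelectionConfig".
#' @export
selectionConfig <- function(nPos = 1500, nNeg = 500, significantOnly = TRUE,
                            alpha = 0.05) {
    stopifnot(nPos >= 0, nNeg >= 0, alpha > 0, alpha < 1)
    structure(list(nPos = nPos, nNeg = nNeg,
                   significantOnly = significantOnly, alpha = alpha),
              class = "SelectionConfig")
}

#' Screen streamlines against a set of stimulation fields
#'
#' @param tractogram A \linkS4class{Tractogram}.
#' @param fields List of \linkS4class{EFieldGrid} (mirrored copies are
#'   appended automatically and count as fields).
#' @param config A \code{\link{screeningConfig}}.
#' @param step Streamline resampling step, mm.
#' @param peaks Optional precomputed \code{\link{computePeakMatrix}} result.
#' @return List with \code{screened} (logical per streamline) and
#'   \code{peaks} (the peak matrix).
#' @export
screenStreamlines <- function(tractogram, fields, config = screeningConfig(),
                              step = 0.5, peaks = NULL) {
    if (is.null(peaks)) {
        if (!length(fields)) .stopf("at least one field is required")
        peaks <- computePeakMatrix(tractogram, fields, step = step)
    }
    if (!nrow(peaks)) .stopf("empty tractogram")
    list(screened = .screenPeaks(peaks, config), peaks = peaks)
}

.screenPeaks <- function(peaks, config, cols = NULL) {
    if (is.null(cols)) cols <- seq_len(ncol(peaks))
    frac <- rowMeans(peaks[, cols, drop = FALSE] > config$eThreshold)
    frac > config$minFieldFraction
}

# All permutations of 1..n as an n! x n matrix (n <= 9).
.permutationsMatrix <- function(n) {
    if (n == 1L) return(matrix(1L, 1L, 1L))
    sub <- .permutationsMatrix(n - 1L)
    out <- matrix(0L, nrow(sub) * n, n)
    for (k in seq_len(n)) {
        rows <- (k - 1L) * nrow(sub) + seq_len(nrow(sub))
        out[rows, 1L] <- k
        rest <- seq_len(n)[-k]
        out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
    }
    out
}

#' Spearman rank correlation with exact small-sample p value
#'
#' Average ranks for ties; two-tailed p value by full permutation
#' enumeration for n <= \code{exactMax} (default 9) and by the
#' t-approximation otherwise. Pairs with a missing value in either vector
#' are deleted pairwise.
#'
#' @param x,y Numeric vectors of equal length (>= 4 complete pairs).
#' @param exactMax Largest n for which the exact null is enumerated.
#' @return List with \code{rho}, \code{p}, \code{n}, and \code{degenerate}
#'   (TRUE when either vector has zero variance, in which case rho and p
#'   are NA).
#' @export
spearmanCorrelate <- function(x, y, exactMax = 9L) {
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    n <- length(x)
    if (n < 4L) .stopf("need >= 4 paired observations, got %d", n)
    if (stats::var(x) == 0 || stats::var(y) == 0)
        return(list(rho = NA_real_, p = NA_real_, n = n, degenerate = TRUE))
    rx <- rank(x); ry <- rank(y)
    rho <- stats::cor(rx, ry)
    if (n <= exactMax) {
        perms <- .permutationsMatrix(n)
        ryp <- matrix(ry[perms], nrow(perms), n)
        rxc <- rx - mean(rx)
        s <- as.numeric(ryp %*% rxc)       # ~ covariance up to constants
        rhos <- s / sqrt(sum(rxc^2) * sum((ry - mean(ry))^2))
        p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    } else {
        tstat <- rho * sqrt((n - 2) / (1 - rho^2))
        p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
    list(rho = rho, p = min(p, 1), n = n, degenerate = FALSE)
}

# Per-row Spearman of peak rows against improvements (t-approximation).
# Fields with zero peak along a streamline (no spatial overlap, e.g. the
# contralateral hemisphere) carry no dose information for it and are
# deleted pairwise, so each streamline's sample is the set of fields folded
# into its hemisphere; rows covered by fewer than minN fields give NA.
.massSpearman <- function(P, y, minN = 10L) {
    mr <- cppMaskedSpearman(P, y, as.integer(minN))
    rho <- .clip(mr[, 1], -1, 1)
    n <- mr[, 2]
    tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-15))
    p <- 2 * stats::pt(-abs(tstat), df = pmax(n - 2, 1))
    p[!is.na(rho) & abs(rho) >= 1 - 1e-12] <- 0
    list(rho = rho, p = p, n = n)
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' @param p Vector of p values in [0, 1] (NA allowed, kept NA).
#' @param alpha Significance level (default 0.05).
#' @return List with \code{q} (monotone step-up q values) and \code{reject}
#'   (q < alpha).
#' @export
fdrCorrect <- function(p, alpha = 0.05) {
    if (!length(p)) .stopf("empty p-value vector")
    stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
    q <- stats::p.adjust(p, method = "BH")
    list(q = q, reject = !is.na(q) & q < alpha)
}

# Selection from a stats data.frame: top nPos by largest rho, top nNeg by
# most negative rho, ties broken by streamline index (stable).
.selectFromStats <- function(rho, screened, q, selection) {
    candidate <- screened & !is.na(rho)
    if (selection$significantOnly)
        candidate <- candidate & !is.na(q) & q < selection$alpha
    idx <- which(candidate)
    pos <- idx[rho[idx] > 0]
    neg <- idx[rho[idx] < 0]
    pos <- pos[order(-rho[pos], pos)]
    neg <- neg[order(rho[neg], neg)]
    list(positive = pos[seq_len(min(selection$nPos, length(pos)))],
         negative = neg[seq_len(min(selection$nNeg, length(neg)))])
}

#' Select the top positive and negative fibers of a symptom
#'
#' Up to \code{nPos} streamlines with the largest positive Spearman R
#' (associated with improvement) and \code{nNeg} with the most negative R
#' (associated with worsening); fewer are taken when fewer are available.
#' Ties at the cutoff are broken by streamline index.
#'
#' @param model A \linkS4class{TractModel}.
#' @param symptom Symptom name in the model.
#' @param nPos,nNeg Selection quotas (defaults 1500 and 500).
#' @param significantOnly Restrict to FDR-significant streamlines (default
#'   taken from the model's selection config).
#' @return List with integer index vectors \code{positive} and
#'   \code{negative}.
#' @export
selectTopFibers <- function(model, symptom, nPos = 1500, nNeg = 500,
                            significantOnly = NULL) {
    st <- streamlineStats(model, symptom)
    sel <- model@selection
    sel$nPos <- nPos
    sel$nNeg <- nNeg
    if (!is.null(significantOnly)) sel$significantOnly <- significantOnly
    .selectFromStats(st$rho, st$screened, st$q, sel)
}

# Core fit on a precomputed peak matrix. `columns` restricts to a subset of
# field columns (cross-validation training folds); improvements are indexed
# patient-wise through colPatient.
.fitStats <- function(peaks, colPatient, patientsTab, symptoms, screening,
                      selection, columns = NULL, minPatients = 10L) {
    if (is.null(columns)) columns <- seq_len(ncol(peaks))
    screened <- .screenPeaks(peaks, screening, columns)
    stats <- list()
    for (sym in symptoms) {
        inc <- applyExclusions(patientsTab, sym)
        if (sum(inc) < minPatients) {
            warning(sprintf("symptom '%s' skipped: only %d included patients",
                            sym, sum(inc)), call. = FALSE)
            next
        }
        cols <- columns[inc[colPatient[columns]]]
        y <- patientsTab[[paste0("improvement_", sym)]][colPatient[cols]]
        st <- data.frame(rho = NA_real_, p = NA_real_, q = NA_real_,
                         screened = screened, selected = FALSE,
                         sign = NA_integer_)[seq_len(nrow(peaks)), ]
        rownames(st) <- NULL
        if (any(screened)) {
            ms <- .massSpearman(peaks[screened, cols, drop = FALSE], y)
            st$rho[screened] <- ms$rho
            st$p[screened] <- ms$p
            # FDR family: all screened streamlines of this symptom
            st$q[screened] <- fdrCorrect(ms$p, selection$alpha)$q
        }
        sel <- .selectFromStats(st$rho, st$screened, st$q, selection)
        st$selected[c(sel$positive, sel$negative)] <- TRUE
        st$sign <- ifelse(is.na(st$rho), NA_integer_, as.integer(sign(st$rho)))
        stats[[sym]] <- st
    }
    stats
}

#' Build the symptom-network library (multi-tract model)
#'
#' Runs the full per-streamline pipeline on a cohort: peak-field matrix
#' (native plus mirrored fields, both accounting for the same improvement
#' values), intensity screening, per-symptom Spearman correlation with the
#' symptom's inclusion mask applied, FDR correction across the screened
#' streamlines of each symptom, and top-fiber selection. The "global"
#' entry is the single-tract model trained on global motor improvement.
#'
#' @param cohort A \linkS4class{DBSCohort}.
#' @param tractogram A \linkS4class{Tractogram}.
#' @param screening A \code{\link{screeningConfig}}.
#' @param selection A \code{\link{selectionConfig}}.
#' @param symptoms Symptom names to model (default: the cohort's symptoms
#'   plus "global").
#' @param step Streamline resampling step, mm.
#' @param peaks Optional precomputed peak matrix (must match the cohort's
#'   field list with mirrored columns).
#' @param minPatients Minimum included patients per symptom (default 10;
#'   symptoms below this are skipped with a warning).
#' @return A \linkS4class{TractModel}.
#' @export
buildTractModel <- function(cohort, tractogram, screening = screeningConfig(),
                            selection = selectionConfig(),
                            symptoms = NULL, step = 0.5, peaks = NULL,
                            minPatients = 10L) {
    symptoms <- symptoms %||% c(cohort@symptoms, "global")
    if (is.null(peaks))
        peaks <- computePeakMatrix(tractogram, cohort@fields, step = step)
    colPatient <- cohort@fieldPatient[attr(peaks, "fieldIndex")]
    stats <- .fitStats(peaks, colPatient, cohort@patients, symptoms,
                       screening, selection, minPatients = minPatients)
    if (!length(stats)) .stopf("no symptom had enough included patients")
    new("TractModel", tractogram = tractogram, stats = stats,
        screening = unclass(screening), selection = unclass(selection),
        provenance = list(cohortHash = .hashObject(cohort@patients$id),
                          nFields = ncol(peaks)))
}

#' Permutation test over rebuilt tract models
#'
#' Re-fits the model after permuting improvement values across patients
#' (each patient's hemisphere fields move jointly) and compares a model
#' statistic with its permutation null:
#' \code{p = (1 + #(perm >= observed)) / (1 + nPerm)}.
#'
#' @param cohort A \linkS4class{DBSCohort}.
#' @param tractogram A \linkS4class{Tractogram}.
#' @param statistic Function mapping a \linkS4class{TractModel} to a scalar.
#' @param nPerm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param ... Passed to \code{\link{buildTractModel}}.
#' @return List with \code{p}, \code{observed}, \code{null} (permuted
#'   statistics).
#' @export
permutationTest <- function(cohort, tractogram, statistic, nPerm = 1000,
                            seed = 1, ...) {
    peaks <- computePeakMatrix(tractogram, cohort@fields)
    observed <- statistic(buildTractModel(cohort, tractogram, peaks = peaks, ...))
    impCols <- grep("^improvement_", names(cohort@patients), value = TRUE)
    set.seed(seed)
    null <- numeric(nPerm)
    for (i in seq_len(nPerm)) {
        perm <- sample(nPatients(cohort))
        permCohort <- cohort
        permCohort@patients[impCols] <- cohort@patients[perm, impCols]
        null[i] <- statistic(suppressWarnings(
            buildTractModel(permCohort, tractogram, peaks = peaks, ...)))
    }
    list(p = (1 + sum(null >= observed)) / (1 + nPerm),
         observed = observed, null = null)
}

#' Two-sample t filtering of binarized activations
#'
#' For every streamline activated in at least \code{minActivationFraction}
#' of the stimulations, compares improvements between activated and
#' non-activated stimulations with a Welch two-sample t-test. "Activation"
#' here means the binarized peak-field criterion supplied by the caller
#' (a stand-in for an axon-model response).
#'
#' @param activations Binary matrix, streamline x stimulation.
#' @param improvements Numeric vector, one per stimulation.
#' @param minActivationFraction Minimum activation fraction (default 0.05).
#' @return data.frame with columns t and p (NA for skipped streamlines).
#' @export
ttestFilter <- function(activations, improvements,
                        minActivationFraction = 0.05) {
    stopifnot(ncol(activations) == length(improvements),
              all(activations %in% c(0, 1)))
    out <- data.frame(t = rep(NA_real_, nrow(activations)),
                      p = NA_real_)
    for (i in seq_len(nrow(activations))) {
        act <- activations[i, ] == 1
        if (mean(act) < minActivationFraction) next
        if (sum(act) < 2L || sum(!act) < 2L) next
        tt <- stats::t.test(improvements[act], improvements[!act])
        out$t[i] <- unname(tt$statistic)
        out$p[i] <- tt$p.value
    }
    out
}

#' Residualize one improvement score against another
#'
#' Ordinary least-squares residuals of \code{y ~ 1 + x}; used to regress
#' one symptom's improvement out of another before re-running the
#' filtering.
#'
#' @param y,x Numeric vectors of equal length (n >= 3).
#' @return Residual vector with mean zero.
#' @export
residualize <- function(y, x) {
    stopifnot(length(y) == length(x), length(y) >= 3L)
    if (stats::var(x, na.rm = TRUE) == 0) .stopf("x has zero variance")
    as.numeric(stats::resid(stats::lm(y ~ x)))
}

#' Power of a two-tailed correlation test (Fisher z approximation)
#'
#' \deqn{power = \Phi(z_\rho \sqrt{n-3} - z_{1-\alpha/2}) +
#'              \Phi(-z_\rho \sqrt{n-3} - z_{1-\alpha/2})}
#' with \eqn{z_\rho = atanh(\rho)}.
#'
#' @param n Sample size (>= 4).
#' @param rho Population correlation, 0 < rho < 1.
#' @param alpha Two-tailed significance level.
#' @return Power in [0, 1].
#' @export
powerCorrelation <- function(n, rho, alpha = 0.05) {
    stopifnot(n >= 4, rho > 0, rho < 1, alpha > 0, alpha < 1)
    za <- stats::qnorm(1 - alpha / 2)
    zr <- atanh(rho) * sqrt(n - 3)
    stats::pnorm(zr - za) + stats::pnorm(-zr - za)
}
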