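#' @import methods
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

#' Tractogram: bundles of 3-D streamlines in world (mm) space
#'
#' Streamlines are polylines stored as n x 3 matrices of world coordinates in
#' a template-like ("MNI") space: x lateral (positive right), y anterior,
#' z superior. Streamline order is a stable identifier: every downstream
#' statistic (screening mask, Spearman R, selection) is indexed by position
#' in this list.
#'
#' @slot streamlines List of numeric matrices (n_i x 3), each with >= 2 rows
#'   of finite coordinates.
#' @slot bundleLabels Optional character vector, one label per streamline.
#' @slot spaceTag Free-form identifier of the coordinate space.
#' @export
setClass("Tractogram",
    representation(streamlines = "list",
                   bundleLabels = "characterOrNULL",
                   spaceTag = "character"),
    prototype(streamlines = list(), bundleLabels = NULL, spaceTag = "MNI"))

setValidity("Tractogram", function(object) {
    msgs <- character()
    for (i in seq_along(object@streamlines)) {
        s <- object@streamlines[[i]]
        if (!is.matrix(s) || ncol(s) != 3L)
            msgs <- c(msgs, sprintf("streamline %d is not an n x 3 matrix", i))
        else if (nrow(s) < 2L)
            msgs <- c(msgs, sprintf("streamline %d has fewer than 2 points", i))
        else if (!all(is.finite(s)))
            msgs <- c(msgs, sprintf("streamline %d has non-finite coordinates", i))
    }
    if (!is.null(object@bundleLabels) &&
        length(object@bundleLabels) != length(object@streamlines))
        msgs <- c(msgs, "bundleLabels must have one entry per streamline")
    if (length(object@spaceTag) != 1L)
        msgs <- c(msgs, "spaceTag must be a single string")
    if (length(msgs)) msgs else TRUE
})

#' Regular 3-D grid of electric-field magnitudes
#'
#' Axis-aligned grid in world mm coordinates; values are field magnitudes in
#' V/mm. `origin` is the world position of the first voxel center and
#' `spacing` the voxel size per axis.
#'
#' @slot origin Numeric length 3, mm.
#' @slot spacing Numeric length 3, mm, all positive.
#' @slot values 3-D numeric array of magnitudes, all finite and >= 0.
#' @slot provenance One of "simulated", "loaded", "mirrored", "jittered".
#' @export
setClass("EFieldGrid",
    representation(origin = "numeric", spacing = "numeric",
                   values = "array", provenance = "character"),
    prototype(provenance = "simulated"))

setValidity("EFieldGrid", function(object) {
    msgs <- character()
    if (length(object@origin) != 3L) msgs <- c(msgs, "origin must have length 3")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
        msgs <- c(msgs, "spacing must be 3 positive values")
    if (length(dim(object@values)) != 3L)
        msgs <- c(msgs, "values must be a 3-D array")
    else if (!all(is.finite(object@values)))
        msgs <- c(msgs, sprintf("%d non-finite voxels",
                                sum(!is.finite(object@values))))
    else if (any(object@values < 0))
        msgs <- c(msgs, "field magnitudes must be >= 0")
    if (length(msgs)) msgs else TRUE
})

#' DBS electrode geometry
#'
#' Contact centers are derived from the registered lead geometry: ring
#' (omnidirectional) contacts sit on the shaft axis at fixed offsets from the
#' tip; directional segments are additionally displaced radially and rotated
#' in 120-degree steps.
#'
#' @slot modelName Registry name, e.g. "medtronic-3389".
#' @slot tip World mm position of the lead tip.
#' @slot shaftDirection Unit vector along the shaft (tip to tail).
#' @slot rotation Rotation of the segment plan around the shaft, degrees.
#' @slot contactCenters Numeric matrix (n_contacts x 3), mm.
#' @slot contactKind "omni" or "segment" per contact.
#' @export
setClass("ElectrodeSpec",
    representation(modelName = "character", tip = "numeric",
                   shaftDirection = "numeric", rotation = "numeric",
                   contactCenters = "matrix", contactKind = "character"))

setValidity("ElectrodeSpec", function(object) {
    msgs <- character()
    if (length(object@tip) != 3L) msgs <- c(msgs, "tip must have length 3")
    if (length(object@shaftDirection) != 3L ||
        abs(sqrt(sum(object@shaftDirection^2)) - 1) > 1e-9)
        msgs <- c(msgs, "shaftDirection must be a unit vector")
    if (nrow(object@contactCenters) != length(object@contactKind))
        msgs <- c(msgs, "one contactKind per contact required")
    if (!all(object@contactKind %in% c("omni", "segment")))
        msgs <- c(msgs, "contactKind must be 'omni' or 'segment'")
    if (length(msgs)) msgs else TRUE
})

#' Cathodic stimulation setting
#'
#' Per-contact currents in mA; cathodic convention, so every current is
#' less than or equal to zero with the case as implicit return.
#'
#' @slot currents Numeric vector, mA, all <= 0.
#' @export
setClass("StimulationSetting", representation(currents = "numeric"))

setValidity("StimulationSetting", function(object) {
    if (any(object@currents > 0))
        return("all currents must be <= 0 (cathodic stimulation only)")
    if (!all(is.finite(object@currents))) return("currents must be finite")
    TRUE
})

#' Cohort of DBS patients with simulated or loaded stimulation fields
#'
#' Couples the clinical table with the per-hemisphere stimulation fields.
#' Each patient contributes exactly two hemisphere fields; `fieldPatient`
#' maps field index to patient row so that patient-wise operations
#' (permutation, cross-validation folds) always move a patient's fields
#' jointly.
#'
#' @slot patients data.frame with one row per patient (id, demographics,
#'   per-symptom baseline/post/improvement columns, global improvement).
#' @slot fields List of \linkS4class{EFieldGrid}, length 2 * n_patients,
#'   native (unmirrored) hemisphere fields.
#' @slot fieldPatient Integer vector mapping each field to its patient row.
#' @slot electrodes List of \linkS4class{ElectrodeSpec} (may be empty when
#'   fields were loaded rather than simulated).
#' @slot settings List of \linkS4class{StimulationSetting}, parallel to
#'   `electrodes`.
#' @slot symptoms Character vector of symptom names with score columns.
#' @export
setClass("DBSCohort",
    representation(patients = "data.frame", fields = "list",
                   fieldPatient = "integer", electrodes = "list",
                   settings = "list", symptoms = "character"))

setValidity("DBSCohort", function(object) {
    msgs <- character()
    n <- nrow(object@patients)
    if (anyDuplicated(object@patients$id))
        msgs <- c(msgs, "patient ids must be unique")
    if (length(object@fields) != 2L * n)
        msgs <- c(msgs, "exactly two hemisphere fields per patient required")
    if (length(object@fieldPatient) != length(object@fields))
        msgs <- c(msgs, "fieldPatient must map every field")
    else if (length(object@fieldPatient) &&
             !all(sort(unique(object@fieldPatient)) == seq_len(n)))
        msgs <- c(msgs, "every patient must own fields")
    if (length(msgs)) msgs else TRUE
})

#' Symptom-network library (multi-tract model)
#'
#' Per-streamline, per-symptom Spearman statistics together with screening
#' and selection state. The special symptom "global" holds the single-tract
#' model trained on global motor (UPDRS-III) improvement.
#'
#' @slot tractogram The \linkS4class{Tractogram} the statistics index into.
#' @slot stats Named list (per symptom) of data.frames with columns
#'   rho, p, q, screened, selected, sign.
#' @slot screening List with e_threshold (V/mm) and min_field_fraction.
#' @slot selection List with n_pos, n_neg, significant_only, alpha.
#' @slot provenance List: cohort hash, number of fields, seed.
#' @export
setClass("TractModel",
    representation(tractogram = "Tractogram", stats = "list",
                   screening = "list", selection = "list",
                   provenance = "list"))

setValidity("TractModel", function(object) {
    msgs <- character()
    if (!length(object@stats)) msgs <- c(msgs, "symptom list must be non-empty")
    ns <- length(object@tractogram@streamlines)
    for (sym in names(object@stats)) {
        st <- object@stats[[sym]]
        if (nrow(st) != ns)
            msgs <- c(msgs, sprintf("stats for '%s' must cover all streamlines", sym))
        if (any(abs(st$rho) > 1 + 1e-12, na.rm = TRUE))
            msgs <- c(msgs, sprintf("|rho| > 1 in '%s'", sym))
        if (any(st$q < st$p - 1e-12, na.rm = TRUE))
            msgs <- c(msgs, sprintf("q < p in '%s'", sym))
        if (any(st$selected & !st$screened))
            msgs <- c(msgs, sprintf("selected but unscreened streamline in '%s'", sym))
    }
    if (length(msgs)) msgs else TRUE
})

#' Suggested stimulation solution
#'
#' Result of the current-steering optimizer for one electrode: the feasible
#' cathodic setting, its objective decomposition, estimated per-symptom and
#' blended improvements, and the trace of evaluated candidates.
#'
#' @slot setting \linkS4class{StimulationSetting} (mA per contact, <= 0).
#' @slot estimates Named numeric, estimated percent improvement per symptom.
#' @slot blended Single numeric, baseline/user-weighted blended estimate.
#' @slot objective List with Fval, S_ff, penalty, A (total mA magnitude).
#' @slot trace data.frame of evaluated candidates (currents, Fval).
#' @export
setClass("CleartuneSolution",
    representation(setting = "StimulationSetting", estimates = "numeric",
                   blended = "numeric", objective = "list",
                   trace = "data.frame"))

setValidity("CleartuneSolution", function(object) {
    o <- object@objective
    if (!all(c("Fval", "S_ff", "penalty", "A") %in% names(o)))
        return("objective must contain Fval, S_ff, penalty, A")
    if (is.finite(o$Fval) && abs(o$Fval - (o$S_ff + o$penalty)) > 1e-9)
        return("Fval must equal S_ff + penalty")
    if (o$penalty < 0) return("penalty must be >= 0")
    TRUE
})
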