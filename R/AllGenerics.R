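#' Accessors and generics
#'
#' Small accessor layer over the S4 containers; user code should not touch
#' slots directly.
#'
#' @param x,object An object of the documented classes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("streamlines", function(x) standardGeneric("streamlines"))
#' @rdname accessors
#' @export
setMethod("streamlines", "Tractogram", function(x) x@streamlines)

#' @rdname accessors
#' @export
setGeneric("nStreamlines", function(x) standardGeneric("nStreamlines"))
#' @rdname accessors
#' @export
setMethod("nStreamlines", "Tractogram", function(x) length(x@streamlines))

#' @rdname accessors
#' @export
setGeneric("bundleLabels", function(x) standardGeneric("bundleLabels"))
#' @rdname accessors
#' @export
setMethod("bundleLabels", "Tractogram", function(x) x@bundleLabels)

#' @rdname accessors
#' @export
setGeneric("spaceTag", function(x) standardGeneric("spaceTag"))
#' @rdname accessors
#' @export
setMethod("spaceTag", "Tractogram", function(x) x@spaceTag)

#' @rdname accessors
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))
#' @rdname accessors
#' @export
setMethod("gridOrigin", "EFieldGrid", function(x) x@origin)

#' @rdname accessors
#' @export
setGeneric("gridSpacing", function(x) standardGeneric("gridSpacing"))
#' @rdname accessors
#' @export
setMethod("gridSpacing", "EFieldGrid", function(x) x@spacing)

#' @rdname accessors
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))
#' @rdname accessors
#' @export
setMethod("gridValues", "EFieldGrid", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setMethod("provenance", "EFieldGrid", function(x) x@provenance)

#' @rdname accessors
#' @export
setGeneric("contactCenters", function(x) standardGeneric("contactCenters"))
#' @rdname accessors
#' @export
setMethod("contactCenters", "ElectrodeSpec", function(x) x@contactCenters)

#' @rdname accessors
#' @export
setGeneric("contactKind", function(x) standardGeneric("contactKind"))
#' @rdname accessors
#' @export
setMethod("contactKind", "ElectrodeSpec", function(x) x@contactKind)

#' @rdname accessors
#' @export
setGeneric("currents", function(x) standardGeneric("currents"))
#' @rdname accessors
#' @export
setMethod("currents", "StimulationSetting", function(x) x@currents)
#' @rdname accessors
#' @export
setMethod("currents", "CleartuneSolution", function(x) x@setting@currents)

#' @rdname accessors
#' @export
setGeneric("patients", function(x) standardGeneric("patients"))
#' @rdname accessors
#' @export
setMethod("patients", "DBSCohort", function(x) x@patients)

#' @rdname accessors
#' @export
setGeneric("nPatients", function(x) standardGeneric("nPatients"))
#' @rdname accessors
#' @export
setMethod("nPatients", "DBSCohort", function(x) nrow(x@patients))

#' @rdname accessors
#' @export
setGeneric("cohortFields", function(x) standardGeneric("cohortFields"))
#' @rdname accessors
#' @export
setMethod("cohortFields", "DBSCohort", function(x) x@fields)

#' @rdname accessors
#' @export
setGeneric("symptomNames", function(x) standardGeneric("symptomNames"))
#' @rdname accessors
#' @export
setMethod("symptomNames", "DBSCohort", function(x) x@symptoms)
#' @rdname accessors
#' @export
setMethod("symptomNames", "TractModel", function(x) names(x@stats))

#' @rdname accessors
#' @export
setGeneric("streamlineStats", function(x, symptom) standardGeneric("streamlineStats"))
#' @rdname accessors
#' @param symptom Symptom name present in the model.
#' @export
setMethod("streamlineStats", "TractModel", function(x, symptom) {
    if (!symptom %in% names(x@stats))
        .stopf("symptom '%s' not in model (have: %s)", symptom,
               paste(names(x@stats), collapse = ", "))
    x@stats[[symptom]]
})

#' @rdname accessors
#' @export
setGeneric("modelTractogram", function(x) standardGeneric("modelTractogram"))
#' @rdname accessors
#' @export
setMethod("modelTractogram", "TractModel", function(x) x@tractogram)

#' Mirror an object across the mid-sagittal plane (x = 0)
#'
#' Negates the x (lateral) coordinate so a left-hemisphere object lands in
#' the right hemisphere and vice versa. For grids the value array is flipped
#' along x and the origin recomputed, so the world-space content is the
#' reflection of the input. Mirroring twice is the identity.
#'
#' @param x A streamline matrix, \linkS4class{Tractogram}, or
#'   \linkS4class{EFieldGrid}.
#' @return Object of the same class, mirrored.
#' @export
setGeneric("mirror", function(x) standardGeneric("mirror"))

setMethod("show", "Tractogram", function(object) {
    cat(sprintf("Tractogram: %d streamlines [space: %s]\n",
                length(object@streamlines), object@spaceTag))
    if (!is.null(object@bundleLabels)) {
        tab <- table(object@bundleLabels)
        cat("  bundles:", paste(sprintf("%s (%d)", names(tab), tab),
                                collapse = ", "), "\n")
    }
})

setMethod("show", "EFieldGrid", function(object) {
    d <- dim(object@values)
    cat(sprintf("EFieldGrid %dx%dx%d [%s], spacing (%g, %g, %g) mm, max %.3g V/mm\n",
                d[1], d[2], d[3], object@provenance,
                object@spacing[1], object@spacing[2], object@spacing[3],
                max(object@values)))
})

setMethod("show", "ElectrodeSpec", function(object) {
    cat(sprintf("ElectrodeSpec '%s': %d contacts at tip (%.1f, %.1f, %.1f) mm\n",
                object@modelName, nrow(object@contactCenters),
                object@tip[1], object@tip[2], object@tip[3]))
})

setMethod("show", "DBSCohort", function(object) {
    cat(sprintf("DBSCohort: %d patients, %d hemisphere fields, symptoms: %s\n",
                nrow(object@patients), length(object@fields),
                paste(object@symptoms, collapse = ", ")))
})

setMethod("show", "TractModel", function(object) {
    cat(sprintf("TractModel over %d streamlines\n",
                length(object@tractogram@streamlines)))
    for (sym in names(object@stats)) {
        st <- object@stats[[sym]]
        cat(sprintf("  %-16s screened %5d  significant %5d  selected %5d\n",
                    sym, sum(st$screened), sum(st$q < object@selection$alpha,
                                               na.rm = TRUE),
                    sum(st$selected)))
    }
})

setMethod("show", "CleartuneSolution", function(object) {
    cat("CleartuneSolution\n  currents (mA):",
        paste(sprintf("%.2f", object@setting@currents), collapse = ", "), "\n")
    cat(sprintf("  Fval %.4f = S_ff %.4f + penalty %.4f (A = %.2f mA)\n",
                object@objective$Fval, object@objective$S_ff,
                object@objective$penalty, object@objective$A))
    cat(sprintf("  blended estimate: %.1f%%\n", object@blended))
})
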