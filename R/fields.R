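#' Electrode geometry registry
#'
#' Reads the YAML registry of lead geometries shipped with the package
#' (contact offsets from tip, ring vs segment plan).
#'
#' @param path Optional path to a custom registry YAML.
#' @return Named list of geometry definitions.
#' @export
electrodeModels <- function(path = NULL) {
    path <- path %||% system.file("extdata", "electrodes.yaml",
                                  package = "fibertune", mustWork = TRUE)
    yaml::read_yaml(path)
}

#' Build an electrode from the geometry registry
#'
#' Ring contact centers are \code{tip + offset * shaftDirection}; segmented
#' contacts are displaced radially by \code{segmentOffset} at their base
#' angle plus the lead rotation, in 120-degree steps per level.
#'
#' @param modelName Name in the registry (e.g. "medtronic-3389",
#'   "bsc-vercise-cartesia").
#' @param tip World mm position of the lead tip.
#' @param shaftDirection Unit vector from tip towards the lead tail.
#' @param rotation Lead rotation around the shaft, degrees (segments only).
#' @param segmentOffset Radial displacement of segment point sources, mm.
#' @param registry Geometry registry (default the shipped one).
#' @return An \linkS4class{ElectrodeSpec}.
#' @examples
#' el <- buildElectrode("medtronic-3389", tip = c(0, 0, 0),
#'                      shaftDirection = c(0, 0, 1))
#' contactCenters(el)[, 3] # 0.75 2.75 4.75 6.75
#' @export
buildElectrode <- function(modelName, tip, shaftDirection = c(0, 0, 1),
                           rotation = 0, segmentOffset = 0.65,
                           registry = electrodeModels()) {
    if (!modelName %in% names(registry))
        .stopf("unknown electrode model '%s' (known: %s)", modelName,
               paste(names(registry), collapse = ", "))
    d <- as.numeric(shaftDirection)
    if (abs(sqrt(sum(d^2)) - 1) > 1e-9)
        .stopf("shaftDirection must be a unit vector (norm %.6f)", sqrt(sum(d^2)))
    # orthonormal basis perpendicular to the shaft for segment placement
    ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    u <- ref - sum(ref * d) * d
    u <- u / sqrt(sum(u^2))
    v <- c(d[2] * u[3] - d[3] * u[2],
           d[3] * u[1] - d[1] * u[3],
           d[1] * u[2] - d[2] * u[1])
    contacts <- registry[[modelName]]$contacts
    centers <- matrix(NA_real_, length(contacts), 3L)
    kind <- character(length(contacts))
    for (i in seq_along(contacts)) {
        ct <- contacts[[i]]
        center <- tip + ct$offset * d
        kind[i] <- ct$kind
        if (ct$kind == "segment") {
            a <- (ct$angle + rotation) * pi / 180
            center <- center + segmentOffset * (cos(a) * u + sin(a) * v)
        }
        centers[i, ] <- center
    }
    new("ElectrodeSpec", modelName = modelName, tip = as.numeric(tip),
        shaftDirection = d, rotation = as.numeric(rotation),
        contactCenters = centers, contactKind = kind)
}

#' Field model configuration
#'
#' Parameters of the analytic conductor model: point current sources in an
#' infinite homogeneous medium, \eqn{E(x) = \sum_c I_c (x - p_c) /
#' (4 \pi \sigma |x - p_c|^3)}, with the magnitude stored on a regular grid.
#'
#' @param sigma Conductivity, S/m (default 0.2, a generic brain-tissue value).
#' @param spacing Grid spacing, mm.
#' @param extent Half-width of the grid around the electrode, mm.
#' @param segmentOffset Radial displacement of segment sources, mm.
#' @param clampRadius Encapsulation radius, mm; field values inside are
#'   clamped to the value at this radius to avoid the point-source
#'   singularity.
#' @return A validated list of class "FieldModelConfig".
#' @export
fieldModelConfig <- function(sigma = 0.2, spacing = 0.5, extent = 15,
                             segmentOffset = 0.65, clampRadius = 0.1) {
    stopifnot(sigma > 0, spacing > 0, extent > 0, segmentOffset > 0,
              clampRadius > 0)
    structure(list(sigma = sigma, spacing = spacing, extent = extent,
                   segmentOffset = segmentOffset, clampRadius = clampRadius),
              class = "FieldModelConfig")
}

# Active point sources (mm positions + mA currents) of a setting.
.activeSources <- function(electrode, setting) {
    cur <- setting@currents
    if (length(cur) != nrow(electrode@contactCenters))
        .stopf("setting has %d currents but electrode '%s' has %d contacts",
               length(cur), electrode@modelName, nrow(electrode@contactCenters))
    act <- which(cur != 0)
    list(sources = electrode@contactCenters[act, , drop = FALSE],
         currents = cur[act])
}

#' Simulate an electric-field magnitude grid
#'
#' Superposes point current sources at the active contact centers in an
#' infinite homogeneous medium and stores the field magnitude (V/mm) on a
#' regular grid centered on the electrode contacts. This is a deliberately
#' simple conductor model: the statistics downstream depend only on
#' suprathreshold field geometry and accept externally computed grids
#' (\code{\link{readFieldGrid}}) interchangeably.
#'
#' @param electrode An \linkS4class{ElectrodeSpec}.
#' @param setting A \linkS4class{StimulationSetting} (one current per contact).
#' @param config A \code{\link{fieldModelConfig}}.
#' @return An \linkS4class{EFieldGrid} with provenance "simulated".
#' @export
simulateEField <- function(electrode, setting, config = fieldModelConfig()) {
    src <- .activeSources(electrode, setting)
    center <- colMeans(electrode@contactCenters)
    n <- 2L * floor(config$extent / config$spacing) + 1L
    origin <- center - (n - 1) / 2 * config$spacing
    dims <- rep(n, 3L)
    if (nrow(src$sources) == 0L) {
        warning("all-zero stimulation setting: returning a zero field",
                call. = FALSE)
        return(EFieldGrid(array(0, dims), origin, config$spacing, "simulated"))
    }
    vals <- cppPointSourceGrid(as.integer(dims), origin,
                               rep(config$spacing, 3L), src$sources,
                               abs(src$currents), config$sigma,
                               config$clampRadius)
    EFieldGrid(array(vals, dims), origin, config$spacing, "simulated")
}

#' Resample a streamline at a fixed arc-length step
#'
#' @param streamline n x 3 matrix of world mm points.
#' @param step Step length, mm.
#' @return Resampled matrix including both endpoints.
#' @export
resampleStreamline <- function(streamline, step = 0.5) {
    .resamplePolyline(as.matrix(streamline), step)
}

#' Peak field magnitude along a streamline
#'
#' The streamline is resampled at \code{step} mm and the grid is sampled by
#' trilinear interpolation at every point; points outside the grid
#' contribute zero. Returns the maximum (the "peak magnitude" each
#' streamline records from a stimulation field).
#'
#' @param grid An \linkS4class{EFieldGrid}.
#' @param streamline n x 3 matrix of world mm points.
#' @param step Resampling step, mm.
#' @return Peak magnitude, V/mm.
#' @export
peakFieldAlong <- function(grid, streamline, step = 0.5) {
    pts <- .resamplePolyline(as.matrix(streamline), step)
    cppPeaksGrid(pts, c(0L, nrow(pts)), as.numeric(grid@values),
                 dim(grid@values), grid@origin, grid@spacing)[1]
}

#' @rdname mirror
#' @export
setMethod("mirror", "matrix", function(x) {
    x[, 1] <- -x[, 1]
    x
})

#' @rdname mirror
#' @export
setMethod("mirror", "Tractogram", function(x) {
    new("Tractogram", streamlines = lapply(x@streamlines, mirror),
        bundleLabels = x@bundleLabels, spaceTag = x@spaceTag)
})

#' @rdname mirror
#' @export
setMethod("mirror", "EFieldGrid", function(x) {
    d <- dim(x@values)
    newOrigin <- x@origin
    newOrigin[1] <- -(x@origin[1] + (d[1] - 1) * x@spacing[1])
    new("EFieldGrid", values = x@values[d[1]:1, , , drop = FALSE],
        origin = newOrigin, spacing = x@spacing, provenance = "mirrored")
})

#' Jitter specification
#'
#' @param fwhm Full width at half maximum of the 3-D Gaussian displacement,
#'   mm (default 2.0). The per-axis standard deviation is
#'   \code{fwhm / (2 sqrt(2 ln 2))}.
#' @param seed Optional integer seed for the displacement draw.
#' @return List of class "JitterSpec".
#' @export
jitterSpec <- function(fwhm = 2.0, seed = NULL) {
    stopifnot(fwhm > 0)
    structure(list(fwhm = fwhm, seed = seed,
                   sigma = fwhm / (2 * sqrt(2 * log(2)))),
              class = "JitterSpec")
}

#' Spatially jitter a field grid
#'
#' Translates the whole grid by a random displacement drawn per axis from
#' a Gaussian with the given FWHM. Values are untouched (translation only),
#' so the operation is exactly invertible.
#'
#' @param grid An \linkS4class{EFieldGrid}.
#' @param spec A \code{\link{jitterSpec}}.
#' @return Jittered \linkS4class{EFieldGrid}.
#' @export
jitterField <- function(grid, spec = jitterSpec()) {
    if (!is.null(spec$seed)) set.seed(spec$seed)
    d <- stats::rnorm(3L, mean = 0, sd = spec$sigma)
    new("EFieldGrid", values = grid@values, origin = grid@origin + d,
        spacing = grid@spacing, provenance = "jittered")
}

#' Peak-field matrix of a tractogram over a set of fields
#'
#' Computes the streamline x field matrix of peak magnitudes used by
#' screening and correlation. With \code{mirrored = TRUE} each field also
#' contributes a mirrored column (fields reflected across the mid-sagittal
#' plane), implemented by sampling the original grid along mirrored
#' streamlines, which is equivalent and avoids copying grids.
#'
#' @param tractogram A \linkS4class{Tractogram}.
#' @param fields List of \linkS4class{EFieldGrid}.
#' @param step Streamline resampling step, mm.
#' @param mirrored Append mirrored-field columns (default TRUE).
#' @param originShifts Optional length(fields) x 3 matrix of translations
#'   added to each grid origin before sampling (used by the jitter
#'   robustness analysis).
#' @return Matrix (n_streamlines x n_columns) with attributes
#'   \code{fieldIndex} (source field of each column) and \code{mirroredCol}.
#' @export
computePeakMatrix <- function(tractogram, fields, step = 0.5,
                              mirrored = TRUE, originShifts = NULL) {
    stk <- .stackStreamlines(tractogram@streamlines, step)
    stkM <- if (mirrored) {
        m <- stk$pts
        m[, 1] <- -m[, 1]
        list(pts = m, offsets = stk$offsets)
    } else NULL
    nf <- length(fields)
    ncols <- if (mirrored) 2L * nf else nf
    P <- matrix(0, length(tractogram@streamlines), ncols)
    for (i in seq_len(nf)) {
        g <- fields[[i]]
        org <- g@origin
        if (!is.null(originShifts)) org <- org + originShifts[i, ]
        vals <- as.numeric(g@values)
        P[, i] <- cppPeaksGrid(stk$pts, stk$offsets, vals, dim(g@values),
                               org, g@spacing)
        if (mirrored) {
            # mirrored field sampled as original field along mirrored points
            orgM <- org
            P[, nf + i] <- cppPeaksGrid(stkM$pts, stkM$offsets, vals,
                                        dim(g@values), orgM, g@spacing)
        }
    }
    structure(P,
              fieldIndex = rep(seq_len(nf), times = if (mirrored) 2L else 1L),
              mirroredCol = rep(c(FALSE, TRUE), each = nf)[seq_len(ncols)])
}
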