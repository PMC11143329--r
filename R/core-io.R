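#' Construct a Tractogram
#'
#' @param streamlines List of n x 3 numeric matrices (world mm coordinates;
#'   x lateral positive right, y anterior, z superior).
#' @param bundleLabels Optional character vector, one per streamline.
#' @param spaceTag Free-form space identifier.
#' @return A \linkS4class{Tractogram}.
#' @examples
#' tg <- Tractogram(list(cbind(0:4, 0, 0), cbind(0, 0:4, 0)))
#' nStreamlines(tg)
#' @export
Tractogram <- function(streamlines, bundleLabels = NULL, spaceTag = "MNI") {
    streamlines <- lapply(streamlines, function(s) {
        s <- as.matrix(s)
        storage.mode(s) <- "double"
        dimnames(s) <- NULL
        s
    })
    new("Tractogram", streamlines = streamlines,
        bundleLabels = bundleLabels, spaceTag = spaceTag)
}

#' Construct an EFieldGrid
#'
#' @param values 3-D array of field magnitudes (V/mm).
#' @param origin World mm position of the first voxel center.
#' @param spacing Voxel size per axis, mm.
#' @param provenance "simulated", "loaded", "mirrored" or "jittered".
#' @return An \linkS4class{EFieldGrid}.
#' @export
EFieldGrid <- function(values, origin, spacing, provenance = "simulated") {
    if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
    new("EFieldGrid", values = values, origin = as.numeric(origin),
        spacing = as.numeric(spacing), provenance = provenance)
}

#' Construct a StimulationSetting
#'
#' @param currents Per-contact currents in mA, all <= 0 (cathodic).
#' @return A \linkS4class{StimulationSetting}.
#' @export
StimulationSetting <- function(currents) {
    new("StimulationSetting", currents = as.numeric(currents))
}

.detectFormat <- function(path, format) {
    if (!is.null(format)) return(match.arg(format, c("trk", "tck", "json")))
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("trk", "tck", "json")) return(ext)
    .stopf("cannot infer tractogram format from '%s'; pass format=", path)
}

# ---- TRK (TrackVis v2) ------------------------------------------------------
# Points are stored in "voxmm" coordinates with the TrackVis corner-of-voxel
# convention: world = vox_to_ras %*% (p / voxel_size - 0.5). The same
# convention nibabel applies when reading to RAS mm.

.trkWorldFromVoxmm <- function(p, affine, voxelSize) {
    v <- sweep(p, 2, voxelSize, "/") - 0.5
    t(affine[1:3, 1:3] %*% t(v) + affine[1:3, 4])
}

.trkVoxmmFromWorld <- function(p, affine, voxelSize) {
    v <- t(solve(affine[1:3, 1:3], t(p) - affine[1:3, 4])) + 0.5
    sweep(v, 2, voxelSize, "*")
}

.readTrk <- function(path) {
    con <- file(path, "rb")
    on.exit(close(con))
    id <- readBin(con, "raw", 6L)
    if (rawToChar(id[1:5]) != "TRACK") .stopf("malformed TRK header in '%s'", path)
    dims <- readBin(con, "integer", 3L, size = 2L, endian = "little")
    voxelSize <- readBin(con, "double", 3L, size = 4L, endian = "little")
    invisible(readBin(con, "double", 3L, size = 4L, endian = "little")) # origin
    nScalars <- readBin(con, "integer", 1L, size = 2L, endian = "little")
    invisible(readBin(con, "raw", 200L))
    nProps <- readBin(con, "integer", 1L, size = 2L, endian = "little")
    invisible(readBin(con, "raw", 200L))
    affine <- matrix(readBin(con, "double", 16L, size = 4L, endian = "little"),
                     4L, 4L, byrow = TRUE)
    invisible(readBin(con, "raw", 444L + 4L + 4L + 24L + 2L + 6L))
    nCount <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    version <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    hdrSize <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (hdrSize != 1000L) .stopf("malformed TRK header (hdr_size %d)", hdrSize)
    if (version >= 2L && affine[4, 4] == 0)
        .stopf("TRK file '%s' has an empty vox_to_ras affine", path)
    if (version < 2L || affine[4, 4] == 0) affine <- diag(4)
    streamlines <- vector("list", max(nCount, 0L))
    i <- 0L
    repeat {
        np <- readBin(con, "integer", 1L, size = 4L, endian = "little")
        if (length(np) == 0L) break
        i <- i + 1L
        if (np < 1L) .stopf("zero-length streamline at index %d in '%s'", i, path)
        dat <- readBin(con, "double", np * (3L + nScalars), size = 4L,
                       endian = "little")
        if (nProps > 0L)
            invisible(readBin(con, "double", nProps, size = 4L, endian = "little"))
        p <- matrix(dat, ncol = 3L + nScalars, byrow = TRUE)[, 1:3, drop = FALSE]
        streamlines[[i]] <- .trkWorldFromVoxmm(p, affine, voxelSize)
    }
    Tractogram(streamlines[seq_len(i)], spaceTag = "world-mm")
}

.writeTrk <- function(tractogram, path, affine) {
    voxelSize <- sqrt(colSums(affine[1:3, 1:3]^2))
    voxmm <- lapply(tractogram@streamlines, .trkVoxmmFromWorld,
                    affine = affine, voxelSize = voxelSize)
    allv <- do.call(rbind, voxmm)
    dims <- if (is.null(allv)) c(1L, 1L, 1L) else
        pmax(as.integer(ceiling(apply(allv, 2, max) / voxelSize)) + 2L, 1L)
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(c(charToRaw("TRACK"), as.raw(0L)), con)
    writeBin(as.integer(dims), con, size = 2L, endian = "little")
    writeBin(as.numeric(voxelSize), con, size = 4L, endian = "little")
    writeBin(numeric(3L), con, size = 4L, endian = "little") # origin (unused)
    writeBin(0L, con, size = 2L, endian = "little")          # n_scalars
    writeBin(raw(200L), con)
    writeBin(0L, con, size = 2L, endian = "little")          # n_properties
    writeBin(raw(200L), con)
    writeBin(as.numeric(t(affine)), con, size = 4L, endian = "little")
    writeBin(raw(444L), con)
    writeBin(c(charToRaw("RAS"), as.raw(0L)), con)           # voxel_order
    writeBin(raw(4L + 24L + 2L + 6L), con)
    writeBin(length(voxmm), con, size = 4L, endian = "little")
    writeBin(2L, con, size = 4L, endian = "little")          # version
    writeBin(1000L, con, size = 4L, endian = "little")
    for (p in voxmm) {
        writeBin(nrow(p), con, size = 4L, endian = "little")
        writeBin(as.numeric(t(p)), con, size = 4L, endian = "little")
    }
    invisible(path)
}

# ---- TCK (MRtrix) -----------------------------------------------------------
# World-mm float32 triplets; streamlines delimited by NaN triplets, stream
# terminated by an Inf triplet.

.readTck <- function(path) {
    hdr <- readLines(path, n = 50L, warn = FALSE)
    if (!grepl("^mrtrix tracks", hdr[1])) .stopf("malformed TCK header in '%s'", path)
    fileLine <- grep("^file:", hdr, value = TRUE)
    if (!length(fileLine)) .stopf("TCK header in '%s' lacks a file: entry", path)
    offset <- as.integer(sub(".*\\.\\s+", "", fileLine[1]))
    dt <- sub("^datatype:\\s*", "", grep("^datatype:", hdr, value = TRUE)[1])
    if (!identical(dt, "Float32LE"))
        .stopf("unsupported TCK datatype '%s'", dt)
    sz <- file.info(path)$size
    con <- file(path, "rb")
    on.exit(close(con))
    invisible(readBin(con, "raw", offset))
    dat <- readBin(con, "double", (sz - offset) / 4L, size = 4L, endian = "little")
    m <- matrix(dat, ncol = 3L, byrow = TRUE)
    isNan <- rowSums(is.na(m)) > 0
    isInf <- rowSums(is.infinite(m)) > 0
    breaks <- which(isNan | isInf)
    starts <- c(1L, head(breaks, -1L) + 1L)
    streamlines <- list()
    for (i in seq_along(breaks)) {
        if (isInf[breaks[i]] && starts[i] == breaks[i]) break
        rows <- starts[i]:(breaks[i] - 1L)
        if (length(rows) < 1L || breaks[i] == starts[i])
            .stopf("zero-length streamline at index %d in '%s'", i, path)
        streamlines[[length(streamlines) + 1L]] <- m[rows, , drop = FALSE]
        if (isInf[breaks[i]]) break
    }
    Tractogram(streamlines, spaceTag = "world-mm")
}

.writeTck <- function(tractogram, path) {
    header <- c("mrtrix tracks", "datatype: Float32LE",
                sprintf("count: %d", length(tractogram@streamlines)))
    # fixed-width offset field so the byte count is exact
    fileLine <- "file: . XXXXX"
    offset <- sum(nchar(c(header, fileLine, "END"))) +
        length(header) + 2L                       # newlines
    header <- c(header, sprintf("file: . %5d", offset), "END")
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(header, con, sep = "\n")
    for (s in tractogram@streamlines) {
        writeBin(as.numeric(t(s)), con, size = 4L, endian = "little")
        writeBin(rep(NaN, 3L), con, size = 4L, endian = "little")
    }
    writeBin(rep(Inf, 3L), con, size = 4L, endian = "little")
    invisible(path)
}

# ---- JSON dialect -----------------------------------------------------------
# Plain-text schema so test fixtures need no binary files:
# {"space": tag, "streamlines": [[[x,y,z], ...], ...], "bundle_labels": [...]}

.readJsonTractogram <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = FALSE)
    sl <- obj$streamlines
    if (is.null(sl)) .stopf("'%s' is not a tractogram JSON (no streamlines)", path)
    streamlines <- lapply(seq_along(sl), function(i) {
        pts <- sl[[i]]
        if (length(pts) < 2L)
            .stopf("zero-length streamline at index %d in '%s'", i, path)
        m <- do.call(rbind, lapply(pts, function(p) as.numeric(unlist(p))))
        if (ncol(m) != 3L)
            .stopf("streamline %d in '%s' is not a list of 3-D points", i, path)
        m
    })
    labels <- obj$bundle_labels
    if (!is.null(labels)) labels <- as.character(unlist(labels))
    Tractogram(streamlines, bundleLabels = labels,
               spaceTag = obj$space %||% "world-mm")
}

.writeJsonTractogram <- function(tractogram, path) {
    obj <- list(space = tractogram@spaceTag,
                streamlines = lapply(tractogram@streamlines, unname))
    if (!is.null(tractogram@bundleLabels))
        obj$bundle_labels <- tractogram@bundleLabels
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Read a tractogram (TRK, TCK or JSON dialect)
#'
#' Coordinates are returned in world mm space: TRK voxel-space points are
#' transformed through the header affine (TrackVis corner convention), TCK
#' and the JSON dialect already store world mm. Streamline order is
#' preserved and acts as the stable index for all downstream statistics.
#'
#' @param path File path.
#' @param format "trk", "tck" or "json"; inferred from the extension when
#'   omitted.
#' @return A \linkS4class{Tractogram}.
#' @export
readTractogram <- function(path, format = NULL) {
    if (!file.exists(path)) .stopf("file '%s' does not exist", path)
    switch(.detectFormat(path, format),
           trk = .readTrk(path),
           tck = .readTck(path),
           json = .readJsonTractogram(path))
}

#' Write a tractogram
#'
#' Round trips with \code{\link{readTractogram}} to floating tolerance.
#' Bundle labels are preserved only by the JSON dialect; TRK and TCK carry
#' geometry alone.
#'
#' @param tractogram A \linkS4class{Tractogram}.
#' @param path Output path.
#' @param format "trk", "tck" or "json"; inferred from extension if omitted.
#' @param affine 4 x 4 voxel-to-world affine used for TRK voxel coordinates
#'   (default identity, i.e. 1 mm isotropic voxels at the world origin).
#' @return The path, invisibly.
#' @export
writeTractogram <- function(tractogram, path, format = NULL, affine = diag(4)) {
    stopifnot(is(tractogram, "Tractogram"))
    validObject(tractogram)
    format <- .detectFormat(path, format)
    if (format != "json" && !is.null(tractogram@bundleLabels))
        warning("bundle labels are only preserved by the json dialect",
                call. = FALSE)
    switch(format,
           trk = .writeTrk(tractogram, path, affine),
           tck = .writeTck(tractogram, path),
           json = .writeJsonTractogram(tractogram, path))
    invisible(path)
}

# ---- NIfTI field grids ------------------------------------------------------

#' Read a field-magnitude grid from NIfTI
#'
#' Accepts single-volume 3-D images with an axis-aligned, positive-diagonal
#' world affine (the convention all grids written by this package use).
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @return An \linkS4class{EFieldGrid} with provenance "loaded".
#' @export
readFieldGrid <- function(path) {
    img <- RNifti::readNifti(path)
    v <- as.array(img)
    if (length(dim(v)) == 4L && dim(v)[4] == 1L) v <- v[, , , 1L]
    if (length(dim(v)) != 3L)
        .stopf("'%s' is not a single-volume 3-D image (dims: %s)", path,
               paste(dim(v), collapse = "x"))
    if (!all(is.finite(v)))
        .stopf("'%s' contains %d non-finite voxels", path, sum(!is.finite(v)))
    aff <- RNifti::xform(img)
    rot <- aff[1:3, 1:3]
    if (any(abs(rot - diag(diag(rot))) > 1e-4) || any(diag(rot) <= 0))
        .stopf("'%s' has a rotated or flipped affine; only axis-aligned RAS grids are supported", path)
    EFieldGrid(unclass(v), origin = aff[1:3, 4], spacing = diag(rot),
               provenance = "loaded")
}

#' Write a field-magnitude grid to NIfTI
#'
#' @param grid An \linkS4class{EFieldGrid}.
#' @param path Output path (.nii or .nii.gz).
#' @return The path, invisibly.
#' @export
writeFieldGrid <- function(grid, path) {
    stopifnot(is(grid, "EFieldGrid"))
    validObject(grid)
    img <- RNifti::asNifti(grid@values)
    RNifti::pixdim(img) <- grid@spacing
    aff <- diag(c(grid@spacing, 1))
    aff[1:3, 4] <- grid@origin
    RNifti::qform(img) <- structure(aff, code = 2L)
    RNifti::sform(img) <- structure(aff, code = 2L)
    RNifti::writeNifti(img, path)
    invisible(path)
}

#' Read a clinical cohort table from CSV
#'
#' A thin, checked wrapper around \code{read.csv}: requires the listed
#' columns, rejects duplicate patient ids, and keeps blank numeric cells as
#' missing values (never zero).
#'
#' @param path CSV file with a header.
#' @param requiredColumns Columns that must be present (default "id").
#' @return A data.frame with one row per patient.
#' @export
readCohort <- function(path, requiredColumns = "id") {
    if (!file.exists(path)) .stopf("file '%s' does not exist", path)
    tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                           na.strings = c("", "NA"))
    missing <- setdiff(requiredColumns, names(tab))
    if (length(missing))
        .stopf("cohort table lacks required column(s): %s",
               paste(missing, collapse = ", "))
    dup <- tab$id[duplicated(tab$id)]
    if (length(dup))
        .stopf("duplicate patient id(s): %s", paste(unique(dup), collapse = ", "))
    itemCols <- grep("^(pre|post)_item", names(tab), value = TRUE)
    for (cl in itemCols)
        if (any(tab[[cl]] < 0, na.rm = TRUE))
            .stopf("negative item scores in column %s", cl)
    tab
}
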