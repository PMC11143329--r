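test_that("tractogram round trips preserve coordinates in every format", {
    tg <- toyTractogram()
    for (fmt in c("json", "tck", "trk")) {
        path <- tempfile(fileext = paste0(".", fmt))
        writeTractogram(if (fmt == "json") tg else
                            Tractogram(streamlines(tg)), path)
        back <- readTractogram(path)
        expect_equal(nStreamlines(back), 3L)
        for (i in 1:3)
            expect_equal(streamlines(back)[[i]], streamlines(tg)[[i]],
                         tolerance = 1e-5, ignore_attr = TRUE)
    }
})

test_that("empty tractograms and bundle labels are handled", {
    empty <- Tractogram(list())
    path <- tempfile(fileext = ".json")
    writeTractogram(empty, path)
    expect_equal(nStreamlines(readTractogram(path)), 0L)
    tg <- toyTractogram()
    writeTractogram(tg, path)
    expect_equal(bundleLabels(readTractogram(path)), c("a", "b", "a"))
    expect_warning(writeTractogram(tg, tempfile(fileext = ".tck")),
                   "bundle labels")
})

test_that("TRK voxel-space points are mapped through the header affine", {
    # hand-written TRK: spacing (2,2,2), translation (-10,-10,-10); a 2-point
    # streamline at voxel coordinates (1,1,1) and (2,3,4). The TrackVis
    # convention stores voxmm = voxel * spacing with corner-of-voxel origin,
    # so world = A %*% (vox - 0.5) for A = diag(2,2,2) + t.
    path <- tempfile(fileext = ".trk")
    con <- file(path, "wb")
    writeBin(c(charToRaw("TRACK"), as.raw(0L)), con)
    writeBin(c(20L, 20L, 20L), con, size = 2L, endian = "little")
    writeBin(c(2, 2, 2), con, size = 4L, endian = "little")
    writeBin(numeric(3), con, size = 4L, endian = "little")
    writeBin(0L, con, size = 2L, endian = "little"); writeBin(raw(200L), con)
    writeBin(0L, con, size = 2L, endian = "little"); writeBin(raw(200L), con)
    A <- rbind(c(2, 0, 0, -10), c(0, 2, 0, -10), c(0, 0, 2, -10),
               c(0, 0, 0, 1))
    writeBin(as.numeric(t(A)), con, size = 4L, endian = "little")
    writeBin(raw(444L), con)
    writeBin(c(charToRaw("RAS"), as.raw(0L)), con)
    writeBin(raw(4L + 24L + 2L + 6L), con)
    writeBin(1L, con, size = 4L, endian = "little")
    writeBin(2L, con, size = 4L, endian = "little")
    writeBin(1000L, con, size = 4L, endian = "little")
    vox <- rbind(c(1, 1, 1), c(2, 3, 4))
    writeBin(2L, con, size = 4L, endian = "little")
    writeBin(as.numeric(t(vox * 2)), con, size = 4L, endian = "little")
    close(con)
    got <- streamlines(readTractogram(path))[[1]]
    expected <- t(apply(vox, 1, function(v) (A %*% c(v - 0.5, 1))[1:3]))
    expect_equal(got, expected, tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("TRK output is readable by an independent reader (nibabel)", {
    tg <- Tractogram(streamlines(toyTractogram()))
    path <- tempfile(fileext = ".trk")
    writeTractogram(tg, path)
    out <- system2("python", c("-c", shQuote(paste0(
        "import nibabel as nib, numpy as np; ",
        "t = nib.streamlines.load('", path, "'); ",
        "print(repr([s.tolist() for s in t.streamlines]))"))),
        stdout = TRUE, stderr = FALSE)
    got <- eval(parse(text = gsub("\\]", ")", gsub("\\[", "list(",
                                                   paste(out, collapse = "")))))
    for (i in 1:3) {
        m <- do.call(rbind, lapply(got[[i]], unlist))
        expect_equal(m, streamlines(tg)[[i]], tolerance = 1e-4,
                     ignore_attr = TRUE)
    }
})

test_that("malformed tractogram input is rejected with informative errors", {
    expect_error(readTractogram(tempfile(), "json"), "does not exist")
    bad <- tempfile(fileext = ".trk")
    writeBin(charToRaw("NOTATRACK"), bad)
    expect_error(readTractogram(bad), "malformed")
    js <- tempfile(fileext = ".json")
    jsonlite::write_json(list(streamlines = list(list(c(1, 2, 3)))), js)
    expect_error(readTractogram(js), "index 1")
    expect_error(readTractogram(js, "xyz"))
})

test_that("field grids round trip through NIfTI with anisotropic spacing", {
    vals <- array(0.5, c(7, 6, 5))
    g <- EFieldGrid(vals, origin = c(-3, -2, -1), spacing = c(0.5, 0.5, 1.0))
    path <- tempfile(fileext = ".nii.gz")
    writeFieldGrid(g, path)
    back <- readFieldGrid(path)
    expect_equal(gridValues(back), gridValues(g), tolerance = 1e-6,
                 ignore_attr = TRUE)
    expect_equal(gridSpacing(back), c(0.5, 0.5, 1.0), tolerance = 1e-6)
    expect_equal(gridOrigin(back), c(-3, -2, -1), tolerance = 1e-6)
    expect_equal(provenance(back), "loaded")
    # trilinear sample at a voxel center equals the stored value
    g2 <- EFieldGrid(array(seq_len(27) / 10, c(3, 3, 3)), c(0, 0, 0),
                     c(1, 1, 1))
    expect_equal(peakFieldAlong(g2, rbind(c(1, 1, 1), c(1, 1, 1 + 1e-9))),
                 gridValues(g2)[2, 2, 2])
})

test_that("degenerate NIfTI inputs are rejected", {
    path <- tempfile(fileext = ".nii.gz")
    img <- RNifti::asNifti(array(1, c(3, 3, 3, 2)))
    RNifti::writeNifti(img, path)
    expect_error(readFieldGrid(path), "3-D")
    img2 <- RNifti::asNifti(array(c(NaN, rep(1, 7)), c(2, 2, 2)))
    RNifti::writeNifti(img2, path)
    expect_error(readFieldGrid(path), "non-finite")
})

test_that("cohort CSV reading enforces ids and keeps blanks missing", {
    path <- tempfile(fileext = ".csv")
    writeLines(c("id,center,age,pre_item22",
                 "p1,A,60,2", "p2,A,55,", "p3,B,61,3"), path)
    tab <- readCohort(path)
    expect_equal(nrow(tab), 3L)
    expect_true(is.na(tab$pre_item22[2]))   # blank stays missing, not zero
    writeLines(c("id,center", "p1,A", "p1,B"), path)
    expect_error(readCohort(path), "p1")
    writeLines(c("center,age", "A,60"), path)
    expect_error(readCohort(path), "id")
})
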