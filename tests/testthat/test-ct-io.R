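test_that("NIfTI write/read round-trips dims, spacing and voxels", {
  ph <- makePhantom("sphere", list(r = 15), spacing_mm = c(1, 1, 2))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  writePhantom(ph, f)
  ct <- readCT(f)
  expect_identical(dim(voxels(ct)), dim(voxels(ph$ct)))
  expect_equal(spacing(ct), spacing(ph$ct), tolerance = 1e-6)
  expect_true(all(abs(voxels(ct) - voxels(ph$ct)) < 1e-6))
  # sidecar carries the analytic truth
  side <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(side$analytic_surface_cm2, ph$analytic_surface_cm2,
               tolerance = 1e-9)
})

test_that("MetaImage files load with correct geometry", {
  ph <- makePhantom("cube", list(a = 10), spacing_mm = c(2, 1, 1))
  f <- withr::local_tempfile(fileext = ".mha")
  ibsa:::.write_metaimage(ph$ct, f)
  ct <- readCT(f)
  expect_identical(dim(voxels(ct)), dim(voxels(ph$ct)))
  expect_equal(spacing(ct), c(2, 1, 1))
  expect_true(all(voxels(ct) == voxels(ph$ct)))
})

test_that("DICOM series is rescaled to HU and sorted by position, not name", {
  d1 <- write_dicom_series(withr::local_tempdir(), stored = 1024L)
  ct <- readCT(d1, format = "dicom_dir")
  expect_true(all(voxels(ct) == 0))            # 1024 * 1 - 1024
  expect_equal(spacing(ct), c(0.7, 0.7, 3))
  # shuffled file names, positions in reverse file order -> identical volume
  d2 <- write_dicom_series(withr::local_tempdir(), n_slices = 4,
                           names = c("z.dcm", "a.dcm", "m.dcm", "b.dcm"))
  d3 <- write_dicom_series(withr::local_tempdir(), n_slices = 4)
  expect_identical(voxels(readCT(d2)), voxels(readCT(d3)))
})

test_that("corrupt DICOM series are rejected with specific errors", {
  # remove the middle slice -> inconsistent series
  d <- write_dicom_series(withr::local_tempdir(), n_slices = 5)
  file.remove(file.path(d, "s03.dcm"))
  expect_error(readCT(d), "inconsistent series")
  # duplicated position
  d2 <- write_dicom_series(withr::local_tempdir(), n_slices = 3, z_step = 0)
  expect_error(readCT(d2), "inconsistent series")
  # two series UIDs mixed in one directory
  d3 <- write_dicom_series(withr::local_tempdir(), n_slices = 2)
  write_dicom_series(d3, n_slices = 2, uid = "1.2.826.0.1.999999.2",
                     names = c("x1.dcm", "x2.dcm"), z0 = 50)
  expect_error(readCT(d3), "multiple series")
  expect_error(readCT(tempfile()), "format error")
})

test_that("slice-spacing/thickness disagreement over 10% warns", {
  d <- write_dicom_series(withr::local_tempdir(), z_step = 1.5, thickness = 3)
  expect_warning(readCT(d), "differs >10%")
})

test_that("mask writing round-trips bit-for-bit and checks geometry", {
  ph <- makePhantom("sphere", list(r = 12))
  mask <- segmentBody(ph$ct, seg_cfg_small)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  writeMask(mask, ph$ct, f)
  back <- readMask(f)
  expect_identical(voxels(back), voxels(mask))
  # all-ones mask: file voxel sum equals grid size
  ones <- BodyMask(array(TRUE, dim = dim(voxels(ph$ct))), spacing(ph$ct))
  f2 <- withr::local_tempfile(fileext = ".nii.gz")
  writeMask(ones, ph$ct, f2)
  expect_equal(sum(voxels(readMask(f2))), prod(dim(voxels(ph$ct))))
  # wrong z dimension -> geometry mismatch
  bad <- BodyMask(array(TRUE, dim = dim(voxels(ph$ct)) + c(0L, 0L, 1L)),
                  spacing(ph$ct))
  expect_error(writeMask(bad, ph$ct, f2), "geometry mismatch")
})

test_that("QC overlays contour the mask and validate slice indices", {
  ph <- makePhantom("sphere", list(r = 12))
  mask <- segmentBody(ph$ct, seg_cfg_small)
  d <- dim(voxels(ph$ct))
  mid <- (d[3] + 1L) %/% 2L
  qc <- qcOverlay(ph$ct, mask, c(1L, mid, d[3]))
  expect_length(qc@overlays, 3L)
  expect_gt(qc@overlays[[2]]$n_contour_px, 0)          # equator has a contour
  expect_identical(dim(qc@overlays[[2]]$ct), d[1:2])   # image matches slice
  # empty mask -> zero contour pixels
  empty <- BodyMask(array(FALSE, dim = d), spacing(ph$ct))
  qc0 <- qcOverlay(ph$ct, empty, mid)
  expect_equal(qc0@overlays[[1]]$n_contour_px, 0)
  expect_error(qcOverlay(ph$ct, mask, d[3] + 1L), "slice out of range")
  # PNG export writes one panel per slice plus 3 projections
  out <- withr::local_tempdir()
  writeQcBundle(qc, out)
  expect_length(list.files(out, pattern = "qc_slice"), 3L)
  expect_length(list.files(out, pattern = "qc_projection"), 3L)
})
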