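test_that("thresholding matches the phantom's voxelization exactly", {
  ph <- sphere40()
  mask <- thresholdBody(ph$ct, -400)
  # direct count oracle: voxel centres inside the sphere
  d <- dim(voxels(ph$ct))
  centre <- (d - 1) / 2
  cx <- (seq_len(d[1]) - 1) - centre[1]
  cy <- (seq_len(d[2]) - 1) - centre[2]
  cz <- (seq_len(d[3]) - 1) - centre[3]
  inside <- outer(outer(cx^2, cy^2, "+"), cz^2, "+") <= 40^2
  expect_equal(sum(voxels(mask)), sum(inside))
  expect_identical(dim(voxels(mask)), d)
})

test_that("threshold boundary cases: all-air empty, below-range full", {
  air <- CTVolume(array(-1000, dim = c(8, 8, 8)), c(1, 1, 1))
  expect_equal(sum(voxels(thresholdBody(air, -400))), 0)
  expect_true(all(voxels(thresholdBody(air, -1025))))
})

test_that("lowering the threshold never shrinks the foreground", {
  set.seed(7)
  ct <- CTVolume(array(runif(8000, -1024, 300), dim = c(20, 20, 20)), c(1, 1, 1))
  counts <- sapply(c(200, 0, -200, -400, -600, -800), function(th)
    sum(voxels(thresholdBody(ct, th))))
  expect_true(all(diff(counts) >= 0))
})

test_that("cavity filling recovers the solid phantom exactly", {
  hollow <- makePhantom("sphere", list(r = 40),
                        cavity = list(shape = "sphere", dimensions = list(r = 20)))
  refined <- segmentBody(hollow$ct, seg_cfg)
  solid_vox <- voxels(thresholdBody(sphere40()$ct, -400))
  expect_identical(voxels(refined), solid_vox)
  expect_equal(countCavities(refined), 0L)
})

test_that("a detached couch-like slab is removed", {
  ph <- makePhantom("sphere", list(r = 30), margin_mm = 12)
  vox <- voxels(ph$ct)
  d <- dim(vox)
  vox[, , 1:2] <- 40                      # 2-voxel slab at the volume edge
  ct <- CTVolume(vox, spacing(ph$ct))
  mask <- segmentBody(ct, seg_cfg)
  expect_false(any(voxels(mask)[, , 1:2]))
  lab <- ibsa:::.cpp_label(as.vector(voxels(mask)), d, 26L)
  expect_equal(attr(lab, "n_components"), 1L)
})

test_that("segmentation is idempotent on its own output", {
  ph <- makePhantom("sphere", list(r = 30),
                    cavity = list(shape = "sphere", dimensions = list(r = 12)))
  mask <- segmentBody(ph$ct, seg_cfg)
  hu <- array(ifelse(voxels(mask), 40, -1000), dim = dim(voxels(mask)))
  mask2 <- segmentBody(CTVolume(hu, spacing(mask)), seg_cfg)
  expect_identical(voxels(mask2), voxels(mask))
})

test_that("composite body segments to one cavity-free component", {
  ph <- makePhantom("body_composite",
                    list(torso_r = 40, torso_h = 80, head_r = 20,
                         head_embed = 8, leg_r = 12, leg_h = 50),
                    cavity = list(shape = "sphere", dimensions = list(r = 15),
                                  hu = -800))          # lung-like inclusion
  mask <- segmentBody(ph$ct, seg_cfg)
  lab <- ibsa:::.cpp_label(as.vector(voxels(mask)), dim(voxels(mask)), 26L)
  expect_equal(attr(lab, "n_components"), 1L)
  expect_equal(countCavities(mask), 0L)
})

test_that("half-voxel translation changes the mask by less than 1%", {
  ph0 <- sphere40()
  ph1 <- makePhantom("sphere", list(r = 40),
                     origin_offset_vox = c(0.5, 0.3, 0.2))
  n0 <- sum(voxels(segmentBody(ph0$ct, seg_cfg)))
  n1 <- sum(voxels(segmentBody(ph1$ct, seg_cfg)))
  expect_lt(abs(n1 - n0) / n0, 0.01)
})

test_that("degenerate inputs raise 'no body found'", {
  air <- CTVolume(array(-1000, dim = c(10, 10, 10)), c(1, 1, 1))
  expect_error(segmentBody(air), "no body found")
  # below the minimum component volume
  ph <- makePhantom("sphere", list(r = 10))
  expect_error(segmentBody(ph$ct, segConfig(min_component_volume_ml = 500)),
               "no body found")
})

test_that("noise far from the threshold does not change the segmentation", {
  quiet <- makePhantom("sphere", list(r = 25))
  noisy <- makePhantom("sphere", list(r = 25), noise_sd_hu = 50, seed = 9)
  expect_identical(voxels(segmentBody(noisy$ct, seg_cfg)),
                   voxels(segmentBody(quiet$ct, seg_cfg)))
})
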