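vol3 <- function(values, spacing = 1, kind = "raw") {
  n <- length(values)
  imageVolume(array(values, c(n, 1, 1)), spacing, kind = kind)
}

test_that("grayscale normalisation truncates, scales and rounds as specified", {
  v <- vol3(c(-100, 0, 510, 1020))
  g <- normalizeGrayscale(v, referenceMax = 1020)
  expect_equal(as.vector(voxelData(g)), c(0, 0, 128, 255))
  expect_equal(volumeKind(g), "gray8")
  # per-volume maximum: a uniform positive volume maps to 255 everywhere
  expect_true(all(voxelData(normalizeGrayscale(vol3(rep(7, 4)))) == 255))
  # all-negative volume with no reference is degenerate
  expect_error(normalizeGrayscale(vol3(c(-5, -1, -10, -2))), "degenerate")
  # idempotent on its own output at referenceMax 255
  g2 <- normalizeGrayscale(imageVolume(voxelData(g), voxelSpacing(g),
                                       kind = "raw"), referenceMax = 255)
  expect_equal(voxelData(g2), voxelData(g))
})

test_that("scanner grayscale conversion is an affine clamped map", {
  g <- vol3(c(0, 100, 200, 255), kind = "gray8")
  expect_equal(voxelData(convertScannerGrayscale(g, 1, 0)), voxelData(g))
  expect_equal(as.vector(voxelData(convertScannerGrayscale(g, 0.5, 10))),
               c(10, 60, 110, 138))
  expect_equal(as.vector(voxelData(convertScannerGrayscale(g, 2, 0))),
               c(0, 200, 255, 255))
})

test_that("partial-volume down-sampling is an overlap-weighted mean", {
  # constant volume stays constant at any target spacing
  u <- imageVolume(array(37, c(4, 4, 4)), 0.5, kind = "gray8")
  expect_true(all(voxelData(downsamplePartialVolume(u, 1.0)) == 37))
  expect_true(all(voxelData(downsamplePartialVolume(u, 0.7)) == 37))
  # 2x2x2 block of {0,255} halves -> single voxel at 128 (127.5 rounded up)
  b <- imageVolume(array(c(rep(0, 4), rep(255, 4)), c(2, 2, 2)), 0.5,
                   kind = "gray8")
  expect_equal(as.vector(voxelData(downsamplePartialVolume(b, 1.0))), 128)
  # 1-D straddle: 0 covers 0.6 of the target cell, 255 covers 0.4 -> 102
  s <- imageVolume(array(c(0, 255), c(1, 1, 2)), c(1, 1, 0.6), kind = "gray8")
  out <- downsamplePartialVolume(s, 1.0)
  expect_equal(voxelData(out)[1, 1, 1], 102)
  # refusing to "down"-sample to a finer grid
  expect_error(downsamplePartialVolume(u, 0.25), "source spacing")
})

test_that("down-sampling conserves mean intensity on commensurate grids", {
  set.seed(5)
  for (rep in 1:5) {
    v <- imageVolume(array(sample(0:255, 8 * 6 * 4, TRUE), c(8, 6, 4)), 0.5,
                     kind = "gray8")
    out <- downsamplePartialVolume(v, 1.0)
    expect_lt(abs(mean(voxelData(out)) - mean(voxelData(v))), 0.5)
  }
})

test_that("segmentation recovers the phantom continuum regions", {
  ph <- fixPhantom()
  g8 <- normalizeGrayscale(ph$volume, referenceMax = 255)
  coarse <- downsamplePartialVolume(g8, 1.0)
  mask <- segmentContinuum(coarse, cementPlanes = ph$truth$cementPlanes,
                           closingRadius = 2L)
  # labels partition the volume
  expect_true(all(voxelData(mask) %in% 0:2))
  expect_identical(dim(voxelData(mask)), dim(voxelData(coarse)))
  # Dice >= 0.95 against the continuum ground truth for both labels
  tl <- voxelData(ph$truth$labels)
  for (L in 1:2) {
    tv <- downsamplePartialVolume(imageVolume((tl == L) * 255, 0.5), 1.0)
    truth <- voxelData(tv) >= 128
    seg <- voxelData(mask) == L
    dice <- 2 * sum(seg & truth) / (sum(seg) + sum(truth))
    expect_gte(dice, 0.95)
  }
})

test_that("segmentation degenerate cases error out", {
  g <- imageVolume(array(c(10, 20, 30, 40, 10, 20, 30, 40), c(2, 2, 2)), 1,
                   kind = "gray8")
  expect_error(segmentContinuum(g, boneThreshold = 200,
                                cementPlanes = c(0, 2)),
               "segmentation failure")
  # everything above threshold with planes at the extremes: one bone block
  allb <- segmentContinuum(g, boneThreshold = 5, cementPlanes = c(-1, 10),
                           closingRadius = 0L)
  expect_true(all(voxelData(allb) == 1L))
})

test_that("volume files round-trip through MetaImage and TIFF", {
  ph <- fixPhantom()
  g8 <- normalizeGrayscale(ph$volume, referenceMax = 255)
  small <- imageVolume(voxelData(g8)[1:8, 1:8, 1:8], voxelSpacing(g8),
                       kind = "gray8")
  mhd <- file.path(tempdir(), "t.mhd")
  writeImageVolume(small, mhd)
  back <- readImageVolume(mhd)
  expect_equal(voxelData(back), voxelData(small))
  expect_equal(voxelSpacing(back), voxelSpacing(small))
  tif <- file.path(tempdir(), "t.tif")
  writeImageVolume(small, tif)
  backT <- readImageVolume(tif, spacing = 0.5)
  expect_equal(voxelData(backT), voxelData(small))
})
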