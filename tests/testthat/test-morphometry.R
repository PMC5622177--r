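test_that("largest-cylinder fitting recovers simple shapes", {
  sp <- 0.5
  d <- c(44, 44, 20)
  xc <- (seq_len(44) - 0.5) * sp - 11
  cylMask <- array(outer(xc^2, xc^2, "+") <= 10^2, d)
  fit <- fitLargestCylinder(cylMask, sp, 0, 10)
  expect_lt(abs(fit@radius - 10), sp)
  expect_lt(max(abs(fit@center - 11)), sp)
  # cone narrowing 10 -> 5 mm: the common circle has the tip radius
  cone <- array(FALSE, d)
  for (k in 1:20) {
    r <- 10 - (k - 1) / 19 * 5
    cone[, , k] <- outer(xc^2, xc^2, "+") <= r^2
  }
  fitC <- fitLargestCylinder(cone, sp, 0, 10)
  expect_lt(abs(fitC@radius - 5), sp)
  expect_error(fitLargestCylinder(array(FALSE, d), sp, 0, 10), "empty|support")
})

test_that("bone volume fraction counts voxels in the ROI", {
  expect_equal(bvtv(array(TRUE, c(4, 4, 4))), 1.0)
  chk <- array((outer(outer(1:4, 1:4, "+"), 1:4, "+")) %% 2 == 0, c(4, 4, 4))
  expect_equal(bvtv(chk), 0.5, tolerance = 1 / 64)
  ph <- fixPhantom()
  expect_lt(abs(bvtv(ph$truth$trabecular, ph$truth$interior) - 0.45), 0.02)
})

test_that("degree of anisotropy and orientation have exact analytic cases", {
  expect_equal(degreeOfAnisotropy(c(1, 1, 1)), 0)
  expect_equal(degreeOfAnisotropy(c(2, 1.5, 1)), 0.5)
  expect_equal(trabecularOrientation(c(0, 0, 1)), 0)
  expect_equal(trabecularOrientation(c(1, 0, 1) / sqrt(2)), 45)
  expect_equal(trabecularOrientation(c(0, 0, -1)), 0)   # antipodal fold
})

test_that("MIL tensor is seed-deterministic and near-isotropic on the isotropic phantom", {
  ph <- fixPhantom(stretch = 1)
  a <- milFabricTensor(ph$truth$trabecular, 0.5, roi = ph$truth$interior,
                       nDirections = 128L, seed = 3L)
  b <- milFabricTensor(ph$truth$trabecular, 0.5, roi = ph$truth$interior,
                       nDirections = 128L, seed = 3L)
  expect_identical(a@H, b@H)
  expect_lt(anisotropyDegree(a), 0.15)
  expect_equal(Matrix::norm(a@H - t(a@H), "M"), 0)
  expect_true(all(milLengths(a) > 0))
})

test_that("DA grows with the axial stretch of the trabecular texture", {
  das <- vapply(c(1, 2, 4), function(st) {
    ph <- fixPhantom(stretch = st)
    anisotropyDegree(milFabricTensor(ph$truth$trabecular, 0.5,
                                     roi = ph$truth$interior,
                                     nDirections = 128L, seed = 3L))
  }, 0)
  expect_true(all(diff(das) > 0))
  # strongly stretched texture aligns with the superior/inferior axis
  ph4 <- fixPhantom(stretch = 4)
  ft4 <- milFabricTensor(ph4$truth$trabecular, 0.5, roi = ph4$truth$interior,
                         nDirections = 128L, seed = 3L)
  expect_lt(trabecularOrientation(ft4), 10)
})

test_that("parallel plates give strong in-plane anisotropy", {
  pl <- array(FALSE, c(40, 40, 40))
  pl[, , (0:39) %% 4 < 2] <- TRUE
  ft <- milFabricTensor(pl, 0.5, nDirections = 128L, seed = 3L)
  expect_gt(anisotropyDegree(ft), 0.5)
  # principal (longest-MIL) direction lies within 10 degrees of the x-y plane
  expect_lt(90 - trabecularOrientation(ft), 10)
})

test_that("DA is invariant to a 90-degree rotation about the axial direction", {
  ph <- fixPhantom(stretch = 2)
  bone <- ph$truth$trabecular
  roi <- ph$truth$interior
  da1 <- anisotropyDegree(milFabricTensor(bone, 0.5, roi = roi,
                                          nDirections = 128L, seed = 3L))
  rot <- function(a) aperm(a, c(2, 1, 3))[dim(a)[2]:1, , , drop = FALSE]
  da2 <- anisotropyDegree(milFabricTensor(rot(bone), 0.5, roi = rot(roi),
                                          nDirections = 128L, seed = 3L))
  expect_lt(abs(da1 - da2), 0.05)
})

test_that("single-phase regions are rejected", {
  expect_error(milFabricTensor(array(TRUE, c(8, 8, 8)), 0.5), "both")
  expect_error(milFabricTensor(array(FALSE, c(8, 8, 8)), 0.5), "both")
})
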