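test_that("phantom realises the requested bone volume fraction and regions", {
  spec <- phantomSpec(bodyRadius = 6, bodyHeight = 10, endcapHeight = 2,
                      voxelSpacing = 0.5, bvtvTarget = 0.45, seed = 3L)
  ph <- generatePhantom(spec)
  expect_lt(abs(ph$truth$bvtv - 0.45), 0.02)
  lab <- voxelData(ph$truth$labels)
  expect_setequal(unique(as.vector(lab)), c(0L, 1L, 2L))
  # cement slabs sit axially outside the body
  zc <- (seq_len(dim(lab)[3]) - 0.5) * 0.5
  cemSlices <- apply(lab == 2L, 3, any)
  expect_true(all(zc[cemSlices] < ph$truth$cementPlanes[1] |
                  zc[cemSlices] > ph$truth$cementPlanes[2]))
  # trabecular microstructure lives inside the interior compartment only
  expect_true(all(ph$truth$interior[ph$truth$trabecular]))
})

test_that("same spec and seed give bit-identical phantoms", {
  spec <- phantomSpec(bodyRadius = 5, bodyHeight = 8, endcapHeight = 2,
                      noiseSd = 3, seed = 99L)
  a <- generatePhantom(spec)
  b <- generatePhantom(spec)
  expect_identical(voxelData(a$volume), voxelData(b$volume))
  expect_identical(a$truth$bvtv, b$truth$bvtv)
})

test_that("phantom spec invariants are enforced", {
  expect_error(phantomSpec(shellThickness = 15), "shellThickness")
  expect_error(phantomSpec(bvtvTarget = 0.97), "bvtvTarget")
  expect_error(phantomSpec(anisotropyStretch = 0.5), "anisotropyStretch")
  expect_error(phantomSpec(cementGray = 300), "gray")
})

test_that("noiseless curves carry their stated slope exactly", {
  # plateau far beyond range, no toe: an exact line through the origin
  cv <- generateCurve(curveSpec(trueStiffness = 7, toeLength = 0,
                                plateauLoad = 1e9, totalDisplacement = 2))
  df <- curveData(cv)
  expect_equal(df$load_kN, 7 * df$displacement_mm)
  expect_equal(apparentStiffness(extractStiffness(cv)), 7.0)
  # with toe and plateau the generator/extractor pair is still consistent
  cv2 <- generateCurve(curveSpec(trueStiffness = 8.4, toeLength = 0.5,
                                 plateauLoad = 9, totalDisplacement = 3))
  expect_equal(apparentStiffness(extractStiffness(cv2)), 8.4,
               tolerance = 1e-9)
})

test_that("curve generation is seed-deterministic and displacement increases", {
  spec <- curveSpec(trueStiffness = 5, noiseSd = 0.1, seed = 17L)
  a <- generateCurve(spec); b <- generateCurve(spec)
  expect_identical(curveData(a), curveData(b))
  expect_true(all(diff(curveData(a)$displacement_mm) > 0))
})

test_that("window-infeasible curve specs are rejected", {
  # linear region shorter than the 0.6 mm analysis window
  expect_error(generateCurve(curveSpec(trueStiffness = 10, toeLength = 0.5,
                                       plateauLoad = 1,
                                       totalDisplacement = 3)),
               "window-infeasible")
  expect_error(curveSpec(totalDisplacement = 0.5), "totalDisplacement")
})
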