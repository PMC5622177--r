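test_that("voxel meshing de-duplicates nodes and counts combinatorially", {
  one <- buildVoxelMesh(labelMask(array(1L, c(1, 1, 1)), 1))
  expect_equal(nrow(meshNodes(one)), 8L)
  expect_equal(nrow(meshElements(one)), 1L)

  two <- array(0L, c(2, 1, 1)); two[] <- 1L
  m2 <- buildVoxelMesh(labelMask(two, 1))
  expect_equal(nrow(meshNodes(m2)), 12L)
  expect_equal(nrow(meshElements(m2)), 2L)
  expect_length(intersect(meshElements(m2)[1, ], meshElements(m2)[2, ]), 4L)

  L <- array(0L, c(2, 2, 1)); L[1, 1, 1] <- L[2, 1, 1] <- L[1, 2, 1] <- 1L
  m3 <- buildVoxelMesh(labelMask(L, 1))
  expect_equal(nrow(meshNodes(m3)), 16L)
  expect_equal(nrow(meshElements(m3)), 3L)

  # full W x H x D block: (W+1)(H+1)(D+1) nodes
  blk <- buildVoxelMesh(labelMask(array(1L, c(4, 3, 2)), 0.5))
  expect_equal(nrow(meshNodes(blk)), 5L * 4L * 3L)
  expect_error(buildVoxelMesh(labelMask(array(0L, c(2, 2, 2)), 1)), "empty")
})

test_that("material assignment follows the linear grayscale law", {
  cube <- fixCubeModel(n = 2L, gray = 100)
  m <- assignMaterials(cube$mesh, cube$gray, alpha = 0.00904)
  expect_equal(elementModuli(m), rep(0.904, 8), tolerance = 1e-12)
  # floor engages at zero gray
  dark <- imageVolume(array(0, c(2, 2, 2)), 1, kind = "gray8")
  mf <- assignMaterials(cube$mesh, dark, alpha = 0.01, EFloor = 0.001)
  expect_equal(elementModuli(mf), rep(0.001, 8))
  # doubling alpha doubles every bone modulus (before flooring)
  m2 <- assignMaterials(cube$mesh, cube$gray, alpha = 2 * 0.00904)
  expect_equal(elementModuli(m2), 2 * elementModuli(m))
  expect_error(assignMaterials(cube$mesh, cube$gray, alpha = 0), "alpha")
})

test_that("cement elements carry the fixed cement modulus", {
  lab <- array(1L, c(2, 2, 3)); lab[, , 1] <- 2L; lab[, , 3] <- 2L
  mesh <- buildVoxelMesh(labelMask(lab, 1))
  gray <- imageVolume(array(100, c(2, 2, 3)), 1, kind = "gray8")
  m <- assignMaterials(mesh, gray, alpha = 0.01)
  expect_equal(unname(elementModuli(m)[elementSets(mesh)$cement]),
               rep(2.45, 8))
  expect_equal(unname(elementModuli(m)[elementSets(mesh)$bone]), rep(1, 4))
})

test_that("Abaqus input decks round-trip", {
  # single element: exact round trip of nodes, element and modulus
  one <- fixCubeModel(n = 1L, gray = 123)
  mats <- assignMaterials(one$mesh, one$gray, alpha = 0.007)
  f <- file.path(tempdir(), "one.inp")
  writeAbaqusInp(one$mesh, mats, loadCase(), f)
  back <- readAbaqusInp(f)
  expect_equal(back$mesh@nodes, unname(one$mesh@nodes))
  expect_equal(back$mesh@elements, one$mesh@elements)
  expect_equal(back$E, elementModuli(mats))
  expect_equal(back$nu, 0.3)
  expect_equal(back$displacement, 1.0)

  # two distinct moduli -> two material sections
  two <- array(1L, c(2, 1, 1))
  mesh2 <- buildVoxelMesh(labelMask(two, 1))
  g2 <- imageVolume(array(c(100, 200), c(2, 1, 1)), 1, kind = "gray8")
  mats2 <- assignMaterials(mesh2, g2, alpha = 0.01)
  f2 <- file.path(tempdir(), "two.inp")
  writeAbaqusInp(mesh2, mats2, loadCase(), f2)
  expect_equal(sum(grepl("^\\*SOLID SECTION", readLines(f2))), 2L)
  expect_equal(readAbaqusInp(f2)$E, c(1, 2))
})

test_that("a phantom-derived deck preserves elements and coordinates", {
  sm <- fixSpecimenModel(301L)
  mats <- assignMaterials(sm$mesh, sm$gray, alpha = 0.008)
  f <- file.path(tempdir(), "phantom.inp")
  writeAbaqusInp(sm$mesh, mats, loadCase(), f)
  back <- readAbaqusInp(f)
  expect_equal(nrow(back$mesh@elements), nrow(meshElements(sm$mesh)))
  expect_equal(back$mesh@nodes, unname(meshNodes(sm$mesh)),
               tolerance = 1e-6)
  expect_equal(sort(back$mesh@elementSets$cement),
               sort(elementSets(sm$mesh)$cement))
})
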