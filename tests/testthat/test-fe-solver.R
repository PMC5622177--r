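test_that("element and global matrices satisfy basic equilibrium", {
  Ke <- vertefem:::hexStiffness(c(1, 1, 1), 0.3)
  expect_equal(Ke, t(Ke))
  # rigid-body translation in each direction produces zero force
  for (c in 1:3) {
    u <- rep(0, 24); u[seq(c, 24, by = 3)] <- 1
    expect_equal(max(abs(Ke %*% u)), 0, tolerance = 1e-12)
  }
  cube <- fixCubeModel(n = 2L)
  sys <- assembleStiffness(cube$mesh,
                           assignMaterials(cube$mesh, cube$gray, alpha = 0.01))
  rigid <- rep(c(1, 0, 0), nrow(meshNodes(cube$mesh)))
  expect_lt(max(abs(sys@K %*% rigid)), 1e-10)
})

test_that("homogeneous cube reproduces EA/L in uniaxial-oracle mode", {
  cube <- fixCubeModel(n = 10L, gray = 100)
  mats <- assignMaterials(cube$mesh, cube$gray, alpha = 0.01)   # E = 1 GPa
  res <- solveCompression(assembleStiffness(cube$mesh, mats),
                          loadCase(mode = "uniaxial-oracle"))
  expect_equal(apparentStiffness(res), 10, tolerance = 1e-10)
  expect_lt(abs(res@diagnostics$equilibriumImbalance),
            1e-8 * abs(res@reactionForce))
})

test_that("two-layer series model matches the spring closed form at nu = 0", {
  cube <- fixCubeModel(n = 10L)
  g <- array(100, c(10, 10, 10)); g[, , 6:10] <- 200
  gray <- imageVolume(g, 1, kind = "gray8")
  mats <- assignMaterials(cube$mesh, gray, alpha = 0.01, nu = 0)
  res <- solveCompression(assembleStiffness(cube$mesh, mats),
                          loadCase(mode = "uniaxial-oracle"))
  expect_equal(apparentStiffness(res), 100 / (5 / 1 + 5 / 2),
               tolerance = 1e-10)
})

test_that("uniform axial strain passes the constant-stress patch test", {
  cube <- fixCubeModel(n = 2L, gray = 100)
  mats <- assignMaterials(cube$mesh, cube$gray, alpha = 0.01)
  sys <- assembleStiffness(cube$mesh, mats)
  eps <- 0.01
  res <- solveCompression(sys, loadCase(displacement = 2 * eps,
                                        mode = "uniaxial-oracle"))
  st <- elementStresses(sys, res)
  expect_equal(as.vector(st[, , 3]), rep(1 * eps, 8 * 8), tolerance = 1e-10)
  expect_lt(max(abs(st[, , c(1, 2, 4, 5, 6)])), 1e-12)
})

test_that("stiffness is linear in the moduli and monotone per element", {
  sm <- fixSpecimenModel(301L)
  m1 <- assignMaterials(sm$mesh, sm$gray, alpha = 0.008)
  k1 <- apparentStiffness(solveCompression(assembleStiffness(sm$mesh, m1)))
  m2 <- new("MaterialField", E = 2 * m1@E, GS = m1@GS, alpha = m1@alpha,
            nu = m1@nu, ECement = m1@ECement)
  k2 <- apparentStiffness(solveCompression(assembleStiffness(sm$mesh, m2)))
  expect_equal(k2, 2 * k1, tolerance = 1e-12)
  # stiffening one element never softens the structure
  m3 <- m1
  m3@E[which.max(m1@E)] <- m1@E[which.max(m1@E)] * 3
  k3 <- apparentStiffness(solveCompression(assembleStiffness(sm$mesh, m3)))
  expect_gte(k3, k1 - 1e-12)
})

test_that("free plate rotation softens a laterally asymmetric specimen", {
  # two-column specimen: stiff column at one side, soft at the other
  lab <- array(1L, c(4, 2, 6))
  mesh <- buildVoxelMesh(labelMask(lab, 1))
  g <- array(50, c(4, 2, 6)); g[1:2, , ] <- 250
  gray <- imageVolume(g, 1, kind = "gray8")
  mats <- assignMaterials(mesh, gray, alpha = 0.01)
  sys <- assembleStiffness(mesh, mats)
  free <- solveCompression(sys, loadCase(mode = "tied"))
  locked <- solveCompression(sys, loadCase(mode = "tied-locked"))
  expect_gt(max(abs(free@diagnostics$plateRotation)), 1e-6)
  expect_lt(apparentStiffness(free), apparentStiffness(locked))
})

test_that("disconnected meshes are diagnosed as singular", {
  # a column spanning the faces plus a floating voxel touching neither
  lab <- array(0L, c(4, 1, 3)); lab[1, 1, ] <- 1L; lab[3, 1, 2] <- 1L
  mesh <- buildVoxelMesh(labelMask(lab, 1))
  gray <- imageVolume(array(100, c(4, 1, 3)), 1, kind = "gray8")
  sys <- assembleStiffness(mesh, assignMaterials(mesh, gray, alpha = 0.01))
  expect_error(solveCompression(sys, loadCase(mode = "tied")),
               "disconnected")
})

test_that("unit-alpha stiffness scales as the material layout dictates", {
  ab <- fixAllBoneModel(301L)
  k1 <- ab$kUnit
  mats2 <- assignMaterials(ab$mesh, ab$gray, alpha = 2)
  k2 <- apparentStiffness(solveCompression(assembleStiffness(ab$mesh, mats2)))
  expect_equal(k2, 2 * k1, tolerance = 1e-10)    # all-bone: exact proportionality

  sm <- fixSpecimenModel(301L)                   # bone + deformable cement
  kA <- apparentStiffness(solveCompression(assembleStiffness(
    sm$mesh, assignMaterials(sm$mesh, sm$gray, alpha = 0.008))))
  kB <- apparentStiffness(solveCompression(assembleStiffness(
    sm$mesh, assignMaterials(sm$mesh, sm$gray, alpha = 0.016))))
  expect_lt(kB, 2 * kA)                          # series compliance of the cement
  # rigid cement restores proportionality (at calibration-scale alpha,
  # where bone moduli are vanishing against the rigid cement)
  kra <- apparentStiffness(solveCompression(assembleStiffness(
    sm$mesh, assignMaterials(sm$mesh, sm$gray, alpha = 0.008,
                             rigidCement = TRUE))))
  krb <- apparentStiffness(solveCompression(assembleStiffness(
    sm$mesh, assignMaterials(sm$mesh, sm$gray, alpha = 0.016,
                             rigidCement = TRUE))))
  expect_equal(krb / kra, 2, tolerance = 1e-4)
})
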