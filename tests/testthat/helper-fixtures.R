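# Shared fixtures, built once per test run and cached. Everything is
# generated in code; nothing is read from disk.

.fix <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fix[[name]])) .fix[[name]] <- builder()
  .fix[[name]]
}

# Desk-scale phantom (12 mm radius body), shared across image/morphometry
# tests; stretch in {1, 2, 4}.
fixPhantom <- function(stretch = 1, seed = 11L) {
  fixture(sprintf("phantom_s%g_seed%d", stretch, seed), function()
    generatePhantom(phantomSpec(anisotropyStretch = stretch, seed = seed)))
}

# Homogeneous all-bone cube mesh: n^3 voxels of `spacing` mm, uniform gray.
fixCubeModel <- function(n = 10L, spacing = 1, gray = 100) {
  mesh <- buildVoxelMesh(labelMask(array(1L, rep(n, 3L)), spacing))
  grayVol <- imageVolume(array(gray, rep(n, 3L)), spacing, kind = "gray8")
  list(mesh = mesh, gray = grayVol)
}

# Small bone+cement cylinder model derived from a phantom through the full
# image pipeline; used for calibration tests.
fixSpecimenModel <- function(seed, bvtv = 0.45, stretch = 1.5) {
  fixture(sprintf("specmodel_%d", seed), function() {
    ph <- generatePhantom(phantomSpec(bodyRadius = 6, bodyHeight = 10,
                                      endcapHeight = 3, shellThickness = 1,
                                      voxelSpacing = 0.5, bvtvTarget = bvtv,
                                      anisotropyStretch = stretch,
                                      seed = seed))
    g8 <- normalizeGrayscale(ph$volume, referenceMax = 255)
    coarse <- downsamplePartialVolume(g8, 1.0)
    mask <- segmentContinuum(coarse, cementPlanes = ph$truth$cementPlanes,
                             closingRadius = 2L)
    list(mesh = buildVoxelMesh(mask), gray = coarse, truth = ph$truth)
  })
}

# All-bone variant (cement labels relabelled to bone): apparent stiffness is
# exactly proportional to alpha, the regime of the closed-form oracle.
fixAllBoneModel <- function(seed) {
  fixture(sprintf("allbone_%d", seed), function() {
    m <- fixSpecimenModel(seed)
    lab <- voxelData(m$gray)  # placeholder to keep shapes aligned
    mk <- m$mesh
    # rebuild mask with every labelled voxel marked bone
    full <- array(0L, dim(voxelData(m$gray)))
    full[mk@elementSource] <- 1L
    mesh <- buildVoxelMesh(labelMask(full, voxelSpacing(m$gray)))
    kUnit <- unitAlphaStiffness(mesh, m$gray)
    list(mesh = mesh, gray = m$gray, kUnit = kUnit)
  })
}

# The packaged demonstration study: 6 phantoms, alpha_true = 0.008, 3/3
# calibration/validation split, experimental stiffness simulated noiselessly
# through the same pipeline. Built and run once (a couple of minutes).
fixDemoReport <- function() {
  fixture("demo_report", function() {
    dir <- file.path(tempdir(), "vertefem-demo-fixture")
    cfg <- makeDemoStudy(dir, seed = 1L, alphaTrue = 0.008)
    list(config = cfg, dir = dir, report = runPipeline(cfg))
  })
}
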