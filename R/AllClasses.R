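#' @import methods
#' @importFrom stats quantile rnorm runif optimize sd cor shapiro.test
#'   kruskal.test wilcox.test fft
#' @importFrom utils combn read.csv write.csv
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' ImageVolume: a 3-D scalar image with physical voxel spacing
#'
#' The central image container of the pipeline. `data` is a 3-D array whose
#' third index runs along the superior/inferior (axial) direction; `spacing`
#' gives the voxel edge lengths in mm (recycled to length 3 if isotropic);
#' `kind` is `"raw"` for signed scanner output or `"gray8"` for normalised
#' 8-bit grayscale (all values integers in \[0, 255\]).
#'
#' World coordinates use 0-based voxel indices: the centre of voxel
#' `(i, j, k)` (0-based) sits at `(i + 0.5) * spacing`.
#'
#' @slot data 3-D numeric array.
#' @slot spacing numeric(3), mm per voxel edge, all > 0.
#' @slot kind `"raw"` or `"gray8"`.
#' @export
setClass("ImageVolume",
  representation(data = "array", spacing = "numeric", kind = "character"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@data)) != 3L)
      msg <- c(msg, "'data' must be a 3-D array")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      msg <- c(msg, "'spacing' must be 3 positive finite values (mm)")
    if (length(object@kind) != 1L || !object@kind %in% c("raw", "gray8"))
      msg <- c(msg, "'kind' must be \"raw\" or \"gray8\"")
    if (identical(object@kind, "gray8")) {
      v <- object@data
      if (any(v < 0 | v > 255, na.rm = TRUE))
        msg <- c(msg, "gray8 volumes must lie in [0, 255]")
    }
    if (length(msg)) msg else TRUE
  })

#' Construct an ImageVolume
#'
#' @param data 3-D numeric array (third index = superior/inferior).
#' @param spacing voxel spacing in mm; scalar (isotropic) or length 3.
#' @param kind `"raw"` (default) or `"gray8"`.
#' @return An [ImageVolume-class] object.
#' @examples
#' vol <- imageVolume(array(0, c(4, 4, 4)), spacing = 0.5)
#' @export
imageVolume <- function(data, spacing, kind = c("raw", "gray8")) {
  kind <- match.arg(kind)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("ImageVolume", data = data, spacing = as.numeric(spacing), kind = kind)
}

#' LabelMask: continuum segmentation labels
#'
#' Voxel labels over \{0 = background, 1 = bone, 2 = cement\}, sharing shape
#' and spacing with the volume it segments.
#'
#' @slot labels 3-D integer array over \{0, 1, 2\}.
#' @slot spacing numeric(3), mm.
#' @export
setClass("LabelMask",
  representation(labels = "array", spacing = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@labels)) != 3L)
      msg <- c(msg, "'labels' must be a 3-D array")
    if (!all(object@labels %in% c(0L, 1L, 2L)))
      msg <- c(msg, "labels must be 0 (background), 1 (bone) or 2 (cement)")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      msg <- c(msg, "'spacing' must be 3 positive values (mm)")
    if (length(msg)) msg else TRUE
  })

#' Construct a LabelMask
#'
#' @param labels 3-D array over \{0, 1, 2\}.
#' @param spacing voxel spacing in mm; scalar or length 3.
#' @return A [LabelMask-class] object.
#' @export
labelMask <- function(labels, spacing) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  storage.mode(labels) <- "integer"
  new("LabelMask", labels = labels, spacing = as.numeric(spacing))
}

#' PhantomSpec: parameters of the synthetic vertebra phantom
#'
#' Describes a cylindrical vertebral-body phantom: cortical shell, trabecular
#' interior realised by thresholding an anisotropic correlated random field,
#' and uniform cement endcap slabs above and below, on an isotropic voxel
#' grid. See [generatePhantom()].
#'
#' @slot bodyRadius,bodyHeight,endcapHeight,shellThickness mm, all > 0;
#'   `shellThickness < bodyRadius`.
#' @slot voxelSpacing mm, isotropic.
#' @slot bvtvTarget target trabecular bone volume fraction, in (0.05, 0.95).
#' @slot anisotropyStretch axial elongation (>= 1) of the random-field
#'   correlation ellipsoid; 1 = isotropic texture.
#' @slot boneGrayMean,cementGray,backgroundGray grayscale levels in \[0, 255\].
#' @slot noiseSd additive Gaussian noise, grayscale units.
#' @slot seed integer RNG seed.
#' @export
setClass("PhantomSpec",
  representation(bodyRadius = "numeric", bodyHeight = "numeric",
    endcapHeight = "numeric", shellThickness = "numeric",
    voxelSpacing = "numeric", bvtvTarget = "numeric",
    anisotropyStretch = "numeric", boneGrayMean = "numeric",
    cementGray = "numeric", backgroundGray = "numeric",
    noiseSd = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    lens <- c(object@bodyRadius, object@bodyHeight, object@endcapHeight,
              object@voxelSpacing)
    if (any(!is.finite(lens)) || any(lens <= 0))
      msg <- c(msg, "all lengths and the voxel spacing must be > 0")
    if (object@shellThickness < 0 || object@shellThickness >= object@bodyRadius)
      msg <- c(msg, "'shellThickness' must be in [0, bodyRadius)")
    grays <- c(object@boneGrayMean, object@cementGray, object@backgroundGray)
    if (any(grays < 0 | grays > 255))
      msg <- c(msg, "gray levels must lie in [0, 255]")
    if (object@bvtvTarget <= 0.05 || object@bvtvTarget >= 0.95)
      msg <- c(msg, "'bvtvTarget' must lie in (0.05, 0.95)")
    if (object@anisotropyStretch < 1)
      msg <- c(msg, "'anisotropyStretch' must be >= 1")
    if (object@noiseSd < 0) msg <- c(msg, "'noiseSd' must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' Construct a PhantomSpec
#'
#' Defaults give a desk-scale phantom: 24 mm diameter, 20 mm body height,
#' 4 mm endcaps, 0.5 mm voxels.
#'
#' @param bodyRadius,bodyHeight,endcapHeight,shellThickness geometry, mm.
#' @param voxelSpacing isotropic voxel edge, mm.
#' @param bvtvTarget target trabecular bone volume fraction.
#' @param anisotropyStretch axial correlation stretch (>= 1).
#' @param boneGrayMean,cementGray,backgroundGray grayscale levels, 0-255.
#' @param noiseSd additive Gaussian noise sd, grayscale units.
#' @param seed integer seed; same spec + seed gives bit-identical phantoms.
#' @return A [PhantomSpec-class] object.
#' @export
phantomSpec <- function(bodyRadius = 12, bodyHeight = 20, endcapHeight = 4,
                        shellThickness = 1, voxelSpacing = 0.5,
                        bvtvTarget = 0.45, anisotropyStretch = 1,
                        boneGrayMean = 180, cementGray = 90,
                        backgroundGray = 20, noiseSd = 0, seed = 1L) {
  new("PhantomSpec", bodyRadius = bodyRadius, bodyHeight = bodyHeight,
      endcapHeight = endcapHeight, shellThickness = shellThickness,
      voxelSpacing = voxelSpacing, bvtvTarget = bvtvTarget,
      anisotropyStretch = anisotropyStretch, boneGrayMean = boneGrayMean,
      cementGray = cementGray, backgroundGray = backgroundGray,
      noiseSd = noiseSd, seed = as.integer(seed))
}

#' CurveSpec: parameters of a synthetic load-displacement curve
#'
#' Piecewise curve emulating an axial compression test to failure: a smooth
#' quadratic toe, a linear region of slope `trueStiffness`, and a post-yield
#' plateau, with optional additive load noise. See [generateCurve()].
#'
#' @slot trueStiffness kN/mm, > 0.
#' @slot toeLength mm.
#' @slot plateauLoad kN.
#' @slot sampleStep mm between displacement samples.
#' @slot totalDisplacement mm; must cover the toe plus at least the 0.6 mm
#'   analysis window plus one sample step.
#' @slot noiseSd kN.
#' @slot seed integer RNG seed.
#' @export
setClass("CurveSpec",
  representation(trueStiffness = "numeric", toeLength = "numeric",
    plateauLoad = "numeric", sampleStep = "numeric",
    totalDisplacement = "numeric", noiseSd = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@trueStiffness <= 0) msg <- c(msg, "'trueStiffness' must be > 0")
    if (object@sampleStep <= 0) msg <- c(msg, "'sampleStep' must be > 0")
    if (object@toeLength < 0) msg <- c(msg, "'toeLength' must be >= 0")
    if (object@noiseSd < 0) msg <- c(msg, "'noiseSd' must be >= 0")
    if (object@totalDisplacement <
        object@toeLength + 0.6 + object@sampleStep)
      msg <- c(msg, paste("'totalDisplacement' must span the toe plus the",
                          "0.6 mm analysis window plus one sample step"))
    if (length(msg)) msg else TRUE
  })

#' Construct a CurveSpec
#' @param trueStiffness linear-region slope, kN/mm.
#' @param toeLength toe-region length, mm.
#' @param plateauLoad post-yield plateau load, kN.
#' @param sampleStep displacement sampling step, mm.
#' @param totalDisplacement total ramp, mm.
#' @param noiseSd additive load noise sd, kN.
#' @param seed integer seed.
#' @return A [CurveSpec-class] object.
#' @export
curveSpec <- function(trueStiffness = 5, toeLength = 0.5, plateauLoad = 9,
                      sampleStep = 0.01, totalDisplacement = 3,
                      noiseSd = 0, seed = 1L) {
  new("CurveSpec", trueStiffness = trueStiffness, toeLength = toeLength,
      plateauLoad = plateauLoad, sampleStep = sampleStep,
      totalDisplacement = totalDisplacement, noiseSd = noiseSd,
      seed = as.integer(seed))
}

#' LoadDisplacementCurve: a compression test record
#'
#' @slot displacement mm, strictly increasing, >= 2 samples.
#' @slot load kN.
#' @slot id specimen identifier.
#' @export
setClass("LoadDisplacementCurve",
  representation(displacement = "numeric", load = "numeric", id = "character"),
  validity = function(object) {
    msg <- character()
    n <- length(object@displacement)
    if (n < 2L) msg <- c(msg, "need at least 2 samples")
    if (length(object@load) != n)
      msg <- c(msg, "'displacement' and 'load' lengths differ")
    if (n >= 2L && any(diff(object@displacement) <= 0))
      msg <- c(msg, "'displacement' must be strictly increasing")
    if (length(msg)) msg else TRUE
  })

#' Construct a LoadDisplacementCurve
#'
#' Samples whose displacement is non-monotone by less than 1 um (machine
#' jitter) are re-sorted; larger reversals are an error.
#'
#' @param displacement mm.
#' @param load kN.
#' @param id specimen identifier.
#' @return A [LoadDisplacementCurve-class] object.
#' @export
loadDisplacementCurve <- function(displacement, load, id = "specimen") {
  stopifnot(length(displacement) == length(load))
  d <- diff(displacement)
  if (any(d <= 0)) {
    if (min(d) > -1e-3) {        # < 1 um reversals: re-sort
      o <- order(displacement)
      displacement <- displacement[o]; load <- load[o]
      keep <- c(TRUE, diff(displacement) > 0)
      displacement <- displacement[keep]; load <- load[keep]
    } else {
      stop("displacement reversals exceed 1 um; refusing to re-sort")
    }
  }
  new("LoadDisplacementCurve", displacement = as.numeric(displacement),
      load = as.numeric(load), id = as.character(id))
}

#' StiffnessEstimate: maximal moving-window slope of a test curve
#'
#' @slot stiffness kN/mm.
#' @slot windowWidth mm (default analysis aperture 0.6 mm).
#' @slot windowCenter mm, centre of the maximising window.
#' @export
setClass("StiffnessEstimate",
  representation(stiffness = "numeric", windowWidth = "numeric",
                 windowCenter = "numeric"))

#' HexMesh: voxel-aligned hexahedral mesh
#'
#' One 8-node trilinear brick per labelled voxel, with de-duplicated nodes.
#' Element corner ordering follows the standard brick convention: nodes 1-4
#' counter-clockwise on the lower (-z) face starting at the local origin,
#' nodes 5-8 directly above.
#'
#' @slot nodes N x 3 matrix of coordinates, mm.
#' @slot elements E x 8 integer matrix of node indices (1-based).
#' @slot elementSource integer(E), linear voxel index each element came from.
#' @slot spacing numeric(3), element edge lengths, mm.
#' @slot nodeSets named list of integer node-index vectors
#'   (`bottom_face`, `top_face`).
#' @slot elementSets named list of integer element-index vectors
#'   (`bone`, `cement`).
#' @export
setClass("HexMesh",
  representation(nodes = "matrix", elements = "matrix",
    elementSource = "integer", spacing = "numeric",
    nodeSets = "list", elementSets = "list"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@nodes) != 3L) msg <- c(msg, "'nodes' must be N x 3")
    if (ncol(object@elements) != 8L) msg <- c(msg, "'elements' must be E x 8")
    if (nrow(object@elements) > 0 &&
        (max(object@elements) > nrow(object@nodes) || min(object@elements) < 1))
      msg <- c(msg, "element node indices out of range")
    if (length(object@elementSource) != nrow(object@elements))
      msg <- c(msg, "'elementSource' length must equal element count")
    if (length(msg)) msg else TRUE
  })

#' MaterialField: per-element isotropic elasticity
#'
#' Bone elements follow the linear grayscale law `E = alpha * GS` (GPa), with
#' a small positive floor so zero-gray elements cannot make the system
#' singular; cement elements carry a fixed modulus. With mm/GPa/kN units,
#' force = GPa * mm^2 = kN and stiffness is kN/mm with no conversion factors.
#'
#' @slot E numeric(E), element moduli, GPa (all >= floor > 0).
#' @slot GS numeric(E), average element grayscale (NA for cement).
#' @slot alpha conversion factor, GPa per grayscale unit.
#' @slot nu Poisson ratio, in (0, 0.5).
#' @slot ECement cement modulus, GPa.
#' @export
setClass("MaterialField",
  representation(E = "numeric", GS = "numeric", alpha = "numeric",
                 nu = "numeric", ECement = "numeric"),
  validity = function(object) {
    msg <- character()
    if (any(object@E <= 0)) msg <- c(msg, "all element moduli must be > 0")
    if (object@nu < 0 || object@nu >= 0.5)
      msg <- c(msg, "'nu' must lie in [0, 0.5)")
    if (length(msg)) msg else TRUE
  })

#' LoadCase: boundary conditions of the axial compression test
#'
#' The default `"tied"` mode reproduces the experiment: the bottom surface of
#' the lower endcap is clamped, and the top surface is tied to a rigid plate
#' with a 6-dof reference point whose axial translation is prescribed
#' (default 1 mm), lateral translations fixed and rotations free. The
#' `"uniaxial-oracle"` mode instead prescribes only axial displacements on
#' both faces, leaves lateral motion free, and pins rigid-body modes, so that
#' closed-form EA/L and series-spring answers are exact.
#'
#' @slot clampedSet,plateSet node-set names (see [HexMesh-class]).
#' @slot referencePoint numeric(3), mm; projected load point on the top plane.
#' @slot displacement prescribed axial displacement, mm (nonzero).
#' @slot mode `"tied"` or `"uniaxial-oracle"`.
#' @export
setClass("LoadCase",
  representation(clampedSet = "character", plateSet = "character",
    referencePoint = "numeric", displacement = "numeric", mode = "character"),
  validity = function(object) {
    msg <- character()
    if (object@displacement == 0) msg <- c(msg, "'displacement' must be nonzero")
    if (!object@mode %in% c("tied", "tied-locked", "uniaxial-oracle"))
      msg <- c(msg, "'mode' must be \"tied\", \"tied-locked\" or \"uniaxial-oracle\"")
    if (length(msg)) msg else TRUE
  })

#' Construct a LoadCase
#' @param displacement prescribed axial displacement, mm.
#' @param mode `"tied"` (rigid plate with free rotations, default),
#'   `"tied-locked"` (plate rotations locked: every plate node fully
#'   prescribed) or `"uniaxial-oracle"`.
#' @param clampedSet,plateSet node-set names in the mesh.
#' @param referencePoint reference-point coordinates, mm; `NULL` uses the
#'   centroid of the plate node set.
#' @return A [LoadCase-class] object.
#' @export
loadCase <- function(displacement = 1.0,
                     mode = c("tied", "tied-locked", "uniaxial-oracle"),
                     clampedSet = "bottom_face", plateSet = "top_face",
                     referencePoint = NULL) {
  mode <- match.arg(mode)
  new("LoadCase", clampedSet = clampedSet, plateSet = plateSet,
      referencePoint = if (is.null(referencePoint)) numeric(0)
                       else as.numeric(referencePoint),
      displacement = displacement, mode = mode)
}

#' FEResult: solution of one compression analysis
#'
#' @slot displacements N x 3 nodal displacement matrix, mm.
#' @slot reactionForce axial reaction at the loading surface, kN.
#' @slot stiffness apparent stiffness = reaction / prescribed displacement,
#'   kN/mm.
#' @slot diagnostics list: dof count, relative residual norm, equilibrium
#'   imbalance, plate rotation vector (tied mode), solver used.
#' @export
setClass("FEResult",
  representation(displacements = "matrix", reactionForce = "numeric",
                 stiffness = "numeric", diagnostics = "list"))

#' SpecimenRecord: one specimen in a calibration/validation study
#'
#' Carries the experimental stiffness together with either a full FE model
#' (mesh + grayscale volume + load case) or a precomputed unit-alpha
#' stiffness `kUnit` for configurations where simulated stiffness scales
#' exactly linearly in alpha (all-bone or rigid-cement models).
#'
#' @slot id specimen identifier.
#' @slot kExp experimental apparent stiffness, kN/mm (> 0).
#' @slot group `"calibration"` or `"validation"`.
#' @slot mesh a [HexMesh-class] or `NULL`.
#' @slot gray an [ImageVolume-class] (gray8, mesh-aligned) or `NULL`.
#' @slot loadCase a [LoadCase-class] or `NULL` (default tied, 1 mm).
#' @slot kUnit numeric or `NULL`: apparent stiffness at alpha = 1.
#' @export
setClass("SpecimenRecord",
  representation(id = "character", kExp = "numeric", group = "character",
    mesh = "ANY", gray = "ANY", loadCase = "ANY", kUnit = "numericOrNULL"),
  validity = function(object) {
    msg <- character()
    if (object@kExp <= 0) msg <- c(msg, "'kExp' must be > 0")
    if (!object@group %in% c("calibration", "validation"))
      msg <- c(msg, "'group' must be \"calibration\" or \"validation\"")
    if (is.null(object@kUnit) &&
        (is.null(object@mesh) || is.null(object@gray)))
      msg <- c(msg, "need either kUnit or a mesh plus grayscale volume")
    if (length(msg)) msg else TRUE
  })

#' Construct a SpecimenRecord
#' @param id specimen identifier.
#' @param kExp experimental stiffness, kN/mm.
#' @param group `"calibration"` or `"validation"`.
#' @param mesh,gray,loadCase FE model pieces (see [SpecimenRecord-class]).
#' @param kUnit precomputed unit-alpha stiffness, kN/mm, for all-bone or
#'   rigid-cement models.
#' @param ... further material arguments stored for FE evaluation
#'   (`ECement`, `nu`, `EFloor`, `rigidCement`).
#' @return A [SpecimenRecord-class] object.
#' @export
specimenRecord <- function(id, kExp, group = c("calibration", "validation"),
                           mesh = NULL, gray = NULL, loadCase = NULL,
                           kUnit = NULL, ...) {
  group <- match.arg(group)
  rec <- new("SpecimenRecord", id = as.character(id), kExp = kExp,
             group = group, mesh = mesh, gray = gray,
             loadCase = if (is.null(loadCase) && !is.null(mesh)) loadCase()
                        else loadCase,
             kUnit = kUnit)
  attr(rec, "matArgs") <- list(...)
  attr(rec, "cache") <- new.env(parent = emptyenv())
  rec
}

#' CalibrationResult: converged conversion factor and its fit
#'
#' @slot alpha converged conversion factor, GPa per grayscale unit.
#' @slot rmse normalised stiffness RMSE at `alpha` (dimensionless fraction).
#' @slot pairs data.frame with per-specimen `id`, `kExp`, `kSim`.
#' @slot iterations number of objective evaluations.
#' @slot termination reason: `"objective_threshold"`, `"objective_plateau"`
#'   or `"bracket_converged"`.
#' @slot trace data.frame of probed `alpha` and objective values, in
#'   evaluation order.
#' @export
setClass("CalibrationResult",
  representation(alpha = "numeric", rmse = "numeric", pairs = "data.frame",
    iterations = "integer", termination = "character", trace = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (object@alpha <= 0) msg <- c(msg, "'alpha' must be > 0")
    if (object@rmse < 0) msg <- c(msg, "'rmse' must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' ROICylinder: cylindrical trabecular region of interest
#'
#' Axis parallel to the superior/inferior image direction.
#'
#' @slot center numeric(2), (x, y) mm.
#' @slot radius mm, > 0.
#' @slot zMin,zMax axial extent, mm.
#' @export
setClass("ROICylinder",
  representation(center = "numeric", radius = "numeric",
                 zMin = "numeric", zMax = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@radius <= 0) msg <- c(msg, "'radius' must be > 0")
    if (object@zMax <= object@zMin) msg <- c(msg, "'zMax' must exceed 'zMin'")
    if (length(msg)) msg else TRUE
  })

#' FabricTensor: mean-intercept-length fabric of a trabecular region
#'
#' `H` is the symmetric positive-definite ellipsoid tensor fitted to
#' directional MIL measurements via `n' H n = 1 / MIL(n)^2`; the MIL
#' eigen-lengths are `1/sqrt(eigen(H))`. The degree of anisotropy follows the
#' BoneJ 1.x convention `DA = 1 - Lmin/Lmax` on MIL lengths (0 = isotropic).
#'
#' @slot H symmetric 3 x 3 matrix.
#' @slot milLengths numeric(3), MIL eigen-lengths, descending.
#' @slot eigenvectors 3 x 3 matrix, columns matching `milLengths`.
#' @slot DA degree of anisotropy in \[0, 1).
#' @slot orientationDeviation degrees in \[0, 90\]: angle between the
#'   principal (longest-MIL) eigenvector and the superior/inferior axis,
#'   folded for antipodal symmetry.
#' @slot nDirections directions retained in the fit.
#' @export
setClass("FabricTensor",
  representation(H = "matrix", milLengths = "numeric",
    eigenvectors = "matrix", DA = "numeric",
    orientationDeviation = "numeric", nDirections = "integer"),
  validity = function(object) {
    msg <- character()
    if (!isTRUE(all.equal(object@H, t(object@H), tolerance = 1e-8)))
      msg <- c(msg, "'H' must be symmetric")
    if (any(object@milLengths <= 0))
      msg <- c(msg, "MIL eigen-lengths must be positive")
    if (is.unsorted(rev(object@milLengths)))
      msg <- c(msg, "'milLengths' must be sorted descending")
    if (object@DA < 0 || object@DA >= 1)
      msg <- c(msg, "'DA' must lie in [0, 1)")
    if (length(msg)) msg else TRUE
  })

#' AgreementReport: concordance between paired measurements
#'
#' @slot ccc Lin's concordance correlation coefficient.
#' @slot pearson Pearson correlation.
#' @slot bias mean difference (second minus first series), kN/mm.
#' @slot loa limits of agreement, `bias +/- 1.96 * sd(diff)`, kN/mm.
#' @slot n number of pairs.
#' @slot pairs data.frame of per-pair means and differences.
#' @export
setClass("AgreementReport",
  representation(ccc = "numeric", pearson = "numeric", bias = "numeric",
    loa = "numeric", n = "integer", pairs = "data.frame"))

#' GroupComparisonReport: between-species comparison of one variable
#'
#' @slot shapiro data.frame: per-group Shapiro-Wilk statistic, p-value and an
#'   applicability flag (constant groups are flagged, not tested).
#' @slot kruskal list: Kruskal-Wallis statistic, df, p-value.
#' @slot pairwise data.frame of pairwise rank-sum tests (raw p-values, no
#'   multiplicity correction).
#' @export
setClass("GroupComparisonReport",
  representation(shapiro = "data.frame", kruskal = "list",
                 pairwise = "data.frame"))
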