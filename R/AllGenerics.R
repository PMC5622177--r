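#' @include AllClasses.R
NULL

#' Accessors for vertefem objects
#'
#' Small accessor family: slot access is internal, these are the supported
#' surface.
#'
#' @param object a vertefem S4 object.
#' @return The corresponding component (array, matrix, numeric or list).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voxelData", function(object) standardGeneric("voxelData"))
#' @rdname accessors
#' @export
setMethod("voxelData", "ImageVolume", function(object) object@data)
#' @rdname accessors
#' @export
setMethod("voxelData", "LabelMask", function(object) object@labels)

#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(object) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "ImageVolume", function(object) object@spacing)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "LabelMask", function(object) object@spacing)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "HexMesh", function(object) object@spacing)

#' @rdname accessors
#' @export
setGeneric("volumeKind", function(object) standardGeneric("volumeKind"))
#' @rdname accessors
#' @export
setMethod("volumeKind", "ImageVolume", function(object) object@kind)

#' @rdname accessors
#' @export
setGeneric("meshNodes", function(object) standardGeneric("meshNodes"))
#' @rdname accessors
#' @export
setMethod("meshNodes", "HexMesh", function(object) object@nodes)

#' @rdname accessors
#' @export
setGeneric("meshElements", function(object) standardGeneric("meshElements"))
#' @rdname accessors
#' @export
setMethod("meshElements", "HexMesh", function(object) object@elements)

#' @rdname accessors
#' @export
setGeneric("nodeSets", function(object) standardGeneric("nodeSets"))
#' @rdname accessors
#' @export
setMethod("nodeSets", "HexMesh", function(object) object@nodeSets)

#' @rdname accessors
#' @export
setGeneric("elementSets", function(object) standardGeneric("elementSets"))
#' @rdname accessors
#' @export
setMethod("elementSets", "HexMesh", function(object) object@elementSets)

#' @rdname accessors
#' @export
setGeneric("elementModuli", function(object) standardGeneric("elementModuli"))
#' @rdname accessors
#' @export
setMethod("elementModuli", "MaterialField", function(object) object@E)

#' @rdname accessors
#' @export
setGeneric("apparentStiffness",
           function(object) standardGeneric("apparentStiffness"))
#' @rdname accessors
#' @export
setMethod("apparentStiffness", "FEResult", function(object) object@stiffness)
#' @rdname accessors
#' @export
setMethod("apparentStiffness", "StiffnessEstimate",
          function(object) object@stiffness)

#' @rdname accessors
#' @export
setGeneric("conversionFactor",
           function(object) standardGeneric("conversionFactor"))
#' @rdname accessors
#' @export
setMethod("conversionFactor", "CalibrationResult", function(object) object@alpha)
#' @rdname accessors
#' @export
setMethod("conversionFactor", "MaterialField", function(object) object@alpha)

#' @rdname accessors
#' @export
setGeneric("anisotropyDegree",
           function(object) standardGeneric("anisotropyDegree"))
#' @rdname accessors
#' @export
setMethod("anisotropyDegree", "FabricTensor", function(object) object@DA)

#' @rdname accessors
#' @export
setGeneric("milLengths", function(object) standardGeneric("milLengths"))
#' @rdname accessors
#' @export
setMethod("milLengths", "FabricTensor", function(object) object@milLengths)

#' @rdname accessors
#' @export
setGeneric("principalDirection",
           function(object) standardGeneric("principalDirection"))
#' @rdname accessors
#' @export
setMethod("principalDirection", "FabricTensor",
          function(object) object@eigenvectors[, 1L])

#' @rdname accessors
#' @export
setGeneric("curveData", function(object) standardGeneric("curveData"))
#' @rdname accessors
#' @export
setMethod("curveData", "LoadDisplacementCurve", function(object)
  data.frame(displacement_mm = object@displacement, load_kN = object@load))

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("ImageVolume [%s]: %d x %d x %d voxels, spacing %s mm, range [%g, %g]\n",
              object@kind, d[1], d[2], d[3],
              paste(signif(object@spacing, 4), collapse = " x "),
              min(object@data), max(object@data)))
})

setMethod("show", "LabelMask", function(object) {
  tab <- tabulate(object@labels + 1L, nbins = 3L)
  cat(sprintf("LabelMask: %s voxels (background %d, bone %d, cement %d)\n",
              paste(dim(object@labels), collapse = " x "),
              tab[1], tab[2], tab[3]))
})

setMethod("show", "HexMesh", function(object) {
  cat(sprintf("HexMesh: %d nodes, %d hexahedral elements (%d bone, %d cement)\n",
              nrow(object@nodes), nrow(object@elements),
              length(object@elementSets$bone), length(object@elementSets$cement)))
})

setMethod("show", "MaterialField", function(object) {
  cat(sprintf("MaterialField: %d elements, alpha = %g GPa/gray, nu = %g, E in [%g, %g] GPa\n",
              length(object@E), object@alpha, object@nu,
              min(object@E), max(object@E)))
})

setMethod("show", "FEResult", function(object) {
  cat(sprintf("FEResult: reaction %.6g kN, apparent stiffness %.6g kN/mm (%d dof)\n",
              object@reactionForce, object@stiffness,
              object@diagnostics$ndof))
})

setMethod("show", "StiffnessEstimate", function(object) {
  cat(sprintf("StiffnessEstimate: %.6g kN/mm (window %.3g mm centred at %.3g mm)\n",
              object@stiffness, object@windowWidth, object@windowCenter))
})

setMethod("show", "CalibrationResult", function(object) {
  cat(sprintf("CalibrationResult: alpha = %.6g GPa/gray, RMSE = %.3f (%d evaluations, %s)\n",
              object@alpha, object@rmse, object@iterations, object@termination))
})

setMethod("show", "FabricTensor", function(object) {
  cat(sprintf("FabricTensor: MIL lengths %s, DA = %.3f, deviation %.2f deg (%d directions)\n",
              paste(signif(object@milLengths, 4), collapse = " / "),
              object@DA, object@orientationDeviation, object@nDirections))
})

setMethod("show", "AgreementReport", function(object) {
  cat(sprintf("AgreementReport: CCC = %.4f (Pearson %.4f), bias %.4g, LoA [%.4g, %.4g], n = %d\n",
              object@ccc, object@pearson, object@bias,
              object@loa[1], object@loa[2], object@n))
})
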