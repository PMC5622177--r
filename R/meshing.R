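#' Build a voxel-aligned hexahedral mesh from a continuum mask
#'
#' Every labelled voxel becomes one 8-node trilinear brick whose edges match
#' the voxel edges, so element size equals the (down-sampled) voxel size.
#' Corner nodes shared between adjacent voxels are de-duplicated, giving a
#' conforming mesh. Element sets `bone` and `cement` come from the mask
#' labels; node sets `bottom_face` and `top_face` collect the nodes on the
#' lowest and highest axial planes of the cement endcaps (or of the whole
#' mesh when there is no cement), ready for the compression load case.
#'
#' @param mask a [LabelMask-class] with at least one labelled voxel.
#' @return A [HexMesh-class].
#' @examples
#' m <- buildVoxelMesh(labelMask(array(1L, c(1, 1, 1)), 1))
#' nrow(meshNodes(m))   # 8
#' @export
buildVoxelMesh <- function(mask) {
  stopifnot(is(mask, "LabelMask"))
  lab <- mask@labels
  d <- dim(lab)
  h <- mask@spacing
  vox <- which(lab > 0L)
  if (!length(vox)) stop("empty mask: nothing to mesh")
  ijk <- arrayInd(vox, d) - 1L                 # 0-based lower corner
  nd <- d + 1L                                  # corner grid
  cornerId <- function(ci, cj, ck) 1L + ci + nd[1] * (cj + nd[2] * ck)
  # standard brick corner ordering: 1-4 CCW on the lower face, 5-8 above
  offs <- rbind(c(0L, 0L, 0L), c(1L, 0L, 0L), c(1L, 1L, 0L), c(0L, 1L, 0L),
                c(0L, 0L, 1L), c(1L, 0L, 1L), c(1L, 1L, 1L), c(0L, 1L, 1L))
  conGrid <- matrix(0L, length(vox), 8L)
  for (a in 1:8)
    conGrid[, a] <- cornerId(ijk[, 1] + offs[a, 1], ijk[, 2] + offs[a, 2],
                             ijk[, 3] + offs[a, 3])
  used <- sort(unique(as.vector(conGrid)))
  remap <- integer(prod(nd))
  remap[used] <- seq_along(used)
  elements <- matrix(remap[conGrid], ncol = 8L)
  cc <- arrayInd(used, nd) - 1L
  nodes <- cbind(cc[, 1] * h[1], cc[, 2] * h[2], cc[, 3] * h[3])

  elementSets <- list(bone = which(lab[vox] == 1L),
                      cement = which(lab[vox] == 2L))
  baseEls <- if (length(elementSets$cement)) elementSets$cement
             else seq_len(nrow(elements))
  baseNodes <- unique(as.vector(elements[baseEls, , drop = FALSE]))
  z <- nodes[baseNodes, 3]
  tol <- h[3] / 2
  nodeSets <- list(bottom_face = baseNodes[z < min(z) + tol],
                   top_face = baseNodes[z > max(z) - tol])
  new("HexMesh", nodes = nodes, elements = elements,
      elementSource = vox, spacing = h,
      nodeSets = nodeSets, elementSets = elementSets)
}

#' Assign element materials from grayscale via the linear conversion law
#'
#' Bone elements receive `E = max(alpha * GS, EFloor)` GPa where `GS` is the
#' mean grayscale of the element's source voxels (one voxel at continuum
#' resolution); cement elements receive the fixed cement modulus. A single
#' Poisson ratio applies to all elements.
#'
#' @param mesh a [HexMesh-class].
#' @param gray a gray8 [ImageVolume-class], voxel-aligned with the mask the
#'   mesh was built from.
#' @param alpha conversion factor, GPa per grayscale unit (> 0).
#' @param ECement cement modulus, GPa (default 2.45).
#' @param nu Poisson ratio (default 0.3, bone and cement alike).
#' @param EFloor minimum element modulus, GPa, so zero-gray elements cannot
#'   produce a singular system.
#' @param rigidCement if `TRUE`, cement is made effectively rigid (1e5 GPa);
#'   in that regime apparent stiffness is exactly proportional to `alpha`.
#' @return A [MaterialField-class].
#' @export
assignMaterials <- function(mesh, gray, alpha, ECement = 2.45, nu = 0.3,
                            EFloor = 0.001, rigidCement = FALSE) {
  stopifnot(is(mesh, "HexMesh"), is(gray, "ImageVolume"))
  if (alpha <= 0) stop("'alpha' must be > 0")
  if (max(mesh@elementSource) > length(gray@data))
    stop("grayscale volume is not aligned with the meshed mask")
  GS <- as.numeric(gray@data[mesh@elementSource])
  E <- pmax(alpha * GS, EFloor)
  cem <- mesh@elementSets$cement
  Ecem <- if (rigidCement) 1e5 else ECement
  if (length(cem)) {
    E[cem] <- Ecem
    GS[cem] <- NA_real_
  }
  new("MaterialField", E = E, GS = GS, alpha = alpha, nu = nu,
      ECement = Ecem)
}
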