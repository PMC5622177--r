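#' Normalise a raw scan to 8-bit grayscale
#'
#' Negative values (air/artefact in signed scanner output) are truncated to
#' zero, then values are scaled by `255 / M` where `M` is `referenceMax` if
#' supplied (for consistent normalisation across specimens of one study) or
#' the volume's own post-truncation maximum, and rounded half-away-from-zero
#' to integers in \[0, 255\].
#'
#' @param volume an [ImageVolume-class] with `kind = "raw"`.
#' @param referenceMax optional fixed scaling maximum.
#' @return An [ImageVolume-class] with `kind = "gray8"`.
#' @examples
#' v <- imageVolume(array(c(-100, 0, 510, 1020, 0, 0, 0, 0), c(2, 2, 2)), 1)
#' voxelData(normalizeGrayscale(v, referenceMax = 1020))[1:4]
#' @export
normalizeGrayscale <- function(volume, referenceMax = NULL) {
  stopifnot(is(volume, "ImageVolume"))
  if (volume@kind != "raw")
    stop("normalizeGrayscale expects a raw volume")
  x <- pmax(volume@data, 0)
  M <- if (is.null(referenceMax)) max(x) else referenceMax
  if (M <= 0)
    stop("degenerate image: post-truncation maximum is zero and no referenceMax given")
  g <- clamp(roundHalfAway(x * (255 / M)), 0, 255)
  imageVolume(g, volume@spacing, kind = "gray8")
}

#' Convert between scanner grayscale conventions
#'
#' Affine remapping `g -> clamp(round(gain * g + offset), 0, 255)` used to
#' bring 8-bit images from a second scanner (e.g. HR-pQCT) onto the
#' grayscale convention of the reference micro-CT before applying a
#' grayscale-to-modulus conversion factor. Gain and offset come from an
#' external cross-scanner calibration and are supplied by configuration.
#'
#' @param volume an [ImageVolume-class] with `kind = "gray8"`.
#' @param gain,offset affine map coefficients.
#' @return A remapped gray8 [ImageVolume-class].
#' @export
convertScannerGrayscale <- function(volume, gain, offset) {
  stopifnot(is(volume, "ImageVolume"))
  if (volume@kind != "gray8")
    stop("convertScannerGrayscale expects a gray8 volume")
  g <- clamp(roundHalfAway(gain * volume@data + offset), 0, 255)
  imageVolume(g, volume@spacing, kind = "gray8")
}

# 1-D fractional-overlap weight matrix: rows = target cells of width `target`
# covering [0, n*src], columns = source cells of width `src`. Entry (t, s) is
# the overlap length of target cell t with source cell s.
overlapWeights <- function(nSrc, src, target) {
  nT <- as.integer(ceiling(nSrc * src / target - 1e-9))
  tEdges <- (0:nT) * target
  sEdges <- (0:nSrc) * src
  W <- matrix(0, nT, nSrc)
  for (t in seq_len(nT)) {
    lo <- pmax(tEdges[t], sEdges[-length(sEdges)])
    hi <- pmin(tEdges[t + 1L], sEdges[-1L])
    W[t, ] <- pmax(hi - lo, 0)
  }
  W
}

#' Down-sample with partial-volume averaging
#'
#' Each coarse voxel's value is the volume-weighted mean of the fine voxels
#' it overlaps, with weights equal to the fractional geometric overlap (a
#' box filter, not interpolation). Coarse voxels at the far boundary that
#' are only partly covered by the source grid are normalised by the covered
#' volume only. Gray8 output is re-rounded half-away-from-zero.
#'
#' @param volume an [ImageVolume-class].
#' @param targetSpacing isotropic coarse voxel edge, mm; must be >= the
#'   source spacing along every axis. Default 1 mm, the continuum element
#'   size.
#' @return An [ImageVolume-class] of the same kind at `targetSpacing`.
#' @export
downsamplePartialVolume <- function(volume, targetSpacing = 1.0) {
  stopifnot(is(volume, "ImageVolume"))
  if (any(targetSpacing < volume@spacing - 1e-12))
    stop("targetSpacing must be >= the source spacing on every axis")
  d <- dim(volume@data)
  W <- lapply(1:3, function(ax) overlapWeights(d[ax], volume@spacing[ax],
                                               targetSpacing))
  num <- volume@data
  den <- array(1, dim = d)
  contract <- function(arr, ax, M) {
    # apply M (nT x nSrc) along axis ax of arr
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(arr, perm)
    da <- dim(a)
    a <- M %*% matrix(a, nrow = da[1])
    dim(a) <- c(nrow(M), da[2], da[3])
    aperm(a, order(perm))
  }
  for (ax in 1:3) {
    num <- contract(num, ax, W[[ax]])
    den <- contract(den, ax, W[[ax]])
  }
  out <- num / den
  if (volume@kind == "gray8") out <- clamp(roundHalfAway(out), 0, 255)
  imageVolume(out, rep(targetSpacing, 3L), kind = volume@kind)
}

#' Segment a normalised volume into continuum bone and cement masks
#'
#' Thresholds the volume (default: Otsu over nonzero voxels), fills
#' trabecular porosity by morphological closing with a ball of
#' `closingRadius` voxels so the result is a continuum-level mask, keeps the
#' largest connected component, and splits the foreground axially at the two
#' `cementPlanes` (mm): foreground between the planes is bone (label 1),
#' outside them cement (label 2).
#'
#' @param volume an [ImageVolume-class] with `kind = "gray8"`.
#' @param boneThreshold optional grayscale threshold; default Otsu over
#'   nonzero voxels.
#' @param cementPlanes numeric(2), axial world coordinates (mm) separating
#'   the cement endcaps from the vertebral body.
#' @param closingRadius structuring-element radius, voxels.
#' @return A [LabelMask-class].
#' @export
segmentContinuum <- function(volume, boneThreshold = NULL, cementPlanes,
                             closingRadius = 2L) {
  stopifnot(is(volume, "ImageVolume"), length(cementPlanes) == 2L)
  if (volume@kind != "gray8")
    stop("segmentContinuum expects a gray8 volume")
  g <- volume@data
  thr <- if (is.null(boneThreshold)) otsuThreshold(g[g > 0]) else boneThreshold
  fg <- g >= thr
  if (!any(fg))
    stop("segmentation failure: no voxel reaches the threshold (", thr, ")")
  fg <- binaryClose3d(fg, closingRadius)
  fg <- largestComponent3d(fg)
  zc <- (seq_len(dim(g)[3]) - 0.5) * volume@spacing[3]
  outside <- zc < min(cementPlanes) | zc > max(cementPlanes)
  labels <- array(0L, dim = dim(g))
  labels[fg] <- 1L
  cem <- array(rep(outside, each = prod(dim(g)[1:2])), dim = dim(g))
  labels[fg & cem] <- 2L
  labelMask(labels, volume@spacing)
}
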