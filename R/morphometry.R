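#' @importFrom grDevices chull
NULL

# Fill the convex hull of foreground pixels of a logical slice. Returns a
# logical matrix of the same size.
convexSupport2d <- function(slice) {
  pts <- which(slice, arr.ind = TRUE)
  if (nrow(pts) == 0L) return(slice & FALSE)
  if (nrow(pts) < 3L) { out <- slice & FALSE; out[pts] <- TRUE; return(out) }
  hull <- pts[chull(pts[, 1], pts[, 2]), , drop = FALSE]
  nh <- nrow(hull)
  gx <- rep(seq_len(nrow(slice)), times = ncol(slice))
  gy <- rep(seq_len(ncol(slice)), each = nrow(slice))
  inside <- rep(TRUE, length(gx))
  for (e in seq_len(nh)) {
    a <- hull[e, ]; b <- hull[e %% nh + 1L, ]
    cross <- (b[1] - a[1]) * (gy - a[2]) - (b[2] - a[2]) * (gx - a[1])
    inside <- inside & cross <= 1e-9
  }
  matrix(inside, nrow(slice), ncol(slice))
}

#' Fit the largest axis-aligned cylinder inside a trabecular mask
#'
#' Finds the largest cylinder, with axis parallel to the superior/inferior
#' image direction, inscribed in the trabecular compartment between two
#' endplate planes: each slice's convex support is computed, the supports
#' of all slices in `[zMin, zMax]` are intersected, and the maximal
#' inscribed circle of the intersection (via a 2-D Euclidean distance
#' transform) gives the radius and centre.
#'
#' @param boneMask logical 3-D array (trabecular bone microstructure).
#' @param spacing voxel spacing, mm (scalar or length 3).
#' @param zMin,zMax axial extent of the region between the endplates, mm.
#' @return An [ROICylinder-class].
#' @export
fitLargestCylinder <- function(boneMask, spacing, zMin, zMax) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  d <- dim(boneMask)
  zc <- (seq_len(d[3]) - 0.5) * spacing[3]
  slices <- which(zc >= zMin & zc <= zMax)
  if (!length(slices)) stop("no slices between zMin and zMax")
  common <- matrix(TRUE, d[1], d[2])
  any_fg <- FALSE
  for (k in slices) {
    s <- convexSupport2d(boneMask[, , k])
    if (any(s)) any_fg <- TRUE
    common <- common & s
  }
  if (!any_fg || !any(common))
    stop("empty intersection: no trabecular support common to all slices")
  dt <- EBImage::distmap(common)
  best <- which.max(dt)
  ctr <- arrayInd(best, dim(dt))
  new("ROICylinder",
      center = c((ctr[1] - 0.5) * spacing[1], (ctr[2] - 0.5) * spacing[2]),
      radius = as.numeric(dt[best]) * spacing[1],
      zMin = zMin, zMax = zMax)
}

#' Voxel mask of a cylindrical ROI
#'
#' @param cyl an [ROICylinder-class].
#' @param dim volume dimensions (voxels).
#' @param spacing voxel spacing, mm.
#' @return Logical 3-D array, `TRUE` inside the cylinder.
#' @export
cylinderMask <- function(cyl, dim, spacing) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  xc <- (seq_len(dim[1]) - 0.5) * spacing[1]
  yc <- (seq_len(dim[2]) - 0.5) * spacing[2]
  zc <- (seq_len(dim[3]) - 0.5) * spacing[3]
  lat <- outer((xc - cyl@center[1])^2, (yc - cyl@center[2])^2, "+") <=
    cyl@radius^2
  inz <- zc >= cyl@zMin & zc <= cyl@zMax
  array(lat, dim) & array(rep(inz, each = dim[1] * dim[2]), dim)
}

#' Bone volume fraction
#'
#' Bone voxels over total voxels of the region of interest.
#'
#' @param bone logical 3-D array of bone voxels.
#' @param roi optional logical array delimiting the ROI (default: all).
#' @return Fraction in \[0, 1\].
#' @export
bvtv <- function(bone, roi = NULL) {
  if (is.null(roi)) return(mean(bone))
  if (!sum(roi)) stop("ROI holds no voxels")
  sum(bone & roi) / sum(roi)
}

# Deterministic quasi-uniform hemisphere directions (golden-angle spiral).
hemisphereDirections <- function(n) {
  i <- seq_len(n) - 0.5
  z <- i / n
  phi <- i * pi * (3 - sqrt(5))
  s <- sqrt(1 - z^2)
  cbind(s * cos(phi), s * sin(phi), z)
}

#' Mean-intercept-length fabric tensor
#'
#' For a quasi-uniform set of hemisphere directions, parallel test lines
#' traverse the region of interest; the mean intercept length in direction
#' `n` is the total line length inside the ROI divided by the number of
#' bone/background crossings along those lines. The fabric ellipsoid tensor
#' `H` is fitted by least squares on `n' H n = 1 / MIL(n)^2`; its
#' eigen-lengths `1/sqrt(eigenvalues)` are the principal mean intercept
#' lengths, the principal eigenvector is the dominant trabecular direction,
#' and the degree of anisotropy is `1 - Lmin/Lmax` (0 = isotropic).
#'
#' Directions along which no crossing occurs are dropped; if more than 20%
#' of directions drop, the structure is too dense or sparse for MIL and an
#' error is raised.
#'
#' @param bone logical 3-D array of bone voxels (high-resolution
#'   microstructure, not the down-sampled continuum image).
#' @param spacing voxel spacing, mm.
#' @param roi optional logical ROI array (e.g. from [cylinderMask()]).
#' @param nDirections number of test directions (default 512).
#' @param lineSpacing spacing between parallel test lines, in voxels
#'   (default 2).
#' @param seed integer seed for the per-direction line-grid jitter.
#' @return A [FabricTensor-class].
#' @export
milFabricTensor <- function(bone, spacing, roi = NULL, nDirections = 512L,
                            lineSpacing = 2, seed = 1L) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  d <- dim(bone)
  if (is.null(roi)) roi <- array(TRUE, d)
  nBone <- sum(bone & roi)
  if (nBone == 0L || nBone == sum(roi))
    stop("ROI must contain both bone and background")
  dirs <- hemisphereDirections(as.integer(nDirections))
  # sample only the ROI bounding box
  bb <- apply(arrayInd(which(roi), d), 2, range)
  ctr <- (colMeans(bb) - 0.5) * spacing
  R <- sqrt(sum(((bb[2, ] - bb[1, ] + 1) * spacing)^2)) / 2
  ls <- lineSpacing * min(spacing)
  step <- 0.5 * min(spacing)
  tSamp <- seq(-R, R, by = step)
  nT <- length(tSamp)
  boneNum <- array(NA_real_, d)
  boneNum[roi] <- as.numeric(bone[roi])
  set.seed(as.integer(seed))
  mil <- rep(NA_real_, nrow(dirs))
  for (k in seq_len(nrow(dirs))) {
    w <- dirs[k, ]
    a <- if (abs(w[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    e1 <- c(w[2] * a[3] - w[3] * a[2], w[3] * a[1] - w[1] * a[3],
            w[1] * a[2] - w[2] * a[1])
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(w[2] * e1[3] - w[3] * e1[2], w[3] * e1[1] - w[1] * e1[3],
            w[1] * e1[2] - w[2] * e1[1])
    jit <- runif(2, 0, ls)
    grid <- expand.grid(a = seq(-R, R, by = ls) + jit[1],
                        b = seq(-R, R, by = ls) + jit[2])
    keep <- grid$a^2 + grid$b^2 <= R^2
    grid <- grid[keep, , drop = FALSE]
    nL <- nrow(grid)
    if (!nL) next
    ox <- ctr[1] + grid$a * e1[1] + grid$b * e2[1]
    oy <- ctr[2] + grid$a * e1[2] + grid$b * e2[2]
    oz <- ctr[3] + grid$a * e1[3] + grid$b * e2[3]
    px <- outer(tSamp * w[1], ox, "+")      # nT x nL
    py <- outer(tSamp * w[2], oy, "+")
    pz <- outer(tSamp * w[3], oz, "+")
    ix <- floor(px / spacing[1]) + 1
    iy <- floor(py / spacing[2]) + 1
    iz <- floor(pz / spacing[3]) + 1
    valid <- ix >= 1 & ix <= d[1] & iy >= 1 & iy <= d[2] & iz >= 1 & iz <= d[3]
    V <- matrix(NA_real_, nT, nL)
    lin <- (ix[valid] - 1) + d[1] * ((iy[valid] - 1) + d[2] * (iz[valid] - 1)) + 1
    V[valid] <- boneNum[lin]
    nIn <- sum(!is.na(V))
    if (!nIn) next
    dV <- abs(V[-1, , drop = FALSE] - V[-nT, , drop = FALSE])
    crossings <- sum(dV > 0.5, na.rm = TRUE)
    if (crossings == 0L) next
    mil[k] <- nIn * step / crossings
  }
  ok <- is.finite(mil)
  if (mean(!ok) > 0.2)
    stop("more than 20% of directions yielded no crossings; ",
         "structure too dense or sparse for MIL analysis")
  nr <- dirs[ok, , drop = FALSE]
  A <- cbind(nr[, 1]^2, nr[, 2]^2, nr[, 3]^2,
             2 * nr[, 1] * nr[, 2], 2 * nr[, 1] * nr[, 3],
             2 * nr[, 2] * nr[, 3])
  h <- qr.solve(A, 1 / mil[ok]^2)
  H <- matrix(c(h[1], h[4], h[5],
                h[4], h[2], h[6],
                h[5], h[6], h[3]), 3, 3)
  eg <- eigen(H, symmetric = TRUE)
  emax <- max(eg$values)
  if (emax <= 0 || any(eg$values < -0.05 * emax))
    stop("fitted fabric tensor is not positive definite")
  # near-singular fits (ideal plate-like structures, where in-plane MIL
  # diverges and the small eigenvalues sit at the fit-noise level) are
  # floored so DA stays finite and < 1
  vals <- pmax(eg$values, 1e-6 * emax)
  lens <- 1 / sqrt(vals)                 # ascending eigenvalue -> descending length
  ordL <- order(lens, decreasing = TRUE)
  lens <- lens[ordL]
  vecs <- eg$vectors[, ordL, drop = FALSE]
  v1 <- vecs[, 1]
  dev <- acos(pmin(abs(v1[3]), 1)) * 180 / pi
  new("FabricTensor", H = (H + t(H)) / 2, milLengths = lens,
      eigenvectors = vecs, DA = 1 - lens[3] / lens[1],
      orientationDeviation = dev, nDirections = sum(ok))
}

#' Degree of anisotropy from MIL eigen-lengths
#'
#' `1 - Lmin/Lmax` on a \[0, 1) scale: 0 for an isotropic structure,
#' approaching 1 for strongly oriented trabeculae.
#'
#' @param lengths numeric(3) MIL eigen-lengths, or a [FabricTensor-class].
#' @return Dimensionless DA.
#' @examples
#' degreeOfAnisotropy(c(1, 1, 1))   # 0
#' @export
degreeOfAnisotropy <- function(lengths) {
  if (is(lengths, "FabricTensor")) return(lengths@DA)
  stopifnot(length(lengths) == 3L, all(lengths > 0))
  1 - min(lengths) / max(lengths)
}

#' Trabecular orientation deviation from the superior/inferior axis
#'
#' `arccos(|v1 . z|)` in degrees, where `v1` is the principal (longest-MIL)
#' eigenvector; the absolute value folds antipodal directions so the result
#' lies in \[0, 90\] degrees.
#'
#' @param x a [FabricTensor-class] or a numeric(3) direction vector.
#' @return Degrees in \[0, 90\].
#' @examples
#' trabecularOrientation(c(1, 0, 1) / sqrt(2))   # 45
#' trabecularOrientation(c(0, 0, -1))            # 0
#' @export
trabecularOrientation <- function(x) {
  v <- if (is(x, "FabricTensor")) x@eigenvectors[, 1] else x
  stopifnot(length(v) == 3L)
  v <- v / sqrt(sum(v^2))
  acos(pmin(abs(v[3]), 1)) * 180 / pi
}
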