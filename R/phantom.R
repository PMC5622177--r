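#' Generate a synthetic vertebra phantom volume
#'
#' Builds a seeded, micro-CT-like image of a cylindrical vertebral body with
#' a solid cortical shell, a trabecular interior, and uniform cement endcap
#' slabs above and below, surrounded by background. The trabecular texture is
#' an anisotropic correlated Gaussian random field (white noise smoothed by
#' an ellipsoidal kernel elongated axially by `anisotropyStretch`),
#' thresholded at the quantile that realises the requested bone volume
#' fraction — so BV/TV and the degree of anisotropy are both continuously
#' and reproducibly controllable.
#'
#' @param spec a [PhantomSpec-class].
#' @param trabecularScale lateral correlation length of the trabecular
#'   texture, mm (axial length is `trabecularScale * anisotropyStretch`).
#' @return A list:
#' \describe{
#'   \item{volume}{[ImageVolume-class] (`kind = "raw"`, values in 0-255).}
#'   \item{truth}{list with `bvtv` (realised interior bone volume fraction),
#'     `axis` (unit axial vector), `labels` (a [LabelMask-class]: 0
#'     background / 1 bone / 2 cement continuum truth), `trabecular`
#'     (logical array: interior bone microstructure), `interior` (logical
#'     array: trabecular compartment), and `cementPlanes` (axial mm
#'     coordinates separating cement from bone).}
#' }
#' @examples
#' ph <- generatePhantom(phantomSpec(bodyRadius = 5, bodyHeight = 8,
#'                                   endcapHeight = 2, voxelSpacing = 1))
#' ph$truth$bvtv
#' @export
generatePhantom <- function(spec, trabecularScale = 0.5) {
  validObject(spec)
  h <- spec@voxelSpacing
  margin <- 1L                       # background rim, voxels
  nx <- as.integer(ceiling(2 * spec@bodyRadius / h)) + 2L * margin
  nz <- as.integer(ceiling((spec@bodyHeight + 2 * spec@endcapHeight) / h))
  d <- c(nx, nx, nz)

  cx <- nx * h / 2
  xc <- (seq_len(nx) - 0.5) * h
  zc <- (seq_len(nz) - 0.5) * h
  r2 <- outer((xc - cx)^2, (xc - cx)^2, "+")          # nx x nx lateral
  inBody2d <- r2 <= spec@bodyRadius^2
  inCore2d <- r2 <= (spec@bodyRadius - spec@shellThickness)^2

  zLow <- spec@endcapHeight
  zHigh <- spec@endcapHeight + spec@bodyHeight
  isCementZ <- zc < zLow | zc > zHigh

  inBody <- array(inBody2d, dim = d)                  # cylinder, all z
  zMask <- array(rep(isCementZ, each = nx * nx), dim = d)
  cement <- inBody & zMask
  body <- inBody & !zMask
  shell <- body & !array(inCore2d, dim = d)
  interior <- body & array(inCore2d, dim = d)

  set.seed(spec@seed)
  noise <- array(rnorm(prod(d)), dim = d)
  sigma <- trabecularScale / h
  field <- gaussianSmooth3d(noise, sigma * c(1, 1, spec@anisotropyStretch))

  q <- quantile(field[interior], probs = 1 - spec@bvtvTarget, names = FALSE)
  trabecular <- interior & (field >= q)
  realizedBvtv <- sum(trabecular) / sum(interior)

  gray <- array(spec@backgroundGray, dim = d)
  gray[cement] <- spec@cementGray
  gray[shell] <- spec@boneGrayMean
  gray[trabecular] <- spec@boneGrayMean
  if (spec@noiseSd > 0) {
    gray <- gray + rnorm(prod(d), sd = spec@noiseSd)
    gray <- clamp(gray, 0, 255)
  }

  labels <- array(0L, dim = d)
  labels[body] <- 1L
  labels[cement] <- 2L

  list(volume = imageVolume(gray, spacing = h, kind = "raw"),
       truth = list(bvtv = realizedBvtv, axis = c(0, 0, 1),
                    labels = labelMask(labels, h),
                    trabecular = trabecular, interior = interior,
                    cementPlanes = c(zLow, zHigh)))
}

#' Generate a synthetic load-displacement curve
#'
#' Emulates an axial compression test to failure: a smooth quadratic toe
#' region (slope rising from 0 and matching the linear slope at its end), a
#' linear region of slope `trueStiffness`, a load plateau at `plateauLoad`,
#' and optional additive Gaussian load noise. The linear region must span at
#' least the 0.6 mm stiffness analysis window, otherwise the parameters are
#' window-infeasible and an error is raised.
#'
#' @param spec a [CurveSpec-class].
#' @param id specimen identifier for the curve.
#' @return A [LoadDisplacementCurve-class].
#' @examples
#' cv <- generateCurve(curveSpec(trueStiffness = 7, toeLength = 0,
#'                               plateauLoad = 1e6))
#' apparentStiffness(extractStiffness(cv))
#' @export
generateCurve <- function(spec, id = "synthetic") {
  validObject(spec)
  k <- spec@trueStiffness
  t <- spec@toeLength
  dPlateau <- spec@plateauLoad / k + t / 2   # where the linear ramp hits the plateau
  if (min(dPlateau, spec@totalDisplacement) - t < 0.6)
    stop("window-infeasible curve spec: the linear region (",
         signif(min(dPlateau, spec@totalDisplacement) - t, 3),
         " mm) is shorter than the 0.6 mm analysis window")
  d <- seq(0, spec@totalDisplacement, by = spec@sampleStep)
  load <- ifelse(d <= t & t > 0, k * d^2 / (2 * t), k * (d - t / 2))
  load <- pmin(load, spec@plateauLoad)
  if (spec@noiseSd > 0) {
    set.seed(spec@seed)
    load <- load + rnorm(length(load), sd = spec@noiseSd)
  }
  loadDisplacementCurve(d, load, id = id)
}
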