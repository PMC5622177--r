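#' Extract apparent stiffness as the maximal moving-window slope
#'
#' The experimental apparent stiffness is the largest slope of the
#' load-displacement curve over a moving window of 0.6 mm aperture: for
#' every window position (the left edge stepping one sample at a time), the
#' slope is the ordinary-least-squares slope of load against displacement
#' over the samples inside the window, and the maximum over positions is
#' returned. Windows holding fewer than 3 samples are skipped.
#'
#' The estimate is equivariant in load scale, invariant to a displacement
#' origin shift, and exact on curves that are linear within some window.
#'
#' @param curve a [LoadDisplacementCurve-class].
#' @param windowWidth analysis aperture, mm (default 0.6).
#' @return A [StiffnessEstimate-class].
#' @examples
#' cv <- loadDisplacementCurve(seq(0, 2, 0.01), 7 * seq(0, 2, 0.01))
#' apparentStiffness(extractStiffness(cv))   # 7
#' @export
extractStiffness <- function(curve, windowWidth = 0.6) {
  stopifnot(is(curve, "LoadDisplacementCurve"), windowWidth > 0)
  d <- curve@displacement
  y <- curve@load
  n <- length(d)
  if (diff(range(d)) < windowWidth)
    stop("curve span (", signif(diff(range(d)), 3),
         " mm) is shorter than the analysis window (", windowWidth, " mm)")
  # prefix sums for O(1) OLS slope per window
  cd <- cumsum(d); cy <- cumsum(y); cdd <- cumsum(d * d); cdy <- cumsum(d * y)
  pre <- function(v, i) if (i == 0L) 0 else v[i]
  last <- findInterval(d + windowWidth, d)      # rightmost sample in window of i
  best <- -Inf; bestCenter <- NA_real_
  for (i in seq_len(n)) {
    j <- last[i]
    m <- j - i + 1L
    if (m < 3L) next
    if (d[j] - d[i] < windowWidth - 1e-12 && j == n) break  # ran off the end
    Sx <- cd[j] - pre(cd, i - 1L)
    Sy <- cy[j] - pre(cy, i - 1L)
    Sxx <- cdd[j] - pre(cdd, i - 1L)
    Sxy <- cdy[j] - pre(cdy, i - 1L)
    denom <- m * Sxx - Sx * Sx
    if (denom <= 0) next
    slope <- (m * Sxy - Sx * Sy) / denom
    if (slope > best) { best <- slope; bestCenter <- d[i] + windowWidth / 2 }
  }
  if (!is.finite(best))
    stop("no window held the minimum of 3 samples; curve too sparse")
  new("StiffnessEstimate", stiffness = best, windowWidth = windowWidth,
      windowCenter = bestCenter)
}
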