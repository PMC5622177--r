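#' Normalised stiffness RMSE
#'
#' Root-mean-square of per-specimen relative stiffness differences,
#' `sqrt(mean(((kSim - kExp)/kExp)^2))` — the calibration objective.
#'
#' @param kExp experimental stiffness values, kN/mm (all > 0).
#' @param kSim simulated stiffness values, kN/mm (same length).
#' @return Dimensionless fraction (0.1 = 10%).
#' @examples
#' rmseNormalized(c(10, 10), c(9, 11))   # 0.10
#' @export
rmseNormalized <- function(kExp, kSim) {
  if (length(kExp) != length(kSim) || length(kExp) < 1L)
    stop("'kExp' and 'kSim' must have equal length >= 1")
  if (any(kExp <= 0)) stop("all experimental stiffness values must be > 0")
  sqrt(mean(((kSim - kExp) / kExp)^2))
}

#' Closed-form conversion factor for linearly scaling models
#'
#' When simulated stiffness is exactly proportional to the conversion
#' factor (all-bone or rigid-cement models: `kSim(alpha) = alpha * kUnit`),
#' the normalised-RMSE objective is a quadratic in alpha and its minimiser
#' has the closed form `alpha* = sum(r) / sum(r^2)` with
#' `r_i = kUnit_i / kExp_i`. Serves as the analytic oracle for the Brent
#' calibration.
#'
#' @param kExp experimental stiffness values, kN/mm.
#' @param kUnit unit-alpha simulated stiffness values, kN/mm.
#' @return The optimal conversion factor, GPa per grayscale unit.
#' @examples
#' closedFormAlpha(c(6, 8), c(600, 1000))   # 225/25625
#' @export
closedFormAlpha <- function(kExp, kUnit) {
  if (length(kExp) != length(kUnit) || length(kExp) < 1L)
    stop("'kExp' and 'kUnit' must have equal length >= 1")
  if (any(kExp <= 0) || any(kUnit <= 0))
    stop("stiffness values must be > 0")
  r <- kUnit / kExp
  den <- sum(r^2)
  if (den == 0) stop("zero denominator in closed-form alpha")
  sum(r) / den
}

# Simulated stiffness of one specimen record at a given alpha, with a
# per-record cache keyed by alpha so optimizer traces are reproducible and
# repeated probes are free.
specimenStiffnessAt <- function(record, alpha) {
  if (!is.null(record@kUnit)) return(alpha * record@kUnit)
  cache <- attr(record, "cache")
  key <- sprintf("%.17g", alpha)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  args <- c(list(mesh = record@mesh, gray = record@gray, alpha = alpha),
            attr(record, "matArgs"))
  mats <- do.call(assignMaterials, args)
  k <- apparentStiffness(
    solveCompression(assembleStiffness(record@mesh, mats), record@loadCase))
  if (!is.null(cache)) cache[[key]] <- k
  k
}

calibrationObjective <- function(records, alpha) {
  kSim <- vapply(records, specimenStiffnessAt, 0, alpha = alpha)
  rmseNormalized(vapply(records, function(r) r@kExp, 0), kSim)
}

#' Calibrate the grayscale-to-modulus conversion factor
#'
#' Minimises the normalised stiffness RMSE between experimental and
#' simulated stiffness over the calibration records by Brent scalar
#' minimisation (golden-section with parabolic steps, via
#' [stats::optimize()]), each objective evaluation re-running the FE
#' compression analysis at the probed alpha (cached per specimen). Two
#' early-termination criteria mirror the usual practice of stopping a
#' stiffness calibration once the fit is good enough: the search stops when
#' the objective drops to `rmseStop` (default 0.1, i.e. 10% RMSE) or when
#' the objective changes between successive evaluations by less than
#' `relChangeStop` times its current value. Set both to 0 to run Brent to
#' its own bracket tolerance (needed when validating against the
#' closed-form oracle).
#'
#' If the minimiser lands on a bracket end, the bracket is expanded once by
#' a factor of 10 on that side and the search repeated; a second boundary
#' hit is an error.
#'
#' @param records list of [SpecimenRecord-class] with `group ==
#'   "calibration"` (records from other groups are rejected to prevent
#'   leakage).
#' @param bracket search interval for alpha, GPa per grayscale unit.
#' @param rmseStop objective threshold for early termination.
#' @param relChangeStop relative objective-plateau threshold.
#' @param tol Brent bracket tolerance on alpha.
#' @return A [CalibrationResult-class].
#' @export
calibrateAlpha <- function(records, bracket = c(1e-5, 0.1),
                           rmseStop = 0.1, relChangeStop = 1e-3,
                           tol = 1e-8) {
  if (!length(records)) stop("need at least one calibration record")
  grp <- vapply(records, function(r) r@group, "")
  if (any(grp != "calibration"))
    stop("records from the validation group leaked into calibration: ",
         paste(vapply(records[grp != "calibration"], function(r) r@id, ""),
               collapse = ", "))
  trace <- new.env(parent = emptyenv())
  trace$alpha <- numeric(0); trace$obj <- numeric(0)
  earlyStop <- function(reason, alpha, value)
    structure(class = c("vertefemEarlyStop", "condition"),
              list(message = reason, call = NULL, alpha = alpha, value = value))
  fobj <- function(a) {
    v <- calibrationObjective(records, a)
    if (!is.finite(v)) stop("objective non-finite at alpha = ", a)
    nprev <- length(trace$obj)
    prev <- if (nprev) trace$obj[nprev] else NA_real_
    trace$alpha <- c(trace$alpha, a); trace$obj <- c(trace$obj, v)
    if (rmseStop > 0 && v <= rmseStop)
      stop(earlyStop("objective_threshold", a, v))
    if (relChangeStop > 0 && nprev >= 3L && is.finite(prev) &&
        abs(v - prev) <= relChangeStop * max(v, .Machine$double.eps))
      stop(earlyStop("objective_plateau", a, v))
    v
  }
  runBrent <- function(br) {
    tryCatch(optimize(fobj, interval = br, tol = tol),
             vertefemEarlyStop = function(c)
               list(minimum = c$alpha, objective = c$value,
                    termination = conditionMessage(c)))
  }
  # check ends are evaluable (without tripping the early-stop machinery)
  for (b in bracket)
    if (!is.finite(calibrationObjective(records, b)))
      stop("objective non-finite at bracket end alpha = ", b)
  res <- runBrent(bracket)
  termination <- if (!is.null(res$termination)) res$termination
                 else "bracket_converged"
  alphaHat <- res$minimum
  # boundary hit: expand the bracket once on that side
  span <- diff(bracket)
  bEps <- max(1e-3 * span, 10 * tol)
  if (termination == "bracket_converged" &&
      (alphaHat - bracket[1] < bEps || bracket[2] - alphaHat < bEps)) {
    newBracket <- if (alphaHat - bracket[1] < bEps)
      c(bracket[1] / 10, bracket[2]) else c(bracket[1], bracket[2] * 10)
    res <- runBrent(newBracket)
    termination <- if (!is.null(res$termination)) res$termination
                   else "bracket_converged"
    alphaHat <- res$minimum
    span <- diff(newBracket)
    bEps <- max(1e-3 * span, 10 * tol)
    if (termination == "bracket_converged" &&
        (alphaHat - newBracket[1] < bEps ||
         newBracket[2] - alphaHat < bEps))
      stop("minimum still at the bracket boundary after one expansion; ",
           "the bracket does not contain the optimum")
  }
  kExp <- vapply(records, function(r) r@kExp, 0)
  kSim <- vapply(records, specimenStiffnessAt, 0, alpha = alphaHat)
  new("CalibrationResult", alpha = alphaHat,
      rmse = rmseNormalized(kExp, kSim),
      pairs = data.frame(id = vapply(records, function(r) r@id, ""),
                         kExp = kExp, kSim = kSim),
      iterations = length(trace$obj), termination = termination,
      trace = data.frame(alpha = trace$alpha, rmse = trace$obj))
}

#' Evaluate a fixed conversion factor on a validation set
#'
#' Runs the FE compression analysis at the given alpha for every validation
#' record and reports the normalised RMSE and per-specimen relative errors.
#'
#' @param alpha conversion factor, GPa per grayscale unit.
#' @param records list of [SpecimenRecord-class] with `group ==
#'   "validation"` (calibration records are rejected to prevent leakage).
#' @return A list: `rmse`, `pairs` (data.frame id/kExp/kSim/relError), and
#'   `maxRelError`.
#' @export
validateAlpha <- function(alpha, records) {
  if (!length(records)) stop("need at least one validation record")
  grp <- vapply(records, function(r) r@group, "")
  if (any(grp != "validation"))
    stop("records from the calibration group leaked into validation: ",
         paste(vapply(records[grp != "validation"], function(r) r@id, ""),
               collapse = ", "))
  kExp <- vapply(records, function(r) r@kExp, 0)
  kSim <- vapply(records, specimenStiffnessAt, 0, alpha = alpha)
  rel <- (kSim - kExp) / kExp
  list(rmse = rmseNormalized(kExp, kSim),
       pairs = data.frame(id = vapply(records, function(r) r@id, ""),
                          kExp = kExp, kSim = kSim, relError = rel),
       maxRelError = max(abs(rel)))
}
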