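test_that("normalised RMSE matches its worked examples", {
  expect_equal(rmseNormalized(c(10, 10), c(9, 11)), 0.10)
  expect_equal(rmseNormalized(c(5, 7, 9), c(5, 7, 9)), 0)
  expect_equal(rmseNormalized(5, 6), 0.20)
  expect_error(rmseNormalized(c(1, 2), 1), "length")
  expect_error(rmseNormalized(c(0, 2), c(1, 2)), "> 0")
})

test_that("closed-form alpha minimises the proportional-model objective", {
  expect_equal(closedFormAlpha(5.8, 580), 0.01)
  expect_equal(closedFormAlpha(c(6, 8), c(600, 1000)), 225 / 25625)
  # scale equivariance: scaling kUnit by c scales alpha by 1/c
  set.seed(2)
  kE <- runif(5, 4, 9); kU <- runif(5, 400, 900)
  expect_equal(closedFormAlpha(kE, 3 * kU), closedFormAlpha(kE, kU) / 3)
  # it is the argmin: nearby alphas never do better
  a <- closedFormAlpha(kE, kU)
  for (da in c(-1e-4, 1e-4))
    expect_gt(rmseNormalized(kE, (a + da) * kU), rmseNormalized(kE, a * kU))
})

test_that("Brent calibration agrees with the closed form on proportional models", {
  set.seed(7)
  kU <- runif(6, 400, 900)
  kE <- 0.008 * kU * exp(rnorm(6, 0, 0.1))
  recs <- lapply(seq_along(kU), function(i)
    specimenRecord(paste0("c", i), kE[i], "calibration", kUnit = kU[i]))
  cal <- calibrateAlpha(recs, rmseStop = 0, relChangeStop = 0)
  expect_equal(conversionFactor(cal), closedFormAlpha(kE, kU),
               tolerance = 1e-6)
  expect_equal(cal@termination, "bracket_converged")
  # converged objective is no worse than any probed alpha
  expect_lte(cal@rmse, min(cal@trace$rmse) + 1e-12)
  # rmse is recomputable from the reported pairs
  expect_equal(cal@rmse, rmseNormalized(cal@pairs$kExp, cal@pairs$kSim))
})

test_that("the early-termination criteria stop the search as configured", {
  recs <- lapply(1:4, function(i)
    specimenRecord(paste0("c", i), 5 + i, "calibration", kUnit = 100 * (5 + i)))
  # objective reaches zero at alpha = 0.01, so the 10% threshold trips first
  cal <- calibrateAlpha(recs, rmseStop = 0.1, relChangeStop = 0)
  expect_equal(cal@termination, "objective_threshold")
  expect_lte(cal@rmse, 0.1)
  cal2 <- calibrateAlpha(recs, rmseStop = 0, relChangeStop = 1e-3)
  expect_true(cal2@termination %in% c("objective_plateau", "bracket_converged"))
})

test_that("the bracket expands once when the optimum lies outside", {
  # optimal alpha = 0.5, far above the default upper end of 0.1
  recs <- list(specimenRecord("big", 5, "calibration", kUnit = 10))
  cal <- calibrateAlpha(recs, rmseStop = 0, relChangeStop = 0)
  expect_equal(conversionFactor(cal), 0.5, tolerance = 1e-5)
})

test_that("calibration and validation groups cannot leak", {
  recC <- specimenRecord("a", 5, "calibration", kUnit = 500)
  recV <- specimenRecord("b", 6, "validation", kUnit = 600)
  expect_error(calibrateAlpha(list(recC, recV)), "leaked")
  expect_error(validateAlpha(0.01, list(recC)), "leaked")
})

test_that("validation reports per-specimen relative errors", {
  recs <- lapply(1:3, function(i)
    specimenRecord(paste0("v", i), i * 2, "validation", kUnit = i * 200))
  # alpha = 0.01 reproduces every specimen exactly
  v <- validateAlpha(0.01, recs)
  expect_equal(v$rmse, 0, tolerance = 1e-12)
  # doubling alpha on proportional models: every relative error is +100%
  v2 <- validateAlpha(0.02, recs)
  expect_equal(v2$pairs$relError, rep(1, 3), tolerance = 1e-12)
  expect_equal(v2$maxRelError, 1, tolerance = 1e-12)
  expect_equal(v2$rmse, 1, tolerance = 1e-12)
})

test_that("full-FE calibration recovers a known conversion factor", {
  # two bone+cement specimens, experimental stiffness simulated at a known
  # alpha with the deformable-cement model itself
  alphaTrue <- 0.008
  recs <- lapply(c(301L, 302L), function(s) {
    sm <- fixSpecimenModel(s)
    k <- apparentStiffness(solveCompression(assembleStiffness(
      sm$mesh, assignMaterials(sm$mesh, sm$gray, alpha = alphaTrue))))
    specimenRecord(paste0("fe", s), k, "calibration",
                   mesh = sm$mesh, gray = sm$gray)
  })
  cal <- calibrateAlpha(recs, rmseStop = 0, relChangeStop = 0, tol = 1e-7)
  expect_equal(conversionFactor(cal), alphaTrue, tolerance = 5e-3)
  expect_lt(cal@rmse, 1e-3)
})
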