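pwCurve <- function(step = 0.01) {
  d <- seq(0, 4, step)
  loadDisplacementCurve(d, ifelse(d < 1, d, ifelse(d < 3, 1 + 5 * (d - 1), 11)))
}

test_that("maximal window slope finds the linear region", {
  # toe slope 1, linear slope 5, plateau: the window settles in the linear part
  est <- extractStiffness(pwCurve())
  expect_equal(apparentStiffness(est), 5.0, tolerance = 1e-12)
  expect_true(est@windowCenter > 1 && est@windowCenter < 3)
  # pure line: any window gives the slope
  d <- seq(0, 2, 0.01)
  expect_equal(apparentStiffness(extractStiffness(
    loadDisplacementCurve(d, 7 * d))), 7.0)
})

test_that("stiffness estimate is scale-equivariant and shift-invariant", {
  cv <- pwCurve()
  df <- curveData(cv)
  expect_equal(apparentStiffness(extractStiffness(
    loadDisplacementCurve(df$displacement_mm, 3 * df$load_kN))), 15.0)
  expect_equal(apparentStiffness(extractStiffness(
    loadDisplacementCurve(df$displacement_mm + 11, df$load_kN))), 5.0)
})

test_that("estimate is invariant to densification of a piecewise-linear curve", {
  expect_equal(apparentStiffness(extractStiffness(pwCurve(0.02))),
               apparentStiffness(extractStiffness(pwCurve(0.002))),
               tolerance = 1e-12)
})

test_that("degenerate curves are rejected", {
  d <- seq(0, 0.4, 0.1)
  expect_error(extractStiffness(loadDisplacementCurve(d, d)), "span")
  # < 3 samples in every window
  expect_error(extractStiffness(loadDisplacementCurve(c(0, 1), c(0, 1)),
                                windowWidth = 0.6), "span|samples")
  # sub-micron reversals are tolerated, larger ones are not
  expect_s4_class(loadDisplacementCurve(c(0, 0.01, 0.0099998, 0.02),
                                        c(0, 1, 1, 2)),
                  "LoadDisplacementCurve")
  expect_error(loadDisplacementCurve(c(0, 0.5, 0.3, 0.8), c(0, 1, 1, 2)),
               "reversal")
})

test_that("curve CSV files round-trip and honour load units", {
  cv <- generateCurve(curveSpec(trueStiffness = 6, seed = 2L))
  f <- file.path(tempdir(), "curve.csv")
  writeLoadCurve(cv, f)
  back <- readLoadCurve(f)
  expect_equal(curveData(back), curveData(cv))
  # loads in newtons are converted to kN
  fn <- file.path(tempdir(), "curve_n.csv")
  df <- curveData(cv)
  utils::write.csv(data.frame(displacement_mm = df$displacement_mm,
                              load_N = df$load_kN * 1000), fn,
                   row.names = FALSE)
  expect_equal(curveData(readLoadCurve(fn))$load_kN, df$load_kN)
  f2 <- file.path(tempdir(), "bad.csv")
  writeLines("a,b\n1,2", f2)
  expect_error(readLoadCurve(f2), "displacement_mm")
})
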