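# The threshold-adjustment function machinery: published models, %Tmean
# evaluation, threshold conversion, composition, serialization.

test_that("published models carry the printed coefficients and R-squared", {
  m1 <- predefinedModel(1)
  expect_equal(modelFamily(m1), "power")
  expect_equal(modelCoefficients(m1), c(130.9, -0.23))
  expect_equal(modelPredictor(m1), "tmean_over_bmin")
  expect_equal(rSquared(m1), 0.81)

  m3 <- predefinedModel(3)
  expect_equal(modelFamily(m3), "linear")
  expect_equal(modelCoefficients(m3), c(1.64, -1634.8))
  expect_equal(modelPredictor(m3), "tmean")
  expect_equal(rSquared(m3), 0.96)

  m8 <- predefinedModel(8)
  expect_equal(modelFamily(m8), "composed")
  expect_equal(modelCoefficients(m8), c(151.62, -0.24, 1.73, -1903.8))

  expect_equal(vapply(1:8, function(i) rSquared(predefinedModel(i)), 0),
               c(0.81, 0.87, 0.96, 0.82, 0.65, 0.74, 0.96, 0.99))
  expect_error(predefinedModel(9), "unknown model")
})

test_that("%Tmean evaluation reproduces the published operating points", {
  # unit predictor ratio: the power term collapses to the scale coefficient
  expect_equal(evaluatePct(predefinedModel(2), 1, 1), 136.09)
  # worked-example operating point (printed 52.88 was computed with
  # unrounded regression coefficients, hence the 0.5-point band)
  expect_equal(evaluatePct(predefinedModel(4), 22146, 464), 52.88,
               tolerance = 0.5 / 52.88)
  # validation-cohort operating point (printed 56.8)
  expect_equal(evaluatePct(predefinedModel(4), 16213.8, 464), 56.8,
               tolerance = 0.5 / 56.8)
})

test_that("model domain violations are rejected", {
  expect_error(evaluatePct(predefinedModel(4), 22146, 0), "model domain")
  expect_error(evaluatePct(predefinedModel(4), 500, 464), "model domain")
  expect_error(evaluatePct(predefinedModel(3), 1000, 464), "predicts Tmax")
  expect_equal(predictTmax(predefinedModel(3), 1000), 1.64 * 1000 - 1634.8)
})

test_that("threshold conversion rounds to the printed gray levels", {
  expect_equal(thresholdFromPct(52.88, 22146), 11711)
  expect_equal(thresholdFromPct(55.92, 17385), 9722)
  expect_equal(thresholdFromPct(100, 12345), 12345)
  expect_equal(thresholdFromPct(50, 101), 51)    # .5 rounds away from zero
  expect_error(thresholdFromPct(0, 100), "> 0")
})

test_that("composition reproduces the published composed coefficients", {
  c4 <- composeModels(predefinedModel(2), predefinedModel(3))
  expect_equal(modelCoefficients(c4), modelCoefficients(predefinedModel(4)))
  c8 <- composeModels(predefinedModel(6), predefinedModel(7))
  expect_equal(modelCoefficients(c8), modelCoefficients(predefinedModel(8)))
  expect_error(composeModels(predefinedModel(1), predefinedModel(3)),
               "tmax_over_bmin")
  expect_error(composeModels(predefinedModel(2), predefinedModel(4)),
               "linear")
})

test_that("composed evaluation equals the manual two-step evaluation", {
  outer <- predefinedModel(2)
  law <- predefinedModel(3)
  comp <- composeModels(outer, law)
  set.seed(11)
  tm <- runif(1000, 2000, 25000)
  bm <- runif(1, 150, 800)
  byHand <- evaluatePct(outer, predictTmax(law, tm), bm)
  expect_equal(evaluatePct(comp, tm, bm), byHand)

  # identity inner law: composed collapses to the outer power model
  ident <- PETseg:::thresholdFunction("linear", c(1, 0), "tmean")
  compId <- composeModels(outer, ident)
  tm2 <- runif(20, 1000, 20000)
  expect_equal(evaluatePct(compId, tm2, 464),
               136.09 * (tm2 / 464)^-0.22)
})

test_that("negative-exponent power laws decrease in the predictor ratio", {
  for (id in c(1, 2, 5, 6)) {
    m <- predefinedModel(id)
    x <- seq(2, 60, length.out = 50)
    y <- evaluatePct(m, x, 1)
    expect_true(all(diff(y) < 0))
  }
  # derived threshold always sits below Tmean whenever %Tmean < 100
  set.seed(5)
  tm <- runif(50, 3000, 25000)
  pct <- evaluatePct(predefinedModel(1), tm, 464)
  expect_true(all(pct < 100))
  expect_true(all(thresholdFromPct(pct, tm) < tm))
})

test_that("models round-trip through the plain-text config block", {
  path <- tempfile(fileext = ".model")
  for (id in c(1, 3, 8)) {
    m <- predefinedModel(id)
    writeThresholdFunction(m, path)
    back <- readThresholdFunction(path)
    expect_equal(modelFamily(back), modelFamily(m))
    expect_equal(modelCoefficients(back), modelCoefficients(m))
    expect_equal(modelPredictor(back), modelPredictor(m))
    expect_equal(rSquared(back), rSquared(m))
  }
  fitted <- fitFamily(1:10, exp(seq(0.1, 1, 0.1)), "exponential")
  writeThresholdFunction(fitted, path)
  expect_equal(modelCoefficients(readThresholdFunction(path)),
               modelCoefficients(fitted))
})
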