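# Calibration: accepted-threshold scans, regression fitting, family
# selection, composed R-squared, slice selection.

test_that("an exact-match area reference accepts only the matching level", {
  v <- matrix(0, 9, 9)
  v[3:6, 3:5] <- 100                       # 12-pixel block at 4 mm pixels
  img <- petSlice(v, dx = 4)
  lung <- lungField(img, matrix(TRUE, 9, 9))
  expect_error(calibrateToArea(img, c(1, 9, 1, 9), lung, 192),
               NA)
  s <- calibrateToArea(img, c(1, 9, 1, 9), lung, 12 * 16)
  df <- as.data.frame(s)
  # levels 0 and 100 both exist; only 100 extracts exactly 12 pixels
  expect_equal(df$ath_min, 100)
  expect_equal(df$ath_max, 100)
  expect_equal(df$threshold, 100)
  expect_equal(df$area_pet_mm2, 192)
  expect_equal(df$pct_tmean, 100 * df$threshold / df$t_mean)
})

test_that("area calibration equals the exhaustive sweep oracle", {
  img <- concentricImage()
  lung <- lungField(img, matrix(TRUE, 9, 9))
  roi <- c(1, 9, 1, 9)
  areaRef <- 25 * 16                       # core + ring
  s <- calibrateToArea(img, roi, lung, areaRef)
  orc <- sweepOracle(intensityValues(img), roi, 4, 4, maskArea, areaRef)
  df <- as.data.frame(s)
  expect_equal(df$ath_min, min(orc$ath))
  expect_equal(df$ath_max, max(orc$ath))
  expect_equal(df$threshold, orc$threshold)
})

test_that("an equidistant area reference keeps both bracketing levels", {
  v <- matrix(0, 5, 5)
  v[2, 2:4] <- c(30, 20, 10)               # nested areas 1, 2, 3 pixels
  img <- petSlice(v, dx = 4)
  lung <- lungField(img, matrix(c(rep(TRUE, 24), FALSE), 5, 5))
  s <- calibrateToArea(img, c(2, 2, 2, 4), lung, 2.5 * 16)
  df <- as.data.frame(s)
  expect_equal(df$ath_min, 10)             # 3-pixel region, error 8 mm2
  expect_equal(df$ath_max, 20)             # 2-pixel region, error 8 mm2
  expect_equal(df$threshold, 15)
})

test_that("axis calibration matches the sweep oracle and edge cases", {
  img <- concentricImage()
  lung <- lungField(img, matrix(TRUE, 9, 9))
  roi <- c(1, 9, 1, 9)
  # bar phantom: two horizontally adjacent hot pixels, centre span 4 mm
  v <- matrix(1, 7, 7)
  v[4, 3:4] <- c(500, 400)
  bar <- petSlice(v, dx = 4)
  lungBar <- lungField(bar, matrix(TRUE, 7, 7))
  s <- calibrateToAxis(bar, c(1, 7, 1, 7), lungBar, 4)
  df <- as.data.frame(s)
  # the only achievable level isolating exactly the bar is 400
  expect_equal(df$ath_min, 400)
  expect_equal(df$ath_max, 400)
  # a zero reference demands a single-pixel region
  s0 <- calibrateToAxis(bar, c(1, 7, 1, 7), lungBar, 0)
  expect_equal(as.data.frame(s0)$ath_min, 500)
  # concentric lesion against its ring-level axis, versus the oracle
  ref <- maskAxis(intensityValues(img) >= 60, 4, 4)
  sC <- calibrateToAxis(img, roi, lung, ref)
  orc <- sweepOracle(intensityValues(img), roi, 4, 4, maskAxis, ref)
  expect_equal(as.data.frame(sC)$threshold, orc$threshold)
  # axis samples record the mean area over accepted thresholds
  expect_equal(as.data.frame(s)$area_pet_mm2, 32)
})

test_that("accepted thresholds form a contiguous run on the intensity ladder", {
  ph <- generatePhantom(phantomSpec(semiAxisA = 12, seed = 9))
  sw <- thresholdSweep(ph$pet, ph$roi)
  expect_true(all(diff(sw$n_pixels) <= 0))     # nested regions
  err <- abs(sw$area_mm2 - ph$truthAreaMm2)
  acc <- which(err <= min(err) + 1e-9)
  expect_equal(acc, seq(min(acc), max(acc)))   # contiguous indices
})

test_that("noiseless generated curves are recovered exactly by their family", {
  x <- seq(2, 60, length.out = 10)
  pw <- fitFamily(x, 130.9 * x^-0.23, "power")
  expect_equal(modelCoefficients(pw), c(130.9, -0.23), tolerance = 1e-9)
  expect_equal(rSquared(pw), 1, tolerance = 1e-6)

  tm <- seq(3000, 20000, length.out = 8)
  ln <- fitFamily(tm, 1.64 * tm - 1634.8, "linear", predictor = "tmean")
  expect_equal(modelCoefficients(ln), c(1.64, -1634.8), tolerance = 1e-9)

  lg <- fitFamily(x, 30 * log(x) + 2, "logarithmic")
  expect_equal(modelCoefficients(lg), c(30, 2), tolerance = 1e-9)
  ex <- fitFamily(x / 60, 5 * exp(-2 * x / 60), "exponential")
  expect_equal(modelCoefficients(ex), c(5, -2), tolerance = 1e-9)
  p2 <- fitFamily(x, 0.05 * x^2 - 2 * x + 90, "polynomial2")
  expect_equal(modelCoefficients(p2), c(0.05, -2, 90), tolerance = 1e-8)
})

test_that("power-law exponents are recovered from noisy samples", {
  set.seed(7)
  errs <- replicate(100, {
    x <- runif(38, 3, 60)
    y <- 130.9 * x^-0.23 + rnorm(38, 0, 2)
    modelCoefficients(fitFamily(x, y, "power"))[2] - (-0.23)
  })
  expect_lt(abs(mean(errs)), 0.05)
  expect_lt(max(abs(errs)), 0.15)
})

test_that("family selection retains the generator's family", {
  set.seed(21)
  x <- runif(30, 3, 60)
  y <- 130.9 * x^-0.23 + rnorm(30, 0, 0.5)
  fit <- selectBestFamily(x, y)
  expect_equal(modelFamily(bestModel(fit)), "power")
  expect_equal(max(familyScores(fit), na.rm = TRUE),
               rSquared(bestModel(fit)))

  # exactly linear data: polynomial2 nests linear, R2 ties at 1;
  # the earlier family in the declared order wins deterministically
  yl <- 2 * x + 1
  fitL <- selectBestFamily(x, yl)
  expect_equal(modelFamily(bestModel(fitL)), "linear")
  expect_gte(familyScores(fitL)[["polynomial2"]],
             familyScores(fitL)[["linear"]] - 1e-12)
})

test_that("composed R-squared behaves at the degenerate extremes", {
  m <- predefinedModel(8)
  tm <- c(5000, 9000, 14000)
  bm <- c(300, 400, 500)
  obs <- mapply(function(t, b) evaluatePct(m, t, b), tm, bm)
  expect_equal(composedRSquared(m, tm, bm, obs), 1)
  # predicting the observed mean everywhere scores exactly zero
  flat <- PETseg:::thresholdFunction("linear", c(0, mean(obs)),
                                     "tmean_over_bmin")
  expect_equal(composedRSquared(flat, tm, bm, obs), 0)
  expect_error(composedRSquared(m, tm, bm, rep(50, 3)), "zero variance")
})

test_that("the published composed model scores high on the printed cohort", {
  tab <- referenceLesionTable("both")
  r2 <- composedRSquared(predefinedModel(8), tab$tmean, tab$bmin,
                         tab$pct_tmean)
  expect_gte(r2, 0.9)
  expect_lte(r2, 1.0)
})

test_that("slice selection picks the largest segmented lesion", {
  mkSlice <- function(d) generatePhantom(
    phantomSpec(semiAxisA = d / 2, noiseSd = 0, seed = 5))
  stack <- lapply(c(24, 34, 28), mkSlice)
  slices <- lapply(stack, `[[`, "pet")
  lungs <- lapply(stack, `[[`, "lung")
  roi <- stack[[2]]$roi
  model <- predefinedModel(1)
  expect_equal(selectSlice(slices, lungs, roi, model), 2L)
  expect_equal(selectSlice(slices[1], lungs[1], roi, model), 1L)
  expect_equal(selectSlice(slices[c(2, 2)], lungs[c(2, 2)], roi, model), 1L)
})
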