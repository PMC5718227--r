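# Calibration: accepted-threshold scans against a reference measurement,
# regression fitting across the spreadsheet families, model selection by R2.

#' Scan every achievable threshold in a ROI
#'
#' Uses every unique pixel intensity inside the ROI as a candidate initial
#' threshold (iTH) and records, for each non-empty extracted region, its
#' pixel count, area and major axis. Because regions are nested as the
#' threshold drops, this ladder visits every achievable region exactly once.
#'
#' @inheritParams thresholdRegion
#' @return data.frame with columns `ith`, `n_pixels`, `area_mm2`,
#'   `major_axis_mm`, ordered by increasing threshold.
#' @export
thresholdSweep <- function(image, roi) {
  roi <- checkRoi(image, roi)
  v <- intensityValues(image)
  sub <- v[roi[1]:roi[2], roi[3]:roi[4], drop = FALSE]
  ths <- sort(unique(as.vector(sub)))
  sp <- pixelSpacing(image)
  rows <- lapply(ths, function(th) {
    mask <- thresholdRegion(image, roi, th)
    n <- sum(mask)
    if (n == 0L) return(NULL)
    data.frame(ith = th, n_pixels = n,
               area_mm2 = n * sp[["dx"]] * sp[["dy"]],
               major_axis_mm = majorAxisLength(mask, sp[["dx"]], sp[["dy"]]))
  })
  do.call(rbind, rows)
}

# Shared accepted-threshold logic: pick all global minimizers of the
# reference discrepancy, take the midpoint of their extremes as the
# Threshold, and measure the target statistics on the region extracted
# there.
acceptThresholds <- function(image, roi, lung, sweep, err, kind, refValue) {
  if (is.null(sweep) || nrow(sweep) == 0L)
    stop("no feasible threshold: every candidate region is empty")
  minErr <- min(err)
  acc <- which(err <= minErr + 1e-9)
  ath <- sweep$ith[acc]
  threshold <- (min(ath) + max(ath)) / 2
  mask <- thresholdRegion(image, roi, threshold)
  st <- regionStats(image, mask)
  areaPet <- if (kind == "ct_area") areaMm2(st) else mean(sweep$area_mm2[acc])
  new("CalibrationSample", referenceKind = kind, referenceValue = refValue,
      athMin = min(ath), athMax = max(ath), threshold = threshold,
      tMean = tMean(st), tMax = tMax(st), bMin = bMin(lung),
      pctTmean = 100 * threshold / tMean(st), areaPet = areaPet)
}

#' Calibrate a threshold against a CT-measured lesion area
#'
#' Scans every unique ROI intensity as an initial threshold and accepts all
#' thresholds (aTH) whose extracted region area is closest (minimum absolute
#' difference) to the reference CT area. The retained Threshold is the
#' midpoint of the smallest and largest accepted thresholds; Tmean, Tmax and
#' %Tmean are measured on the region extracted at that Threshold.
#'
#' @param image a [PETSlice-class] (the PET slice).
#' @param roi lesion ROI `c(row1, row2, col1, col2)`, 1-based inclusive.
#' @param lung a [LungField-class] for the same slice.
#' @param areaCt reference lesion area on the CT image, mm^2 (> 0).
#' @return A [CalibrationSample-class].
#' @export
calibrateToArea <- function(image, roi, lung, areaCt) {
  stopifnot(areaCt > 0)
  sweep <- thresholdSweep(image, roi)
  acceptThresholds(image, roi, lung, sweep,
                   abs(sweep$area_mm2 - areaCt), "ct_area", areaCt)
}

#' Calibrate a threshold against a histological major axis
#'
#' As [calibrateToArea()], but thresholds are accepted when the extracted
#' region's major axis is closest to the reference histological major axis.
#' The recorded PET area is the mean area over the accepted thresholds.
#'
#' @inheritParams calibrateToArea
#' @param maxisHist reference major axis from histology, mm (>= 0).
#' @return A [CalibrationSample-class].
#' @export
calibrateToAxis <- function(image, roi, lung, maxisHist) {
  stopifnot(maxisHist >= 0)
  sweep <- thresholdSweep(image, roi)
  acceptThresholds(image, roi, lung, sweep,
                   abs(sweep$major_axis_mm - maxisHist), "hist_axis",
                   maxisHist)
}

.fitFamilies <- c("linear", "exponential", "logarithmic", "power",
                  "polynomial2")

checkFitDomain <- function(x, y, family) {
  if (family %in% c("logarithmic", "power") && any(x <= 0))
    stop("model domain: family '", family, "' requires x > 0")
  if (family %in% c("exponential", "power") && any(y <= 0))
    stop("model domain: family '", family, "' requires y > 0")
  invisible(TRUE)
}

#' Fit one regression family
#'
#' Least-squares fit of a single family to `(x, y)` samples. Power and
#' exponential families are fitted by ordinary least squares on the
#' log-transformed response (the spreadsheet trend-line convention);
#' the polynomial family is degree 2. The reported R-squared is always
#' computed on the original, untransformed y scale as 1 - SSres/SStot.
#'
#' @param x,y numeric sample vectors (>= 3 points).
#' @param family one of `"linear"`, `"exponential"`, `"logarithmic"`,
#'   `"power"`, `"polynomial2"`.
#' @param predictor recorded predictor tag for the returned model.
#' @return A [ThresholdFunction-class] with `rSquared` set.
#' @examples
#' x <- seq(2, 60, length.out = 10)
#' fitFamily(x, 130.9 * x^-0.23, "power")
#' @export
fitFamily <- function(x, y, family, predictor = "tmean_over_bmin") {
  family <- match.arg(family, .fitFamilies)
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3L) stop("need at least 3 samples")
  checkFitDomain(x, y, family)
  if (stats::var(x) < .Machine$double.eps)
    stop("degenerate fit: no variation in x")
  fit <- switch(family,
    linear = stats::lm(y ~ x),
    logarithmic = stats::lm(y ~ log(x)),
    polynomial2 = stats::lm(y ~ x + I(x^2)),
    power = stats::lm(log(y) ~ log(x)),
    exponential = stats::lm(log(y) ~ x))
  if (any(is.na(stats::coef(fit)))) stop("degenerate fit: singular design")
  cf <- unname(stats::coef(fit))
  coefs <- switch(family,
    linear = c(cf[2], cf[1]),
    logarithmic = c(cf[2], cf[1]),
    polynomial2 = c(cf[3], cf[2], cf[1]),
    power = c(exp(cf[1]), cf[2]),
    exponential = c(exp(cf[1]), cf[2]))
  model <- thresholdFunction(family, coefs, predictor)
  pred <- evalFamilyAtRatio(model, x)
  ssTot <- sum((y - mean(y))^2)
  r2 <- if (ssTot > 0) 1 - sum((y - pred)^2) / ssTot else NA_real_
  model@rSquared <- max(0, min(1, r2))
  model
}

# Evaluate a non-composed family directly at predictor ratio values.
evalFamilyAtRatio <- function(model, x) {
  co <- model@coefficients
  switch(model@family,
    linear = co[1] * x + co[2],
    logarithmic = co[1] * log(x) + co[2],
    polynomial2 = co[1] * x^2 + co[2] * x + co[3],
    power = co[1] * x^co[2],
    exponential = co[1] * exp(co[2] * x),
    stop("cannot evaluate family '", model@family, "' at a plain ratio"))
}

#' Fit all applicable families and retain the best by R-squared
#'
#' Fits every requested family whose domain admits the data and keeps the
#' one with the largest coefficient of determination (computed on the
#' original y scale). Exact ties are broken by the declared family order,
#' deterministically.
#'
#' @inheritParams fitFamily
#' @param families candidate families, in tie-break priority order.
#' @return A [RegressionFit-class] with the retained model, its residuals,
#'   and the family-to-R-squared table (NA for inapplicable families).
#' @export
selectBestFamily <- function(x, y, families = .fitFamilies,
                             predictor = "tmean_over_bmin") {
  families <- match.arg(families, .fitFamilies, several.ok = TRUE)
  fits <- lapply(families, function(f)
    tryCatch(fitFamily(x, y, f, predictor), error = function(e) NULL))
  scores <- vapply(fits, function(f)
    if (is.null(f)) NA_real_ else f@rSquared, 0)
  names(scores) <- families
  if (all(is.na(scores))) stop("degenerate fit: no family applicable")
  best <- which.max(round(scores, 12))  # first max wins exact ties
  model <- fits[[best]]
  new("RegressionFit", model = model,
      residuals = y - evalFamilyAtRatio(model, x), familyScores = scores)
}

#' R-squared of a composed model on observed operating points
#'
#' A composed model is built analytically, not fitted, so its coefficient
#' of determination must be measured against data: this computes
#' 1 - SSres/SStot of predicted versus observed %Tmean over samples of
#' (Tmean, Bmin, observed %Tmean).
#'
#' @param model a composed (or any %Tmean-valued) [ThresholdFunction-class].
#' @param tMean,bMinValues,observedPct parallel numeric vectors (>= 3).
#' @return R-squared (may be negative if the model underperforms the mean).
#' @export
composedRSquared <- function(model, tMean, bMinValues, observedPct) {
  n <- length(observedPct)
  if (n < 3L || length(tMean) != n || length(bMinValues) != n)
    stop("need >= 3 parallel samples")
  pred <- mapply(function(t, b) evaluatePct(model, t, b), tMean, bMinValues)
  ssTot <- sum((observedPct - mean(observedPct))^2)
  if (ssTot <= 0) stop("degenerate: zero variance in observed %Tmean")
  1 - sum((observedPct - pred)^2) / ssTot
}

#' Pick the slice with the largest segmented lesion area
#'
#' Segments each slice of a stack with the iterative algorithm and returns
#' the (1-based) index of the slice with the largest segmented area; ties go
#' to the lowest index. Degenerate or failing slices are skipped.
#'
#' @param slices list of [PETSlice-class] objects.
#' @param lungs list of [LungField-class] objects, one per slice.
#' @param roi lesion ROI applied to every slice.
#' @param model threshold-adjustment [ThresholdFunction-class].
#' @param maxIter iteration cap per slice.
#' @return Integer slice index.
#' @export
selectSlice <- function(slices, lungs, roi, model, maxIter = 100L) {
  stopifnot(length(slices) >= 1L, length(lungs) == length(slices))
  areas <- vapply(seq_along(slices), function(i) {
    res <- tryCatch(
      segmentIterative(slices[[i]], lungs[[i]], roi, model, maxIter),
      error = function(e) NULL)
    if (is.null(res) || isDegenerate(res)) NA_real_
    else areaMm2(segStats(res))
  }, 0)
  if (all(is.na(areas))) stop("no lesion found: all slices degenerate")
  which.max(areas)  # NAs never win; first max takes ties
}
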