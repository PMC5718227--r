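#' A 2D PET or CT slice with physical pixel spacing
#'
#' Container for a rectangular grid of non-negative intensities (PET counts,
#' or a CT-derived activity/attenuation map) together with the in-plane pixel
#' spacing in millimetres. All pixel-level measurements in the package
#' (region statistics, threshold sweeps, segmentation) operate on this class.
#'
#' @slot values numeric matrix of finite, non-negative intensities.
#' @slot dx,dy pixel width and height in mm (both > 0).
#'
#' @seealso [petSlice()], [regionStats()], [thresholdRegion()]
#' @export
setClass("PETSlice",
  slots = c(values = "matrix", dx = "numeric", dy = "numeric"))

setValidity("PETSlice", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be a numeric matrix")
  if (length(object@dx) != 1L || length(object@dy) != 1L ||
      !is.finite(object@dx) || !is.finite(object@dy) ||
      object@dx <= 0 || object@dy <= 0)
    return("dx and dy must be single positive numbers (mm)")
  if (any(!is.finite(v))) return("all intensities must be finite")
  if (any(v < 0)) return("all intensities must be >= 0")
  TRUE
})

#' Construct a PETSlice
#'
#' @param values numeric matrix of intensities (rows = image rows).
#' @param dx,dy pixel spacing in mm; `dy` defaults to `dx` (square pixels).
#' @return A [PETSlice-class] object.
#' @examples
#' img <- petSlice(matrix(0:24, 5, 5), dx = 4)
#' dim(intensityValues(img))
#' @export
petSlice <- function(values, dx = 4, dy = dx) {
  new("PETSlice", values = as.matrix(values), dx = as.numeric(dx),
      dy = as.numeric(dy))
}

#' Pixel-level summary statistics of a segmented region
#'
#' Holds the target statistics measured on a masked region of a slice:
#' mean and maximum intensity (Tmean, Tmax), physical area, major axis
#' (largest pixel-centre to pixel-centre distance), and the coefficient of
#' variation of uptake (population SD / mean), used as a heterogeneity proxy.
#'
#' @slot tMean,tMax mean and maximum intensity over the region.
#' @slot areaMm2 pixel count times pixel area, mm^2.
#' @slot majorAxisMm maximum pairwise pixel-centre distance, mm.
#' @slot cov population SD of intensities divided by the mean.
#' @slot nPixels number of member pixels.
#' @export
setClass("RegionStats",
  slots = c(tMean = "numeric", tMax = "numeric", areaMm2 = "numeric",
            majorAxisMm = "numeric", cov = "numeric", nPixels = "integer"))

setValidity("RegionStats", function(object) {
  if (object@nPixels < 1L) return("region must contain at least one pixel")
  if (object@tMax < object@tMean) return("tMax must be >= tMean")
  if (object@cov < 0) return("cov must be >= 0")
  TRUE
})

#' Lung field context for background measurement
#'
#' Pairs a lung mask (aligned to its PET slice) with the minimum intensity
#' measured inside it, the empirical background parameter driving every
#' threshold-adjustment function. The mask may include the (hot) lesion:
#' the lesion cannot contain the lung minimum.
#'
#' @slot mask logical matrix flagging lung pixels.
#' @slot bMin minimum intensity over the mask.
#' @seealso [lungField()]
#' @export
setClass("LungField", slots = c(mask = "matrix", bMin = "numeric"))

#' Construct a LungField
#'
#' @param image a [PETSlice-class].
#' @param mask logical (or 0/1) matrix with the same dimensions as `image`.
#' @return A [LungField-class] holding the mask and its measured minimum.
#' @export
lungField <- function(image, mask) {
  mask <- asMask(mask)
  checkGeometry(image, mask)
  new("LungField", mask = mask, bMin = minInMask(image, mask))
}

#' A threshold-adjustment function
#'
#' A fitted or published mapping from image parameters to the segmentation
#' threshold expressed as a percentage of the region mean uptake. Families
#' follow the spreadsheet regression conventions: `power` and `exponential`
#' are two-coefficient (scale, exponent/rate), `linear` and `logarithmic`
#' are (slope, intercept), `polynomial2` is (a2, a1, a0) in descending
#' degree, and `composed` chains a power law on Tmax/Bmin with a linear
#' Tmax-from-Tmean law: coefficients (outer scale, outer exponent, slope,
#' intercept).
#'
#' @slot family one of `"linear"`, `"exponential"`, `"logarithmic"`,
#'   `"power"`, `"polynomial2"`, `"composed"`.
#' @slot coefficients numeric vector, length fixed by the family.
#' @slot predictor `"tmean_over_bmin"`, `"tmax_over_bmin"` or `"tmean"`
#'   (the last for linear Tmax-versus-Tmean laws).
#' @slot rSquared coefficient of determination in `[0, 1]`, or `NA` if unset.
#' @seealso [predefinedModel()], [evaluatePct()], [fitFamily()]
#' @export
setClass("ThresholdFunction",
  slots = c(family = "character", coefficients = "numeric",
            predictor = "character", rSquared = "numeric"))

.tfFamilies <- c("linear", "exponential", "logarithmic", "power",
                 "polynomial2", "composed")
.tfPredictors <- c("tmean_over_bmin", "tmax_over_bmin", "tmean")
.tfCoefCount <- c(linear = 2L, exponential = 2L, logarithmic = 2L,
                  power = 2L, polynomial2 = 3L, composed = 4L)

setValidity("ThresholdFunction", function(object) {
  if (length(object@family) != 1L || !object@family %in% .tfFamilies)
    return(paste("family must be one of:", paste(.tfFamilies, collapse = ", ")))
  if (length(object@predictor) != 1L || !object@predictor %in% .tfPredictors)
    return(paste("predictor must be one of:", paste(.tfPredictors, collapse = ", ")))
  want <- .tfCoefCount[[object@family]]
  if (length(object@coefficients) != want)
    return(sprintf("family '%s' needs %d coefficients, got %d",
                   object@family, want, length(object@coefficients)))
  if (any(!is.finite(object@coefficients)))
    return("coefficients must be finite")
  r2 <- object@rSquared
  if (length(r2) != 1L) return("rSquared must be a single value (may be NA)")
  if (!is.na(r2) && (r2 < 0 || r2 > 1)) return("rSquared must lie in [0, 1]")
  TRUE
})

thresholdFunction <- function(family, coefficients, predictor,
                              rSquared = NA_real_) {
  new("ThresholdFunction", family = family,
      coefficients = as.numeric(coefficients), predictor = predictor,
      rSquared = as.numeric(rSquared))
}

#' One calibration sample derived from a reference measurement
#'
#' Records, for one reference lesion, the accepted-threshold scan result:
#' the extremes of the accepted threshold set (aTH), their midpoint (the
#' retained Threshold), the target statistics measured on the region
#' extracted at that threshold, the lung background minimum, and the
#' threshold expressed as a percentage of the region mean.
#'
#' @slot referenceKind `"ct_area"` (reference is a CT-delineated area, mm^2)
#'   or `"hist_axis"` (reference is a histological major axis, mm).
#' @slot referenceValue the reference measurement.
#' @slot athMin,athMax extremes of the accepted threshold set.
#' @slot threshold midpoint of `athMin` and `athMax`.
#' @slot tMean,tMax mean/max intensity of the region at `threshold`.
#' @slot bMin lung background minimum.
#' @slot pctTmean `100 * threshold / tMean`.
#' @slot areaPet region area at `threshold` (ct_area kind) or the mean area
#'   over accepted thresholds (hist_axis kind), mm^2.
#' @seealso [calibrateToArea()], [calibrateToAxis()]
#' @export
setClass("CalibrationSample",
  slots = c(referenceKind = "character", referenceValue = "numeric",
            athMin = "numeric", athMax = "numeric", threshold = "numeric",
            tMean = "numeric", tMax = "numeric", bMin = "numeric",
            pctTmean = "numeric", areaPet = "numeric"))

setValidity("CalibrationSample", function(object) {
  if (!object@referenceKind %in% c("ct_area", "hist_axis"))
    return("referenceKind must be 'ct_area' or 'hist_axis'")
  if (object@athMin > object@threshold || object@threshold > object@athMax)
    return("must have athMin <= threshold <= athMax")
  if (object@tMax < object@tMean) return("tMax must be >= tMean")
  if (abs(object@pctTmean - 100 * object@threshold / object@tMean) > 1e-6)
    return("pctTmean must equal 100 * threshold / tMean")
  TRUE
})

#' Result of the iterative fixed-point segmentation
#'
#' @slot mask logical matrix: the final delineated region.
#' @slot stats a [RegionStats-class] computed on `mask`.
#' @slot trace data.frame with one row per iteration: `iter`, `pct_tmean`,
#'   `threshold`, `t_mean` (mean of the region just extracted), `n_pixels`.
#' @slot converged `TRUE` if the pixel set reached a fixed point (the last
#'   two trace rows then agree in `n_pixels` and `t_mean`); `FALSE` on a
#'   cycle or when the iteration cap was hit.
#' @slot degenerate `TRUE` if a computed threshold exceeded the region
#'   maximum, in which case the region collapses to the single hottest pixel.
#' @seealso [segmentIterative()]
#' @export
setClass("SegmentationResult",
  slots = c(mask = "matrix", stats = "RegionStats", trace = "data.frame",
            converged = "logical", degenerate = "logical"))

#' Specification of one synthetic PET/CT phantom
#'
#' Describes an elliptical lesion embedded in a low-uptake lung field inside
#' a warmer body, imaged at CT resolution (crisp truth) and at PET resolution
#' after Gaussian point-spread blurring, detector binning and additive noise.
#'
#' @slot semiAxisA,semiAxisB lesion ellipse semi-axes, mm.
#' @slot rotationDeg lesion rotation, degrees.
#' @slot centerMm lesion centre (x, y) in mm from the grid corner.
#' @slot lesionActivity,lungActivity,bodyActivity activity levels; lesion >
#'   lung background > 0; body is the tissue outside the lung field.
#' @slot noiseSd SD of additive Gaussian noise on the PET grid (clipped at 0).
#' @slot psfFwhmMm full width at half maximum of the Gaussian PSF, mm.
#' @slot petSpacingMm,ctSpacingMm pixel spacings, mm (PET must be an integer
#'   multiple of CT so detector binning is an exact block average).
#' @slot extentMm side length of the square field of view, mm.
#' @slot seed integer seed for the noise stream.
#' @seealso [phantomSpec()], [generatePhantom()]
#' @export
setClass("PhantomSpec",
  slots = c(semiAxisA = "numeric", semiAxisB = "numeric",
            rotationDeg = "numeric", centerMm = "numeric",
            lesionActivity = "numeric", lungActivity = "numeric",
            bodyActivity = "numeric", noiseSd = "numeric",
            psfFwhmMm = "numeric", petSpacingMm = "numeric",
            ctSpacingMm = "numeric", extentMm = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (object@semiAxisA <= 0 || object@semiAxisB <= 0)
    return("lesion semi-axes must be > 0")
  if (!(object@lesionActivity > object@lungActivity &&
        object@lungActivity > 0))
    return("need lesionActivity > lungActivity > 0")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  if (object@psfFwhmMm < 0) return("psfFwhmMm must be >= 0")
  if (object@petSpacingMm <= 0 || object@ctSpacingMm <= 0)
    return("spacings must be > 0")
  f <- object@petSpacingMm / object@ctSpacingMm
  if (abs(f - round(f)) > 1e-9)
    return("petSpacingMm must be an integer multiple of ctSpacingMm")
  if (length(object@centerMm) != 2L) return("centerMm must be length 2")
  if (object@extentMm <= 0) return("extentMm must be > 0")
  TRUE
})

#' Outcome of fitting and selecting regression families
#'
#' @slot model the retained [ThresholdFunction-class] (maximal R-squared).
#' @slot residuals observed minus predicted response for the retained model.
#' @slot familyScores named numeric vector of R-squared per fitted family
#'   (NA where a family was inapplicable to the data domain).
#' @seealso [selectBestFamily()]
#' @export
setClass("RegressionFit",
  slots = c(model = "ThresholdFunction", residuals = "numeric",
            familyScores = "numeric"))

setValidity("RegressionFit", function(object) {
  sc <- object@familyScores
  if (all(is.na(sc))) return("at least one family must have been fitted")
  if (!is.na(object@model@rSquared) &&
      object@model@rSquared < max(sc, na.rm = TRUE) - 1e-9)
    return("retained model must carry the maximal R-squared")
  TRUE
})
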