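# Accessor generics and show methods. Slots are never read directly by user
# code; these accessors are the supported surface.

#' @rdname PETSlice-class
#' @param object,x a PETSlice
#' @export
setGeneric("intensityValues", function(x) standardGeneric("intensityValues"))
#' @rdname PETSlice-class
#' @export
setMethod("intensityValues", "PETSlice", function(x) x@values)

#' @rdname PETSlice-class
#' @export
setGeneric("pixelSpacing", function(x) standardGeneric("pixelSpacing"))
#' @rdname PETSlice-class
#' @export
setMethod("pixelSpacing", "PETSlice", function(x) c(dx = x@dx, dy = x@dy))

#' @rdname PETSlice-class
#' @export
setMethod("dim", "PETSlice", function(x) dim(x@values))

setMethod("show", "PETSlice", function(object) {
  v <- object@values
  cat(sprintf("PETSlice: %d x %d pixels, %.3g x %.3g mm, intensity [%g, %g]\n",
              nrow(v), ncol(v), object@dx, object@dy, min(v), max(v)))
})

#' @rdname RegionStats-class
#' @param x,object a RegionStats
#' @export
setGeneric("tMean", function(x) standardGeneric("tMean"))
#' @rdname RegionStats-class
#' @export
setMethod("tMean", "RegionStats", function(x) x@tMean)

#' @rdname RegionStats-class
#' @export
setGeneric("tMax", function(x) standardGeneric("tMax"))
#' @rdname RegionStats-class
#' @export
setMethod("tMax", "RegionStats", function(x) x@tMax)

#' @rdname RegionStats-class
#' @export
setGeneric("areaMm2", function(x) standardGeneric("areaMm2"))
#' @rdname RegionStats-class
#' @export
setMethod("areaMm2", "RegionStats", function(x) x@areaMm2)

#' @rdname RegionStats-class
#' @export
setGeneric("majorAxisMm", function(x) standardGeneric("majorAxisMm"))
#' @rdname RegionStats-class
#' @export
setMethod("majorAxisMm", "RegionStats", function(x) x@majorAxisMm)

#' @rdname RegionStats-class
#' @export
setGeneric("covUptake", function(x) standardGeneric("covUptake"))
#' @rdname RegionStats-class
#' @export
setMethod("covUptake", "RegionStats", function(x) x@cov)

#' @rdname RegionStats-class
#' @export
setGeneric("nPixels", function(x) standardGeneric("nPixels"))
#' @rdname RegionStats-class
#' @export
setMethod("nPixels", "RegionStats", function(x) x@nPixels)

setMethod("show", "RegionStats", function(object) {
  cat(sprintf(paste0("RegionStats: n=%d, Tmean=%.1f, Tmax=%g, ",
                     "area=%.1f mm2, major axis=%.1f mm, COV=%.3f\n"),
              object@nPixels, object@tMean, object@tMax, object@areaMm2,
              object@majorAxisMm, object@cov))
})

#' @rdname LungField-class
#' @param x,object a LungField
#' @export
setGeneric("bMin", function(x) standardGeneric("bMin"))
#' @rdname LungField-class
#' @export
setMethod("bMin", "LungField", function(x) x@bMin)

#' @rdname LungField-class
#' @export
setGeneric("lungMask", function(x) standardGeneric("lungMask"))
#' @rdname LungField-class
#' @export
setMethod("lungMask", "LungField", function(x) x@mask)

setMethod("show", "LungField", function(object) {
  cat(sprintf("LungField: %d lung pixels, Bmin=%g\n",
              sum(object@mask), object@bMin))
})

#' @rdname ThresholdFunction-class
#' @param x,object a ThresholdFunction
#' @export
setGeneric("modelFamily", function(x) standardGeneric("modelFamily"))
#' @rdname ThresholdFunction-class
#' @export
setMethod("modelFamily", "ThresholdFunction", function(x) x@family)

#' @rdname ThresholdFunction-class
#' @export
setGeneric("modelCoefficients", function(x) standardGeneric("modelCoefficients"))
#' @rdname ThresholdFunction-class
#' @export
setMethod("modelCoefficients", "ThresholdFunction", function(x) x@coefficients)

#' @rdname ThresholdFunction-class
#' @export
setGeneric("modelPredictor", function(x) standardGeneric("modelPredictor"))
#' @rdname ThresholdFunction-class
#' @export
setMethod("modelPredictor", "ThresholdFunction", function(x) x@predictor)

#' @rdname ThresholdFunction-class
#' @export
setGeneric("rSquared", function(x) standardGeneric("rSquared"))
#' @rdname ThresholdFunction-class
#' @export
setMethod("rSquared", "ThresholdFunction", function(x) x@rSquared)

setMethod("show", "ThresholdFunction", function(object) {
  cat(sprintf("ThresholdFunction: %s on %s\n  coefficients: %s\n  R2: %s\n",
              object@family, object@predictor,
              paste(signif(object@coefficients, 6), collapse = ", "),
              ifelse(is.na(object@rSquared), "unset",
                     format(object@rSquared))))
})

#' @rdname SegmentationResult-class
#' @param x,object a SegmentationResult
#' @export
setGeneric("segMask", function(x) standardGeneric("segMask"))
#' @rdname SegmentationResult-class
#' @export
setMethod("segMask", "SegmentationResult", function(x) x@mask)

#' @rdname SegmentationResult-class
#' @export
setGeneric("segStats", function(x) standardGeneric("segStats"))
#' @rdname SegmentationResult-class
#' @export
setMethod("segStats", "SegmentationResult", function(x) x@stats)

#' @rdname SegmentationResult-class
#' @export
setGeneric("segTrace", function(x) standardGeneric("segTrace"))
#' @rdname SegmentationResult-class
#' @export
setMethod("segTrace", "SegmentationResult", function(x) x@trace)

#' @rdname SegmentationResult-class
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))
#' @rdname SegmentationResult-class
#' @export
setMethod("isConverged", "SegmentationResult", function(x) x@converged)

#' @rdname SegmentationResult-class
#' @export
setGeneric("isDegenerate", function(x) standardGeneric("isDegenerate"))
#' @rdname SegmentationResult-class
#' @export
setMethod("isDegenerate", "SegmentationResult", function(x) x@degenerate)

setMethod("show", "SegmentationResult", function(object) {
  cat(sprintf("SegmentationResult: %d iterations, %s%s\n",
              nrow(object@trace),
              if (object@converged) "converged" else "not converged",
              if (object@degenerate) " (degenerate)" else ""))
  show(object@stats)
})

#' @rdname CalibrationSample-class
#' @param x a CalibrationSample
#' @param row.names,optional,... passed through (unused)
#' @export
as.data.frame.CalibrationSample <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  data.frame(reference_kind = x@referenceKind,
             reference_value = x@referenceValue,
             ath_min = x@athMin, ath_max = x@athMax,
             threshold = x@threshold, t_mean = x@tMean, t_max = x@tMax,
             b_min = x@bMin, pct_tmean = x@pctTmean,
             area_pet_mm2 = x@areaPet, stringsAsFactors = FALSE)
}

setMethod("show", "CalibrationSample", function(object) {
  cat(sprintf(paste0("CalibrationSample (%s = %g): aTH [%g, %g], ",
                     "Threshold=%g, Tmean=%.1f, %%Tmean=%.2f, Bmin=%g\n"),
              object@referenceKind, object@referenceValue, object@athMin,
              object@athMax, object@threshold, object@tMean,
              object@pctTmean, object@bMin))
})

setMethod("show", "RegressionFit", function(object) {
  cat("RegressionFit; R2 per family:\n")
  print(round(object@familyScores, 4))
  show(object@model)
})

#' @rdname RegressionFit-class
#' @param x,object a RegressionFit
#' @export
setGeneric("bestModel", function(x) standardGeneric("bestModel"))
#' @rdname RegressionFit-class
#' @export
setMethod("bestModel", "RegressionFit", function(x) x@model)

#' @rdname RegressionFit-class
#' @export
setGeneric("familyScores", function(x) standardGeneric("familyScores"))
#' @rdname RegressionFit-class
#' @export
setMethod("familyScores", "RegressionFit", function(x) x@familyScores)
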