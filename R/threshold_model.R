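# Threshold-adjustment functions: evaluation, the published models,
# composition and plain-text serialization.

roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

# The eight published threshold-adjustment functions. Coefficients are
# stored exactly as printed; R2 values are the printed coefficients of
# determination. Models 1-4 were adjusted on the CT-referenced cohort,
# models 5-8 on the histology-referenced cohort. Models 4 and 8 are the
# compositions of (2, 3) and (6, 7) respectively.
.predefined <- list(
  list(family = "power", coefficients = c(130.9, -0.23),
       predictor = "tmean_over_bmin", rSquared = 0.81),
  list(family = "power", coefficients = c(136.09, -0.22),
       predictor = "tmax_over_bmin", rSquared = 0.87),
  list(family = "linear", coefficients = c(1.64, -1634.8),
       predictor = "tmean", rSquared = 0.96),
  list(family = "composed", coefficients = c(136.09, -0.22, 1.64, -1634.8),
       predictor = "tmean_over_bmin", rSquared = 0.82),
  list(family = "power", coefficients = c(152.93, -0.27),
       predictor = "tmean_over_bmin", rSquared = 0.65),
  list(family = "power", coefficients = c(151.62, -0.24),
       predictor = "tmax_over_bmin", rSquared = 0.74),
  list(family = "linear", coefficients = c(1.73, -1903.8),
       predictor = "tmean", rSquared = 0.96),
  list(family = "composed", coefficients = c(151.62, -0.24, 1.73, -1903.8),
       predictor = "tmean_over_bmin", rSquared = 0.99))

#' The eight published threshold-adjustment functions
#'
#' Returns one of the published models with its printed coefficients and
#' coefficient of determination. Models #1-#3 were adjusted with CT-measured
#' lesion areas as the reference (power laws of Tmean/Bmin and Tmax/Bmin,
#' plus a linear Tmax-versus-Tmean law), #4 is the composition of #2 and #3;
#' #5-#8 are their histology-referenced counterparts. Model #4 is the
#' validated adjustment function used for segmentation.
#'
#' @param id integer 1 to 8.
#' @return A [ThresholdFunction-class].
#' @examples
#' predefinedModel(4)
#' @export
predefinedModel <- function(id) {
  if (length(id) != 1L || is.na(id) || !id %in% 1:8)
    stop("unknown model id; must be 1..8")
  p <- .predefined[[as.integer(id)]]
  thresholdFunction(p$family, p$coefficients, p$predictor, p$rSquared)
}

#' Evaluate a threshold-adjustment function
#'
#' Returns the threshold as a percentage of the region mean uptake
#' (%Tmean). The predictor ratio is `t / bMin` where `t` is the intensity
#' feeding the model (Tmean for `tmean_over_bmin` models, Tmax for
#' `tmax_over_bmin` ones); composed models evaluate the inner linear
#' Tmax-from-Tmean law first. The output is not clamped: values at or above
#' 100 signal a degenerate operating point handled by [segmentIterative()].
#'
#' @param model a [ThresholdFunction-class].
#' @param t intensity driving the predictor (vectorized).
#' @param bMin lung background minimum; must be > 0.
#' @return %Tmean value(s), typically 40--100.
#' @examples
#' evaluatePct(predefinedModel(4), 22146, 464)
#' @export
evaluatePct <- function(model, t, bMin) {
  stopifnot(is(model, "ThresholdFunction"))
  if (length(bMin) != 1L || !is.finite(bMin) || bMin <= 0)
    stop("model domain: bMin must be a single positive intensity")
  if (model@predictor == "tmean")
    stop("model predicts Tmax, not %Tmean; use predictTmax()")
  co <- model@coefficients
  if (model@family == "composed") {
    base <- (co[3] * t + co[4]) / bMin
    if (any(base <= 0))
      stop("model domain: composed base (slope*t + intercept)/bMin must be > 0")
    return(co[1] * base^co[2])
  }
  x <- t / bMin
  switch(model@family,
    power = {
      if (any(x <= 0)) stop("model domain: predictor ratio must be > 0")
      co[1] * x^co[2]
    },
    exponential = co[1] * exp(co[2] * x),
    linear = co[1] * x + co[2],
    logarithmic = {
      if (any(x <= 0)) stop("model domain: predictor ratio must be > 0")
      co[1] * log(x) + co[2]
    },
    polynomial2 = co[1] * x^2 + co[2] * x + co[3])
}

#' Predict Tmax from Tmean with a linear law
#'
#' @param model a linear [ThresholdFunction-class] with predictor `"tmean"`.
#' @param tMean mean intensity (vectorized).
#' @return Predicted maximum intensity.
#' @export
predictTmax <- function(model, tMean) {
  stopifnot(is(model, "ThresholdFunction"))
  if (model@family != "linear" || model@predictor != "tmean")
    stop("predictTmax needs a linear model with predictor 'tmean'")
  co <- model@coefficients
  co[1] * tMean + co[2]
}

#' Convert %Tmean to an absolute threshold
#'
#' Inverts the definition %Tmean = 100 * Threshold / Tmean and rounds to
#' the nearest integer gray level (PET intensities are integer counts;
#' ties round half away from zero). With the worked-example pair
#' (52.88, 22146) this gives 11711.
#'
#' @param pct threshold as a percentage of `tMean`; must be > 0.
#' @param tMean region mean intensity; must be > 0.
#' @return Integer-valued threshold (gray level).
#' @examples
#' thresholdFromPct(52.88, 22146)
#' @export
thresholdFromPct <- function(pct, tMean) {
  if (any(pct <= 0) || any(tMean <= 0))
    stop("pct and tMean must be > 0")
  roundHalfAway(pct / 100 * tMean)
}

#' Compose a Tmax/Bmin power law with a Tmax-from-Tmean linear law
#'
#' Substitutes the linear prediction of Tmax into the power law so the
#' result is driven by Tmean alone: the published models #4 and #8 are the
#' compositions of (#2, #3) and (#6, #7).
#'
#' @param outer power [ThresholdFunction-class] with predictor
#'   `"tmax_over_bmin"`.
#' @param tmaxLaw linear [ThresholdFunction-class] with predictor `"tmean"`.
#' @return A composed [ThresholdFunction-class] (rSquared unset: the
#'   composition's fit quality must be measured on data, see
#'   [composedRSquared()]).
#' @examples
#' composeModels(predefinedModel(2), predefinedModel(3))
#' @export
composeModels <- function(outer, tmaxLaw) {
  stopifnot(is(outer, "ThresholdFunction"), is(tmaxLaw, "ThresholdFunction"))
  if (outer@family != "power" || outer@predictor != "tmax_over_bmin")
    stop("outer must be a power model on tmax_over_bmin")
  if (tmaxLaw@family != "linear" || tmaxLaw@predictor != "tmean")
    stop("tmaxLaw must be a linear model with predictor 'tmean'")
  thresholdFunction("composed",
                    c(outer@coefficients, tmaxLaw@coefficients),
                    "tmean_over_bmin")
}

#' Write / read a threshold-adjustment function as plain text
#'
#' The on-disk form is a small key: value block (family, predictor,
#' coefficients, r_squared), round-trip safe at full double precision.
#'
#' @param model a [ThresholdFunction-class].
#' @param path file path.
#' @return `writeThresholdFunction` returns `path` invisibly;
#'   `readThresholdFunction` returns the model.
#' @export
writeThresholdFunction <- function(model, path) {
  stopifnot(is(model, "ThresholdFunction"))
  lines <- c(
    paste("family:", model@family),
    paste("predictor:", model@predictor),
    paste("coefficients:",
          paste(formatC(model@coefficients, format = "g", digits = 17),
                collapse = " ")),
    paste("r_squared:", ifelse(is.na(model@rSquared), "NA",
                               formatC(model@rSquared, format = "g",
                                       digits = 17))))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeThresholdFunction
#' @export
readThresholdFunction <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexec("^([a-z_]+):\\s*(.*)$", lines))
  keys <- vapply(kv, `[`, "", 2)
  vals <- vapply(kv, `[`, "", 3)
  need <- c("family", "predictor", "coefficients", "r_squared")
  if (!all(need %in% keys))
    stop("model file must declare family, predictor, coefficients, r_squared")
  get1 <- function(k) vals[match(k, keys)]
  thresholdFunction(get1("family"),
                    as.numeric(strsplit(trimws(get1("coefficients")),
                                        "\\s+")[[1]]),
                    get1("predictor"),
                    suppressWarnings(as.numeric(get1("r_squared"))))
}
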