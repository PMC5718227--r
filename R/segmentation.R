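# Iterative fixed-point segmentation: threshold -> region -> Tmean ->
# threshold, starting from Tmean = Tmax, until the pixel set stabilizes.

maskKey <- function(mask) paste(which(mask), collapse = ",")

singleMaxMask <- function(image, roi) {
  roi <- checkRoi(image, roi)
  v <- intensityValues(image)
  sub <- v[roi[1]:roi[2], roi[3]:roi[4], drop = FALSE]
  anchor <- rowMajorArgMax(sub)
  out <- matrix(FALSE, nrow(v), ncol(v))
  out[roi[1] + anchor[1] - 1L, roi[3] + anchor[2] - 1L] <- TRUE
  out
}

#' Iterative adaptive-threshold segmentation of a lesion
#'
#' Implements the fixed-point loop of the adaptive-thresholding strategy.
#' The lung background minimum Bmin is measured once and held fixed. The
#' region mean Tmean is initialized to the ROI maximum Tmax; each iteration
#' evaluates the threshold-adjustment function at (Tmean, Bmin) to get
#' %Tmean, converts it to an absolute threshold, extracts the 8-connected
#' region anchored at the ROI maximum, and re-measures Tmean on that region.
#' Iterations stop when the pixel set repeats immediately (a fixed point:
#' converged) or revisits an earlier state (a cycle: reported unconverged
#' with the last state), or at `maxIter`. If a computed threshold exceeds
#' the achievable maximum the region collapses to the single hottest pixel
#' and the result is flagged degenerate -- the small-lesion failure mode is
#' reported, not hidden.
#'
#' @param image a [PETSlice-class].
#' @param lung a [LungField-class] (provides Bmin; must be > 0).
#' @param roi lesion ROI `c(row1, row2, col1, col2)`, 1-based inclusive.
#' @param model a [ThresholdFunction-class] driven by Tmean (predictor
#'   `"tmean_over_bmin"` or a composed model).
#' @param maxIter iteration cap (the worked clinical example converges in 3).
#' @param tMeanInit optional starting Tmean; defaults to the ROI maximum.
#' @return A [SegmentationResult-class].
#' @examples
#' ph <- generatePhantom(phantomSpec(semiAxisA = 15, seed = 1))
#' res <- segmentIterative(ph$pet, ph$lung, ph$roi, predefinedModel(4))
#' segTrace(res)
#' @export
segmentIterative <- function(image, lung, roi, model, maxIter = 100L,
                             tMeanInit = NULL) {
  stopifnot(is(image, "PETSlice"), is(lung, "LungField"),
            is(model, "ThresholdFunction"))
  roi <- checkRoi(image, roi)
  if (model@predictor == "tmean")
    stop("model predicts Tmax; segmentation needs a %Tmean model")
  b <- bMin(lung)
  if (!is.finite(b) || b <= 0)
    stop("model domain: Bmin must be > 0")
  v <- intensityValues(image)
  sub <- v[roi[1]:roi[2], roi[3]:roi[4], drop = FALSE]
  tMeanCur <- if (is.null(tMeanInit)) max(sub) else tMeanInit
  trace <- vector("list", maxIter)
  keys <- character(0)
  mask <- NULL
  converged <- FALSE
  degenerate <- FALSE
  for (it in seq_len(maxIter)) {
    pct <- evaluatePct(model, tMeanCur, b)
    thr <- thresholdFromPct(pct, tMeanCur)
    mask <- thresholdRegion(image, roi, thr)
    if (!any(mask)) {
      mask <- singleMaxMask(image, roi)
      degenerate <- TRUE
      newTmean <- v[mask][1]
      trace[[it]] <- data.frame(iter = it, pct_tmean = pct, threshold = thr,
                                t_mean = newTmean, n_pixels = 1L)
      break
    }
    newTmean <- mean(v[mask])
    trace[[it]] <- data.frame(iter = it, pct_tmean = pct, threshold = thr,
                              t_mean = newTmean, n_pixels = sum(mask))
    key <- maskKey(mask)
    pos <- match(key, keys)
    if (!is.na(pos)) {
      converged <- pos == length(keys)  # immediate repeat = fixed point
      break
    }
    keys <- c(keys, key)
    tMeanCur <- newTmean
  }
  new("SegmentationResult", mask = mask, stats = regionStats(image, mask),
      trace = do.call(rbind, trace[!vapply(trace, is.null, TRUE)]),
      converged = converged, degenerate = degenerate)
}

#' Build the validation table comparing segmentations to references
#'
#' Given per-lesion measurements (PET against CT and/or histology
#' references), computes the signed relative differences and splits the
#' lesions into the two reported size groups: histological major axis at or
#' below 20 mm, and 20--45 mm. Records with no usable reference are dropped
#' with a warning.
#'
#' @param records data.frame with columns `lesion_id`, `maaxis_hist_mm`,
#'   `maaxis_pet_mm`, `maaxis_ct_mm`, `area_pet_mm2`, `area_ct_mm2`, `cov`
#'   (missing references may be NA).
#' @return list with `table` (per-lesion rows plus dVs columns and a
#'   `group` factor) and `summary` (per group and metric: mean, population
#'   SD, min, max, n).
#' @export
runValidation <- function(records) {
  cols <- c("maaxis_hist_mm", "maaxis_pet_mm", "maaxis_ct_mm",
            "area_pet_mm2", "area_ct_mm2", "cov")
  if (nrow(records) == 0L)
    return(list(table = records, summary = data.frame()))
  for (cl in setdiff(cols, names(records))) records[[cl]] <- NA_real_
  hasRef <- !is.na(records$maaxis_hist_mm) | !is.na(records$maaxis_ct_mm)
  if (any(!hasRef)) {
    warning(sum(!hasRef), " record(s) without any reference skipped")
    records <- records[hasRef, , drop = FALSE]
  }
  safeDelta <- function(a, b) ifelse(is.na(a) | is.na(b), NA_real_,
                                     100 * (a - b) / b)
  tab <- records
  tab$dvs_maaxis_pet_hist <- safeDelta(tab$maaxis_pet_mm, tab$maaxis_hist_mm)
  tab$dvs_maaxis_ct_hist <- safeDelta(tab$maaxis_ct_mm, tab$maaxis_hist_mm)
  tab$dvs_maaxis_pet_ct <- safeDelta(tab$maaxis_pet_mm, tab$maaxis_ct_mm)
  tab$dvs_area_pet_ct <- safeDelta(tab$area_pet_mm2, tab$area_ct_mm2)
  tab$group <- factor(ifelse(tab$maaxis_hist_mm <= 20, "le20mm", "20to45mm"),
                      levels = c("le20mm", "20to45mm"))
  metrics <- c("dvs_maaxis_pet_hist", "dvs_maaxis_ct_hist",
               "dvs_maaxis_pet_ct", "dvs_area_pet_ct", "cov",
               "maaxis_hist_mm")
  summ <- do.call(rbind, lapply(levels(tab$group), function(g) {
    sel <- tab[tab$group %in% g, , drop = FALSE]
    do.call(rbind, lapply(metrics, function(m) {
      x <- sel[[m]][!is.na(sel[[m]])]
      if (length(x) == 0L) return(NULL)
      s <- summarizeStat(x)
      data.frame(group = g, metric = m, mean = s$mean, sd = s$sd,
                 min = s$min, max = s$max, n = s$n)
    }))
  }))
  list(table = tab, summary = summ)
}
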