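# Comparison statistics: signed relative differences, column summaries,
# and the difference surface between two threshold-adjustment functions.

#' Signed relative difference in percent
#'
#' The validation statistic dVs: `100 * (a - b) / b`, the difference of a
#' measurement from its reference, in percent of the reference. Vectorized.
#'
#' @param a measured value(s).
#' @param b reference value(s); must be > 0.
#' @return Percent difference(s).
#' @examples
#' deltaVs(14.4, 12)   # +20
#' @export
deltaVs <- function(a, b) {
  if (any(!is.finite(b)) || any(b <= 0))
    stop("reference: b must be positive and finite")
  100 * (a - b) / b
}

#' Summary of a measurement column
#'
#' Arithmetic mean, population standard deviation (divisor n -- the
#' convention that reproduces the published group SDs), and extremes.
#' A single observation yields sd = 0 with `degenerateSd = TRUE`.
#'
#' @param x numeric vector (>= 1 value).
#' @return list with `mean`, `sd`, `min`, `max`, `n`, `degenerateSd`.
#' @export
summarizeStat <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0L) stop("empty table")
  m <- mean(x)
  list(mean = m,
       sd = if (n > 1L) sqrt(mean((x - m)^2)) else 0,
       min = min(x), max = max(x), n = n, degenerateSd = n == 1L)
}

#' Pointwise difference between two threshold-adjustment functions
#'
#' Evaluates %Tmean under both models at each (Tmean, Bmin) operating
#' point and reports the signed differences (`m2 - m1`) and the maximum
#' absolute difference. Points outside either model's domain are flagged,
#' excluded from the maximum, and reported with a warning.
#'
#' @param m1,m2 [ThresholdFunction-class] objects evaluable as %Tmean.
#' @param tMean,bMinValues parallel vectors of operating points.
#' @return list with `points` (data.frame: t_mean, b_min, pct1, pct2,
#'   diff, ok) and `maxAbsDiff`.
#' @examples
#' functionDifference(predefinedModel(4), predefinedModel(8),
#'                    1949.3, 195)$maxAbsDiff
#' @export
functionDifference <- function(m1, m2, tMean, bMinValues) {
  stopifnot(length(tMean) == length(bMinValues))
  evalOne <- function(model, t, b)
    tryCatch(evaluatePct(model, t, b), error = function(e) NA_real_)
  p1 <- mapply(evalOne, t = tMean, b = bMinValues,
               MoreArgs = list(model = m1))
  p2 <- mapply(evalOne, t = tMean, b = bMinValues,
               MoreArgs = list(model = m2))
  ok <- is.finite(p1) & is.finite(p2)
  if (any(!ok))
    warning(sum(!ok), " point(s) outside a model domain excluded")
  if (!any(ok)) stop("model domain: no evaluable points")
  pts <- data.frame(t_mean = tMean, b_min = bMinValues, pct1 = p1,
                    pct2 = p2, diff = p2 - p1, ok = ok)
  list(points = pts, maxAbsDiff = max(abs(pts$diff[ok])))
}

#' Dense difference surface between two functions
#'
#' Evaluates `m2 - m1` on the grid `tMeanGrid` x `bMinGrid`, for plotting
#' or export. Both closed forms are smooth over the clinical domain, so
#' adjacent cells differ little at moderate resolution.
#'
#' @inheritParams functionDifference
#' @param tMeanGrid,bMinGrid grid axis values.
#' @return numeric matrix, rows indexing `tMeanGrid`, columns `bMinGrid`.
#' @export
differenceSurface <- function(m1, m2, tMeanGrid, bMinGrid) {
  outer(tMeanGrid, bMinGrid, function(t, b) {
    mapply(function(ti, bi)
      evaluatePct(m2, ti, bi) - evaluatePct(m1, ti, bi), t, b)
  })
}

.lesionTableCols <- c("lesion_id", "maaxis_hist_mm", "bmin", "tmean",
                      "pct_tmean", "maaxis_pet_mm", "maaxis_ct_mm",
                      "area_pet_mm2", "area_ct_mm2", "cov")

#' Read a lesion measurement table
#'
#' Comma-separated, period decimal point, header row required; lines
#' starting with `#` are comments. The required raw columns are
#' `lesion_id`, `maaxis_hist_mm`, `bmin`, `tmean`, `pct_tmean`,
#' `maaxis_pet_mm`, `maaxis_ct_mm`, `area_pet_mm2`, `area_ct_mm2`, `cov`;
#' extra columns (e.g. transcribed dVs values) are kept.
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
readLesionTable <- function(path) {
  tab <- utils::read.csv(path, comment.char = "#", check.names = TRUE)
  missing <- setdiff(.lesionTableCols, names(tab))
  if (length(missing))
    stop("lesion table lacks required columns: ",
         paste(missing, collapse = ", "))
  tab
}

#' The bundled clinical reference lesion tables
#'
#' Per-lesion measurements for the two published validation cohorts of the
#' histology-referenced group: 10 lesions with histological major axis at
#' or below 20 mm (`"le20mm"`, table1.csv) and 17 lesions with major axis
#' between 20 and 45 mm (`"20to45mm"`, table2.csv). Columns carry the raw
#' measurements plus the transcribed per-lesion dVs percentages used by the
#' consistency checks.
#'
#' @param group which cohort, or `"both"` to row-bind them.
#' @return data.frame.
#' @examples
#' nrow(referenceLesionTable("both"))
#' @export
referenceLesionTable <- function(group = c("le20mm", "20to45mm", "both")) {
  group <- match.arg(group)
  fetch <- function(f) readLesionTable(
    system.file("extdata", f, package = "PETseg", mustWork = TRUE))
  switch(group,
         le20mm = fetch("table1.csv"),
         `20to45mm` = fetch("table2.csv"),
         both = rbind(fetch("table1.csv"), fetch("table2.csv")))
}
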