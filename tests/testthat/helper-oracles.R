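# Independent oracles and tiny fixture builders used across the suite.
# Each oracle deliberately takes a different computational route than the
# package implementation it checks.

# Naive per-pixel loop over the masked pixels.
bruteRegionStats <- function(values, mask, dx, dy) {
  vals <- c()
  rows <- c()
  cols <- c()
  for (i in seq_len(nrow(values))) for (j in seq_len(ncol(values))) {
    if (mask[i, j]) {
      vals <- c(vals, values[i, j])
      rows <- c(rows, i)
      cols <- c(cols, j)
    }
  }
  n <- length(vals)
  m <- sum(vals) / n
  best <- 0
  if (n > 1) for (p in 1:(n - 1)) for (q in (p + 1):n) {
    d <- sqrt(((rows[p] - rows[q]) * dy)^2 + ((cols[p] - cols[q]) * dx)^2)
    if (d > best) best <- d
  }
  list(tMean = m, tMax = max(vals), areaMm2 = n * dx * dy,
       majorAxisMm = best,
       cov = sqrt(sum((vals - m)^2) / n) / m, nPixels = n)
}

# 8-connected component containing the ROI maximum, via an adjacency graph
# (igraph), not the package's dilation loop.
graphComponentMask <- function(values, roi, threshold) {
  out <- matrix(FALSE, nrow(values), ncol(values))
  sub <- values[roi[1]:roi[2], roi[3]:roi[4], drop = FALSE]
  if (max(sub) < threshold) return(out)
  cand <- which(sub >= threshold)
  rc <- arrayInd(cand, dim(sub))
  id <- seq_along(cand)
  edges <- c()
  for (p in id) for (q in id) {
    if (p < q && abs(rc[p, 1] - rc[q, 1]) <= 1 && abs(rc[p, 2] - rc[q, 2]) <= 1)
      edges <- c(edges, p, q)
  }
  g <- igraph::make_empty_graph(n = length(cand), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  mx <- which(sub[cand] == max(sub))
  mx <- mx[order(rc[mx, 1], rc[mx, 2])[1]]
  keep <- cand[comp == comp[mx]]
  subMask <- matrix(FALSE, nrow(sub), ncol(sub))
  subMask[keep] <- TRUE
  out[roi[1]:roi[2], roi[3]:roi[4]] <- subMask
  out
}

# Exhaustive accepted-threshold sweep oracle: every unique intensity tried,
# regions extracted through the graph oracle, minimizers of the metric kept.
sweepOracle <- function(values, roi, dx, dy, metricFun, reference) {
  ths <- sort(unique(as.vector(values[roi[1]:roi[2], roi[3]:roi[4]])))
  kept <- c()
  err <- c()
  for (th in ths) {
    mask <- graphComponentMask(values, roi, th)
    if (!any(mask)) next
    kept <- c(kept, th)
    err <- c(err, abs(metricFun(mask, dx, dy) - reference))
  }
  ath <- kept[err <= min(err) + 1e-9]
  list(ath = ath, threshold = (min(ath) + max(ath)) / 2)
}

maskArea <- function(mask, dx, dy) sum(mask) * dx * dy
maskAxis <- function(mask, dx, dy) {
  rc <- arrayInd(which(mask), dim(mask))
  best <- 0
  n <- nrow(rc)
  if (n > 1) for (p in 1:(n - 1)) for (q in (p + 1):n) {
    d <- sqrt(((rc[p, 1] - rc[q, 1]) * dy)^2 + ((rc[p, 2] - rc[q, 2]) * dx)^2)
    best <- max(best, d)
  }
  best
}

# Exhaustive fixed-point oracle for the iterative segmentation: a region R
# extracted at an achievable threshold is a fixed point iff re-deriving the
# threshold from R's mean intensity reproduces exactly the same pixel set.
fixedPointKeys <- function(image, lung, roi, model) {
  v <- intensityValues(image)
  sub <- v[roi[1]:roi[2], roi[3]:roi[4], drop = FALSE]
  keys <- character(0)
  for (T in sort(unique(as.vector(sub)))) {
    mask <- thresholdRegion(image, roi, T)
    if (!any(mask)) next
    m <- mean(v[mask])
    thr2 <- tryCatch(thresholdFromPct(evaluatePct(model, m, bMin(lung)), m),
                     error = function(e) NA_real_)
    if (is.na(thr2)) next
    if (identical(thresholdRegion(image, roi, thr2), mask))
      keys <- c(keys, paste(which(mask), collapse = ","))
  }
  unique(keys)
}

maskKeyOf <- function(mask) paste(which(mask), collapse = ",")

# A small concentric three-level lesion: hot core, warm ring, cold outside.
concentricImage <- function(core = 100, ring = 60, background = 5) {
  v <- matrix(background, 9, 9)
  v[3:7, 3:7] <- ring
  v[4:6, 4:6] <- core
  petSlice(v, dx = 4)
}
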