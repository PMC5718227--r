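# Synthetic PET/CT phantoms: an elliptical lesion in a low-uptake lung
# field inside a warmer body, rendered crisp at CT resolution and blurred,
# binned and noised at PET resolution.

# Run expr with a local RNG state; the caller's stream is untouched.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Construct a PhantomSpec
#'
#' Defaults describe a typical study lesion: a 30 mm round lesion of
#' moderate uptake in a quiet lung field, imaged at the clinical 7 mm
#' spatial resolution on a 4 x 4 mm2 PET grid with a 1 mm CT grid.
#'
#' @param semiAxisA,semiAxisB lesion ellipse semi-axes, mm.
#' @param rotationDeg lesion rotation, degrees.
#' @param centerMm lesion centre (x, y) mm; default is the grid centre.
#' @param lesionActivity,lungActivity,bodyActivity activity levels
#'   (lesion > lung > 0; body is the tissue surrounding the lung field).
#' @param noiseSd SD of additive Gaussian PET noise (clipped at 0).
#' @param psfFwhmMm Gaussian PSF full width at half maximum, mm.
#' @param petSpacingMm,ctSpacingMm pixel spacings, mm.
#' @param extentMm square field-of-view side, mm.
#' @param seed integer seed for the noise stream.
#' @return A [PhantomSpec-class].
#' @export
phantomSpec <- function(semiAxisA = 15, semiAxisB = semiAxisA,
                        rotationDeg = 0, centerMm = c(extentMm, extentMm) / 2,
                        lesionActivity = 10000, lungActivity = 400,
                        bodyActivity = 1000, noiseSd = 50, psfFwhmMm = 7,
                        petSpacingMm = 4, ctSpacingMm = 1, extentMm = 192,
                        seed = 1L) {
  new("PhantomSpec", semiAxisA = semiAxisA, semiAxisB = semiAxisB,
      rotationDeg = rotationDeg, centerMm = centerMm,
      lesionActivity = lesionActivity, lungActivity = lungActivity,
      bodyActivity = bodyActivity, noiseSd = noiseSd, psfFwhmMm = psfFwhmMm,
      petSpacingMm = petSpacingMm, ctSpacingMm = ctSpacingMm,
      extentMm = extentMm, seed = as.integer(seed))
}

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(paste0("PhantomSpec: %g x %g mm lesion (rot %g deg), ",
                     "activity %g/%g/%g, noise %g, FWHM %g mm, ",
                     "PET %g mm / CT %g mm, seed %d\n"),
              2 * object@semiAxisA, 2 * object@semiAxisB,
              object@rotationDeg, object@lesionActivity,
              object@lungActivity, object@bodyActivity, object@noiseSd,
              object@psfFwhmMm, object@petSpacingMm, object@ctSpacingMm,
              object@seed))
})

# Logical ellipse membership for pixel centres of an n x n grid at spacing s.
ellipseMask <- function(n, s, spec) {
  ctr <- ((1:n) - 0.5) * s
  x <- matrix(ctr, n, n, byrow = TRUE)  # column coordinate -> x
  y <- matrix(ctr, n, n)                # row coordinate -> y
  th <- spec@rotationDeg * pi / 180
  xr <- cos(th) * (x - spec@centerMm[1]) + sin(th) * (y - spec@centerMm[2])
  yr <- -sin(th) * (x - spec@centerMm[1]) + cos(th) * (y - spec@centerMm[2])
  (xr / spec@semiAxisA)^2 + (yr / spec@semiAxisB)^2 <= 1
}

blockAverage <- function(m, f) {
  nr <- nrow(m) %/% f
  nc <- ncol(m) %/% f
  a <- array(m[seq_len(nr * f), seq_len(nc * f)], dim = c(f, nr, f, nc))
  apply(a, c(2, 4), mean)
}

#' Generate one synthetic PET/CT phantom
#'
#' Renders the activity map (body, elliptical lung field, elliptical
#' lesion) at CT resolution; the CT slice carries the crisp map and the
#' ground-truth lesion mask. The PET slice is the same map convolved with
#' a Gaussian PSF of the stated FWHM (applied at CT resolution, before
#' detector binning), block-averaged down to the PET spacing, plus seeded
#' additive Gaussian noise clipped at 0. The lung mask (PET grid) covers
#' the lung field including the hot lesion, which cannot hold the minimum.
#'
#' @param spec a [PhantomSpec-class].
#' @return list with elements `pet`, `ct` ([PETSlice-class]), `lung`
#'   ([LungField-class]), `lungMask`, `truthMask` (CT grid), `truthAreaMm2`,
#'   `truthMajorAxisMm`, `roi` (lesion ROI on the PET grid, 1-based
#'   inclusive), and `spec`.
#' @examples
#' ph <- generatePhantom(phantomSpec(seed = 7))
#' ph$truthAreaMm2
#' @export
generatePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  sCt <- spec@ctSpacingMm
  sPet <- spec@petSpacingMm
  f <- as.integer(round(sPet / sCt))
  nPet <- floor(spec@extentMm / sPet)
  nCt <- nPet * f
  halfSpan <- max(spec@semiAxisA, spec@semiAxisB)
  if (any(spec@centerMm - halfSpan < 0) ||
      any(spec@centerMm + halfSpan > nCt * sCt))
    stop("geometry: lesion does not fit inside the grid")

  lesionCt <- ellipseMask(nCt, sCt, spec)
  lungSpec <- spec
  lungSpec@semiAxisA <- lungSpec@semiAxisB <- 0.44 * spec@extentMm
  lungSpec@rotationDeg <- 0
  lungSpec@centerMm <- c(nCt * sCt, nCt * sCt) / 2
  lungCt <- ellipseMask(nCt, sCt, lungSpec)
  if (!all(lesionCt[lesionCt] & lungCt[lesionCt]))
    stop("geometry: lesion extends outside the lung field")

  act <- matrix(spec@bodyActivity, nCt, nCt)
  act[lungCt] <- spec@lungActivity
  act[lesionCt] <- spec@lesionActivity

  blurred <- act
  if (spec@psfFwhmMm > 0) {
    sigmaPx <- spec@psfFwhmMm / (2 * sqrt(2 * log(2))) / sCt
    blurred <- EBImage::gblur(act, sigma = sigmaPx)
  }
  petVals <- blockAverage(blurred, f)
  if (spec@noiseSd > 0)
    petVals <- petVals + withSeed(spec@seed,
      matrix(stats::rnorm(length(petVals), 0, spec@noiseSd),
             nrow(petVals), ncol(petVals)))
  petVals <- pmax(petVals, 0)

  pet <- petSlice(petVals, sPet)
  ct <- petSlice(act, sCt)
  lungPet <- ellipseMask(nPet, sPet, lungSpec)
  lung <- lungField(pet, lungPet)

  # ROI: lesion bounding box on the PET grid plus a 12 mm margin.
  margin <- 12
  rows <- range(which(rowSums(lesionCt) > 0)) * sCt
  cols <- range(which(colSums(lesionCt) > 0)) * sCt
  roi <- c(max(1, floor((rows[1] - margin) / sPet) + 1),
           min(nPet, ceiling((rows[2] + margin) / sPet)),
           max(1, floor((cols[1] - margin) / sPet) + 1),
           min(nPet, ceiling((cols[2] + margin) / sPet)))

  idx <- which(lesionCt)
  list(pet = pet, ct = ct, lung = lung, lungMask = lungPet,
       truthMask = lesionCt, truthAreaMm2 = sum(lesionCt) * sCt^2,
       truthMajorAxisMm = maxPairDistanceRC(arrayInd(idx, dim(lesionCt)),
                                            sCt, sCt),
       roi = as.integer(roi), spec = spec)
}

#' Generate a cohort of phantoms
#'
#' Draws `n` phantom specifications with fields uniform over the given
#' ranges under one master seed (per-phantom noise seeds are drawn from the
#' same stream), then generates each phantom. Default ranges mirror the
#' clinical cohorts: lesion major axis 10--45 mm, mild eccentricity, uptake
#' contrasts giving Tmean/Bmin roughly 5--60.
#'
#' @param n number of phantoms (>= 1).
#' @param majorAxisMm,aspect,lesionActivity,lungActivity length-2 ranges.
#' @param seed master seed.
#' @param ... fixed [phantomSpec()] fields applied to every phantom
#'   (e.g. `noiseSd`, `psfFwhmMm`).
#' @return list of `n` phantom bundles (see [generatePhantom()]).
#' @export
generateCohort <- function(n, majorAxisMm = c(10, 45), aspect = c(0.6, 1),
                           lesionActivity = c(3000, 20000),
                           lungActivity = c(250, 700), seed = 1L, ...) {
  stopifnot(n >= 1L)
  ranges <- list(majorAxisMm = majorAxisMm, aspect = aspect,
                 lesionActivity = lesionActivity,
                 lungActivity = lungActivity)
  for (r in names(ranges))
    if (length(ranges[[r]]) != 2L || ranges[[r]][1] > ranges[[r]][2])
      stop("invalid range for ", r)
  draw <- withSeed(seed, {
    data.frame(
      major = stats::runif(n, majorAxisMm[1], majorAxisMm[2]),
      aspect = stats::runif(n, aspect[1], aspect[2]),
      rot = stats::runif(n, 0, 180),
      lesion = stats::runif(n, lesionActivity[1], lesionActivity[2]),
      lungAct = stats::runif(n, lungActivity[1], lungActivity[2]),
      jx = stats::runif(n, -8, 8), jy = stats::runif(n, -8, 8),
      seed = sample.int(.Machine$integer.max - 1L, n))
  })
  lapply(seq_len(n), function(i) {
    a <- draw$major[i] / 2
    spec <- phantomSpec(semiAxisA = a, semiAxisB = a * draw$aspect[i],
                        rotationDeg = draw$rot[i],
                        lesionActivity = draw$lesion[i],
                        lungActivity = draw$lungAct[i],
                        seed = draw$seed[i], ...)
    spec@centerMm <- spec@centerMm + c(draw$jx[i], draw$jy[i])
    generatePhantom(spec)
  })
}
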