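# Pixel-level measurements: region statistics, background minimum,
# threshold-based region extraction, major axis.

test_that("region statistics match closed forms on tiny masks", {
  img <- petSlice(matrix(5, 3, 3), dx = 4)
  st <- regionStats(img, matrix(TRUE, 3, 3))
  expect_equal(tMean(st), 5)
  expect_equal(tMax(st), 5)
  expect_equal(covUptake(st), 0)
  expect_equal(areaMm2(st), 9 * 16)

  img2 <- petSlice(matrix(c(10, 20, 0, 0), 2, 2), dx = 4)
  st2 <- regionStats(img2, matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2))
  expect_equal(tMean(st2), 15)
  expect_equal(tMax(st2), 20)
  expect_equal(covUptake(st2), 5 / 15)
  expect_equal(nPixels(st2), 2L)
})

test_that("region statistics equal a brute-force per-pixel loop", {
  set.seed(1)
  for (rep in 1:5) {
    v <- matrix(round(runif(36, 1, 1000)), 6, 6)
    mask <- matrix(FALSE, 6, 6)
    mask[sample.int(36, 10)] <- TRUE
    img <- petSlice(v, dx = 4, dy = 3)
    st <- regionStats(img, mask)
    br <- bruteRegionStats(v, mask, dx = 4, dy = 3)
    expect_equal(tMean(st), br$tMean)
    expect_equal(tMax(st), br$tMax)
    expect_equal(areaMm2(st), br$areaMm2)
    expect_equal(majorAxisMm(st), br$majorAxisMm)
    expect_equal(covUptake(st), br$cov)
  }
})

test_that("background minimum is the minimum over the mask", {
  img <- petSlice(matrix(c(464, 700, 9000, 50), 2, 2), dx = 4)
  lungs <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  expect_equal(minInMask(img, lungs), 464)
  single <- matrix(c(FALSE, TRUE, FALSE, FALSE), 2, 2)
  expect_equal(minInMask(img, single), 700)
  expect_equal(minInMask(petSlice(matrix(7, 2, 2)), matrix(TRUE, 2, 2)), 7)
  expect_error(minInMask(img, matrix(FALSE, 2, 2)), "empty region")
  expect_error(minInMask(img, matrix(TRUE, 3, 3)), "geometry")
})

test_that("threshold extraction keeps the component holding the ROI max", {
  v <- matrix(0, 10, 10)
  v[3:5, 3:5] <- 100                      # uniform square "disc"
  img <- petSlice(v, dx = 4)
  roi <- c(1, 10, 1, 10)
  mask <- thresholdRegion(img, roi, 100)
  expect_equal(sum(mask), 9)
  expect_true(all(mask[3:5, 3:5]))

  expect_equal(sum(thresholdRegion(img, roi, 101)), 0)  # above the max

  # two blobs; only the one with the global ROI max survives
  v2 <- matrix(0, 10, 10)
  v2[2:3, 2:3] <- 80
  v2[7:8, 7:8] <- c(90, 95, 92, 99)
  img2 <- petSlice(v2, dx = 4)
  mask2 <- thresholdRegion(img2, roi, 75)
  expect_identical(mask2, graphComponentMask(v2, roi, 75))
  expect_equal(sum(mask2), 4)
  expect_false(any(mask2[2:3, 2:3]))
})

test_that("lowering the threshold never removes pixels", {
  set.seed(7)
  v <- matrix(round(runif(144, 0, 500)), 12, 12)
  img <- petSlice(v, dx = 4)
  roi <- c(2, 11, 2, 11)
  ths <- sort(unique(as.vector(v[2:11, 2:11])), decreasing = TRUE)
  prev <- matrix(FALSE, 12, 12)
  for (th in ths) {
    cur <- thresholdRegion(img, roi, th)
    expect_true(all(cur[prev]))  # superset of the previous (higher) level
    prev <- cur
  }
  expect_equal(areaMm2(regionStats(img, prev)) %% 16, 0)
})

test_that("major axis matches pairwise pixel-centre geometry", {
  m <- matrix(FALSE, 6, 6)
  m[2, 2] <- TRUE
  expect_equal(majorAxisLength(m, 4), 0)
  m[2, 3] <- TRUE
  expect_equal(majorAxisLength(m, 4), 4)
  r <- matrix(FALSE, 8, 8)
  r[2:4, 2:5] <- TRUE                  # 3 x 4 pixel block
  expect_equal(majorAxisLength(r, 4), sqrt(8^2 + 12^2))
  expect_equal(round(majorAxisLength(r, 4), 1), 14.4)
  expect_error(majorAxisLength(matrix(FALSE, 3, 3)), "empty region")
})

test_that("major axis is invariant under translation and 90-degree rotation", {
  set.seed(3)
  for (rep in 1:10) {
    block <- matrix(FALSE, 5, 5)
    block[sample.int(25, 6)] <- TRUE
    m <- matrix(FALSE, 7, 7)
    m[1:5, 1:5] <- block
    ax <- majorAxisLength(m, 4)
    shifted <- matrix(FALSE, 7, 7)
    shifted[3:7, 3:7] <- m[1:5, 1:5]
    expect_equal(majorAxisLength(shifted, 4), ax)
    rotated <- t(m)[, 7:1]
    expect_equal(majorAxisLength(rotated, 4), ax)
  }
})

test_that("geometry violations raise errors", {
  img <- petSlice(matrix(1:9, 3, 3))
  expect_error(regionStats(img, matrix(FALSE, 3, 3)), "empty region")
  expect_error(regionStats(img, matrix(TRUE, 2, 2)), "geometry")
  expect_error(thresholdRegion(img, c(0, 3, 1, 3), 1), "geometry")
  expect_error(thresholdRegion(img, c(3, 2, 1, 3), 1), "geometry")
  expect_error(petSlice(matrix(-1, 2, 2)), ">= 0")
  expect_error(petSlice(matrix(1, 2, 2), dx = 0), "positive")
})
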