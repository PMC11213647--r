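# cylindrical "rectum" fixture: circular contours in a dose grid
cylContours <- function(nSlices = 8, center = c(0, 0), r = 9, nv = 72)
  lapply(seq_len(nSlices), function(s) circleContour("RECTUM", s, center, r,
                                                     n = nv))

doseGridFrom <- function(fn, d = c(8L, 64L, 64L), sp = c(2.5, 1, 1)) {
  g <- ImageGrid(array(0, d), spacing = sp, modality = "DOSE", units = "Gy")
  z <- sctDose:::axisCoords(g, 1); y <- sctDose:::axisCoords(g, 2)
  x <- sctDose:::axisCoords(g, 3)
  v <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2]))
    v[i, j, ] <- fn(z[i], y[j], x)
  sctDose:::withVoxels(g, v)
}

test_that("a circular contour in a uniform field unwraps to a constant map", {
  dose <- doseGridFrom(function(z, y, x) rep(50, length(x)))
  dsm <- unwrapSurface(dose, cylContours())
  expect_equal(dim(dsm@raw), c(8L, 100L))
  expect_true(all(abs(dsm@raw - 50) < 1e-9))
})

test_that("an anterior dose ramp puts each row minimum at the posterior anchor", {
  dose <- doseGridFrom(function(z, y, x) rep(40 + y, length(x)))
  dsm <- unwrapSurface(dose, cylContours())
  for (i in 1:8) expect_equal(which.min(dsm@raw[i, ]), 1)
  # and the anchor dose equals the analytic posterior-wall value
  expect_equal(dsm@raw[1, 1], 40 - 9, tolerance = 0.2)
})

test_that("unwrapping is invariant to the contour's starting vertex", {
  dose <- doseGridFrom(function(z, y, x) 40 + y + 0.3 * x)
  cns <- cylContours(3)
  rotated <- lapply(cns, function(cn) {
    p <- cn@points
    k <- 17
    Contour(cn@structure, cn@slice, rbind(p[k:nrow(p), ], p[1:(k - 1), ]))
  })
  a <- unwrapSurface(dose, cns)
  b <- unwrapSurface(dose, rotated)
  expect_equal(a@raw, b@raw, tolerance = 1e-9)
})

test_that("posterior-anchor clockwise convention heads toward patient-right", {
  # dose increasing toward patient-left (+col): the first columns after the
  # anchor (patient-right motion) must dip below the anchor value
  dose <- doseGridFrom(function(z, y, x) 50 + x)
  dsm <- unwrapSurface(dose, cylContours(3))
  expect_lt(dsm@raw[1, 6], dsm@raw[1, 1])
  expect_gt(dsm@raw[1, 56], dsm@raw[1, 1])   # opposite side is patient-left
})

test_that("DSM interpolation to 42 x 42 matches a direct bilinear oracle", {
  const <- DoseSurfaceMap(raw = matrix(55, 6, 10))
  ci <- interpolateDSM(const)
  expect_equal(dim(ci@interpolated), c(42L, 42L))
  expect_true(all(abs(ci@interpolated - 55) < 1e-12))

  already <- DoseSurfaceMap(raw = matrix(runif(42 * 42, 30, 70), 42, 42))
  expect_equal(interpolateDSM(already)@interpolated, already@raw,
               tolerance = 1e-12)

  set.seed(13)
  raw <- matrix(runif(21 * 21, 0, 70), 21, 21)
  got <- interpolateDSM(DoseSurfaceMap(raw = raw))@interpolated
  oracle <- matrix(0, 42, 42)
  for (i in 1:42) for (j in 1:42) {
    fr <- (i - 1) / 41 * 20; fc <- (j - 1) / 42 * 21
    r0 <- min(floor(fr), 19); c0 <- floor(fc)
    wr <- fr - r0; wc <- fc - c0
    c1 <- (c0 + 1) %% 21
    oracle[i, j] <-
      raw[r0 + 1, c0 + 1] * (1 - wr) * (1 - wc) +
      raw[r0 + 1, c1 + 1] * (1 - wr) * wc +
      raw[r0 + 2, c0 + 1] * wr * (1 - wc) +
      raw[r0 + 2, c1 + 1] * wr * wc
  }
  expect_equal(got, oracle, tolerance = 1e-9)
})

test_that("unwrap + interpolate commutes with dose scaling", {
  dose <- doseGridFrom(function(z, y, x) 40 + y + 0.5 * x + z)
  dose2 <- sctDose:::withVoxels(dose, voxels(dose) * 1.7)
  cns <- cylContours()
  a <- interpolateDSM(unwrapSurface(dose, cns))@interpolated
  b <- interpolateDSM(unwrapSurface(dose2, cns))@interpolated
  expect_equal(b, 1.7 * a, tolerance = 1e-9)
})

test_that("binary maps, relative areas and EQD2 gating", {
  m <- DoseSurfaceMap(raw = matrix(70, 42, 42),
                      interpolated = matrix(70, 42, 42), isEQD2 = TRUE)
  b <- binarizeDSM(m, 51)
  expect_equal(b$relArea, 1)
  half <- matrix(rep(c(70, 20), each = 21 * 42 / 2), 42, 42)
  mh <- DoseSurfaceMap(raw = half, interpolated = half, isEQD2 = TRUE)
  expect_equal(binarizeDSM(mh, 51)$relArea, 0.5)
  notE <- DoseSurfaceMap(raw = half, interpolated = half, isEQD2 = FALSE)
  expect_error(binarizeDSM(notE, 51), "EQD2")
})

test_that("relative area is non-decreasing under pointwise dose increase", {
  set.seed(3)
  base <- matrix(runif(42 * 42, 30, 70), 42, 42)
  a <- binarizeDSM(DoseSurfaceMap(raw = base, interpolated = base,
                                  isEQD2 = TRUE), 51)$relArea
  up <- base + 4
  b <- binarizeDSM(DoseSurfaceMap(raw = up, interpolated = up,
                                  isEQD2 = TRUE), 51)$relArea
  expect_gte(b, a)
})

test_that("largest-cluster ellipse: degenerate, band and wrapped clusters", {
  empty <- matrix(FALSE, 42, 42)
  fit0 <- largestClusterEllipse(empty)
  expect_equal(fit0@relativeLateralExtent, 0)
  expect_equal(fit0@clusterSize, 0L)

  # solid 42-row x 21-column band: moment-ellipse extent 21*(2/sqrt(3))/42
  band <- matrix(FALSE, 42, 42); band[, 6:26] <- TRUE
  fit <- largestClusterEllipse(band)
  expect_equal(fit@relativeLateralExtent, 21 * (2 / sqrt(3)) / 42,
               tolerance = 1e-9)

  # same band wrapped across the circumferential seam: identical extent
  wrapped <- matrix(FALSE, 42, 42)
  wrapped[, c(33:42, 1:11)] <- TRUE
  fitW <- largestClusterEllipse(wrapped)
  expect_equal(fitW@relativeLateralExtent, fit@relativeLateralExtent,
               tolerance = 1e-9)
  expect_equal(fitW@clusterSize, fit@clusterSize)

  # largest of two clusters wins
  two <- matrix(FALSE, 42, 42)
  two[5:10, 5:10] <- TRUE; two[20:35, 20:30] <- TRUE
  fit2 <- largestClusterEllipse(two)
  expect_equal(fit2@clusterSize, 16L * 11L)
})

test_that("cranio-caudal-only dose variation gives row-constant maps", {
  dose <- doseGridFrom(function(z, y, x) rep(60 + 3 * z, length(x)))
  cns <- cylContours(8)
  dsm <- interpolateDSM(unwrapSurface(dose, cns))
  rowSpread <- apply(dsm@interpolated, 1, function(r) diff(range(r)))
  expect_lt(max(rowSpread), 1e-6)
  dsmE <- DoseSurfaceMap(raw = dsm@raw, interpolated = dsm@interpolated,
                         isEQD2 = TRUE)
  b <- binarizeDSM(dsmE, 60)
  rowFrac <- mean(apply(dsm@interpolated >= 60, 1, all))
  expect_equal(b$relArea, rowFrac, tolerance = 1 / 42 + 1e-9)
})

test_that("the published DSM decision thresholds gate the risk flags", {
  dose <- doseGridFrom(function(z, y, x) rep(48, length(x)))
  cns <- cylContours(8)
  p <- dsmParameters(dose, cns, fractions = 20)
  # 48 Gy in 20 fx -> EQD2 52.3 Gy: all cells above 51, none above 61
  expect_equal(p$relArea51, 1)
  expect_true(p$flagArea51)      # 1.0 > 0.374
  expect_equal(p$relLatExtent61, 0)
  expect_false(p$flagExtent61)   # 0 < 0.591
})
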