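test_that("NIfTI round trip preserves voxels, spacing and origin", {
  set.seed(42)
  grid <- ImageGrid(array(rnorm(4 * 8 * 8, 0, 100), c(4, 8, 8)),
                    spacing = c(2.5, 0.98, 0.98))
  f <- tempfile(fileext = ".nii.gz")
  writeVolume(grid, f, "nifti")
  back <- readVolume(f, "nifti")
  expect_equal(voxels(back), voxels(grid), tolerance = 1e-6)
  expect_equal(spacing(back), c(2.5, 0.98, 0.98), tolerance = 1e-6)
  expect_equal(origin(back), origin(grid), tolerance = 1e-4)
  expect_true(file.exists(f) && !dir.exists(f))  # single file
})

test_that("DICOM series round trip is exact for integer HU and 1e-6 for floats", {
  intGrid <- ImageGrid(array(sample(-1024:2000, 3 * 6 * 6, TRUE),
                             c(3, 6, 6)))
  d1 <- file.path(tempdir(), "dcm_int")
  writeVolume(intGrid, d1, "dicom_series")
  expect_length(list.files(d1, pattern = "\\.dcm$"), 3L)  # one per slice
  back <- readVolume(d1, "dicom_series")
  expect_identical(dim(back), dim(intGrid))
  expect_equal(max(abs(voxels(back) - voxels(intGrid))), 0)
  expect_equal(spacing(back), spacing(intGrid), tolerance = 1e-9)
  expect_equal(origin(back), origin(intGrid), tolerance = 1e-9)

  set.seed(7)
  doseGrid <- ImageGrid(array(runif(3 * 6 * 6, 0, 65), c(3, 6, 6)),
                        modality = "DOSE", units = "Gy")
  d2 <- file.path(tempdir(), "dcm_float")
  writeVolume(doseGrid, d2, "dicom_series")
  back2 <- readVolume(d2, "dicom_series")
  expect_lt(max(abs(voxels(back2) - voxels(doseGrid))), 1e-6)
})

test_that("DICOM rescale slope/intercept is applied on read", {
  # stored value 1024 with intercept -1024 must read back as 0 HU
  grid <- ImageGrid(array(c(-1024, 0, 500, -1024, 76, 1976), c(1, 2, 3)))
  d <- file.path(tempdir(), "dcm_rescale")
  writeVolume(grid, d, "dicom_series")
  tags <- sctDose:::parseDicomFile(list.files(d, full.names = TRUE)[1])
  expect_equal(sctDose:::dcmNumerics(tags, "00281052"), -1024)  # intercept
  expect_equal(sctDose:::dcmNumerics(tags, "00281053"), 1)
  back <- readVolume(d, "dicom_series")
  expect_equal(voxels(back)[1, 2, 1], 0)   # stored 1024 -> 0 HU
})

test_that("mixed-orientation DICOM series are rejected and junk files error", {
  grid <- ImageGrid(array(0:17, c(3, 2, 3)))
  d <- file.path(tempdir(), "dcm_mixed")
  writeVolume(grid, d, "dicom_series")
  f2 <- list.files(d, full.names = TRUE)[2]
  raw <- readBin(f2, "raw", file.info(f2)$size)
  # corrupt the orientation string of one slice
  pat <- charToRaw("1\\0\\0\\0\\1\\0")
  hit <- which(vapply(seq_len(length(raw) - length(pat)), function(i)
    all(raw[i:(i + length(pat) - 1)] == pat), logical(1)))[1]
  raw[hit] <- charToRaw("0")
  writeBin(raw, f2)
  expect_error(readVolume(d, "dicom_series"), "mixed-orientation")
  junk <- tempfile(fileext = ".dcm")
  writeBin(as.raw(rep(1, 200)), junk)
  dj <- file.path(tempdir(), "dcm_junk"); dir.create(dj, showWarnings = FALSE)
  file.copy(junk, file.path(dj, "a.dcm"))
  expect_error(readVolume(dj, "dicom_series"), "DICM")
})

test_that("JSON contour files round trip", {
  cns <- list(circleContour("RECTUM", 2L, c(-30, 0), 9),
              Contour("BODY", 1L, cbind(c(-5, -5, 5, 5), c(-5, 5, 5, -5))))
  f <- tempfile(fileext = ".json")
  writeContours(cns, f)
  back <- readContours(f)
  expect_length(back, 2L)
  expect_equal(back[[1]]@points, cns[[1]]@points, tolerance = 1e-12)
  expect_identical(back[[2]]@slice, 1L)
  expect_identical(back[[2]]@structure, "BODY")
})

test_that("rasterization follows the even-odd voxel-center rule", {
  ref <- makeGrid(d = c(3L, 40L, 40L), spacing = c(2.5, 1, 1))
  # axis-aligned 10 x 10 mm square between voxel centers -> exactly 100 voxels
  sq <- Contour("S", 2L, cbind(c(-5, -5, 5, 5), c(-5, 5, 5, -5)))
  m <- rasterizeContours(list(sq), ref)
  expect_equal(sum(voxels(m)), 100)
  expect_equal(sum(voxels(m)[c(1, 3), , ]), 0)   # no inter-slice fill

  # circle r = 15 px: area within 5% of pi r^2, and identical to the
  # point-in-polygon oracle (mgcv::in.out) at every voxel center
  circ <- circleContour("C", 1L, c(0, 0), 15, n = 256)
  mc <- rasterizeContours(list(circ), ref)
  expect_lt(abs(sum(voxels(mc)) - pi * 15^2) / (pi * 15^2), 0.05)
  centers <- as.matrix(expand.grid(
    col = origin(ref)[3] + (0:39) * 1, row = origin(ref)[2] + (0:39) * 1))
  bnd <- rbind(circ@points[, c(2, 1)], circ@points[1, c(2, 1)])
  oracle <- mgcv::in.out(bnd, centers)
  got <- as.vector(aperm(voxels(mc)[1, , , drop = FALSE], c(1, 3, 2)))
  expect_equal(got, oracle)
})

test_that("rasterization is monotone and handles degenerate input", {
  ref <- makeGrid(d = c(1L, 30L, 30L), spacing = c(2.5, 1, 1))
  inner <- circleContour("A", 1L, c(0, 0), 6)
  outer <- circleContour("B", 1L, c(0, 0), 12)
  mi <- voxels(rasterizeContours(list(inner), ref))
  mo <- voxels(rasterizeContours(list(outer), ref))
  expect_true(all(mo[mi]))                       # superset
  expect_false(any(voxels(rasterizeContours(list(), ref))))
  expect_error(rasterizeContours(list(circleContour("A", 5L, c(0, 0), 5)),
                                 ref), "outside reference extent")
})

test_that("resampling: identity, constants, analytic ramp, value sets", {
  g <- ImageGrid(array(rnorm(4 * 8 * 8), c(4, 8, 8)), spacing = c(2, 2, 2))
  expect_equal(voxels(resampleGrid(g, g, "trilinear")), voxels(g),
               tolerance = 1e-12)
  const <- makeGrid(50, d = c(4L, 8L, 8L), spacing = c(4, 4, 4))
  fine <- makeGrid(0, d = c(6L, 12L, 12L), spacing = c(2, 2, 2))
  res <- resampleGrid(const, fine, "trilinear")
  interior <- voxels(res)[2:5, 3:10, 3:10]
  expect_true(all(interior == 50))

  # linear ramp along rows, half-spacing target: interior equals the ramp
  ramp <- ImageGrid(array(rep(rep(seq(0, 70, by = 10), each = 2),
                              times = 8), c(2, 8, 8)),
                    spacing = c(2.5, 2, 2))
  tgt <- ImageGrid(array(0, c(2, 15, 15)), spacing = c(2.5, 1, 1),
                   origin = c(origin(ramp)[1], origin(ramp)[2:3]))
  rr <- resampleGrid(ramp, tgt, "trilinear")
  expected <- 0:14 * 5   # 5 HU per mm along the row axis
  expect_equal(voxels(rr)[1, , 4], expected, tolerance = 1e-9)

  nn <- resampleGrid(ramp, tgt, "nearest")
  expect_true(all(voxels(nn) %in% voxels(ramp)))  # no new values

  far <- ImageGrid(array(0, c(2, 4, 4)), spacing = c(2.5, 1, 1),
                   origin = c(1000, 1000, 1000))
  expect_error(resampleGrid(ramp, far), "disjoint")
})

test_that("mask resampling fills outside voxels with FALSE", {
  m <- ImageGrid(array(TRUE, c(2, 4, 4)), spacing = c(2.5, 1, 1),
                 modality = "MASK", units = "bool")
  big <- ImageGrid(array(FALSE, c(2, 12, 12)), spacing = c(2.5, 1, 1),
                   modality = "MASK", units = "bool")
  res <- resampleGrid(m, big, "nearest")
  expect_type(voxels(res), "logical")
  expect_equal(sum(voxels(res)), 2 * 4 * 4)
})
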