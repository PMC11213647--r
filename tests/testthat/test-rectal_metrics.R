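maskAll <- function(d) ImageGrid(array(TRUE, d), modality = "MASK",
                                 units = "bool")

test_that("DVH counting and cumulative curve behave as volume fractions", {
  d <- c(1L, 2L, 5L)
  doses <- c(10, 20, 30, 40, 50, 55, 60, 61, 62, 63)
  dose <- ImageGrid(array(doses, d), modality = "DOSE", units = "Gy")
  dvh <- computeDVH(dose, maskAll(d))
  expect_equal(dvhMetric(dvh, "V", doseGy = 60), 0.40)   # 4 of 10 voxels
  expect_equal(sum(dvh@vDiff), 1)

  uni <- ImageGrid(array(50, d), modality = "DOSE", units = "Gy")
  dvhU <- computeDVH(uni, maskAll(d))
  expect_equal(dvhMetric(dvhU, "V", doseGy = 30), 1)
  expect_equal(dvhMetric(dvhU, "V", doseGy = 50), 1)
  expect_equal(dvhMetric(dvhU, "V", doseGy = 50.2), 0)
  expect_error(computeDVH(uni, ImageGrid(array(FALSE, d), modality = "MASK",
                                         units = "bool")), "empty")
})

test_that("cumulative DVH equals the sort-based oracle at every bin edge", {
  set.seed(21)
  d <- c(10L, 10L, 10L)
  v <- runif(1000, 0, 70)
  dose <- ImageGrid(array(v, d), modality = "DOSE", units = "Gy")
  dvh <- computeDVH(dose, maskAll(d), binWidth = 0.1)
  oracle <- vapply(dvh@binEdges, function(e) mean(v >= e), numeric(1))
  expect_equal(dvh@cumulative, oracle, tolerance = 1e-12)
})

test_that("D-metrics follow the right-continuous interpolation convention", {
  d <- c(1L, 1L, 10L)
  uni <- ImageGrid(array(60, d), modality = "DOSE", units = "Gy")
  dvhU <- computeDVH(uni, maskAll(d))
  expect_equal(dvhMetric(dvhU, "D95"), 60, tolerance = 0.1)
  expect_equal(dvhMetric(dvhU, "Dmedian"), 60, tolerance = 0.1)

  half <- ImageGrid(array(rep(c(40, 60), each = 5), d), modality = "DOSE",
                    units = "Gy")
  dvhH <- computeDVH(half, maskAll(d))
  # V(60) = 0.5 exactly: the median sits at the upper plateau edge
  expect_equal(dvhMetric(dvhH, "Dmedian"), 60, tolerance = 1e-9)
  expect_error(dvhMetric(dvhH, "Dmax"), "unknown metric")
})

test_that("EQD2 closed form: anchors, fixed point, zero", {
  expect_equal(eqd2(60, 20, 3), 72)           # 60 * (3+3)/(2+3)
  expect_equal(eqd2(40, 20, 3), 40)           # 2 Gy/fx fixed point
  expect_equal(eqd2(0, 20, 3), 0)
  expect_equal(eqd2(40, 20, 10), 40)          # fixed point for any a/b
  expect_equal(eqd2(c(60, 40), 20, 3), c(72, 40))
})

test_that("gEUD power-mean: constants, mean, serial-organ weighting", {
  d <- c(1L, 1L, 10L)
  uni <- computeDVH(ImageGrid(array(60, d), modality = "DOSE",
                              units = "Gy"), maskAll(d))
  for (n in c(0.085, 0.5, 1)) expect_equal(gEUD(uni, n), 60, tolerance = 0.1)

  half <- computeDVH(ImageGrid(array(rep(c(60, 0), each = 5), d),
                               modality = "DOSE", units = "Gy"),
                     maskAll(d), binWidth = 0.01)
  expect_equal(gEUD(half, 1), 30, tolerance = 0.05)
  expect_equal(gEUD(half, 0.085), 60 * 0.5^0.085, tolerance = 0.3)
  expect_error(gEUD(half, 0), "> 0")
})

test_that("gEUD at n = 1 equals the DVH mean dose to 1e-12", {
  set.seed(5)
  d <- c(5L, 5L, 5L)
  dose <- ImageGrid(array(runif(125, 0, 70), d), modality = "DOSE",
                    units = "Gy")
  dvh <- computeDVH(dose, maskAll(d))
  centers <- (dvh@binEdges[-1] + dvh@binEdges[-length(dvh@binEdges)]) / 2
  expect_equal(gEUD(dvh, 1), sum(dvh@vDiff * centers), tolerance = 1e-12)
})

test_that("LKB NTCP anchors and published parameter sets", {
  g2 <- g2rbParams()
  expect_equal(c(g2@td50, g2@m, g2@n, g2@alphaBeta), c(97.7, 0.27, 0.085, 3))
  lfi <- lfiParams()
  expect_equal(c(lfi@td50, lfi@m, lfi@n, lfi@alphaBeta), c(105, 0.43, 1, 3))
  expect_equal(lkbNTCP(97.7, g2)@ntcp, 0.5)
  expect_equal(lkbNTCP(97.7 * 1.27, g2)@ntcp, pnorm(1), tolerance = 1e-12)
  # strictly increasing in gEUD
  probs <- vapply(seq(40, 120, by = 10), function(g) lkbNTCP(g, g2)@ntcp,
                  numeric(1))
  expect_true(all(diff(probs) > 0))
  expect_error(LKBParams(97.7, 0.27, 1.5), "n must be")
})

test_that("gEUD is monotone under pointwise dose increase", {
  set.seed(31)
  d <- c(4L, 4L, 4L)
  base <- array(runif(64, 10, 60), d)
  lower <- computeDVH(ImageGrid(base, modality = "DOSE", units = "Gy"),
                      maskAll(d))
  higher <- computeDVH(ImageGrid(base + 3, modality = "DOSE", units = "Gy"),
                       maskAll(d))
  for (n in c(0.085, 1)) expect_gt(gEUD(higher, n), gEUD(lower, n))
})
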