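waterPhantomFixture <- function() {
  memoFixture("waterPhantom", {
    d <- c(10L, 64L, 64L)
    red <- ImageGrid(array(1, d), spacing = c(2.5, 2, 2),
                     modality = "CT", units = "arbitrary")
    tgt <- array(FALSE, d)
    tgt[4:7, 28:37, 28:37] <- TRUE
    target <- ImageGrid(tgt, spacing = c(2.5, 2, 2), modality = "MASK",
                        units = "bool")
    list(red = red, target = target)
  })
}

test_that("HU to RED calibration hits its anchors and interpolates linearly", {
  curve <- CalibrationCurve()
  g <- ImageGrid(array(c(0, -1000, -537.5, 5000, -2000, 102),
                       c(1, 2, 3)))
  red <- voxels(huToRED(g, curve))
  expect_equal(red[1, 1, 1], 1.0)          # water
  expect_equal(red[1, 2, 1], 0.0)          # air
  # midpoint of the (-1000, -75) segment -> mean of endpoint REDs
  expect_equal(red[1, 1, 2], (0 + 0.97) / 2)
  expect_equal(red[1, 2, 2], 1.60)         # clamped above
  expect_equal(red[1, 1, 3], 0)            # clamped below
  expect_error(new("CalibrationCurve", hu = c(0, 100), red = c(1, 0.5)),
               "increasing")
})

test_that("parallel-opposed beams give a midplane-symmetric dose", {
  fx <- waterPhantomFixture()
  plan <- PlanConfig(nBeams = 2)           # 0 and 180 degrees
  dose <- computeDose(fx$red, plan, fx$target)
  v <- voxels(dose)
  flipped <- v[, rev(seq_len(dim(v)[2])), ]
  expect_lt(max(abs(v - flipped)), 1e-6)
})

test_that("denser medium with fixed fluence strictly reduces target dose", {
  fx <- waterPhantomFixture()
  plan <- PlanConfig()
  plan@muScale <- 1
  d1 <- computeDose(fx$red, plan, fx$target)
  red2 <- sctDose:::withVoxels(fx$red, voxels(fx$red) * 2)
  d2 <- computeDose(red2, plan, fx$target)
  iso <- c(6, 33, 33)
  expect_lt(voxels(d2)[iso[1], iso[2], iso[3]],
            voxels(d1)[iso[1], iso[2], iso[3]])
})

test_that("dose is linear in the fluence scale", {
  fx <- waterPhantomFixture()
  plan <- PlanConfig()
  plan@muScale <- 1
  d1 <- computeDose(fx$red, plan, fx$target)
  plan@muScale <- 2
  d2 <- computeDose(fx$red, plan, fx$target)
  expect_equal(voxels(d2), 2 * voxels(d1), tolerance = 1e-12)
})

test_that("central-axis depth dose matches the closed-form attenuation", {
  # single anterior beam, no penumbra, uniform RED = 1
  d <- c(6L, 80L, 40L)
  red <- ImageGrid(array(1, d), spacing = c(2.5, 2, 2), units = "arbitrary")
  tgt <- array(FALSE, d); tgt[, 30:50, 15:25] <- TRUE
  target <- ImageGrid(tgt, spacing = c(2.5, 2, 2), modality = "MASK",
                      units = "bool")
  plan <- new("PlanConfig", prescriptionGy = 60, fractions = 20,
              gantryAngles = c(0, 0), beamWeights = c(0.5, 0.5),
              apertureMarginMm = 10, penumbraSigmaMm = 0, muEff = 0.005,
              isocenter = c(0, 0, 0), muScale = 1)
  dose <- computeDose(red, plan, target, stepMm = 0.25)
  rows <- sctDose:::axisCoords(red, 2)
  axis <- voxels(dose)[3, , 20]
  entry <- max(rows)                        # beam enters from anterior
  expected <- exp(-0.005 * (entry - rows))
  sel <- rows < entry - 2                   # skip the entry voxel
  expect_lt(max(abs(axis[sel] / expected[sel] - 1)), 0.01)
})

test_that("planning normalizes the target median and recalc is a pure replay", {
  pp <- plannedPhantom(1)
  ph <- pp$phantom
  ptv <- structureMask(ph@structures, "PTV60")
  expect_equal(median(voxels(pp$dose)[voxels(ptv)]), 60, tolerance = 1e-9)
  expect_false(is.na(ph@plan@muScale))
  again <- recalcFixedMU(ph@ct, ph@plan, ptv)
  expect_identical(voxels(again), voxels(pp$dose))   # bit-identical replay
  unplanned <- PlanConfig()
  expect_error(recalcFixedMU(ph@ct, unplanned, ptv), "muScale")
})

test_that("bulk-density recalculation on a bony phantom shifts target dose", {
  pp <- plannedPhantom(1)
  ph <- pp$phantom
  ptv <- structureMask(ph@structures, "PTV60")
  sct <- makeSCT(ph, "bdw")
  dose <- recalcFixedMU(sct, ph@plan, ptv)
  med <- median(voxels(dose)[voxels(ptv)])
  expect_gt(abs(med - 60), 1e-3)           # nonzero error must exist
})

test_that("gamma analysis: identity, within-tolerance scaling, asymmetry", {
  pp <- plannedPhantom(1)
  g0 <- gammaAnalysis(pp$dose, pp$dose)
  expect_equal(g0@passRate, 100)
  expect_equal(max(voxels(g0@gammaMap), na.rm = TRUE), 0)

  scaled <- sctDose:::withVoxels(pp$dose, voxels(pp$dose) * 1.01)
  g1 <- gammaAnalysis(pp$dose, scaled)
  expect_equal(g1@passRate, 100)
  expect_lte(max(voxels(g1@gammaMap), na.rm = TRUE), 0.5 + 1e-9)

  # local gamma is asymmetric in (reference, evaluated)
  a <- ImageGrid(array(10, c(4, 8, 8)), spacing = c(2.5, 1, 1),
                 modality = "DOSE", units = "Gy")
  bV <- array(10, c(4, 8, 8)); bV[2, 4, 4] <- 13
  b <- sctDose:::withVoxels(a, bV)
  gab <- gammaAnalysis(a, b, GammaCriteria(0.02, 2, 0.2))
  gba <- gammaAnalysis(b, a, GammaCriteria(0.02, 2, 0.2))
  expect_false(isTRUE(all.equal(gab@passRate, gba@passRate)))

  low <- sctDose:::withVoxels(a, array(0.1, c(4, 8, 8)))
  expect_error(gammaAnalysis(sctDose:::withVoxels(a, array(1, c(4, 8, 8))) ,
                             sctDose:::withVoxels(a, array(1, c(4, 8, 8))),
                             GammaCriteria(0.02, 2, 1.5)), "threshold")
})

test_that("gamma map equals the exhaustive-search oracle on small grids", {
  set.seed(11)
  d <- c(8L, 8L, 8L)
  refV <- array(30 + 10 * runif(prod(d)), d)
  evV <- refV * (1 + array(rnorm(prod(d), 0, 0.02), d))
  sp <- c(2.5, 1, 1)
  ref <- ImageGrid(refV, spacing = sp, modality = "DOSE", units = "Gy")
  ev <- ImageGrid(evV, spacing = sp, modality = "DOSE", units = "Gy")
  crit <- GammaCriteria(0.02, 1, 0.2)   # 1 mm DTA keeps the oracle exhaustive
  got <- voxels(gammaAnalysis(ref, ev, crit)@gammaMap)
  thr <- 0.2 * max(refV)
  want <- bruteGamma(refV, evV, sp, 0.02, 1, thr, 3, 0.5)
  expect_equal(got, want, tolerance = 1e-6)
})
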